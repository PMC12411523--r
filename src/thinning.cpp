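#include <Rcpp.h>
using namespace Rcpp;

// 2-D parallel medial-axis thinning (Zhang & Suen style, two
// subiterations per pass). Reduces a binary mask to a one-pixel-wide,
// 8-connected skeleton; pixels outside the matrix count as background.
// [[Rcpp::export]]
LogicalMatrix thin_mask_cpp(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  std::vector<unsigned char> img((size_t)nr * nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      img[(size_t)j * nr + i] = mask(i, j) ? 1 : 0;

  auto at = [&](int i, int j) -> unsigned char {
    if (i < 0 || i >= nr || j < 0 || j >= nc) return 0;
    return img[(size_t)j * nr + i];
  };

  std::vector<size_t> kill;
  bool changed = true;
  while (changed) {
    changed = false;
    for (int sub = 0; sub < 2; ++sub) {
      kill.clear();
      for (int j = 0; j < nc; ++j) {
        for (int i = 0; i < nr; ++i) {
          if (!img[(size_t)j * nr + i]) continue;
          // neighbors clockwise from north (p2..p9)
          unsigned char p2 = at(i - 1, j),     p3 = at(i - 1, j + 1);
          unsigned char p4 = at(i, j + 1),     p5 = at(i + 1, j + 1);
          unsigned char p6 = at(i + 1, j),     p7 = at(i + 1, j - 1);
          unsigned char p8 = at(i, j - 1),     p9 = at(i - 1, j - 1);
          int B = p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9;
          if (B < 2 || B > 6) continue;
          int A = (p2 == 0 && p3 == 1) + (p3 == 0 && p4 == 1) +
                  (p4 == 0 && p5 == 1) + (p5 == 0 && p6 == 1) +
                  (p6 == 0 && p7 == 1) + (p7 == 0 && p8 == 1) +
                  (p8 == 0 && p9 == 1) + (p9 == 0 && p2 == 1);
          if (A != 1) continue;
          if (sub == 0) {
            if (p2 * p4 * p6 != 0 || p4 * p6 * p8 != 0) continue;
          } else {
            if (p2 * p4 * p8 != 0 || p2 * p6 * p8 != 0) continue;
          }
          kill.push_back((size_t)j * nr + i);
        }
      }
      if (!kill.empty()) {
        changed = true;
        for (size_t k : kill) img[k] = 0;
      }
    }
  }

  LogicalMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      out(i, j) = img[(size_t)j * nr + i] != 0;
  return out;
}
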
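test_that("label layer at angle 0 is the column index", {
  ll <- gradient_label_layer(c(5, 5), 0)
  expect_equal(ll$n_labels, 5L)
  expect_equal(ll$labels, matrix(rep(0:4, each = 5), 5, 5))
})

test_that("label layer covers every pixel exactly once at any angle", {
  for (a in c(-60, -45, -20, -7, 0, 3, 15, 45, 80)) {
    ll <- gradient_label_layer(c(24, 40), a)
    counts <- tabulate(as.vector(ll$labels) + 1L, nbins = ll$n_labels)
    expect_equal(sum(counts), 24 * 40)
    expect_true(all(counts > 0))
  }
  expect_error(gradient_label_layer(c(1, 5), 0), "degenerate")
  expect_error(gradient_label_layer(c(5, 5), 90), "< 90")
})

test_that("45-degree labels match the projection-and-round oracle within one", {
  ll <- gradient_label_layer(c(8, 8), 45)
  r <- matrix(0:7, 8, 8)
  cc <- matrix(rep(0:7, each = 8), 8, 8)
  oracle <- round(cc - r * tan(45 * pi / 180))
  oracle <- oracle - min(oracle)
  expect_true(all(abs(ll$labels - oracle) <= 1))
  # every pixel has exactly one label
  expect_true(all(tabulate(ll$labels + 1L, ll$n_labels) > 0))
})

test_that("transposed shape at the mirrored angle gives the transposed layer", {
  ll <- gradient_label_layer(c(5, 9), 0)
  llt <- gradient_label_layer(c(9, 5), 0)
  expect_equal(dim(llt$labels), rev(dim(ll$labels)))
  # angle 0 labels are columns in both, so the construction is symmetric
  expect_equal(llt$n_labels, 5L)
})

test_that("extract_profile reproduces masked per-column means", {
  nr <- 10; nc <- 12
  intens <- matrix(rep(c(0, 1), length.out = nc), nr, nc, byrow = TRUE)
  img <- masked_image(intens, matrix(TRUE, nr, nc), 100)
  g <- partition_grids(img, nr)[[1]]
  ll <- gradient_label_layer(c(nr, nc), 0)
  p <- extract_profile(g, 1, ll)
  expect_equal(p$values, rep(c(0, 1), length.out = nc))
  expect_equal(p$step_um, 0.01)

  # constant grid -> constant profile
  img2 <- masked_image(matrix(3, nr, nc), matrix(TRUE, nr, nc), 100)
  g2 <- partition_grids(img2, nr)[[1]]
  expect_equal(extract_profile(g2, 1, ll)$values, rep(3, nc))

  # random image + random mask against the loop oracle at angle 0
  set.seed(11)
  ri <- matrix(runif(nr * nc), nr)
  rm <- matrix(runif(nr * nc) > 0.3, nr)
  rm[, 3] <- TRUE  # guarantee 2+ non-empty labels
  rm[, 9] <- TRUE
  img3 <- masked_image(ri, rm, 100)
  g3 <- partition_grids(img3, nr)[[1]]
  p3 <- extract_profile(g3, 1, ll)
  oracle <- bf_column_profile(ri, rm)
  # interior empties are interpolated by extract_profile; oracle keeps NA
  expect_equal(p3$values[!is.na(oracle)], oracle[!is.na(oracle)])
})

test_that("masked-out columns are trimmed at ends and interpolated inside", {
  nr <- 6; nc <- 8
  intens <- matrix(rep(c(0, 1), length.out = nc), nr, nc, byrow = TRUE)
  mask <- matrix(FALSE, nr, nc)
  mask[, c(1, 3, 5, 7)] <- TRUE  # even intensities 0 live on odd columns
  img <- masked_image(intens, mask, 100)
  g <- partition_grids(img, nr)[[1]]
  p <- extract_profile(g, 1, gradient_label_layer(c(nr, nc), 0))
  # ends trimmed to columns 1..7, odd columns all 0, gaps interpolated to 0
  expect_equal(p$values, rep(0, 7))

  mask2 <- matrix(FALSE, nr, nc)
  mask2[, 4] <- TRUE
  img2 <- masked_image(intens, mask2, 100)
  g2 <- partition_grids(img2, nr)[[1]]
  expect_error(extract_profile(g2, 1, gradient_label_layer(c(nr, nc), 0)),
               class = "mpscorr_profile_too_short")
})

test_that("sweep_angles enumerates angles and pairs channels on one layer", {
  img <- masked_image(list(matrix(runif(400), 20), matrix(runif(400), 20)),
                      matrix(TRUE, 20, 20), 100)
  g <- partition_grids(img, 20)[[1]]
  sw <- sweep_angles(g, c(-20, 20), 1)
  expect_length(sw, 41)
  sw0 <- sweep_angles(g, c(0, 0), 1)
  expect_length(sw0, 1)
  # per-angle profile lengths match between channels (shared label layer)
  for (e in sw[c(1, 21, 41)]) {
    expect_equal(e$profiles[[1]]$n_points, e$profiles[[2]]$n_points)
  }
  expect_error(sweep_angles(g, c(10, 0), 1), "invalid")
})

test_that("sweep fast path agrees with the public layer/extract route", {
  set.seed(3)
  ri <- matrix(runif(30 * 50), 30)
  rm <- matrix(runif(30 * 50) > 0.4, 30)
  img <- masked_image(ri, rm, 100)
  g <- partition_grids(img, 30)[[1]]
  sw <- sweep_angles(g, c(-10, 10), 5)
  for (e in sw) {
    ll <- gradient_label_layer(c(30, 50), e$angle_deg)
    ref <- extract_profile(g, 1, ll)
    expect_equal(e$profiles[[1]]$values, ref$values)
  }
})

test_that("best-angle amplitude is stable under pattern rotation", {
  amps <- vapply(c(-15, 0, 15), function(th) {
    img <- striped_image(100, 500, period_px = 20, angle_deg = th)
    res <- analyze_image(img, analysis_config())
    res$per_grid$amp_ch1[1]
  }, numeric(1))
  expect_lt(max(abs(amps - amps[2]) / amps[2]), 0.05)
})
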
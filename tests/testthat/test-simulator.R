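test_that("synthetic axon mask has the requested geometry and is reproducible", {
  straight <- synthetic_axon_mask(10, 0.6, curvature = 0, pixels_per_um = 100,
                                  seed = 1)
  expect_equal(sum(straight),
               round(10 * 0.6 * 100^2), tolerance = 0.02)
  # straight band: every column has the same vertical extent
  expect_equal(length(unique(colSums(straight))), 1L)

  m1 <- synthetic_axon_mask(seed = 5)
  m2 <- synthetic_axon_mask(seed = 5)
  expect_identical(m1, m2)
  expect_false(identical(m1, synthetic_axon_mask(seed = 6)))

  narrow <- synthetic_axon_mask(6, 0.5, curvature = 0, pixels_per_um = 100,
                                seed = 1)
  expect_equal(unique(colSums(narrow)), 51, tolerance = 2 / 51)
})

test_that("backbone of a straight band is its midline at nearly full length", {
  band <- matrix(TRUE, 50, 1000)
  bb <- backbone_from_mask(band)
  len <- sum(sqrt(diff(bb[, 1])^2 + diff(bb[, 2])^2))
  expect_gt(len, 0.98 * 1000)
  mid <- bb[bb[, 2] > 100 & bb[, 2] < 900, 1]
  expect_true(all(abs(mid - 25.5) <= 1))
})

test_that("backbone follows the longest path and fixes thin lines", {
  plus <- matrix(FALSE, 61, 101)
  plus[28:34, ] <- TRUE       # long horizontal bar
  plus[, 48:54] <- TRUE       # short vertical bar
  bb <- backbone_from_mask(plus)
  expect_gt(diff(range(bb[, 2])), 90)   # spans the long bar
  expect_lt(diff(range(bb[, 1])), 20)   # not the short bar

  line <- matrix(FALSE, 5, 40); line[3, ] <- TRUE
  bl <- backbone_from_mask(line)
  expect_equal(nrow(bl), 40)
  expect_true(all(bl[, 1] == 3))

  two <- matrix(FALSE, 20, 20)
  two[2:8, 2:18] <- TRUE
  two[14:19, 2:18] <- TRUE
  expect_error(backbone_from_mask(two), class = "mpscorr_disconnected_mask")
})

test_that("zone map stripes sit at the ring spacing and partition the mask", {
  band <- matrix(TRUE, 50, 1000)
  bb <- backbone_from_mask(band)
  zm <- build_zone_map(band, bb, spacing_nm = 200, line_halfwidth_px = 2,
                       pixels_per_um = 100)
  # partition: on + off = mask, disjoint by construction of the coding
  expect_equal(sum(zm$zones != 0), sum(band))
  expect_true(all(zm$zones[!band] == 0))
  # vertical stripes every 20 px: on-line columns in the interior
  on_cols <- sort(unique(which(zm$zones == 1, arr.ind = TRUE)[, 2]))
  on_cols <- on_cols[on_cols > 50 & on_cols < 950]
  gaps <- diff(on_cols)
  expect_true(all(gaps %in% c(1L, 16L)))  # 5-px stripes, 15-px gaps
  # halfwidth 2 -> stripes 5 px wide -> on fraction ~ 5/20 in the interior
  interior <- zm$zones[, 100:900]
  expect_equal(sum(interior == 1) / sum(interior != 0), 0.25,
               tolerance = 0.04)
})

test_that("alternating map is the base map advanced by half a period", {
  band <- matrix(TRUE, 40, 600)
  bb <- backbone_from_mask(band)
  base <- build_zone_map(band, bb, pixels_per_um = 100)
  alt <- alternating_zone_map(band, bb, pixels_per_um = 100)
  bc <- unique(which(base$zones == 1, arr.ind = TRUE)[, 2])
  ac <- unique(which(alt$zones == 1, arr.ind = TRUE)[, 2])
  bc <- bc[bc > 60 & bc < 540]; ac <- ac[ac > 60 & ac < 540]
  # shifted stripe columns are the base stripe columns + 10 px
  expect_true(all((bc + 10) %in% c(ac, ac + 20)))
  # minimal overlap when halfwidth < quarter spacing
  both <- sum(base$zones == 1 & alt$zones == 1)
  expect_lt(both / sum(base$zones == 1), 0.05)

  # a full-period shift reproduces the base map away from the ends
  same <- build_zone_map(band, bb, pixels_per_um = 100, shift_nm = 200)
  mid <- 100:500
  expect_equal(base$zones[, mid], same$zones[, mid])
})

test_that("spawn counts follow the density and split equations", {
  fake_map <- function(a_on, a_off) {
    z <- matrix(0L, 1, a_on + a_off)
    z[1, seq_len(a_on)] <- 1L
    z[1, a_on + seq_len(a_off)] <- 2L
    structure(list(zones = z), class = "zone_map")
  }
  cfg <- simulation_config(point_density = 100, plp = 100)
  sc <- spawn_counts(fake_map(5000, 15000), cfg)
  expect_equal(sc$P_total, 200)       # 100 * 20000 / 100^2
  expect_equal(sc$P_on, 200)          # F = 100: all on-line
  expect_equal(sc$P_off, 0)

  cfg50 <- simulation_config(point_density = 100, plp = 50)
  sc50 <- spawn_counts(fake_map(5000, 15000), cfg50)
  expect_equal(sc50$P_on, 50)         # F = 50 reduces to area proportions
  expect_equal(sc50$P_off, 150)
  expect_equal(sc50$P_on + sc50$P_off, sc50$P_total)

  # conservation at awkward fractions
  for (f in c(55, 63, 72, 91)) {
    cfgf <- simulation_config(plp = f)
    scf <- spawn_counts(fake_map(3777, 11111), cfgf)
    expect_equal(scf$P_on + scf$P_off, scf$P_total)
  }
})

test_that("kernels are unit-peak Gaussians with ordered widths", {
  red <- make_kernel("RED", 100)
  orange <- make_kernel("ORANGE", 100)
  expect_equal(max(red), 1)
  expect_equal(red[(nrow(red) + 1) / 2, (ncol(red) + 1) / 2], 1)
  expect_lt(nrow(red), nrow(orange))
  # discrete mass approximates the Gaussian integral 2*pi*sigma^2
  sigma <- (60 / 1000 * 100) / (2 * sqrt(2 * log(2)))
  expect_equal(sum(red), 2 * pi * sigma^2, tolerance = 0.02)
  expect_error(make_kernel("RED", 20), "at least 2 px")
})

test_that("rendering stamps kernels exactly and controls the noise floor", {
  z <- matrix(0L, 60, 60)
  z[30, 30] <- 1L
  zm <- structure(list(zones = z), class = "zone_map")
  counts <- structure(list(P_total = 1L, P_on = 1L, P_off = 0L,
                           A_on = 1L, A_off = 0L), class = "spawn_counts")
  cfg <- simulation_config()
  img <- render(zm, counts, cfg, seed = 1)
  kern <- make_kernel("RED", 100)
  rad <- (nrow(kern) - 1) / 2
  expect_equal(img[(30 - rad):(30 + rad), (30 - rad):(30 + rad)], kern,
               ignore_attr = TRUE)
  # no noise: pixels beyond the kernel support are exactly zero
  expect_true(all(img[1:10, 1:10] == 0))

  cfgn <- simulation_config(noise_pct = 10)
  imgn <- render(zm, counts, cfgn, seed = 2)
  bg <- imgn[1:50, 1:50]  # far from the single point
  expect_equal(sd(bg), 0.10, tolerance = 0.15)

  over <- structure(list(P_total = 5L, P_on = 5L, P_off = 0L,
                         A_on = 1L, A_off = 0L), class = "spawn_counts")
  expect_error(render(zm, over, cfg, seed = 1),
               class = "mpscorr_overfull_zone")
})

test_that("realized point draws match the spawn counts and the seed", {
  mask <- synthetic_axon_mask(8, 0.6, seed = 3)
  bb <- backbone_from_mask(mask)
  zm <- build_zone_map(mask, bb)
  cfg <- simulation_config(plp = 80)
  counts <- spawn_counts(zm, cfg)
  img <- render(zm, counts, cfg, seed = 9)
  expect_length(attr(img, "points_on"), counts$P_on)
  expect_length(attr(img, "points_off"), counts$P_off)
  expect_true(all(zm$zones[attr(img, "points_on")] == 1L))
  expect_true(all(zm$zones[attr(img, "points_off")] == 2L))
  img2 <- render(zm, counts, cfg, seed = 9)
  expect_identical(img, img2)
})

test_that("uniform spawning at plp 50 is zone-agnostic", {
  mask <- synthetic_axon_mask(10, 0.6, seed = 4)
  bb <- backbone_from_mask(mask)
  zm <- build_zone_map(mask, bb)
  cfg <- simulation_config(plp = 50, point_density = 300)
  counts <- spawn_counts(zm, cfg)
  a_on <- counts$A_on; a_off <- counts$A_off
  # expected on-zone share equals the area share
  expect_equal(counts$P_on / counts$P_total, a_on / (a_on + a_off),
               tolerance = 0.01)
  # spatial uniformity: chi-square of point counts over four column
  # quarters of the mask, pooled over repeated draws
  nr <- nrow(zm$zones)
  ncz <- ncol(zm$zones)
  quarter <- function(idx) {
    col <- (idx - 1) %/% nr + 1
    pmin(4L, (col - 1L) %/% (ncz %/% 4L) + 1L)
  }
  area <- tabulate(quarter(which(zm$zones != 0L)), 4)
  obs <- numeric(4)
  for (s in 1:25) {
    img <- render(zm, counts, cfg, seed = 100 + s)
    pts <- c(attr(img, "points_on"), attr(img, "points_off"))
    obs <- obs + tabulate(quarter(pts), 4)
  }
  expected <- sum(obs) * area / sum(area)
  chi2 <- sum((obs - expected)^2 / expected)
  expect_gt(stats::pchisq(chi2, df = 3, lower.tail = FALSE), 0.01)
})

test_that("two-channel pairs respect the pattern geometry and the seed", {
  mask <- synthetic_axon_mask(8, 0.6, seed = 12)
  bb <- backbone_from_mask(mask)
  base <- build_zone_map(mask, bb)
  alt <- alternating_zone_map(mask, bb)
  maps <- list(base = base, alt = alt)
  cfg <- simulation_config()

  ov <- simulate_pair(cfg, "overlapping", 100, 100, zone_maps = maps, seed = 1)
  expect_length(ov$image$channels, 2L)
  expect_equal(ov$truth$pattern, "overlapping")
  # both channels' points only in the base on-line zones
  for (cnt in ov$counts) expect_equal(cnt$P_off, 0L)

  al <- simulate_pair(cfg, "alternating", 100, 100, zone_maps = maps, seed = 1)
  expect_equal(al$truth$pattern, "alternating")

  ov2 <- simulate_pair(cfg, "overlapping", 100, 100, zone_maps = maps, seed = 1)
  expect_identical(ov$image$channels, ov2$image$channels)
})

test_that("pipeline recovers the generator spacing and ranks plp levels", {
  maps <- study_maps_pool(4)
  hi <- run_single_level(maps, 100, seed = 500)
  lo <- run_single_level(maps, 50, seed = 600)
  med <- median(hi$freq_ch1_nm, na.rm = TRUE)
  expect_lte(abs(med - 200), 10)  # one lag at 100 px/um
  expect_gt(mean(hi$amp_ch1), mean(lo$amp_ch1))
})
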
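test_that("local_counts matches single-point geometry and the brute-force oracle", {
  # empty set: all-zero matrix
  empty <- spermcasa:::particle_set_from_positions(numeric(0), numeric(0), 64, 64)
  expect_true(all(local_counts(empty, 10) == 0))

  # one centroid at (50,50), R=10: inside at the centre and at (58,50),
  # outside at (61,50)
  one <- spermcasa:::particle_set_from_positions(50, 50, 100, 100)
  lc <- local_counts(one, 10)
  expect_equal(lc[50 + 1, 50 + 1], 1)
  expect_equal(lc[50 + 1, 58 + 1], 1)
  expect_equal(lc[50 + 1, 61 + 1], 0)

  # random instances vs the per-pixel brute-force oracle
  set.seed(5)
  for (rep in 1:6) {
    w <- sample(24:64, 1); h <- sample(24:64, 1)
    n <- sample(0:60, 1); R <- runif(1, 2, 12)
    ps <- spermcasa:::particle_set_from_positions(
      runif(n, 0, w - 1), runif(n, 0, h - 1), w, h
    )
    expect_equal(local_counts(ps, R), brute_local_counts(ps, R))
  }
})

test_that("raw counts are conserved: total equals per-particle in-range pixels", {
  set.seed(8)
  ps <- spermcasa:::particle_set_from_positions(runif(30, 0, 47), runif(30, 0, 39),
                                                48, 40)
  R <- 6.5
  raw <- local_counts(ps, R)
  per_particle <- vapply(seq_len(nrow(ps)), function(i) {
    g <- expand.grid(x = 0:47, y = 0:39)
    sum((g$x - ps$x_px[i])^2 + (g$y - ps$y_px[i])^2 <= R^2)
  }, numeric(1))
  expect_equal(sum(raw), sum(per_particle))
})

test_that("boundary fraction is 1 in the interior, ~1/4 at corners, ~1/2 at edges", {
  fracs <- boundary_fraction(100, 80, 10)
  expect_equal(fracs[40 + 1, 50 + 1], 1) # interior: whole disk inside
  # rasterisation keeps the whole axis row/column of the disc in-bounds at
  # a corner or edge, so the fraction exceeds the continuous value by at
  # most (2R + 2) / (pi R^2)
  ras_tol <- (2 * 10 + 2) / (pi * 10^2)
  expect_equal(fracs[0 + 1, 0 + 1], brute_fraction(0, 0, 100, 80, 10))
  expect_lt(abs(fracs[0 + 1, 0 + 1] - 0.25), ras_tol) # quarter disk
  expect_equal(fracs[40 + 1, 0 + 1], brute_fraction(0, 40, 100, 80, 10))
  expect_lt(abs(fracs[40 + 1, 0 + 1] - 0.5), ras_tol)  # half disk
  # whole map vs the oracle on a small image
  small <- boundary_fraction(12, 9, 4)
  for (x in 0:11) for (y in 0:8) {
    expect_equal(small[y + 1, x + 1], brute_fraction(x, y, 12, 9, 4))
  }
  expect_true(all(small > 0 & small <= 1))
})

test_that("boundary correction divides raw counts by the in-bounds fraction", {
  raw <- matrix(c(4, 2, 0, 6), 2, 2)
  fr <- matrix(c(1, 0.25, 0.5, 1), 2, 2)
  expect_equal(correct_counts(raw, fr), matrix(c(4, 8, 0, 6), 2, 2))
  expect_true(all(correct_counts(raw, fr) >= raw))
  expect_error(correct_counts(raw, matrix(0, 2, 2)), "positive")
  expect_equal(correct_counts(matrix(0, 3, 3), matrix(0.5, 3, 3)),
               matrix(0, 3, 3))
})

test_that("display scaling hits 0 and 255 and rounds half-up", {
  m <- matrix(c(0, 5, 10, 2), 2, 2)
  s <- scale_to_display(m)
  expect_equal(min(s), 0)
  expect_equal(max(s), 255)
  expect_equal(s[2, 1], 128L) # 5 -> 127.5 -> half-up 128
  # constant map: degenerate scaling maps to all zeros
  expect_true(all(scale_to_display(matrix(3.7, 4, 4)) == 0))
  # any non-constant map attains both ends
  set.seed(2)
  for (rep in 1:5) {
    r <- matrix(runif(30, 0, 50), 5, 6)
    sc <- scale_to_display(r)
    expect_equal(range(sc), c(0L, 255L))
  }
})

test_that("the Jet LUT has 256 entries and renders a ramp row-for-row", {
  lut <- jet_lut()
  expect_equal(dim(lut), c(256L, 3L))
  expect_true(all(lut >= 0 & lut <= 255))
  # index 0 cold (blue-dominant), 255 warm (red-dominant)
  expect_gt(lut[1, "b"], lut[1, "r"])
  expect_gt(lut[256, "r"], lut[256, "b"])
  ramp <- matrix(0:255, nrow = 1)
  img <- apply_jet_lut(ramp)
  expect_equal(img[1, , 1], unname(lut[, "r"]))
  expect_equal(img[1, , 2], unname(lut[, "g"]))
  expect_equal(img[1, , 3], unname(lut[, "b"]))
  expect_error(apply_jet_lut(matrix(300, 1, 1)), "\\[0, 255\\]")
})

test_that("video maps interpolate linearly between sampled keyframes", {
  set.seed(3)
  mk <- function(seed) {
    set.seed(seed)
    spermcasa:::particle_set_from_positions(runif(12, 0, 39), runif(12, 0, 39),
                                            40, 40, frame_index = 0L)
  }
  frames <- lapply(1:6, mk)
  params <- accumulation_params(radius_px = 6, sampling_f = 5)
  maps <- heatmap_video(frames, params)
  A <- accumulation_map(frames[[1]], params)
  B <- accumulation_map(frames[[6]], params)
  # frame index 2 (third frame) = 0.6 A + 0.4 B per pixel
  expect_equal(maps[[3]]$corrected, 0.6 * A$corrected + 0.4 * B$corrected)
  # keyframes equal the still-image path
  expect_equal(maps[[1]]$corrected, A$corrected)
  expect_equal(maps[[6]]$corrected, B$corrected)
  # f = 1, W = 1: every frame is exactly the still-image computation
  maps1 <- heatmap_video(frames, accumulation_params(radius_px = 6))
  for (i in 1:6) {
    expect_equal(maps1[[i]]$corrected,
                 accumulation_map(frames[[i]],
                                  accumulation_params(radius_px = 6))$corrected)
  }
})

test_that("W x W windows are painted with their centre value", {
  set.seed(4)
  ps <- spermcasa:::particle_set_from_positions(runif(15, 0, 29), runif(15, 0, 29),
                                                30, 30)
  full <- accumulation_map(ps, accumulation_params(radius_px = 5))
  win <- accumulation_map(ps, accumulation_params(radius_px = 5, window_w = 3))
  for (bx in 0:9) for (by in 0:9) {
    block <- win$corrected[by * 3 + 1:3, bx * 3 + 1:3]
    expect_equal(unique(as.vector(block)),
                 full$corrected[by * 3 + 2, bx * 3 + 2])
  }
})

test_that("ROI counts are nested, boundary-inclusive, and per-frame relative", {
  # all particles within r: 100% in every circle
  ps <- spermcasa:::particle_set_from_positions(c(49, 51, 50), c(50, 50, 51),
                                                100, 100)
  s <- roi_timeseries(ps, c(50, 50), 5)
  expect_equal(c(s$n_r, s$n_2r, s$n_3r), c(3, 3, 3))
  expect_equal(s$pct_r, 100)

  # a particle at distance exactly r is counted inside (<= rule)
  edge <- spermcasa:::particle_set_from_positions(55, 50, 100, 100)
  expect_equal(roi_timeseries(edge, c(50, 50), 5)$n_r, 1)

  # zero detected particles: relative values are missing, not 0
  none <- spermcasa:::particle_set_from_positions(numeric(0), numeric(0), 100, 100)
  s0 <- roi_timeseries(none, c(50, 50), 5)
  expect_equal(s0$N, 0)
  expect_true(is.na(s0$pct_r))

  # nested monotonicity across random frames
  set.seed(6)
  frames <- lapply(1:8, function(f) {
    n <- sample(5:60, 1)
    spermcasa:::particle_set_from_positions(runif(n, 0, 99), runif(n, 0, 99),
                                            100, 100, frame_index = f - 1L)
  })
  ser <- roi_timeseries(frames, c(40, 60), 12)
  expect_true(all(ser$n_r <= ser$n_2r & ser$n_2r <= ser$n_3r & ser$n_3r <= ser$N))
  expect_true(all(ser$pct_r >= 0 & ser$pct_3r <= 100, na.rm = TRUE))

  # binomial sampling oracle: uniform placement, expected share = area ratio
  set.seed(10)
  n <- 10000
  big <- spermcasa:::particle_set_from_positions(runif(n, 0, 199), runif(n, 0, 199),
                                                 200, 200)
  sb <- roi_timeseries(big, c(100, 100), 30)
  p <- pi * 30^2 / (200 * 200)
  se <- sqrt(p * (1 - p) / n)
  expect_lt(abs(sb$n_r / n - p), 3 * se)
})

test_that("ROI centre must be inside the image and radius positive", {
  ps <- spermcasa:::particle_set_from_positions(5, 5, 20, 20)
  expect_error(roi_timeseries(ps, c(25, 5), 3), "inside")
  expect_error(roi_timeseries(ps, c(5, 5), 0), "> 0")
})
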
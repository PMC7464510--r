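test_that("grayscale conversion is the Rec. 601 weighted sum", {
  rgb <- array(0, dim = c(2, 2, 3))
  rgb[, , 1] <- 255 # pure red field
  g <- to_grayscale(field_frame(rgb, scale = 0.5))
  expect_equal(unique(as.vector(g$pixels)), 0.299 * 255)
  expect_equal(g$scale, 0.5)

  # channel-equal pixels keep their value; black stays black
  v <- matrix(c(0, 17, 130, 255), 2, 2)
  eq <- array(c(v, v, v), dim = c(2, 2, 3))
  expect_equal(to_grayscale(field_frame(eq))$pixels, v)

  # per-pixel weighted-sum oracle on random RGB
  set.seed(42)
  px <- array(sample(0:255, 24 * 3, replace = TRUE), dim = c(4, 6, 3))
  got <- to_grayscale(field_frame(px))$pixels
  want <- matrix(0, 4, 6)
  for (i in 1:4) for (j in 1:6) {
    want[i, j] <- sum(c(0.299, 0.587, 0.114) * px[i, j, ])
  }
  expect_equal(got, want)

  # intensity input passes through unchanged
  f <- field_frame(v)
  expect_identical(to_grayscale(f), f)
})

test_that("histogram equalisation matches a brute-force CDF oracle", {
  # constant image is returned unchanged
  const <- fr(matrix(77, 5, 5))
  expect_equal(equalize_histogram(const)$pixels, const$pixels)

  # a two-level 0/255 image is already at maximal contrast
  two <- fr(matrix(c(rep(0, 8), rep(255, 8)), 4, 4))
  expect_equal(sort(unique(as.vector(equalize_histogram(two)$pixels))), c(0, 255))

  # 4-level ramp vs an independently computed CDF mapping
  ramp <- fr(matrix(rep(c(10, 20, 30, 40), times = c(8, 4, 2, 2)), 4, 4))
  out <- equalize_histogram(ramp)$pixels
  counts <- table(factor(ramp$pixels, levels = 0:255))
  cdf <- cumsum(as.integer(counts))
  cdf_min <- min(cdf[cdf > 0])
  lut <- round(255 * (cdf - cdf_min) / (16 - cdf_min))
  for (lvl in c(10, 20, 30, 40)) {
    expect_equal(unique(out[ramp$pixels == lvl]), unname(lut[lvl + 1]))
  }
  expect_true(all(out >= 0 & out <= 255))
})

test_that("Otsu level maximises between-class variance (exhaustive oracle)", {
  # well-separated bimodal image: level falls strictly between the modes
  bim <- fr(matrix(c(rep(20, 40), rep(230, 24)), 8, 8))
  t_bim <- otsu_level(bim)
  expect_gt(t_bim, 20)
  expect_lt(t_bim, 230)
  mask <- binarize(bim, detection_params())
  expect_identical(mask, bim$pixels >= t_bim)
  expect_identical(sum(mask), 24L) # exactly the bright-mode pixels

  # synthetic 3-blob histogram vs independent scan of all 256 levels
  set.seed(7)
  v <- round(c(rnorm(300, 40, 8), rnorm(200, 120, 10), rnorm(150, 210, 6)))
  v <- pmin(pmax(v, 0), 255)
  img <- fr(matrix(v, 25, 26))
  hist_counts <- tabulate(v + 1L, nbins = 256)
  best <- -Inf; best_t <- NA
  for (t in 1:255) { # classes {value < t} and {value >= t}
    n0 <- sum(hist_counts[1:t]); n1 <- sum(hist_counts) - n0
    if (n0 == 0 || n1 == 0) next
    mu0 <- sum((0:(t - 1)) * hist_counts[1:t]) / n0
    mu1 <- sum((t:255) * hist_counts[(t + 1):256]) / n1
    bcv <- (n0 / sum(hist_counts)) * (n1 / sum(hist_counts)) * (mu0 - mu1)^2
    if (bcv > best) { best <- bcv; best_t <- t }
  }
  expect_equal(otsu_level(img), best_t)

  # constant image: empty mask plus a warning
  expect_warning(m <- binarize(fr(matrix(100, 4, 4))), "constant")
  expect_false(any(m))
})

test_that("dark-cell polarity inverts the foreground", {
  img <- fr(matrix(c(rep(230, 40), rep(20, 24)), 8, 8))
  p_dark <- detection_params(polarity = "dark")
  mask <- binarize(img, p_dark)
  expect_identical(mask, img$pixels < otsu_level(img))
  expect_identical(sum(mask), 24L) # the dark-mode pixels
})

test_that("particle detection recovers planted disks with sub-pixel centroids", {
  centres <- cbind(c(10, 30, 50, 20, 45), c(12, 8, 40, 45, 20))
  mask <- disk_mask(64, 64, centres, r = 3.2)
  ps <- detect_particles(mask, scale = 1,
                         detection_params(min_area_um2 = 5, max_area_um2 = 100))
  expect_equal(nrow(ps), 5)
  # centroids within 0.5 px of planted centres (match by nearest)
  for (i in 1:5) {
    d <- sqrt((ps$x_px - centres[i, 1])^2 + (ps$y_px - centres[i, 2])^2)
    expect_lt(min(d), 0.5)
  }
  # areas obey area_um2 = pixel_count * scale^2 exactly
  expect_equal(ps$area_um2, ps$pixel_count * 1^2)
  ps2 <- detect_particles(mask, scale = 0.5,
                          detection_params(min_area_um2 = 5, max_area_um2 = 100))
  expect_equal(ps2$area_um2, ps2$pixel_count * 0.25)

  # empty mask: zero particles, not an error
  expect_equal(nrow(detect_particles(matrix(FALSE, 8, 8))), 0)
})

test_that("size filter drops components outside the um^2 bounds", {
  mask <- disk_mask(80, 80, cbind(c(15, 60), c(15, 55)), r = 3)
  mask[30:70, 5:45][disk_mask(41, 41, cbind(20, 20), r = 15)] <- TRUE # debris
  params <- detection_params(min_area_um2 = 5, max_area_um2 = 60)
  ps <- detect_particles(mask, scale = 1, params)
  expect_equal(nrow(ps), 2) # the oversized blob is excluded
  expect_true(all(ps$area_um2 >= 5 & ps$area_um2 <= 60))
})

test_that("connectivity setting controls diagonal merging", {
  m <- matrix(FALSE, 6, 6)
  m[2, 2] <- TRUE; m[3, 3] <- TRUE # touch only diagonally
  p <- function(conn) detection_params(min_area_um2 = 0.5, max_area_um2 = 100,
                                       connectivity = conn)
  expect_equal(nrow(detect_particles(m, 1, p(8))), 1)
  expect_equal(nrow(detect_particles(m, 1, p(4))), 2)
})

test_that("component labelling agrees with an independent implementation", {
  skip_if_not_installed("EBImage")
  set.seed(11)
  for (rep in 1:5) {
    mask <- matrix(runif(60 * 60) < 0.25, 60, 60)
    ours <- spermcasa:::label_components(mask, 4L)
    ref <- EBImage::imageData(EBImage::bwlabel(t(mask) * 1)) # EBImage is x,y
    ref <- t(ref)
    expect_equal(max(ours), max(ref))
    # identical partitions: label pairs must be in bijection
    tab <- table(ours[mask], ref[mask])
    expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))
  }
})

test_that("the detection chain is deterministic", {
  gen <- make_field(field_spec(n_cells = 15, noise_sd = 4, seed = 9))
  a <- find_cells(gen$frame)
  b <- find_cells(gen$frame)
  expect_identical(a, b)
})
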
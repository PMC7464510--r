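test_that("field generation is seed-deterministic with in-bounds, separated cells", {
  spec <- field_spec(n_cells = 25, noise_sd = 3, seed = 17)
  a <- make_field(spec)
  b <- make_field(spec)
  expect_identical(a$frame$pixels, b$frame$pixels)
  expect_identical(a$truth, b$truth)
  c <- make_field(field_spec(n_cells = 25, noise_sd = 3, seed = 18))
  expect_false(identical(a$frame$pixels, c$frame$pixels))

  # truth positions are in-bounds and pairwise separated
  expect_true(all(a$truth$x_px >= 0 & a$truth$x_px < 512))
  d <- as.matrix(stats::dist(a$truth[, c("x_px", "y_px")]))
  diag(d) <- Inf
  expect_gt(min(d), 2 * (9 / 0.5) / 2) # centres farther apart than a head length

  # zero cells: pure background
  bg <- make_field(field_spec(n_cells = 0, background = 20, seed = 1))
  expect_true(all(bg$frame$pixels == 20))
  expect_equal(nrow(bg$truth), 0)
})

test_that("overcrowded specifications fail with guidance", {
  expect_error(make_field(field_spec(width = 64, height = 64, n_cells = 200,
                                     seed = 1)),
               "density")
})

test_that("detection on noiseless and noisy fields recovers the planted count", {
  gen <- make_field(field_spec(n_cells = 40, seed = 23))
  ps <- find_cells(gen$frame)
  expect_equal(nrow(ps), 40)
  # centroids close to planted positions
  for (i in seq_len(40)) {
    d <- sqrt((ps$x_px - gen$truth$x_px[i])^2 + (ps$y_px - gen$truth$y_px[i])^2)
    expect_lt(min(d), 1)
  }
  # on a noisy dark-background field the chain without contrast
  # stretching (as used for fluorescence fields) still separates cells:
  # equalisation would spread the background noise across the full range
  noisy <- make_field(field_spec(n_cells = 40, noise_sd = 8, seed = 23))
  expect_equal(nrow(find_cells(noisy$frame, equalize = FALSE)), 40)
})

test_that("unbiased motion has no net drift; full drift converges on the source", {
  fs <- field_spec(width = 256, height = 256, n_cells = 300, seed = 2)
  ctrl <- make_motion_video(fs, motion_spec(n_frames = 40, kappa = 0, seed = 5))
  first <- ctrl$truth[ctrl$truth$frame == 0, ]
  last <- ctrl$truth[ctrl$truth$frame == 39, ]
  disp <- sqrt(mean(last$x_px - first$x_px)^2 + mean(last$y_px - first$y_px)^2)
  # mean displacement ~ 0 relative to the accumulated path length
  expect_lt(disp, 5)

  drift <- make_motion_video(fs, motion_spec(n_frames = 120, kappa = 1,
                                             step_px = 4, seed = 5))
  fin <- drift$truth[drift$truth$frame == 119, ]
  d_att <- sqrt((fin$x_px - 127.5)^2 + (fin$y_px - 127.5)^2)
  expect_gt(mean(d_att < 30), 0.99) # essentially all cells at the source
  s <- roi_timeseries(drift$particle_sets, c(127.5, 127.5), 40)
  expect_gt(s$pct_r[120], 99)
})

test_that("motion truth and particle sets stay in-bounds and aligned", {
  fs <- field_spec(width = 128, height = 96, n_cells = 50, seed = 3)
  vid <- make_motion_video(fs, motion_spec(n_frames = 20, kappa = 0.3, seed = 9))
  expect_true(all(vid$truth$x_px >= 0 & vid$truth$x_px <= 127))
  expect_true(all(vid$truth$y_px >= 0 & vid$truth$y_px <= 95))
  expect_length(vid$particle_sets, 20)
  f7 <- vid$truth[vid$truth$frame == 7, ]
  expect_equal(vid$particle_sets[[8]]$x_px, f7$x_px)
  expect_equal(attr(vid$particle_sets[[8]], "frame_index"), 7L)
})

test_that("rendered motion frames support the full detection chain", {
  fs <- field_spec(width = 192, height = 192, n_cells = 12, seed = 4)
  vid <- make_motion_video(fs, motion_spec(n_frames = 3, kappa = 0.5, seed = 7),
                           render = TRUE)
  expect_length(vid$frames, 3)
  ps <- find_cells(vid$frames[[2]])
  # moving cells may collide and merge into one component; the expected
  # count is the number of single-linkage groups of planted positions at
  # the head-length merge distance
  tr <- vid$truth[vid$truth$frame == 1, ]
  groups <- stats::cutree(
    stats::hclust(stats::dist(tr[, c("x_px", "y_px")]), method = "single"),
    h = 9 / 0.5 # one head length in px
  )
  expect_equal(nrow(ps), length(unique(groups)))
})

test_that("stained fields are seed-deterministic and honour proportions", {
  spec <- stain_spec(n_cells = 30, width = 450, height = 450, seed = 12)
  a <- make_stained_field(spec)
  b <- make_stained_field(spec)
  expect_identical(a$frame$pixels, b$frame$pixels)
  expect_identical(a$truth, b$truth)
  expect_true(all(a$truth$subtype %in% c("IAIM", "IADM", "DAIM", "DADM", "IFI")))

  # equal proportions with n divisible by 5: exact counts by construction
  eq <- make_stained_field(stain_spec(
    proportions = c(IAIM = 0.2, IADM = 0.2, DAIM = 0.2, DADM = 0.2, IFI = 0.2),
    n_cells = 25, width = 450, height = 450, seed = 13
  ))
  expect_equal(nrow(eq$truth), 25)

  # empty spec: empty truth, classifier summarises to total 0
  none <- make_stained_field(stain_spec(n_cells = 0, seed = 1))
  expect_equal(nrow(none$truth), 0)
  # an all-background field has a constant value channel: the threshold
  # is undefined and the chain warns on its way to an empty result
  expect_warning(cells <- classify_field(none$frame), "constant")
  expect_equal(summarize_functionality(cells)$total, 0)
})

test_that("agreement statistics match direct arithmetic", {
  x <- c(3, 8, 1, 9, 4, 7, 2)
  expect_equal(agreement_stats(x, x)$r, 1)
  expect_equal(agreement_stats(x, x)$bias, 0)
  shifted <- agreement_stats(x, x + 2)
  expect_equal(shifted$r, 1)
  expect_equal(shifted$bias, -2)
  # reverse-ranked: perfect inverse rank correlation
  expect_equal(agreement_stats(x, -x, method = "spearman")$r, -1)
  # constant series: correlation undefined, reported missing
  expect_true(is.na(agreement_stats(rep(5, 5), 1:5)$r))
  expect_equal(agreement_stats(rep(5, 5), 1:5)$bias, 5 - 3)
  expect_error(agreement_stats(1:2, 1:2), "at least 3")
  expect_error(agreement_stats(1:4, 1:5), "equal length")
})
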
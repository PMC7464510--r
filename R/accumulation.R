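#' Accumulation parameters
#'
#' @param radius_px search radius R in pixels; exactly one of
#'   `radius_px`/`radius_um` must be given.
#' @param radius_um search radius in micrometres (converted with the
#'   frame scale at use time).
#' @param sampling_f compute a full heat map every `f` frames of a video
#'   and interpolate the frames in between (integer >= 1).
#' @param window_w odd window side W >= 1; counts are evaluated only at
#'   the centre pixel of each W x W window and the whole window painted
#'   with that value.
#' @return a list of class `accumulation_params`.
#' @export
accumulation_params <- function(radius_px = NULL, radius_um = NULL,
                                sampling_f = 1L, window_w = 1L) {
  if (is.null(radius_px) == is.null(radius_um)) {
    stop("give exactly one of `radius_px` or `radius_um`")
  }
  if (!is.null(radius_px) && radius_px <= 0) stop("radius must be > 0")
  if (!is.null(radius_um) && radius_um <= 0) stop("radius must be > 0")
  sampling_f <- as.integer(sampling_f)
  window_w <- as.integer(window_w)
  if (sampling_f < 1) stop("`sampling_f` must be >= 1")
  if (window_w < 1 || window_w %% 2L == 0L) stop("`window_w` must be odd and >= 1")
  structure(
    list(radius_px = radius_px, radius_um = radius_um,
         sampling_f = sampling_f, window_w = window_w),
    class = "accumulation_params"
  )
}

resolve_radius_px <- function(params, scale) {
  if (!is.null(params$radius_px)) params$radius_px else params$radius_um / scale
}

#' Per-pixel neighbourhood counts
#'
#' For every pixel of the field, counts the particle centroids whose
#' Euclidean distance from the pixel centre is `<= R` (pixels on the
#' circle boundary are counted inside). This is the raw accumulation
#' signal before boundary correction.
#'
#' @param particles a `particle_set` (see [detect_particles()]), whose
#'   `width`/`height` attributes set the output dimensions.
#' @param radius_px search radius R in pixels.
#' @return integer matrix (height x width) of counts.
#' @export
local_counts <- function(particles, radius_px) {
  if (radius_px <= 0) stop("`radius_px` must be > 0")
  w <- attr(particles, "width"); h <- attr(particles, "height")
  counts <- matrix(0L, h, w)
  if (nrow(particles) == 0) return(counts)
  r2 <- radius_px^2
  for (i in seq_len(nrow(particles))) {
    cx <- particles$x_px[i]; cy <- particles$y_px[i]
    xs <- max(0, ceiling(cx - radius_px)):min(w - 1, floor(cx + radius_px))
    ys <- max(0, ceiling(cy - radius_px)):min(h - 1, floor(cy + radius_px))
    if (length(xs) == 0 || length(ys) == 0) next
    inside <- outer((ys - cy)^2, (xs - cx)^2, `+`) <= r2
    counts[ys + 1, xs + 1] <- counts[ys + 1, xs + 1] + inside
  }
  counts
}

#' In-bounds fraction of the search circle
#'
#' For every pixel, the fraction of the rasterised R-circle centred at
#' that pixel which lies inside the image. The circle is rasterised on
#' the native pixel grid (offsets `(dx, dy)` with `dx^2 + dy^2 <= R^2`),
#' so interior pixels have fraction exactly 1 and the fraction is the
#' denominator that makes border densities unbiased.
#'
#' @param width,height image dimensions in pixels.
#' @param radius_px search radius R in pixels.
#' @return numeric matrix (height x width) of fractions in (0, 1\].
#' @export
boundary_fraction <- function(width, height, radius_px) {
  if (radius_px <= 0) stop("`radius_px` must be > 0")
  rad <- floor(radius_px)
  dxs <- (-rad):rad
  halfh <- floor(sqrt(radius_px^2 - dxs^2)) # column half-height at each dx
  total <- sum(2 * halfh + 1)
  y <- 0:(height - 1)
  counts <- matrix(0, height, width)
  for (j in seq_along(dxs)) {
    dx <- dxs[j]; hh <- halfh[j]
    # in-bounds rows of this circle column, as a function of the centre row y
    colcnt <- pmin(hh, height - 1 - y) + pmin(hh, y) + 1
    colcnt[colcnt < 0] <- 0
    x0 <- max(0, -dx); x1 <- min(width - 1, width - 1 - dx)
    if (x0 > x1) next
    counts[, (x0 + 1):(x1 + 1)] <- counts[, (x0 + 1):(x1 + 1)] + colcnt
  }
  counts / total
}

#' Boundary-correct raw counts
#'
#' Divides the raw neighbourhood counts by the in-bounds circle
#' fraction, restoring an unbiased density estimate at the image
#' borders (an interior pixel is unchanged; a corner pixel, whose
#' circle is only about a quarter inside, is scaled by about 4).
#'
#' @param raw integer matrix from [local_counts()].
#' @param fractions matrix from [boundary_fraction()] with the same shape.
#' @return numeric matrix of corrected counts.
#' @export
correct_counts <- function(raw, fractions) {
  stopifnot(all(dim(raw) == dim(fractions)))
  if (any(fractions <= 0)) stop("boundary fractions must be positive")
  raw / fractions
}

#' Linear display scaling to 0-255
#'
#' Scales the corrected map linearly so its minimum maps to 0 and its
#' maximum to 255: `scaled(x) = (x - x_min) * 255 / (x_max - x_min)`,
#' rounded half-up to an integer. A constant map (`x_max = x_min`, the
#' degenerate case where the scaling is undefined) maps to all zeros.
#'
#' @param corrected numeric matrix.
#' @return integer matrix with values in \[0, 255\].
#' @export
scale_to_display <- function(corrected) {
  stopifnot(length(corrected) >= 1)
  x_min <- min(corrected); x_max <- max(corrected)
  if (x_max == x_min) {
    return(matrix(0L, nrow(corrected), ncol(corrected)))
  }
  scaled <- (corrected - x_min) * 255 / (x_max - x_min)
  matrix(as.integer(floor(scaled + 0.5)), nrow(corrected), ncol(corrected))
}

#' Build an accumulation map for one frame
#'
#' Runs the full still-image chain: per-pixel neighbourhood counts,
#' boundary correction, and display scaling. With `window_w > 1`,
#' counts are evaluated only at the centre pixel of each W x W window
#' and every window is painted with its centre's value (the video
#' acceleration described for the method; it reduces work by W^2 at the
#' cost of a blockier map).
#'
#' @inheritParams local_counts
#' @param params an [accumulation_params()].
#' @return an `accumulation_map`: list with matrices `raw`, `corrected`,
#'   `scaled`, plus `radius_px` and `frame_index`.
#' @export
accumulation_map <- function(particles, params) {
  radius_px <- resolve_radius_px(params, attr(particles, "scale"))
  w <- attr(particles, "width"); h <- attr(particles, "height")
  raw <- local_counts(particles, radius_px)
  frac <- boundary_fraction(w, h, radius_px)
  corrected <- correct_counts(raw, frac)
  W <- params$window_w
  if (W > 1L) {
    raw <- paint_windows(raw, W)
    corrected <- paint_windows(corrected, W)
  }
  structure(
    list(raw = raw, corrected = corrected, scaled = scale_to_display(corrected),
         radius_px = radius_px, frame_index = attr(particles, "frame_index")),
    class = "accumulation_map"
  )
}

# Replicate each W x W window's centre value over the whole window.
# Windows tile from the top-left corner; centres of partial windows at
# the right/bottom edges are clamped in-bounds.
paint_windows <- function(m, W) {
  h <- nrow(m); w <- ncol(m)
  half <- (W - 1L) %/% 2L
  centre_of <- function(n, idx) pmin(((idx - 1L) %/% W) * W + half, n - 1L)
  ry <- centre_of(h, seq_len(h)) + 1L
  rx <- centre_of(w, seq_len(w)) + 1L
  m[ry, rx]
}

#' Accumulation maps for a video
#'
#' Computes full accumulation maps every `sampling_f` frames (always
#' including the first and last frame) and fills the frames in between
#' by per-pixel linear interpolation of the two flanking computed maps,
#' accelerating long videos by roughly the sampling factor. Display
#' scaling is per frame by default; `global_scale = TRUE` scales every
#' frame with the video-wide min/max so colours are comparable across
#' time.
#'
#' @param frames list of `particle_set`, one per video frame.
#' @param params an [accumulation_params()].
#' @param global_scale logical; see above.
#' @return list of `accumulation_map`, one per frame.
#' @export
heatmap_video <- function(frames, params, global_scale = FALSE) {
  n <- length(frames)
  if (n == 0) stop("empty frame sequence")
  f <- params$sampling_f
  keyframes <- unique(c(seq(1L, n, by = f), n))
  key_maps <- lapply(keyframes, function(i) accumulation_map(frames[[i]], params))
  maps <- vector("list", n)
  for (k in seq_along(keyframes)) maps[[keyframes[k]]] <- key_maps[[k]]
  for (i in seq_len(n)) {
    if (!is.null(maps[[i]])) next
    lo <- max(keyframes[keyframes < i]); hi <- min(keyframes[keyframes > i])
    whi <- (i - lo) / (hi - lo)
    corrected <- (1 - whi) * maps[[lo]]$corrected + whi * maps[[hi]]$corrected
    raw <- (1 - whi) * maps[[lo]]$raw + whi * maps[[hi]]$raw
    maps[[i]] <- structure(
      list(raw = raw, corrected = corrected,
           scaled = scale_to_display(corrected),
           radius_px = maps[[lo]]$radius_px, frame_index = i - 1L),
      class = "accumulation_map"
    )
  }
  if (global_scale) {
    rng <- range(unlist(lapply(maps, function(m) range(m$corrected))))
    for (i in seq_len(n)) {
      if (rng[2] > rng[1]) {
        sc <- (maps[[i]]$corrected - rng[1]) * 255 / (rng[2] - rng[1])
        maps[[i]]$scaled <- matrix(as.integer(floor(sc + 0.5)),
                                   nrow(sc), ncol(sc))
      } else {
        maps[[i]]$scaled <- matrix(0L, nrow(maps[[i]]$corrected),
                                   ncol(maps[[i]]$corrected))
      }
    }
  }
  maps
}

#' @export
print.accumulation_map <- function(x, ...) {
  cat(sprintf(
    "<accumulation_map> %d x %d px, R = %.3g px, frame %d, max corrected %.3g\n",
    ncol(x$raw), nrow(x$raw), x$radius_px, x$frame_index, max(x$corrected)
  ))
  invisible(x)
}

#' Counts in concentric regions of interest over time
#'
#' For each frame, counts the particle centroids within distance `r`,
#' `2r` and `3r` of the ROI centre (distance `<= r` counts inside), and
#' expresses each count relative to that frame's total number of
#' detected particles. The concentric circles let accumulation near an
#' attractant source be monitored alongside the adjacent areas; the
#' per-frame denominator makes the relative series robust to cells
#' entering or leaving the field. Frames with zero detected particles
#' report the relative values as missing (`NA`), not 0.
#'
#' @param frames list of `particle_set`, one per frame (a single
#'   `particle_set` is accepted for stills).
#' @param center_px length-2 numeric, ROI centre `(x, y)` in pixels.
#' @param radius_px ROI radius r in pixels.
#' @return a `roi_series` tibble with columns `frame`, `n_r`, `n_2r`,
#'   `n_3r`, `N`, `pct_r`, `pct_2r`, `pct_3r` and attributes
#'   `center_px`, `radius_px`, `radius_um`.
#' @export
roi_timeseries <- function(frames, center_px, radius_px) {
  if (inherits(frames, "particle_set")) frames <- list(frames)
  if (radius_px <= 0) stop("`radius_px` must be > 0")
  w <- attr(frames[[1]], "width"); h <- attr(frames[[1]], "height")
  if (center_px[1] < 0 || center_px[1] >= w || center_px[2] < 0 || center_px[2] >= h) {
    stop("ROI centre must lie inside the image")
  }
  rows <- purrr::map2_dfr(frames, seq_along(frames), function(ps, i) {
    d2 <- (ps$x_px - center_px[1])^2 + (ps$y_px - center_px[2])^2
    n <- nrow(ps)
    n_r <- sum(d2 <= radius_px^2)
    n_2r <- sum(d2 <= (2 * radius_px)^2)
    n_3r <- sum(d2 <= (3 * radius_px)^2)
    tibble::tibble(
      frame = attr(ps, "frame_index") %||% (i - 1L),
      n_r = n_r, n_2r = n_2r, n_3r = n_3r, N = n,
      pct_r = if (n > 0) 100 * n_r / n else NA_real_,
      pct_2r = if (n > 0) 100 * n_2r / n else NA_real_,
      pct_3r = if (n > 0) 100 * n_3r / n else NA_real_
    )
  })
  attr(rows, "center_px") <- center_px
  attr(rows, "radius_px") <- radius_px
  attr(rows, "radius_um") <- radius_px * attr(frames[[1]], "scale")
  class(rows) <- c("roi_series", class(rows))
  rows
}
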
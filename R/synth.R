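#' Specification of a synthetic sperm field
#'
#' Defines a dark-background microscopy still with bright elliptical
#' sperm heads at known positions. Cells are placed by rejection
#' sampling so that they never overlap and lie fully in-bounds; heads
#' are rendered as filled ellipses with random orientation and a
#' Gaussian edge softening of sigma = 1 px so thresholding is stable.
#'
#' Defaults emulate a 20x bull-sperm field: 0.5 um/px, head 9 x 4.5 um
#' (about 32 um^2), bright heads (200) on a dim background (20).
#'
#' @param width,height image size in pixels.
#' @param scale micrometres per pixel.
#' @param n_cells number of cells to plant.
#' @param axes_um full major/minor head axes in micrometres.
#' @param intensity head brightness in \[0, 255\].
#' @param background background level in \[0, 255\].
#' @param noise_sd standard deviation of additive Gaussian pixel noise
#'   (0 = noiseless).
#' @param seed integer seed; every generator in the package is
#'   seed-deterministic.
#' @return a list of class `field_spec`.
#' @export
field_spec <- function(width = 512, height = 512, scale = 0.5, n_cells = 50,
                       axes_um = c(9, 4.5), intensity = 200, background = 20,
                       noise_sd = 0, seed = 1L) {
  stopifnot(width >= 1, height >= 1, scale > 0, n_cells >= 0,
            axes_um[1] >= axes_um[2], intensity > background, noise_sd >= 0)
  structure(
    list(width = as.integer(width), height = as.integer(height), scale = scale,
         n_cells = as.integer(n_cells), axes_um = axes_um,
         intensity = intensity, background = background, noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "field_spec"
  )
}

# Rejection-sample n non-overlapping centres with minimum pairwise
# distance `min_dist` and margin `margin` from every border (0-based
# pixel coordinates).
place_centres <- function(n, width, height, min_dist, margin, max_tries = 2000L) {
  xs <- numeric(0); ys <- numeric(0)
  tries <- 0L
  while (length(xs) < n) {
    if (tries >= max_tries * max(n, 1)) {
      stop("could not place ", n, " non-overlapping cells; lower the density")
    }
    tries <- tries + 1L
    x <- stats::runif(1, margin, width - 1 - margin)
    y <- stats::runif(1, margin, height - 1 - margin)
    if (length(xs) == 0 || all((xs - x)^2 + (ys - y)^2 >= min_dist^2)) {
      xs <- c(xs, x); ys <- c(ys, y)
    }
  }
  list(x = xs, y = ys)
}

# Pixel membership of a rotated filled ellipse (0-based coordinates);
# returns matrix indices into an height x width raster.
ellipse_pixels <- function(cx, cy, a, b, theta, width, height) {
  xs <- max(0, floor(cx - a)):min(width - 1, ceiling(cx + a))
  ys <- max(0, floor(cy - a)):min(height - 1, ceiling(cy + a))
  g <- expand.grid(y = ys, x = xs)
  dx <- g$x - cx; dy <- g$y - cy
  u <- (dx * cos(theta) + dy * sin(theta)) / a
  v <- (-dx * sin(theta) + dy * cos(theta)) / b
  keep <- u^2 + v^2 <= 1
  list(rows = g$y[keep] + 1L, cols = g$x[keep] + 1L, u = u[keep])
}

# Separable Gaussian blur (sigma in px, kernel truncated at 3 sigma).
gaussian_blur <- function(m, sigma = 1) {
  if (sigma <= 0) return(m)
  rad <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-rad:rad, sd = sigma)
  k <- k / sum(k)
  band <- function(n) {
    K <- matrix(0, n, n)
    for (d in -rad:rad) {
      i <- seq_len(n - abs(d))
      K[cbind(i + max(0, -d), i + max(0, d))] <- k[d + rad + 1]
    }
    K
  }
  band(nrow(m)) %*% m %*% band(ncol(m))
}

#' Generate a synthetic sperm field with planted truth
#'
#' @param spec a [field_spec()].
#' @return list with `frame` (an intensity [field_frame()]) and `truth`
#'   (tibble `cell`, `x_px`, `y_px`, `theta`).
#' @export
make_field <- function(spec) {
  stopifnot(inherits(spec, "field_spec"))
  set.seed(spec$seed)
  a <- (spec$axes_um[1] / spec$scale) / 2
  b <- (spec$axes_um[2] / spec$scale) / 2
  margin <- a + 4
  ctr <- place_centres(spec$n_cells, spec$width, spec$height,
                       min_dist = 2 * a + 6, margin = margin)
  theta <- stats::runif(spec$n_cells, 0, pi)
  cells <- matrix(0, spec$height, spec$width)
  for (i in seq_len(spec$n_cells)) {
    px <- ellipse_pixels(ctr$x[i], ctr$y[i], a, b, theta[i],
                         spec$width, spec$height)
    cells[cbind(px$rows, px$cols)] <- spec$intensity - spec$background
  }
  img <- gaussian_blur(cells, 1) + spec$background
  if (spec$noise_sd > 0) {
    img <- img + stats::rnorm(length(img), sd = spec$noise_sd)
  }
  img <- pmin(pmax(round(img), 0), 255)
  list(
    frame = field_frame(matrix(img, spec$height, spec$width), scale = spec$scale),
    truth = tibble::tibble(cell = seq_len(spec$n_cells),
                           x_px = ctr$x, y_px = ctr$y, theta = theta)
  )
}

#' Specification of synthetic motion around a point source
#'
#' Cells take random-length steps (Rayleigh-distributed) whose
#' directions follow a circular mixture: with probability `kappa` the
#' step heads toward the attractant point (bearing plus a small wrapped-
#' normal wobble), otherwise the direction is uniform. `kappa = 0` is
#' the unbiased control (the attractant point is inert); `kappa = 1`
#' sends every step toward the source. Cells reflect at the image
#' boundaries.
#'
#' @param n_frames number of video frames.
#' @param step_px Rayleigh scale of the per-frame step length, pixels.
#' @param attractant_px length-2 `(x, y)` position of the source; `NULL`
#'   = image centre.
#' @param kappa drift strength in \[0, 1\].
#' @param wobble_sd angular wobble (radians) around the bearing for
#'   drifting steps.
#' @param seed integer seed.
#' @return a list of class `motion_spec`.
#' @export
motion_spec <- function(n_frames = 150, step_px = 4, attractant_px = NULL,
                        kappa = 0.5, wobble_sd = 0.3, seed = 1L) {
  stopifnot(n_frames >= 1, step_px > 0, kappa >= 0, kappa <= 1)
  structure(
    list(n_frames = as.integer(n_frames), step_px = step_px,
         attractant_px = attractant_px, kappa = kappa, wobble_sd = wobble_sd,
         seed = as.integer(seed)),
    class = "motion_spec"
  )
}

#' Generate a synthetic drift-vs-random motion video
#'
#' Initial positions are uniform over the field; each frame the cells
#' step per the [motion_spec()]. The per-frame particle positions are
#' the planted truth; they are returned both as a tidy truth table and
#' as ready-made `particle_set` frames that feed [roi_timeseries()] and
#' [heatmap_video()] directly. Set `render = TRUE` to also rasterise
#' every frame as an intensity image (cells drawn as in [make_field()]),
#' for exercising the full detection chain.
#'
#' @param field a [field_spec()] (sets field size, scale, cell count and
#'   rendering style).
#' @param motion a [motion_spec()].
#' @param render also rasterise the frames (slower); default `FALSE`.
#' @return list with `truth` (tibble `frame`, `cell`, `x_px`, `y_px`),
#'   `particle_sets` (list of `particle_set`), and `frames` (list of
#'   [field_frame()] or `NULL`).
#' @export
make_motion_video <- function(field, motion, render = FALSE) {
  stopifnot(inherits(field, "field_spec"), inherits(motion, "motion_spec"))
  set.seed(motion$seed)
  w <- field$width; h <- field$height
  att <- motion$attractant_px %||% c((w - 1) / 2, (h - 1) / 2)
  n <- field$n_cells
  x <- stats::runif(n, 0, w - 1)
  y <- stats::runif(n, 0, h - 1)
  frames_xy <- vector("list", motion$n_frames)
  frames_xy[[1]] <- list(x = x, y = y)
  for (f in seq_len(motion$n_frames - 1L)) {
    step <- motion$step_px * sqrt(-2 * log(stats::runif(n))) # Rayleigh
    bearing <- atan2(att[2] - y, att[1] - x)
    drift <- stats::runif(n) < motion$kappa
    ang <- ifelse(drift,
                  bearing + stats::rnorm(n, sd = motion$wobble_sd),
                  stats::runif(n, 0, 2 * pi))
    x <- x + step * cos(ang)
    y <- y + step * sin(ang)
    # reflect at boundaries
    x <- ifelse(x < 0, -x, x); x <- ifelse(x > w - 1, 2 * (w - 1) - x, x)
    y <- ifelse(y < 0, -y, y); y <- ifelse(y > h - 1, 2 * (h - 1) - y, y)
    x <- pmin(pmax(x, 0), w - 1); y <- pmin(pmax(y, 0), h - 1)
    frames_xy[[f + 1L]] <- list(x = x, y = y)
  }
  truth <- purrr::map2_dfr(frames_xy, seq_along(frames_xy) - 1L, function(p, f) {
    tibble::tibble(frame = f, cell = seq_len(n), x_px = p$x, y_px = p$y)
  })
  head_px <- prod(field$axes_um / field$scale) * pi / 4
  particle_sets <- purrr::map2(frames_xy, seq_along(frames_xy) - 1L, function(p, f) {
    particle_set_from_positions(p$x, p$y, w, h, scale = field$scale,
                                frame_index = f,
                                pixel_count = as.integer(round(head_px)),
                                area_um2 = rep(head_px * field$scale^2, n))
  })
  frames <- NULL
  if (render) {
    a <- (field$axes_um[1] / field$scale) / 2
    b <- (field$axes_um[2] / field$scale) / 2
    frames <- purrr::map2(frames_xy, seq_along(frames_xy) - 1L, function(p, f) {
      cells <- matrix(0, h, w)
      for (i in seq_len(n)) {
        px <- ellipse_pixels(p$x[i], p$y[i], a, b, 0, w, h)
        cells[cbind(px$rows, px$cols)] <- field$intensity - field$background
      }
      img <- gaussian_blur(cells, 1) + field$background
      if (field$noise_sd > 0) img <- img + stats::rnorm(length(img), sd = field$noise_sd)
      field_frame(matrix(pmin(pmax(round(img), 0), 255), h, w),
                  scale = field$scale, frame_index = f)
    })
  }
  list(truth = truth, particle_sets = particle_sets, frames = frames)
}

#' Specification of a synthetic stained fluorescence field
#'
#' Renders cells in the five staining patterns of the triple-stain
#' read-out, with hues drawn strictly inside the colour bands:
#' \describe{
#'   \item{IAIM}{blue head with a green acrosomal cap}
#'   \item{IADM}{red head with a green acrosomal cap}
#'   \item{DAIM}{blue head}
#'   \item{DADM}{red head}
#'   \item{IFI}{green head and green tail}
#' }
#' Optional per-pixel hue jitter (wrapped Gaussian on the 0-255 hue
#' scale) emulates chromatic noise.
#'
#' @param proportions named numeric vector over
#'   `c(IAIM, IADM, DAIM, DADM, IFI)`, summing to 1.
#' @param n_cells number of cells.
#' @param width,height,scale field geometry as in [field_spec()].
#' @param hue_jitter_sd per-pixel hue jitter SD on the 0-255 scale
#'   (0 = noiseless).
#' @param cap_t cut along the normalised major axis beyond which head
#'   pixels belong to the acrosomal cap (0.33 puts about 30% of the
#'   head area in the cap).
#' @param seed integer seed.
#' @return a list of class `stain_spec`.
#' @export
stain_spec <- function(proportions = c(IAIM = 0.45, IADM = 0.2, DAIM = 0.05,
                                       DADM = 0.2, IFI = 0.1),
                       n_cells = 150, width = 768, height = 768, scale = 0.5,
                       hue_jitter_sd = 0, cap_t = 0.33, seed = 1L) {
  stopifnot(setequal(names(proportions), c("IAIM", "IADM", "DAIM", "DADM", "IFI")),
            abs(sum(proportions) - 1) < 1e-8, all(proportions >= 0),
            n_cells >= 0, hue_jitter_sd >= 0)
  structure(
    list(proportions = proportions[c("IAIM", "IADM", "DAIM", "DADM", "IFI")],
         n_cells = as.integer(n_cells), width = as.integer(width),
         height = as.integer(height), scale = scale,
         hue_jitter_sd = hue_jitter_sd, cap_t = cap_t, seed = as.integer(seed)),
    class = "stain_spec"
  )
}

# In-band reference hues on the 0-255 scale.
STAIN_HUES <- c(red = 8, green = 85, blue = 170)

hue_to_rgb <- function(h255, value = 230) {
  h <- (h255 %% 256) / 255 * 360
  c6 <- h / 60
  x <- value * (1 - abs(c6 %% 2 - 1))
  r <- ifelse(c6 < 1, value, ifelse(c6 < 2, x, ifelse(c6 < 3, 0,
       ifelse(c6 < 4, 0, ifelse(c6 < 5, x, value)))))
  g <- ifelse(c6 < 1, x, ifelse(c6 < 2, value, ifelse(c6 < 3, value,
       ifelse(c6 < 4, x, 0))))
  b <- ifelse(c6 < 3, 0, ifelse(c6 < 4, x, ifelse(c6 < 5, value, x)))
  cbind(r, g, b)
}

#' Generate a synthetic stained field with planted subtype labels
#'
#' @param spec a [stain_spec()].
#' @param axes_um head axes in micrometres (as [field_spec()]).
#' @return list with `frame` (RGB [field_frame()]) and `truth` (tibble
#'   `cell`, `x_px`, `y_px`, `subtype`).
#' @export
make_stained_field <- function(spec, axes_um = c(9, 4.5)) {
  stopifnot(inherits(spec, "stain_spec"))
  set.seed(spec$seed)
  a <- (axes_um[1] / spec$scale) / 2
  b <- (axes_um[2] / spec$scale) / 2
  tail_len <- 1.5 * a
  margin <- a + tail_len + 4
  ctr <- place_centres(spec$n_cells, spec$width, spec$height,
                       min_dist = 2 * a + tail_len + 4, margin = margin)
  theta <- stats::runif(spec$n_cells, 0, pi)
  n_sub <- stats::rmultinom(1, spec$n_cells, spec$proportions)[, 1]
  subtype <- sample(rep(names(spec$proportions), n_sub))
  hue <- matrix(NA_real_, spec$height, spec$width)
  val <- matrix(0, spec$height, spec$width)
  put <- function(rows, cols, h255) {
    hue[cbind(rows, cols)] <<- h255
    val[cbind(rows, cols)] <<- 230
  }
  for (i in seq_len(spec$n_cells)) {
    px <- ellipse_pixels(ctr$x[i], ctr$y[i], a, b, theta[i],
                         spec$width, spec$height)
    body_hue <- switch(subtype[i],
      IAIM = , DAIM = STAIN_HUES[["blue"]],
      IADM = , DADM = STAIN_HUES[["red"]],
      IFI = STAIN_HUES[["green"]]
    )
    put(px$rows, px$cols, body_hue)
    if (subtype[i] %in% c("IAIM", "IADM")) {
      cap <- px$u > spec$cap_t
      put(px$rows[cap], px$cols[cap], STAIN_HUES[["green"]])
    }
    if (subtype[i] == "IFI") {
      # tail: a 2-px-wide line from the posterior pole away from the head
      t_steps <- seq(a, a + tail_len, by = 0.5)
      tx <- round(ctr$x[i] - t_steps * cos(theta[i]))
      ty <- round(ctr$y[i] - t_steps * sin(theta[i]))
      for (ddx in 0:1) for (ddy in 0:1) {
        ok <- tx + ddx >= 0 & tx + ddx < spec$width &
              ty + ddy >= 0 & ty + ddy < spec$height
        put(ty[ok] + ddy + 1L, tx[ok] + ddx + 1L, STAIN_HUES[["green"]])
      }
    }
  }
  lit <- which(!is.na(hue))
  h <- hue[lit]
  if (spec$hue_jitter_sd > 0) {
    h <- (h + stats::rnorm(length(h), sd = spec$hue_jitter_sd)) %% 256
  }
  rgbv <- hue_to_rgb(h, value = 230)
  chan <- array(0, dim = c(spec$height, spec$width, 3))
  for (ch in 1:3) {
    m <- matrix(0, spec$height, spec$width)
    m[lit] <- rgbv[, ch]
    chan[, , ch] <- gaussian_blur(m, 1)
  }
  chan <- pmin(pmax(round(chan), 0), 255)
  list(
    frame = field_frame(chan, scale = spec$scale),
    truth = tibble::tibble(cell = seq_len(spec$n_cells), x_px = ctr$x,
                           y_px = ctr$y, subtype = subtype)
  )
}
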
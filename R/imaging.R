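#' Detection parameters for particle analysis
#'
#' Bundles the settings of the segmentation stage shared by all
#' pipelines: how the image is thresholded and which physical sizes
#' count as a sperm head. Size bounds are expressed in um^2 (converted
#' through the image scale), never in raw pixels, so the same parameter
#' file transfers between magnifications.
#'
#' @param min_area_um2,max_area_um2 lower/upper bound on particle area in
#'   square micrometres; `0 < min < max`.
#' @param threshold_method `"otsu"` or `"fixed"`.
#' @param threshold_level fixed threshold level in \[0, 255\]; only used
#'   when `threshold_method = "fixed"`.
#' @param connectivity pixel connectivity for component labelling, 4 or 8
#'   (default 8: compact sperm heads).
#' @param polarity `"bright"` for fluorescence-style bright cells on a
#'   dark background (default), `"dark"` for dark cells on a bright
#'   background as in negative phase contrast.
#' @return a list of class `detection_params`.
#' @export
detection_params <- function(min_area_um2 = 10, max_area_um2 = 80,
                             threshold_method = c("otsu", "fixed"),
                             threshold_level = 128,
                             connectivity = 8,
                             polarity = c("bright", "dark")) {
  threshold_method <- match.arg(threshold_method)
  polarity <- match.arg(polarity)
  if (!(min_area_um2 > 0 && min_area_um2 < max_area_um2)) {
    stop("need 0 < min_area_um2 < max_area_um2")
  }
  if (!connectivity %in% c(4, 8)) stop("`connectivity` must be 4 or 8")
  structure(
    list(
      min_area_um2 = min_area_um2, max_area_um2 = max_area_um2,
      threshold_method = threshold_method, threshold_level = threshold_level,
      connectivity = as.integer(connectivity), polarity = polarity
    ),
    class = "detection_params"
  )
}

#' Convert an RGB frame to intensity
#'
#' Rec. 601 luminance: `0.299 R + 0.587 G + 0.114 B`. Intensity input is
#' passed through unchanged; dimensions, scale and frame index are
#' preserved. The result is kept unquantised (doubles in \[0, 255\]).
#'
#' @param frame a [field_frame()].
#' @return an intensity [field_frame()].
#' @export
to_grayscale <- function(frame) {
  stopifnot(is_field_frame(frame))
  if (frame$channels == 1) return(frame)
  px <- frame$pixels
  gray <- 0.299 * px[, , 1] + 0.587 * px[, , 2] + 0.114 * px[, , 3]
  field_frame(gray, scale = frame$scale, frame_index = frame$frame_index)
}

#' Global histogram equalisation
#'
#' Classic 256-bin global equalisation: values are binned to the nearest
#' integer level, and each level `v` maps to
#' `round(255 * (cdf(v) - cdf_min) / (n - cdf_min))` where `cdf` is the
#' cumulative histogram and `cdf_min` its smallest non-zero value. A
#' constant image (degenerate histogram) is returned unchanged.
#'
#' @param frame an intensity [field_frame()].
#' @return an intensity [field_frame()] with values in \[0, 255\].
#' @export
equalize_histogram <- function(frame) {
  stopifnot(is_field_frame(frame))
  if (frame$channels != 1) stop("equalize_histogram() needs an intensity frame")
  v <- round(frame$pixels)
  counts <- tabulate(as.integer(v) + 1L, nbins = 256L)
  cdf <- cumsum(counts)
  n <- length(v)
  cdf_min <- min(cdf[cdf > 0])
  if (n == cdf_min) return(frame) # constant image
  lut <- round(255 * (cdf - cdf_min) / (n - cdf_min))
  out <- matrix(lut[as.integer(v) + 1L], nrow(v), ncol(v))
  field_frame(out, scale = frame$scale, frame_index = frame$frame_index)
}

#' Otsu threshold level
#'
#' Exhaustive scan of all 256 candidate levels, choosing the level that
#' maximises the between-class variance of the (rounded) intensity
#' histogram. The level `t` splits the histogram into `{v < t}` and
#' `{v >= t}`; for bright cells the foreground is `v >= t`. Ties are
#' broken toward the lowest level, so on a well-separated bimodal image
#' the chosen level lies strictly between the modes.
#'
#' @param frame an intensity [field_frame()] or a numeric matrix of
#'   values in \[0, 255\].
#' @return integer level `t` in \[1, 255\], or `NA` for a constant
#'   image (no split has two non-empty classes).
#' @export
otsu_level <- function(frame) {
  v <- if (is_field_frame(frame)) frame$pixels else frame
  counts <- tabulate(as.integer(round(v)) + 1L, nbins = 256L)
  n <- sum(counts)
  levels <- 0:255
  cdf <- cumsum(counts)
  csum <- cumsum(counts * levels)
  total <- csum[256]
  # candidate t in 1..255: class 0 holds values 0..t-1
  w0 <- cdf[1:255]
  w1 <- n - w0
  valid <- w0 > 0 & w1 > 0
  mu0 <- csum[1:255] / w0
  mu1 <- (total - csum[1:255]) / w1
  bcv <- ifelse(valid, (w0 / n) * (w1 / n) * (mu0 - mu1)^2, -Inf)
  if (all(!is.finite(bcv))) return(NA_integer_) # constant image
  as.integer(which.max(bcv))              # which.max takes the first (lowest) maximum
}

#' Binarise an intensity frame
#'
#' Thresholds the frame into a logical foreground mask. By default the
#' Otsu level is used and bright pixels (`value >= t`) are foreground;
#' with `polarity = "dark"` the mask is inverted (`value < t`), for
#' dark-on-bright negative phase contrast. A constant image yields an
#' empty mask with a warning.
#'
#' @param frame an intensity [field_frame()].
#' @param params a [detection_params()] (supplies method, level, polarity).
#' @return logical matrix, `TRUE` = cell (foreground).
#' @export
binarize <- function(frame, params = detection_params()) {
  stopifnot(is_field_frame(frame))
  if (frame$channels != 1) stop("binarize() needs an intensity frame")
  t <- if (params$threshold_method == "otsu") {
    otsu_level(frame)
  } else {
    as.integer(params$threshold_level)
  }
  if (is.na(t)) {
    warning("constant image: threshold undefined, returning empty mask")
    return(matrix(FALSE, nrow(frame$pixels), ncol(frame$pixels)))
  }
  v <- round(frame$pixels)
  if (params$polarity == "bright") v >= t else v < t
}

# Two-pass connected-component labelling with union-find over foreground
# pixels only (masks are sparse, so the scan is over cells, not the
# whole raster). Returns an integer matrix; 0 = background, components
# numbered 1..k in raster order of first appearance.
label_components <- function(mask, connectivity = 8L) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  fg <- which(mask)
  if (length(fg) == 0) return(lab)
  rows <- ((fg - 1L) %% h) + 1L
  cols <- ((fg - 1L) %/% h) + 1L
  ord <- order(rows, cols) # raster order: left-to-right within top-to-bottom
  parent <- integer(length(fg))
  find <- function(i) {
    root <- i
    while (parent[root] != root) root <- parent[root]
    while (parent[i] != root) { nxt <- parent[i]; parent[i] <<- root; i <- nxt }
    root
  }
  # provisional labels stored in lab as indices into `parent`
  nlab <- 0L
  for (k in ord) {
    r <- rows[k]; cc <- cols[k]
    nb <- integer(0)
    if (cc > 1L && lab[r, cc - 1L] > 0L) nb <- c(nb, lab[r, cc - 1L])
    if (r > 1L && lab[r - 1L, cc] > 0L) nb <- c(nb, lab[r - 1L, cc])
    if (connectivity == 8L && r > 1L) {
      if (cc > 1L && lab[r - 1L, cc - 1L] > 0L) nb <- c(nb, lab[r - 1L, cc - 1L])
      if (cc < w && lab[r - 1L, cc + 1L] > 0L) nb <- c(nb, lab[r - 1L, cc + 1L])
    }
    if (length(nb) == 0) {
      nlab <- nlab + 1L
      parent[nlab] <- nlab
      lab[r, cc] <- nlab
    } else {
      roots <- vapply(unique(nb), find, integer(1))
      keep <- min(roots)
      lab[r, cc] <- keep
      for (rt in roots) parent[rt] <- keep
    }
  }
  # resolve and renumber in raster order of first appearance
  roots <- vapply(seq_len(nlab), find, integer(1))
  vals <- lab[cbind(rows[ord], cols[ord])]
  resolved <- roots[vals]
  newid <- integer(nlab)
  nxt <- 0L
  for (i in seq_along(resolved)) {
    rt <- resolved[i]
    if (newid[rt] == 0L) { nxt <- nxt + 1L; newid[rt] <- nxt }
  }
  lab[cbind(rows[ord], cols[ord])] <- newid[resolved]
  lab
}

#' Detect particles in a binary mask
#'
#' Connected-component particle analysis: components are labelled with
#' the configured connectivity, their centroids taken as the arithmetic
#' mean of member pixel coordinates (0-based, pixel-centre convention),
#' and components whose physical area falls outside
#' `[min_area_um2, max_area_um2]` are discarded. Area is
#' `pixel_count * scale^2`.
#'
#' @param mask logical matrix (from [binarize()]).
#' @param scale micrometres per pixel.
#' @param params a [detection_params()].
#' @param frame_index frame ordinal carried onto the result.
#' @return a `particle_set`: a tibble with columns `particle`, `x_px`,
#'   `y_px`, `pixel_count`, `area_um2` and attributes `width`, `height`,
#'   `scale`, `frame_index`, plus the label matrix (`labels`) and the
#'   id of the retained component for each particle (`label_id`).
#' @export
detect_particles <- function(mask, scale = 1, params = detection_params(),
                             frame_index = 0L) {
  stopifnot(is.logical(mask) || all(mask %in% c(0, 1)))
  mask <- mask > 0
  lab <- label_components(mask, params$connectivity)
  k <- max(lab)
  if (k == 0) {
    res <- tibble::tibble(
      particle = integer(0), x_px = numeric(0), y_px = numeric(0),
      pixel_count = integer(0), area_um2 = numeric(0)
    )
  } else {
    fg <- which(lab > 0)
    ids <- lab[fg]
    x <- ((fg - 1L) %/% nrow(lab))      # 0-based column
    y <- ((fg - 1L) %% nrow(lab))       # 0-based row
    npx <- tabulate(ids, nbins = k)
    cx <- rowsum(x, ids)[, 1] / npx
    cy <- rowsum(y, ids)[, 1] / npx
    area <- npx * scale^2
    keep <- which(area >= params$min_area_um2 & area <= params$max_area_um2)
    res <- tibble::tibble(
      particle = seq_along(keep),
      x_px = unname(cx[keep]), y_px = unname(cy[keep]),
      pixel_count = npx[keep], area_um2 = unname(area[keep])
    )
    attr(res, "label_id") <- keep
  }
  attr(res, "labels") <- lab
  attr(res, "width") <- ncol(mask)
  attr(res, "height") <- nrow(mask)
  attr(res, "scale") <- scale
  attr(res, "frame_index") <- as.integer(frame_index)
  class(res) <- c("particle_set", class(res))
  res
}

#' Detect particles in a frame (full preprocessing chain)
#'
#' Convenience wrapper running the complete segmentation chain on one
#' frame: grayscale conversion, optional histogram equalisation,
#' thresholding and size-filtered component extraction.
#'
#' @inheritParams detect_particles
#' @param frame a [field_frame()].
#' @param equalize apply [equalize_histogram()] before thresholding
#'   (default `TRUE`; disable for fluorescence fields where segmentation
#'   runs on the brightness channel without contrast stretching).
#' @return a `particle_set` tibble (see [detect_particles()]).
#' @export
find_cells <- function(frame, params = detection_params(), equalize = TRUE) {
  g <- to_grayscale(frame)
  if (equalize) g <- equalize_histogram(g)
  mask <- binarize(g, params)
  detect_particles(mask, scale = frame$scale, params = params,
                   frame_index = frame$frame_index)
}

# Build a particle_set directly from known positions (used by the
# synthetic generator's truth path and by tests).
particle_set_from_positions <- function(x, y, width, height, scale = 1,
                                        frame_index = 0L, pixel_count = 1L,
                                        area_um2 = NULL) {
  stopifnot(length(x) == length(y))
  if (is.null(area_um2)) area_um2 <- rep(pixel_count * scale^2, length(x))
  res <- tibble::tibble(
    particle = seq_along(x), x_px = as.numeric(x), y_px = as.numeric(y),
    pixel_count = rep(as.integer(pixel_count), length(x)),
    area_um2 = as.numeric(area_um2)
  )
  attr(res, "width") <- width
  attr(res, "height") <- height
  attr(res, "scale") <- scale
  attr(res, "frame_index") <- as.integer(frame_index)
  class(res) <- c("particle_set", class(res))
  res
}
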
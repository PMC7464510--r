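#' Counting-chamber geometry
#'
#' The sampled volume is the imaged field area times the chamber depth.
#' By default the field dimensions come from the image (pixels times the
#' um/pixel scale); both can be overridden for grid-based counting
#' conventions where the counted area is set by the chamber ruling
#' rather than the camera field.
#'
#' @param depth_um chamber depth in micrometres (10 for a Neubauer
#'   improved haemocytometer).
#' @param field_width_um,field_height_um imaged field dimensions in
#'   micrometres; `NA` (default) means take them from the image.
#' @param dilution_factor multiplier restoring the pre-dilution
#'   concentration after counting a diluted aliquot (>= 1, default 1).
#' @return a list of class `chamber_geometry`.
#' @export
chamber_geometry <- function(depth_um = 10, field_width_um = NA,
                             field_height_um = NA, dilution_factor = 1) {
  if (depth_um <= 0) stop("`depth_um` must be > 0")
  if (!is.na(field_width_um) && field_width_um <= 0) stop("field width must be > 0")
  if (!is.na(field_height_um) && field_height_um <= 0) stop("field height must be > 0")
  if (dilution_factor < 1) stop("`dilution_factor` must be >= 1")
  structure(
    list(depth_um = depth_um, field_width_um = field_width_um,
         field_height_um = field_height_um, dilution_factor = dilution_factor),
    class = "chamber_geometry"
  )
}

#' Count sperm in one field
#'
#' Runs the segmentation chain ([find_cells()]) and returns the number
#' of size-filtered particles; particles whose centroid is in-bounds
#' are counted (the deterministic analogue of manual two-edge
#' haemocytometer rules).
#'
#' @param frame a [field_frame()].
#' @param params a [detection_params()].
#' @param equalize apply histogram equalisation before thresholding.
#' @return integer count.
#' @export
count_field <- function(frame, params = detection_params(), equalize = TRUE) {
  nrow(find_cells(frame, params, equalize = equalize))
}

#' Concentration from a count and chamber geometry
#'
#' `concentration (M cells/mL) = n * dilution * 1e6 / volume_um3`,
#' where `volume_um3 = field_width_um * field_height_um * depth_um`
#' (1 mL = 1e12 um^3 and 1 M = 1e6 cells). The result carries all its
#' inputs for audit.
#'
#' @param n non-negative integer count of detected cells.
#' @param geometry a [chamber_geometry()] with resolved field
#'   dimensions (use [estimate_concentration()] to derive them from an
#'   image).
#' @return a `concentration_result` tibble row: `n_counted`,
#'   `volume_um3`, `dilution_factor`, `mcells_per_ml`.
#' @export
compute_concentration <- function(n, geometry) {
  stopifnot(inherits(geometry, "chamber_geometry"))
  if (n < 0) stop("`n` must be >= 0")
  if (is.na(geometry$field_width_um) || is.na(geometry$field_height_um)) {
    stop("field dimensions unresolved; supply them or use estimate_concentration()")
  }
  volume <- geometry$field_width_um * geometry$field_height_um * geometry$depth_um
  res <- tibble::tibble(
    n_counted = as.integer(n),
    volume_um3 = volume,
    dilution_factor = geometry$dilution_factor,
    mcells_per_ml = n * geometry$dilution_factor * 1e6 / volume
  )
  class(res) <- c("concentration_result", class(res))
  res
}

#' Estimate concentration from one field image
#'
#' Counts cells in the frame and converts the count to millions of
#' cells per mL using the imaged field area (image dimensions x scale)
#' and the chamber depth.
#'
#' @param frame a [field_frame()].
#' @param geometry a [chamber_geometry()].
#' @param params a [detection_params()].
#' @param equalize apply histogram equalisation before thresholding.
#' @return a `concentration_result` tibble row (see
#'   [compute_concentration()]).
#' @export
estimate_concentration <- function(frame, geometry = chamber_geometry(),
                                   params = detection_params(),
                                   equalize = TRUE) {
  stopifnot(is_field_frame(frame))
  if (is.na(geometry$field_width_um)) {
    geometry$field_width_um <- frame_width(frame) * frame$scale
  }
  if (is.na(geometry$field_height_um)) {
    geometry$field_height_um <- frame_height(frame) * frame$scale
  }
  n <- count_field(frame, params, equalize = equalize)
  compute_concentration(n, geometry)
}

#' Aggregate concentrations over several fields
#'
#' Mean and sample standard deviation of per-field concentration
#' estimates, with the per-field table retained.
#'
#' @param results a `concentration_result` tibble with one row per
#'   field (rows of [compute_concentration()] bound together), or a
#'   list of such rows.
#' @return a `concentration_aggregate`: list with `per_field` (tibble),
#'   `k`, `mean_mcells_per_ml`, `sd_mcells_per_ml` (`NA` for k = 1).
#' @export
aggregate_fields <- function(results) {
  if (is.list(results) && !is.data.frame(results)) {
    results <- dplyr::bind_rows(results)
  }
  if (nrow(results) == 0) stop("no fields to aggregate")
  structure(
    list(
      per_field = tibble::as_tibble(results),
      k = nrow(results),
      mean_mcells_per_ml = mean(results$mcells_per_ml),
      sd_mcells_per_ml = stats::sd(results$mcells_per_ml)
    ),
    class = "concentration_aggregate"
  )
}

#' @export
print.concentration_aggregate <- function(x, ...) {
  cat(sprintf("<concentration_aggregate> %d fields: %.3g +/- %.3g M cells/mL\n",
              x$k, x$mean_mcells_per_ml,
              if (is.na(x$sd_mcells_per_ml)) 0 else x$sd_mcells_per_ml))
  invisible(x)
}
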
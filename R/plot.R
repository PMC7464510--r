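#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an accumulation heat map
#'
#' Renders the display-scaled map through the Jet LUT, warm colours
#' marking dense regions.
#'
#' @param object an `accumulation_map` (see [accumulation_map()]).
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot accumulation_map
#' @export
autoplot.accumulation_map <- function(object, ...) {
  df <- tidy.accumulation_map(object)
  lut <- jet_lut()
  cols <- grDevices::rgb(lut[, "r"], lut[, "g"], lut[, "b"], maxColorValue = 255)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x_px, y = .data$y_px,
                                   fill = .data$scaled)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradientn(colours = cols, limits = c(0, 255),
                                  name = "accumulation") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (px)", y = "y (px)",
                  title = sprintf("Accumulation map, R = %.3g px",
                                  object$radius_px)) +
    ggplot2::theme_minimal()
}

#' Plot ROI accumulation over time
#'
#' Relative counts inside the ROI circle and its 2x and 3x concentric
#' extensions, per frame — the accumulation-dynamics read-out of the
#' chemotaxis assay.
#'
#' @param object a `roi_series` (see [roi_timeseries()]).
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot roi_series
#' @export
autoplot.roi_series <- function(object, ...) {
  df <- tidyr::pivot_longer(
    tibble::as_tibble(object)[c("frame", "pct_r", "pct_2r", "pct_3r")],
    -"frame", names_to = "circle", values_to = "pct"
  )
  df$circle <- factor(df$circle, levels = c("pct_r", "pct_2r", "pct_3r"),
                      labels = c("r", "2r", "3r"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$frame, y = .data$pct,
                                   colour = .data$circle)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "frame", y = "% of detected cells in circle",
                  colour = "radius") +
    ggplot2::theme_minimal()
}

#' Plot subtype composition
#'
#' @param object a `functionality_summary` (see
#'   [summarize_functionality()]).
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot functionality_summary
#' @export
autoplot.functionality_summary <- function(object, ...) {
  df <- object$by_subtype
  df$subtype <- factor(df$subtype, levels = df$subtype)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$subtype, y = .data$pct)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "% of cells",
                  title = sprintf("%d cells", object$total)) +
    ggplot2::theme_minimal()
}

#' Display a field frame
#'
#' @param object a [field_frame()].
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot field_frame
#' @export
autoplot.field_frame <- function(object, ...) {
  h <- frame_height(object); w <- frame_width(object)
  if (object$channels == 3) {
    px <- object$pixels
    fill <- grDevices::rgb(as.vector(px[, , 1]), as.vector(px[, , 2]),
                           as.vector(px[, , 3]), maxColorValue = 255)
  } else {
    v <- as.vector(object$pixels) / 255
    fill <- grDevices::gray(v)
  }
  df <- tibble::tibble(
    x_px = rep(0:(w - 1), each = h),
    y_px = rep(0:(h - 1), times = w),
    fill = fill
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x_px, y = .data$y_px)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$fill)) +
    ggplot2::scale_fill_identity() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (px)", y = "y (px)") +
    ggplot2::theme_minimal()
}
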
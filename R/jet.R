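#' The 256-entry Jet look-up table
#'
#' The classic Jet colormap (blue -> cyan -> green -> yellow -> red),
#' built once from its piecewise-linear channel ramps over 256 indices:
#' for `t = i/255`, each channel is `clamp(1.5 - |4t - c|)` with channel
#' offsets `c = 3` (red), `2` (green), `1` (blue), scaled to 0-255. The
#' table is generated deterministically from these ramps so rendering is
#' bit-exact across platforms. Index 0 is the coldest entry (dark blue),
#' index 255 the warmest (dark red).
#'
#' @return a 256 x 3 integer matrix with columns `r`, `g`, `b` in
#'   \[0, 255\]; row `i` is the colour of scaled value `i - 1`.
#' @export
jet_lut <- function() {
  t <- (0:255) / 255
  ramp <- function(offset) pmin(pmax(1.5 - abs(4 * t - offset), 0), 1)
  lut <- cbind(r = ramp(3), g = ramp(2), b = ramp(1))
  matrix(as.integer(round(lut * 255)), 256, 3,
         dimnames = list(NULL, c("r", "g", "b")))
}

#' Render a scaled map through the Jet LUT
#'
#' Each scaled value in \[0, 255\] indexes the 256-entry Jet table; the
#' result is the heat-map image in which cold and warm colours represent
#' low and high accumulation values.
#'
#' @param scaled integer matrix with values in \[0, 255\] (from
#'   [scale_to_display()] or an `accumulation_map`'s `scaled` field).
#' @return height x width x 3 numeric array with values in \[0, 255\].
#' @export
apply_jet_lut <- function(scaled) {
  if (inherits(scaled, "accumulation_map")) scaled <- scaled$scaled
  if (any(scaled < 0 | scaled > 255)) stop("scaled values must lie in [0, 255]")
  lut <- jet_lut()
  idx <- as.integer(scaled) + 1L
  array(c(lut[idx, "r"], lut[idx, "g"], lut[idx, "b"]),
        dim = c(nrow(scaled), ncol(scaled), 3))
}

#' Render an accumulation map as an RGB field frame
#'
#' @param map an `accumulation_map` (see [accumulation_map()]).
#' @param scale micrometres per pixel recorded on the output frame.
#' @return an RGB [field_frame()] heat-map image.
#' @export
render_heatmap <- function(map, scale = 1) {
  stopifnot(inherits(map, "accumulation_map"))
  field_frame(apply_jet_lut(map$scaled), scale = scale,
              frame_index = map$frame_index)
}
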
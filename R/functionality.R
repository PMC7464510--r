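#' Hue bands for fluorescence colour classification
#'
#' The staining read-out works on the hue channel of the HSV colour
#' model, expressed on a 0-255 scale (the 8-bit hue convention; 360
#' degrees map to 256 levels, so pure green at 120 degrees sits at
#' H = 85 and pure blue at 240 degrees at H = 170). The default bands
#' are: red when `H > 200` or `H < 20`, green when `50 < H < 125`, blue
#' when `130 < H < 185`, all inequalities strict; any other hue — and
#' any pixel too dark or too desaturated for its hue to be meaningful —
#' is unclassified.
#'
#' @param red_high,red_low red band: `H > red_high` or `H < red_low`.
#' @param green_low,green_high green band: `green_low < H < green_high`.
#' @param blue_low,blue_high blue band: `blue_low < H < blue_high`.
#' @param min_value,min_saturation pixels with brightness or saturation
#'   below these (0-255 scale) are unclassified regardless of hue, to
#'   avoid hue noise on background-adjacent pixels.
#' @return a list of class `hue_bands`.
#' @export
hue_bands <- function(red_high = 200, red_low = 20,
                      green_low = 50, green_high = 125,
                      blue_low = 130, blue_high = 185,
                      min_value = 30, min_saturation = 30) {
  if (!(red_low <= green_low && green_high <= blue_low && blue_high <= red_high)) {
    stop("hue bands must be pairwise disjoint")
  }
  structure(
    list(red_high = red_high, red_low = red_low,
         green_low = green_low, green_high = green_high,
         blue_low = blue_low, blue_high = blue_high,
         min_value = min_value, min_saturation = min_saturation),
    class = "hue_bands"
  )
}

#' Pixel hue on the 0-255 scale
#'
#' Standard HSV hue of 8-bit RGB pixels, scaled to \[0, 256) (degrees x
#' 255/360). Achromatic pixels (saturation 0) have no defined hue and
#' are reported as `NA`.
#'
#' @param r,g,b numeric vectors of 8-bit channel values in \[0, 255\].
#' @return numeric vector of hues in \[0, 256), `NA` where undefined.
#' @export
pixel_hue <- function(r, g, b) {
  hsv <- grDevices::rgb2hsv(rbind(r, g, b), maxColorValue = 255)
  h <- hsv["h", ] * 255
  h[hsv["s", ] == 0] <- NA_real_
  unname(h)
}

#' Classify a hue into a colour band
#'
#' @param h numeric vector of hues in \[0, 256), `NA` = undefined.
#' @param bands a [hue_bands()].
#' @return character vector in `{"red", "green", "blue", "none"}`.
#' @export
classify_pixel <- function(h, bands = hue_bands()) {
  out <- rep("none", length(h))
  defined <- !is.na(h)
  out[defined & (h > bands$red_high | h < bands$red_low)] <- "red"
  out[defined & h > bands$green_low & h < bands$green_high] <- "green"
  out[defined & h > bands$blue_low & h < bands$blue_high] <- "blue"
  out
}

#' Colour ratios of one cell
#'
#' Fraction of the cell's pixels whose hue falls in each colour band.
#' The denominator is the total number of segmented pixels of the cell
#' (including unclassified ones), so the three ratios sum to at most 1.
#' Pixels darker than `min_value` or less saturated than
#' `min_saturation` are unclassified.
#'
#' @param r,g,b numeric vectors, the 8-bit channels of the cell's pixels.
#' @param bands a [hue_bands()].
#' @return named numeric vector `c(red_ratio, green_ratio, blue_ratio)`.
#' @export
color_ratios <- function(r, g, b, bands = hue_bands()) {
  n <- length(r)
  if (n == 0) stop("cell has no pixels: invalid segmentation")
  hsv <- grDevices::rgb2hsv(rbind(r, g, b), maxColorValue = 255)
  h <- hsv["h", ] * 255
  h[hsv["s", ] == 0] <- NA_real_
  h[hsv["v", ] * 255 < bands$min_value] <- NA_real_
  h[hsv["s", ] * 255 < bands$min_saturation] <- NA_real_
  cls <- classify_pixel(h, bands)
  c(red_ratio = sum(cls == "red") / n,
    green_ratio = sum(cls == "green") / n,
    blue_ratio = sum(cls == "blue") / n)
}

#' Decision-tree thresholds for subtype classification
#'
#' @param tau_ifi minimum green ratio for the whole-cell-green IFI
#'   subtype (default 0.75).
#' @param tau_acrosome minimum green ratio indicating an intact (green-
#'   labelled) acrosome (default 0.10).
#' @return a list of class `tree_params`.
#' @export
tree_params <- function(tau_ifi = 0.75, tau_acrosome = 0.10) {
  if (!(tau_acrosome > 0 && tau_acrosome < tau_ifi && tau_ifi <= 1)) {
    stop("need 0 < tau_acrosome < tau_ifi <= 1")
  }
  structure(list(tau_ifi = tau_ifi, tau_acrosome = tau_acrosome),
            class = "tree_params")
}

#' Classify one cell into a functionality subtype
#'
#' Deterministic decision tree over a cell's colour ratios. The five
#' subpopulations come from a triple stain in which the membrane-
#' impermeant dye marks membrane-damaged cells red, the DNA dye marks
#' membrane-intact cells blue, and the esterase substrate marks an
#' intact acrosome (or, for IFI cells, the whole head and tail) green:
#'
#' 1. `green_ratio >= tau_ifi` -> **IFI** (whole cell green: increased
#'    fluorescence intensity);
#' 2. otherwise acrosome status: intact iff `green_ratio >= tau_acrosome`
#'    (a green acrosomal cap);
#' 3. membrane status by majority between the body dyes: damaged iff
#'    `red_ratio > blue_ratio`, intact iff `blue_ratio > red_ratio`;
#' 4. cells with no usable membrane signal (`red_ratio == blue_ratio`,
#'    including both 0) -> **UNCLASSIFIED**.
#'
#' Steps 2-3 combine to IAIM / IADM / DAIM / DADM (Intact/Damaged
#' Acrosome x Intact/Damaged Membrane).
#'
#' @param ratios named numeric vector from [color_ratios()] (or any
#'   vector `c(red, green, blue)` of ratios in \[0, 1\]).
#' @param params a [tree_params()].
#' @return one of `"IAIM"`, `"IADM"`, `"DAIM"`, `"DADM"`, `"IFI"`,
#'   `"UNCLASSIFIED"`.
#' @export
classify_cell <- function(ratios, params = tree_params()) {
  red <- ratios[[1]]; green <- ratios[[2]]; blue <- ratios[[3]]
  if (green >= params$tau_ifi) return("IFI")
  acrosome_intact <- green >= params$tau_acrosome
  if (red > blue) {
    if (acrosome_intact) "IADM" else "DADM"
  } else if (blue > red) {
    if (acrosome_intact) "IAIM" else "DAIM"
  } else {
    "UNCLASSIFIED"
  }
}

#' Classify every cell in a stained field
#'
#' Full functionality pipeline for one RGB fluorescence field: cells
#' are segmented on the brightness (value) channel — histogram
#' equalisation is off by default here, since stretching the channels
#' would distort hue — then each cell's pixels are classified in the
#' original RGB and the subtype assigned by the decision tree.
#'
#' @param frame an RGB [field_frame()].
#' @param det a [detection_params()].
#' @param bands a [hue_bands()].
#' @param tree a [tree_params()].
#' @param equalize run histogram equalisation before thresholding
#'   (default `FALSE` for fluorescence fields).
#' @return a `cell_records` tibble with one row per cell: `cell_id`,
#'   `x_px`, `y_px`, `area_um2`, `pixel_count`, `red_ratio`,
#'   `green_ratio`, `blue_ratio`, `subtype`.
#' @export
classify_field <- function(frame, det = detection_params(),
                           bands = hue_bands(), tree = tree_params(),
                           equalize = FALSE) {
  stopifnot(is_field_frame(frame))
  if (frame$channels != 3) stop("classify_field() needs an RGB frame")
  value <- field_frame(pmax(frame$pixels[, , 1], frame$pixels[, , 2],
                            frame$pixels[, , 3]),
                       scale = frame$scale, frame_index = frame$frame_index)
  if (equalize) value <- equalize_histogram(value)
  mask <- binarize(value, det)
  ps <- detect_particles(mask, scale = frame$scale, params = det,
                         frame_index = frame$frame_index)
  lab <- attr(ps, "labels")
  ids <- attr(ps, "label_id")
  rch <- frame$pixels[, , 1]; gch <- frame$pixels[, , 2]; bch <- frame$pixels[, , 3]
  ratios <- purrr::map_dfr(seq_len(nrow(ps)), function(i) {
    px <- which(lab == ids[i])
    rr <- color_ratios(rch[px], gch[px], bch[px], bands)
    tibble::as_tibble(as.list(rr))
  })
  if (nrow(ps) == 0) {
    ratios <- tibble::tibble(red_ratio = numeric(0), green_ratio = numeric(0),
                             blue_ratio = numeric(0))
  }
  out <- dplyr::bind_cols(
    tibble::tibble(cell_id = ps$particle, x_px = ps$x_px, y_px = ps$y_px,
                   area_um2 = ps$area_um2, pixel_count = ps$pixel_count),
    ratios
  )
  out$subtype <- vapply(seq_len(nrow(out)), function(i) {
    classify_cell(c(out$red_ratio[i], out$green_ratio[i], out$blue_ratio[i]),
                  tree)
  }, character(1))
  attr(out, "frame_index") <- frame$frame_index
  class(out) <- c("cell_records", class(out))
  out
}

SUBTYPE_LEVELS <- c("IAIM", "IADM", "DAIM", "DADM", "IFI", "UNCLASSIFIED")

#' Summarise subtype composition of a field
#'
#' Per-subtype counts and percentages, plus the two integrity
#' aggregates: acrosome-intact % = (IAIM + IADM) / total, and
#' membrane-intact % = (IAIM + DAIM \[+ IFI\]) / total. IFI cells are
#' included in the membrane-intact aggregate by default, since whole-
#' cell esterase fluorescence requires a membrane retaining the
#' substrate; set `ifi_membrane_intact = FALSE` to exclude them.
#'
#' @param cells a `cell_records` tibble (from [classify_field()]) or any
#'   data frame with a `subtype` column.
#' @param ifi_membrane_intact logical; see above.
#' @return a `functionality_summary`: list with `total`, a `by_subtype`
#'   tibble (`subtype`, `n`, `pct`), `pct_acrosome_intact` and
#'   `pct_membrane_intact` (both `NA` for an empty field).
#' @export
summarize_functionality <- function(cells, ifi_membrane_intact = TRUE) {
  st <- factor(cells$subtype, levels = SUBTYPE_LEVELS)
  n <- as.integer(table(st))
  total <- length(st)
  by_subtype <- tibble::tibble(
    subtype = SUBTYPE_LEVELS, n = n,
    pct = if (total > 0) 100 * n / total else rep(NA_real_, length(n))
  )
  cnt <- stats::setNames(n, SUBTYPE_LEVELS)
  membrane <- cnt[["IAIM"]] + cnt[["DAIM"]] +
    if (ifi_membrane_intact) cnt[["IFI"]] else 0L
  structure(
    list(
      total = total,
      by_subtype = by_subtype,
      pct_acrosome_intact =
        if (total > 0) 100 * (cnt[["IAIM"]] + cnt[["IADM"]]) / total else NA_real_,
      pct_membrane_intact = if (total > 0) 100 * membrane / total else NA_real_
    ),
    class = "functionality_summary"
  )
}

#' @export
print.functionality_summary <- function(x, ...) {
  cat(sprintf("<functionality_summary> %d cells\n", x$total))
  if (x$total > 0) {
    tab <- x$by_subtype[x$by_subtype$n > 0 | x$by_subtype$subtype != "UNCLASSIFIED", ]
    for (i in seq_len(nrow(tab))) {
      cat(sprintf("  %-12s %4d  (%.1f%%)\n", tab$subtype[i], tab$n[i], tab$pct[i]))
    }
    cat(sprintf("  acrosome-intact %.1f%%, membrane-intact %.1f%%\n",
                x$pct_acrosome_intact, x$pct_membrane_intact))
  }
  invisible(x)
}
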
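#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a functionality summary
#'
#' One row per subtype with its count and percentage.
#'
#' @param x a `functionality_summary` (from [summarize_functionality()]).
#' @param ... unused.
#' @return a tibble with columns `subtype`, `n`, `pct`.
#' @method tidy functionality_summary
#' @export
tidy.functionality_summary <- function(x, ...) x$by_subtype

#' One-row overview of a functionality summary
#'
#' @param x a `functionality_summary`.
#' @param ... unused.
#' @return a one-row tibble: `total`, `pct_acrosome_intact`,
#'   `pct_membrane_intact`.
#' @method glance functionality_summary
#' @export
glance.functionality_summary <- function(x, ...) {
  tibble::tibble(
    total = x$total,
    pct_acrosome_intact = x$pct_acrosome_intact,
    pct_membrane_intact = x$pct_membrane_intact
  )
}

#' Tidy a concentration aggregate
#'
#' @param x a `concentration_aggregate` (from [aggregate_fields()]).
#' @param ... unused.
#' @return the per-field tibble with a `field` index column.
#' @method tidy concentration_aggregate
#' @export
tidy.concentration_aggregate <- function(x, ...) {
  dplyr::mutate(x$per_field, field = dplyr::row_number(), .before = 1)
}

#' One-row overview of a concentration aggregate
#'
#' @param x a `concentration_aggregate`.
#' @param ... unused.
#' @return a one-row tibble: `k`, `mean_mcells_per_ml`, `sd_mcells_per_ml`.
#' @method glance concentration_aggregate
#' @export
glance.concentration_aggregate <- function(x, ...) {
  tibble::tibble(
    k = x$k,
    mean_mcells_per_ml = x$mean_mcells_per_ml,
    sd_mcells_per_ml = x$sd_mcells_per_ml
  )
}

#' Tidy an accumulation map
#'
#' Long per-pixel table; useful for ad-hoc ggplot2 work beyond
#' [autoplot.accumulation_map()].
#'
#' @param x an `accumulation_map`.
#' @param ... unused.
#' @return a tibble with columns `x_px`, `y_px`, `raw`, `corrected`,
#'   `scaled`.
#' @method tidy accumulation_map
#' @export
tidy.accumulation_map <- function(x, ...) {
  h <- nrow(x$raw); w <- ncol(x$raw)
  tibble::tibble(
    x_px = rep(0:(w - 1), each = h),
    y_px = rep(0:(h - 1), times = w),
    raw = as.vector(x$raw),
    corrected = as.vector(x$corrected),
    scaled = as.vector(x$scaled)
  )
}
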
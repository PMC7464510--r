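#' Agreement between two measurement series
#'
#' The small comparison machinery used to validate an automated read-out
#' against a manual one: a correlation coefficient (Pearson for normal
#' data, Spearman otherwise) plus the Bland-Altman bias, the mean of the
#' paired differences `x - y`. Constant series have an undefined
#' correlation, which is reported as missing rather than an error.
#'
#' @param x,y numeric vectors of equal length >= 3 (e.g. manual vs
#'   automated percentages).
#' @param method `"pearson"` or `"spearman"`.
#' @return a tibble with columns `method`, `n`, `r`, `bias` (and
#'   `loa_lower`/`loa_upper`, the 95% Bland-Altman limits of agreement).
#' @examples
#' agreement_stats(1:10, 1:10 + 2)
#' @export
agreement_stats <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop("`x` and `y` must have equal length")
  if (length(x) < 3) stop("need at least 3 paired observations")
  r <- if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    NA_real_
  } else {
    stats::cor(x, y, method = method)
  }
  d <- x - y
  tibble::tibble(
    method = method, n = length(x), r = r, bias = mean(d),
    loa_lower = mean(d) - 1.96 * stats::sd(d),
    loa_upper = mean(d) + 1.96 * stats::sd(d)
  )
}
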
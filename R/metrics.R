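#' Coefficient of determination of the predicted-vs-actual line
#'
#' Computed as the squared Pearson correlation between predicted and actual
#' concentrations — the R-squared of the straight line fitted through the
#' predicted-versus-actual scatter. It is symmetric in its arguments and
#' invariant to affine rescaling of either one.
#'
#' @param pred Predicted concentrations.
#' @param actual True concentrations; must not be constant.
#'
#' @return A number in \[0, 1\].
#' @export
r_squared <- function(pred, actual) {
  if (length(pred) != length(actual)) {
    stop("`pred` and `actual` must have equal length", call. = FALSE)
  }
  if (length(actual) < 2L) stop("need at least 2 points", call. = FALSE)
  if (stats::sd(actual) == 0) {
    stop("`actual` is constant; R^2 is undefined", call. = FALSE)
  }
  if (stats::sd(pred) == 0) {
    warning("`pred` is constant; returning R^2 = 0")
    return(0)
  }
  stats::cor(pred, actual)^2
}

#' Root-mean-square error
#'
#' @param pred Predicted concentrations (mg/L).
#' @param actual True concentrations (mg/L), same length.
#'
#' @return RMSE in mg/L.
#' @export
rmse <- function(pred, actual) {
  if (length(pred) != length(actual)) {
    stop("`pred` and `actual` must have equal length", call. = FALSE)
  }
  if (length(pred) < 1L) stop("need at least 1 point", call. = FALSE)
  sqrt(mean((pred - actual)^2))
}
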
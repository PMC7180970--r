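#' Regression error and agreement metrics
#'
#' `rmse()` is the root mean squared error sqrt(sum((P - O)^2) / N) between
#' predicted (P) and observed (O) concentrations. `pearson()` is the standard
#' product-moment correlation. `r_squared()` is, by default, the squared
#' Pearson correlation of predicted versus observed — the convention used
#' throughout the evaluation reports, under which the prediction-set R² can
#' exceed the calibration R² even when RMSEP exceeds RMSEC. The residual
#' definition 1 - SSres/SStot is available via `method = "residual"`.
#'
#' @param predicted,observed Numeric vectors of equal length (mg/L
#'   equivalents), paired by sample.
#' @return `rmse()`: a non-negative scalar in the units of the inputs, zero
#'   iff the vectors are identical. `pearson()`: a value in \[-1, 1\].
#'   `r_squared()` with the default method: a value in \[0, 1\].
#' @examples
#' rmse(c(1, 2, 3), c(0, 0, 0))      # sqrt(14/3)
#' r_squared(2 * (1:5) + 7, 1:5)     # 1: affine-invariant
#' @export
rmse <- function(predicted, observed) {
  check_paired(predicted, observed, min_n = 1)
  sqrt(sum((predicted - observed)^2) / length(predicted))
}

#' @rdname rmse
#' @param x,y Numeric vectors of equal length, each with nonzero variance.
#' @export
pearson <- function(x, y) {
  check_paired(x, y, min_n = 2)
  if (sd(x) == 0 || sd(y) == 0) {
    wp_data_error("pearson correlation undefined for a constant sequence")
  }
  cor(x, y)
}

#' @rdname rmse
#' @param method `"pearson"` (default; squared correlation) or `"residual"`
#'   (1 - SSres/SStot, which can be negative).
#' @export
r_squared <- function(predicted, observed, method = c("pearson", "residual")) {
  method <- match.arg(method)
  check_paired(predicted, observed, min_n = 2)
  if (method == "pearson") {
    return(pearson(predicted, observed)^2)
  }
  if (sd(observed) == 0) {
    wp_data_error("residual R-squared undefined: observed values are constant")
  }
  1 - sum((observed - predicted)^2) / sum((observed - mean(observed))^2)
}

check_paired <- function(a, b, min_n = 1) {
  if (!is.numeric(a) || !is.numeric(b)) {
    wp_usage_error("inputs must be numeric vectors")
  }
  if (length(a) != length(b)) {
    wp_usage_error("predicted and observed must have equal length")
  }
  if (length(a) < min_n) {
    wp_usage_error(sprintf("at least %d paired value(s) required", min_n))
  }
  if (any(!is.finite(a)) || any(!is.finite(b))) {
    wp_data_error("inputs must be finite")
  }
  invisible(TRUE)
}
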
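#' Evaluation metrics for estimation and forecasting
#'
#' The pipeline scores estimated or forecast series against reference values
#' with four quantities: mean squared error, the coefficient of
#' determination, a normalized-RMSE fit percentage, and a paired two-sided
#' test of the differences.
#'
#' `mse_metric` is \eqn{\frac{1}{n}\sum_i (y_i - \hat y_i)^2}.
#'
#' `r2_metric` is \eqn{1 - \sum_i (y_i - \hat y_i)^2 / \sum_i (y_i - \bar y)^2};
#' it can be negative for fits worse than the mean and is reported as
#' computed.
#'
#' `fit_percent` is the normalized-RMSE fit used in system identification,
#' \eqn{100\,(1 - \lVert y - \hat y\rVert_2 / \lVert y - \bar y\rVert_2)};
#' it relates to R2 by \eqn{fit = 100(1 - \sqrt{1 - R^2})} whenever
#' \eqn{R^2 \le 1}.
#'
#' @param y Numeric vector of reference values.
#' @param y_hat Numeric vector of predictions, same length.
#' @return A scalar metric value.
#' @examples
#' mse_metric(c(1, 2), c(2, 2)) # 0.5
#' r2_metric(0:2, 0:2) # 1
#' @export
mse_metric <- function(y, y_hat) {
  check_paired(y, y_hat)
  mean((y - y_hat)^2)
}

#' @rdname mse_metric
#' @export
r2_metric <- function(y, y_hat) {
  check_paired(y, y_hat, min_n = 2L)
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot <= 0) stop("degenerate-input: zero variance in 'y'")
  1 - sum((y - y_hat)^2) / ss_tot
}

#' @rdname mse_metric
#' @export
fit_percent <- function(y, y_hat) {
  check_paired(y, y_hat, min_n = 2L)
  denom <- sqrt(sum((y - mean(y))^2))
  if (denom <= 0) stop("degenerate-input: zero variance in 'y'")
  100 * (1 - sqrt(sum((y - y_hat)^2)) / denom)
}

#' Paired two-sided test of prediction differences
#'
#' Tests whether the paired differences `y - y_hat` have mean zero. The
#' default is a paired t-test; a Wilcoxon signed-rank test is available via
#' `method = "wilcoxon"`. Degenerate inputs are handled by convention: if all
#' differences are exactly zero the predictions are perfect and `p = 1` is
#' returned with a warning; if the differences are a non-zero constant the
#' test statistic is infinite and `p = 0` is returned with a warning.
#'
#' @inheritParams mse_metric
#' @param method `"t"` (paired t-test, default) or `"wilcoxon"`.
#' @return The two-sided p-value.
#' @export
paired_pvalue <- function(y, y_hat, method = c("t", "wilcoxon")) {
  method <- match.arg(method)
  check_paired(y, y_hat, min_n = 2L)
  d <- y - y_hat
  if (stats::sd(d) == 0) {
    if (all(d == 0)) {
      warning("degenerate: predictions identical to observations; p = 1 by convention")
      return(1)
    }
    warning("degenerate: zero variance in paired differences; p = 0 by convention")
    return(0)
  }
  if (method == "t") {
    stats::t.test(d)$p.value
  } else {
    stats::wilcox.test(d, exact = FALSE)$p.value
  }
}

#' Bundle the evaluation metrics into one report
#'
#' @inheritParams paired_pvalue
#' @return A list of class `metric_report` with fields `mse`, `r2`,
#'   `fit_percent`, `p_value`, `n` and `test`.
#' @export
metric_report <- function(y, y_hat, method = c("t", "wilcoxon")) {
  method <- match.arg(method)
  structure(
    list(
      mse = mse_metric(y, y_hat),
      r2 = r2_metric(y, y_hat),
      fit_percent = fit_percent(y, y_hat),
      p_value = suppressWarnings(paired_pvalue(y, y_hat, method)),
      n = length(y),
      test = if (method == "t") "paired t-test" else "wilcoxon signed-rank"
    ),
    class = "metric_report"
  )
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf(
    "<metric_report> n = %d: MSE = %.4g, R2 = %.4g, fit = %.1f%%, p = %.3g (%s)\n",
    x$n, x$mse, x$r2, x$fit_percent, x$p_value, x$test
  ))
  invisible(x)
}

check_paired <- function(y, y_hat, min_n = 1L) {
  if (length(y) != length(y_hat)) {
    stop("invalid-argument: 'y' and 'y_hat' must have equal length")
  }
  if (length(y) < min_n) {
    stop(sprintf("invalid-argument: need at least %d paired observations", min_n))
  }
  if (anyNA(y) || anyNA(y_hat)) stop("invalid-argument: NA values in input")
  invisible(TRUE)
}
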
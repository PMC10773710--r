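#' Coefficient of determination (R-squared)
#'
#' Computes \eqn{R^2 = 1 - \sum (y_i - P_i)^2 / \sum (y_i - \bar y)^2}
#' between a measured series \eqn{y} and a predicted series \eqn{P}.
#' This is the 1:1-line definition used throughout model evaluation here;
#' it is at most 1 and can be negative when predictions are worse than the
#' mean of the measured values. It is not clamped.
#'
#' @param measured numeric vector of measured values (\eqn{y_i}).
#' @param predicted numeric vector of predicted values (\eqn{P_i}), same
#'   length as `measured`.
#' @return A single number, \eqn{\le 1}, unbounded below.
#' @examples
#' r_squared(c(1, 2, 3), c(1, 2, 4))  # 0.5
#' @export
r_squared <- function(measured, predicted) {
  check_paired(measured, predicted, min_n = 2L)
  ss_tot <- sum((measured - mean(measured))^2)
  if (ss_tot == 0) {
    stop("r_squared is undefined for a constant measured series (zero denominator)")
  }
  1 - sum((measured - predicted)^2) / ss_tot
}

#' Root mean square error
#'
#' \eqn{RMSE = \sqrt{\sum (y_i - P_i)^2 / n}}, in the units of the inputs.
#'
#' @inheritParams r_squared
#' @return Non-negative number; 0 iff the two series are identical.
#' @examples
#' rmse(c(1, 2), c(2, 4))  # sqrt(5/2)
#' @export
rmse <- function(measured, predicted) {
  check_paired(measured, predicted, min_n = 1L)
  sqrt(sum((measured - predicted)^2) / length(measured))
}

#' Normalized root mean square error
#'
#' RMSE divided by the range of the measured series,
#' \eqn{nRMSE = RMSE / (y_{max} - y_{min})}. Dimensionless; invariant under
#' adding a constant to both series.
#'
#' @inheritParams r_squared
#' @return Non-negative dimensionless number.
#' @export
nrmse <- function(measured, predicted) {
  check_paired(measured, predicted, min_n = 1L)
  rng <- max(measured) - min(measured)
  if (rng == 0) {
    stop("nrmse is undefined when the measured series has zero range")
  }
  rmse(measured, predicted) / rng
}

#' Pearson correlation with significance flag
#'
#' Product-moment correlation
#' \eqn{r = \sum (X_i-\bar X)(Y_i-\bar Y) /
#' \sqrt{\sum (X_i-\bar X)^2 \sum (Y_i-\bar Y)^2}} with a two-sided p-value
#' from the exact t-transform \eqn{t = r\sqrt{(n-2)/(1-r^2)}} on \eqn{n-2}
#' degrees of freedom. Significance is screened at `alpha` with no
#' multiple-testing correction, matching the per-leaf / per-index screening
#' convention this package follows; pass the returned p-values through
#' [stats::p.adjust()] (e.g. Holm) if family-wise control is wanted.
#'
#' @param x,y numeric vectors of equal length, neither constant.
#' @param alpha significance threshold (default 0.05).
#' @return A list with elements `r`, `p`, `n` and `significant`. With
#'   `n < 3` the p-value is `NA` and `significant` is `NA`.
#' @examples
#' pearson_r(c(1, 2, 3), c(1, 2, 4))$r  # ~0.9820
#' @export
pearson_r <- function(x, y, alpha = 0.05) {
  check_paired(x, y, min_n = 2L)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("pearson_r is undefined when either vector is constant")
  }
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  if (n >= 3) {
    # guard |r| = 1 exactly: t is infinite, p is 0
    if (abs(r) >= 1) {
      p <- 0
    } else {
      tval <- r * sqrt((n - 2) / (1 - r^2))
      p <- 2 * stats::pt(abs(tval), df = n - 2, lower.tail = FALSE)
    }
  } else {
    p <- NA_real_
  }
  list(r = r, p = p, n = n, significant = if (is.na(p)) NA else p < alpha)
}

check_paired <- function(a, b, min_n) {
  if (length(a) != length(b)) {
    stop("paired series must have equal length (", length(a), " vs ", length(b), ")")
  }
  if (length(a) < min_n) {
    stop("need at least ", min_n, " paired observations, got ", length(a))
  }
  if (anyNA(a) || anyNA(b)) {
    stop("paired series must not contain missing values")
  }
  invisible(TRUE)
}

#' Evaluation metrics block
#'
#' Convenience wrapper returning the standard metric set (`r2`, `rmse`,
#' `nrmse`, `n`) for one measured/predicted pair, as used in validation
#' reports and serialized model records. `nrmse` is `NA` when the measured
#' range is zero.
#'
#' @inheritParams r_squared
#' @return Named list `r2`, `rmse`, `nrmse`, `n`.
#' @export
metric_block <- function(measured, predicted) {
  list(
    r2 = r_squared(measured, predicted),
    rmse = rmse(measured, predicted),
    nrmse = if (max(measured) > min(measured)) nrmse(measured, predicted) else NA_real_,
    n = length(measured)
  )
}
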
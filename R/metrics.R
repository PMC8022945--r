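#' Spearman rank correlation
#'
#' Pearson correlation of average (tie-adjusted) ranks. Returns 0 with a
#' warning when either vector is constant (rank correlation undefined),
#' which happens e.g. for a constant-prediction model.
#'
#' @param y,yhat Numeric vectors of equal length `>= 2`.
#' @return Scalar in `[-1, 1]`.
#' @export
spearman_cor <- function(y, yhat) {
  if (length(y) != length(yhat)) stop("length mismatch")
  if (length(y) < 2) stop("need at least two observations")
  ry <- rank(y); rp <- rank(yhat)
  if (stats::sd(ry) == 0 || stats::sd(rp) == 0) {
    warning("constant vector: Spearman correlation undefined, returning 0")
    return(0)
  }
  stats::cor(ry, rp)
}

#' Mean arctangent absolute percentage error (MAAPE)
#'
#' \deqn{\mathrm{MAAPE} = \frac1n \sum_i
#'       \arctan\left|\frac{y_i - \hat y_i}{y_i}\right|,}
#' a bounded (`[0, pi/2]`) variant of the absolute percentage error that
#' remains usable with zero observations: a term is 0 when
#' `y_i = yhat_i = 0` and `pi/2` (the limit of `arctan(Inf)`) when
#' `y_i = 0, yhat_i != 0`. These zero conventions matter here because
#' observed counts contain many zeros.
#'
#' @inheritParams spearman_cor
#' @return Scalar in `[0, pi/2]`.
#' @examples
#' maape(2, 4)  # pi/4
#' maape(0, 1)  # pi/2
#' @export
maape <- function(y, yhat) {
  if (length(y) != length(yhat)) stop("length mismatch")
  term <- ifelse(y == 0,
                 ifelse(yhat == 0, 0, pi / 2),
                 atan(abs((y - yhat) / y)))
  mean(term)
}

#' Mean absolute error
#'
#' @inheritParams spearman_cor
#' @return Scalar `>= 0`.
#' @export
mae <- function(y, yhat) {
  if (length(y) != length(yhat)) stop("length mismatch")
  mean(abs(y - yhat))
}

#' Mean and standard error over cross-validation folds
#'
#' @param values Per-fold metric values (`k >= 2`).
#' @return Named numeric vector `c(mean, se)` with `se = sd / sqrt(k)`.
#' @examples
#' fold_summary(c(0, 2))  # mean 1, se 1
#' @export
fold_summary <- function(values) {
  values <- values[!is.na(values)]
  k <- length(values)
  if (k < 2) stop("need at least two fold values for a standard error")
  c(mean = mean(values), se = stats::sd(values) / sqrt(k))
}
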
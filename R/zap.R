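#' Fit a zero-altered Poisson random forest
#'
#' Two-step hurdle construction:
#'
#' 1. *Zero part.* A binary (Gini) forest is fit to the indicator
#'    `I(Y = 0)` on all rows; its ensemble prediction is the estimated
#'    structural-zero probability `theta_hat`.
#' 2. *Truncated part.* A forest with the zero-truncated Poisson
#'    log-likelihood splitting criterion is fit on the `N+` rows with
#'    `Y > 0`; its ensemble prediction is the estimated rate `mu_hat`.
#'
#' Both parts share the hyperparameters (`ntree`, `mtry`, `nodesize`), and
#' their seeds are derived deterministically from `seed`.
#'
#' @inheritParams fit_forest
#' @param y Non-negative integer counts, containing both zeros and
#'   positives.
#' @param threshold Zero-probability threshold of the classification rule
#'   (see [predict.zapforest_zap()]); default 0.5.
#' @return An object of class `zapforest_zap` with components
#'   `zero_forest`, `pos_forest`, `threshold`.
#' @examples
#' set.seed(1)
#' X <- matrix(rbinom(400, 1, 0.4), 100, 4)
#' y <- rzap(100, theta = plogis(X[, 1] - 0.5), mu = exp(0.5 + 0.6 * X[, 2]))
#' m <- fit_zap(X, y, ntree = 30, mtry = 2, nodesize = 5)
#' head(predict(m, X))
#' @export
fit_zap <- function(X, y, ntree = 500,
                    mtry = max(1, floor(ncol(as_design(X)) / 3)),
                    nodesize = 5, max_depth = Inf, threshold = 0.5,
                    seed = 1) {
  X <- as_design(X)
  if (any(y < 0) || any(y != floor(y)))
    stop("`y` must contain non-negative integer counts")
  if (threshold <= 0 || threshold >= 1) stop("`threshold` must lie in (0, 1)")
  pos <- y > 0
  if (!any(!pos))
    stop("zero part is unfittable: the response contains no zeros")
  if (!any(pos))
    stop("truncated part is unfittable: the response contains no positive counts")
  if (sum(pos) < 2 * nodesize)
    stop("truncated part is unfittable: fewer than 2 * nodesize positive counts")
  zero_forest <- fit_forest(X, as.numeric(y == 0), "gini", ntree = ntree,
                            mtry = mtry, nodesize = nodesize,
                            max_depth = max_depth, seed = seed * 2 + 1)
  pos_forest <- fit_forest(X[pos, , drop = FALSE], y[pos], "ztp",
                           ntree = ntree, mtry = mtry, nodesize = nodesize,
                           max_depth = max_depth, seed = seed * 2 + 2)
  structure(list(zero_forest = zero_forest, pos_forest = pos_forest,
                 threshold = threshold, seed = seed, p = ncol(X),
                 feature_names = colnames(X)),
            class = "zapforest_zap")
}

#' Predict from a zero-altered Poisson random forest
#'
#' Three prediction types:
#' * `"mean"` (ZAP_RF): the hurdle expected value
#'   \eqn{\hat Y = (1-\hat\theta)\,\hat\mu / (1 - e^{-\hat\mu})},
#'   the ZAP mean evaluated at the two forest outputs;
#' * `"class"` (ZAPC_RF): 0 where \eqn{\hat\theta >} `threshold`,
#'   otherwise \eqn{\hat\mu} (the boundary \eqn{\hat\theta =} threshold
#'   goes to the count branch);
#' * `"parts"`: a data frame with columns `theta` and `mu`.
#'
#' @param object A `zapforest_zap` model.
#' @param newdata Design matrix.
#' @param type `"mean"`, `"class"` or `"parts"`.
#' @param aggregate How the truncated part pools its trees: `"mu"`
#'   (default) averages the per-tree rate estimates and applies the ZAP
#'   mean formula once at the forest level; `"mean"` averages the
#'   per-tree ZTP means and converts back to a pooled rate.
#' @param ... Unused.
#' @return Numeric vector (or data frame for `type = "parts"`).
#' @export
predict.zapforest_zap <- function(object, newdata,
                                  type = c("mean", "class", "parts"),
                                  aggregate = c("mu", "mean"), ...) {
  type <- match.arg(type)
  aggregate <- match.arg(aggregate)
  theta <- predict(object$zero_forest, newdata)
  if (aggregate == "mu") {
    mu <- predict(object$pos_forest, newdata)
  } else {
    M <- predict(object$pos_forest, newdata, trees = TRUE)
    mu <- cpp_ztp_mu_from_mean(rowMeans(ztp_mean(M)))
  }
  mu <- pmax(mu, MU_MIN)
  switch(type,
    parts = data.frame(theta = theta, mu = mu),
    # the hurdle expected value, by construction the ZAP mean at
    # (theta-hat, mu-hat)
    mean = zap_moments(theta, mu)$mean,
    class = ifelse(theta > object$threshold, 0, mu)
  )
}

#' @export
print.zapforest_zap <- function(x, ...) {
  cat("Zero-altered Poisson random forest\n",
      "  zero part:      ", x$zero_forest$ntree, " Gini trees\n",
      "  truncated part: ", x$pos_forest$ntree, " ZTP trees on ",
      x$pos_forest$trees[[1]]$n[1], " positive rows\n",
      "  classification threshold: ", x$threshold, "\n", sep = "")
  invisible(x)
}
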
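#' Fit a bagged random forest
#'
#' `ntree` trees are grown on independent bootstrap samples of size `n`
#' (with replacement), each under the requested splitting criterion; see
#' [grow_tree()]. Per-tree random streams are derived deterministically
#' from `seed` and the tree index, so fits are bit-reproducible and
#' independent of R's RNG state.
#'
#' @inheritParams grow_tree
#' @param ntree Number of trees `B`.
#' @param bootstrap Set `FALSE` to grow every tree on the full sample
#'   (test hook; with `ntree = 1` the forest then equals a single tree).
#' @param keep_inbag Keep the bootstrap membership counts (needed for
#'   [oob_error()]).
#' @return An object of class `zapforest_forest`.
#' @seealso [predict.zapforest_forest()], [fit_zap()]
#' @examples
#' set.seed(1)
#' X <- matrix(rbinom(200, 1, 0.5), 50, 4)
#' y <- rpois(50, 2 + X[, 1])
#' f <- fit_forest(X, y, "ls", ntree = 20, mtry = 2, nodesize = 5)
#' head(predict(f, X))
#' @export
fit_forest <- function(X, y, criterion = c("ls", "gini", "ztp"),
                       ntree = 500, mtry = max(1, floor(ncol(as_design(X)) / 3)),
                       nodesize = 5, max_depth = Inf, seed = 1,
                       bootstrap = TRUE, keep_inbag = FALSE) {
  X <- as_design(X)
  code <- check_response(y, criterion)
  if (length(y) != nrow(X)) stop("length(y) must equal nrow(X)")
  if (nrow(X) < 2 * nodesize)
    stop("need at least 2 * nodesize observations")
  if (mtry < 1 || mtry > ncol(X)) stop("`mtry` must lie in [1, ncol(X)]")
  md <- if (is.finite(max_depth)) as.integer(max_depth) else .Machine$integer.max
  fit <- cpp_grow_forest(X, as.numeric(y), code, as.integer(mtry),
                         as.integer(nodesize), md, as.integer(ntree),
                         as.numeric(seed), bootstrap, keep_inbag)
  structure(list(trees = fit$trees, inbag = fit$inbag,
                 criterion = match.arg(criterion), ntree = as.integer(ntree),
                 mtry = as.integer(mtry), nodesize = as.integer(nodesize),
                 max_depth = max_depth, seed = seed, bootstrap = bootstrap,
                 p = ncol(X), feature_names = colnames(X)),
            class = "zapforest_forest")
}

#' Predict from a random forest
#'
#' The ensemble prediction is the arithmetic mean of the per-tree
#' predictions: the response mean for `"ls"` forests, the class-1
#' probability for `"gini"` forests, and the pooled truncated-Poisson rate
#' for `"ztp"` forests.
#'
#' @param object A `zapforest_forest`.
#' @param newdata Design matrix with the training feature count.
#' @param trees Return the full rows-by-trees prediction matrix instead of
#'   its row means.
#' @param ... Unused.
#' @return Numeric vector (or matrix when `trees = TRUE`).
#' @export
predict.zapforest_forest <- function(object, newdata, trees = FALSE, ...) {
  newdata <- as_design(newdata)
  if (ncol(newdata) != object$p)
    stop("newdata has ", ncol(newdata), " columns; forest was fit with ",
         object$p)
  M <- cpp_predict_forest_trees(object$trees, newdata)
  if (trees) M else rowMeans(M)
}

#' Out-of-bag prediction error
#'
#' Diagnostic only (the benchmark protocol always scores held-out test
#' folds): each training row is predicted by the trees whose bootstrap
#' sample omitted it, and the mean squared error (or misclassification
#' rate at 0.5 for `"gini"` forests) of these OOB predictions is returned.
#'
#' @param object A forest fit with `keep_inbag = TRUE`.
#' @param X,y The training data.
#' @return Scalar OOB error.
#' @export
oob_error <- function(object, X, y) {
  stopifnot(inherits(object, "zapforest_forest"))
  if (is.null(object$inbag)) stop("refit with keep_inbag = TRUE")
  M <- predict(object, X, trees = TRUE)
  oob <- object$inbag == 0L
  pred <- rowSums(M * oob) / rowSums(oob)
  keep <- rowSums(oob) > 0
  if (object$criterion == "gini")
    mean((pred[keep] > 0.5) != (y[keep] == 1))
  else
    mean((pred[keep] - y[keep])^2)
}

#' @export
print.zapforest_forest <- function(x, ...) {
  cat("Random forest (criterion: ", x$criterion, "): ", x$ntree,
      " trees, mtry = ", x$mtry, ", nodesize = ", x$nodesize,
      ", p = ", x$p, "\n", sep = "")
  invisible(x)
}
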
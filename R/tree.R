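criterion_code <- function(criterion) {
  switch(match.arg(criterion, c("ls", "gini", "ztp")),
         ls = 1L, gini = 2L, ztp = 3L)
}

check_response <- function(y, criterion) {
  if (length(y) == 0) stop("empty response")
  if (anyNA(y)) stop("response contains NA")
  code <- criterion_code(criterion)
  if (code == 2L && !all(y %in% c(0, 1)))
    stop("Gini criterion requires a 0/1 response")
  if (code == 3L && (any(y < 1) || any(y != floor(y))))
    stop("zero-truncated Poisson criterion requires integer responses >= 1 ",
         "(filter to the positive observations first)")
  invisible(code)
}

as_design <- function(X) {
  if (is.data.frame(X)) X <- as.matrix(X)
  if (!is.matrix(X)) X <- matrix(X, ncol = 1)
  storage.mode(X) <- "double"
  X
}

#' Node score under a splitting criterion
#'
#' * `"ls"`: within-node sum of squared errors (lower is better);
#' * `"gini"`: `n * p * (1 - p)` for the node's class-1 proportion `p`
#'   (lower is better; for a 0/1 response this equals the SSE);
#' * `"ztp"`: the zero-truncated Poisson log-likelihood [ztp_loglik()]
#'   evaluated at the node MLE [ztp_mle()] (higher is better).
#'
#' @param y Response values in one node.
#' @param criterion One of `"ls"`, `"gini"`, `"ztp"`.
#' @return Scalar score.
#' @export
node_score <- function(y, criterion = c("ls", "gini", "ztp")) {
  code <- check_response(y, criterion)
  if (code == 3L) return(ztp_loglik(y, ztp_mle(y)))
  sum((y - mean(y))^2)
}

#' Best binary split of a node
#'
#' Scans the candidate features; candidate thresholds are midpoints between
#' consecutive distinct sorted values (the single threshold 0.5 for a 0/1
#' marker). Among splits leaving at least `nodesize` observations in each
#' child it returns the one optimizing the summed child criterion (summed
#' SSE / weighted Gini minimized, summed ZTP log-likelihood maximized). The
#' log-factorial term of the ZTP likelihood cancels between a parent and
#' the union of its children and is dropped from the comparison. Ties go to
#' the lowest feature index, then the lowest threshold. A split must beat
#' the unsplit node by a relative tolerance of 1e-9 (this absorbs
#' summation-order floating noise, so a constant node never splits).
#'
#' @param X Numeric design matrix (rows = observations).
#' @param y Response vector, matched to `criterion`.
#' @inheritParams node_score
#' @param candidate_features Column indices to consider.
#' @param nodesize Minimum observations per child.
#' @return `NULL` if no admissible split strictly improves the score,
#'   otherwise a list with `feature`, `threshold` and `gain` (> 0).
#' @examples
#' best_split(matrix(c(0, 0, 1, 1)), c(1, 1, 5, 5), "ztp")
#' @export
best_split <- function(X, y, criterion = c("ls", "gini", "ztp"),
                       candidate_features = seq_len(ncol(as_design(X))),
                       nodesize = 1) {
  X <- as_design(X)
  code <- check_response(y, criterion)
  if (length(y) != nrow(X)) stop("length(y) must equal nrow(X)")
  cf <- sort(unique(as.integer(candidate_features)))
  if (length(cf) == 0) stop("`candidate_features` must be nonempty")
  if (any(cf < 1) || any(cf > ncol(X))) stop("candidate feature out of range")
  cpp_best_split(X, as.numeric(y), seq_len(nrow(X)) - 1L, cf - 1L,
                 as.integer(nodesize), code)
}

#' Grow a single decision tree
#'
#' Recursive binary splitting: at each node a fresh `mtry`-subset of the
#' features is drawn without replacement from the tree's seeded random
#' stream, the best admissible split among them is taken ([best_split()]),
#' and growth stops when a node holds fewer than `2 * nodesize`
#' observations, is pure, reaches `max_depth`, or no split improves the
#' criterion. No pruning is performed. Leaves store the node mean (`"ls"`),
#' the class-1 proportion (`"gini"`), or the ZTP rate MLE (`"ztp"`).
#'
#' @inheritParams best_split
#' @param mtry Number of candidate features drawn at each node.
#' @param max_depth Maximum depth (`Inf` = unlimited, the default).
#' @param seed Integer seed for the tree's internal random stream
#'   (independent of R's RNG).
#' @return An object of class `zapforest_tree`.
#' @export
grow_tree <- function(X, y, criterion = c("ls", "gini", "ztp"),
                      mtry = ncol(as_design(X)), nodesize = 1,
                      max_depth = Inf, seed = 1) {
  X <- as_design(X)
  code <- check_response(y, criterion)
  if (length(y) != nrow(X)) stop("length(y) must equal nrow(X)")
  if (mtry < 1 || mtry > ncol(X)) stop("`mtry` must lie in [1, ncol(X)]")
  md <- if (is.finite(max_depth)) as.integer(max_depth) else .Machine$integer.max
  tr <- cpp_grow_tree(X, as.numeric(y), code, as.integer(mtry),
                      as.integer(nodesize), md, as.numeric(seed))
  structure(list(nodes = tr, criterion = match.arg(criterion), p = ncol(X),
                 feature_names = colnames(X)),
            class = "zapforest_tree")
}

#' @export
predict.zapforest_tree <- function(object, newdata, ...) {
  newdata <- as_design(newdata)
  if (ncol(newdata) != object$p)
    stop("newdata has ", ncol(newdata), " columns; tree was grown with ",
         object$p)
  cpp_predict_tree(object$nodes, newdata)
}

#' @export
print.zapforest_tree <- function(x, ...) {
  n_leaf <- sum(x$nodes$feature == -1L)
  cat("Decision tree (criterion: ", x$criterion, "), ",
      length(x$nodes$feature), " nodes, ", n_leaf, " leaves, ",
      x$nodes$n[1], " training rows\n", sep = "")
  invisible(x)
}
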
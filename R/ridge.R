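# Penalized linear baselines. Both losses penalize only the slope
# coefficients; the intercept is free. The penalty is applied on the raw
# feature scale by default, matching the closed-form solution
# b = Sxy / (Sxx + lambda) in the single-feature case; standardization is
# available as an option (markers are 0/1, so scales are already
# comparable).

center_design <- function(X, standardize) {
  xbar <- colMeans(X)
  Xc <- sweep(X, 2, xbar)
  s <- rep(1, ncol(X))
  if (standardize && ncol(X) > 0) {
    s <- apply(Xc, 2, stats::sd)
    s[s == 0 | is.na(s)] <- 1
    Xc <- sweep(Xc, 2, s, "/")
  }
  list(Xc = Xc, xbar = xbar, s = s)
}

ridge_coef_svd <- function(sv, yc, lambda) {
  # minimizer of ||yc - Xc b||^2 + lambda ||b||^2 via X = U D V'
  d <- sv$d
  uty <- crossprod(sv$u, yc)
  drop(sv$v %*% (uty * d / (d^2 + lambda)))
}

#' Ridge regression with an unpenalized intercept
#'
#' Exact minimizer of the penalized residual sum of squares
#' \deqn{\sum_i (y_i - \beta_0 - x_i^\top\beta)^2 + \lambda \sum_j \beta_j^2}
#' computed from the SVD of the centered design, so it is unique for
#' `lambda > 0` even when `p > n`.
#'
#' @param X Numeric design matrix.
#' @param y Numeric response.
#' @param lambda Penalty, `>= 0`. `lambda = 0` requires a full-rank
#'   centered design (otherwise an error instructs to use `lambda > 0`).
#' @param standardize Scale columns to unit standard deviation before
#'   fitting (coefficients are returned on the original scale). Default
#'   `FALSE`: the penalty applies to the raw-scale coefficients exactly as
#'   written in the loss.
#' @return An object of class `zapforest_ridge` with `intercept`,
#'   `coefficients`, `lambda`, `family = "gaussian"`.
#' @examples
#' fit_ridge(matrix(c(0, 0, 1, 1)), c(1, 1, 3, 3), lambda = 1)$coefficients
#' @export
fit_ridge <- function(X, y, lambda, standardize = FALSE) {
  X <- as_design(X)
  stopifnot(length(y) == nrow(X), lambda >= 0)
  cd <- center_design(X, standardize)
  sv <- svd(cd$Xc)
  if (lambda == 0 && (ncol(X) > 0) &&
      (length(sv$d) < ncol(X) || min(sv$d) < max(sv$d, 1) * 1e-10))
    stop("design is rank deficient at lambda = 0; use lambda > 0")
  yc <- y - mean(y)
  b <- if (ncol(X) == 0) numeric(0) else ridge_coef_svd(sv, yc, lambda) / cd$s
  structure(list(intercept = mean(y) - sum(cd$xbar * b), coefficients = b,
                 lambda = lambda, family = "gaussian",
                 feature_names = colnames(X)),
            class = "zapforest_ridge")
}

poisson_ridge_objective <- function(X, y, intercept, beta, lambda) {
  eta <- intercept + drop(X %*% beta)
  sum(exp(eta) - y * eta) + lambda * sum(beta^2)
}

#' Ridge-penalized Poisson regression (log link)
#'
#' Minimizes the negative penalized Poisson log-likelihood
#' \deqn{-\sum_i (-\mu_i + y_i \log \mu_i) + \lambda \sum_j \beta_j^2,
#'       \quad \mu_i = \exp(\eta + x_i^\top\beta),}
#' by iteratively reweighted penalized least squares (Newton steps with
#' step halving), intercept unpenalized. Predictions are strictly
#' positive. A fold whose response is all zeros is handled by the
#' intercept limit (a large negative intercept), not an error.
#'
#' @inheritParams fit_ridge
#' @param y Non-negative integer counts.
#' @param tol Convergence tolerance on the maximum coefficient change.
#' @param max_iter Maximum Newton iterations; non-convergence is an error
#'   carrying the iteration trace.
#' @return An object of class `zapforest_ridge` with `family = "poisson"`.
#' @export
fit_poisson_ridge <- function(X, y, lambda, standardize = FALSE,
                              tol = 1e-8, max_iter = 100) {
  X <- as_design(X)
  stopifnot(length(y) == nrow(X), lambda >= 0)
  if (any(y < 0) || any(y != floor(y)))
    stop("`y` must contain non-negative integer counts")
  cd <- center_design(X, standardize)
  Xc <- cd$Xc
  p <- ncol(X)
  ybar_floor <- max(mean(y), 1e-12)  # intercept limit for an all-zero fold
  b0 <- log(ybar_floor)
  b <- numeric(p)
  if (all(y == 0)) {
    # no interior optimum: the likelihood pushes mu to 0; report the
    # intercept limit with zero slopes (predictions ~ 0)
    return(structure(list(intercept = b0, coefficients = b, lambda = lambda,
                          family = "poisson", feature_names = colnames(X),
                          iterations = 0L),
                     class = "zapforest_ridge"))
  }
  drop_const <- apply(Xc, 2, function(v) all(v == 0))
  trace <- numeric(0)
  if (!all(drop_const)) {
    obj <- poisson_ridge_objective(Xc, y, b0, b, lambda)
    converged <- p == 0
    for (it in seq_len(max_iter)) {
      eta <- b0 + drop(Xc %*% b)
      mu <- pmin(exp(eta), 1e10)
      w <- mu
      z <- eta + (y - mu) / mu
      # Newton system for the penalized objective: Hessian X'WX + 2*lambda*D
      A <- crossprod(Xc, Xc * w)
      diag(A) <- diag(A) + 2 * lambda
      A <- rbind(c(sum(w), colSums(Xc * w)), cbind(colSums(Xc * w), A))
      rhs <- c(sum(w * z), crossprod(Xc, w * z))
      sol <- tryCatch(solve(A, rhs), error = function(e) NULL)
      if (is.null(sol)) sol <- drop(MASS_ginv(A) %*% rhs)
      step0 <- sol[1] - b0; step <- sol[-1] - b
      # step halving keeps the Newton iteration monotone
      alpha <- 1
      repeat {
        new_obj <- poisson_ridge_objective(Xc, y, b0 + alpha * step0,
                                           b + alpha * step, lambda)
        if (is.finite(new_obj) && new_obj <= obj + 1e-12) break
        alpha <- alpha / 2
        if (alpha < 1e-8) break
      }
      b0 <- b0 + alpha * step0
      b <- b + alpha * step
      obj <- poisson_ridge_objective(Xc, y, b0, b, lambda)
      delta <- max(abs(c(alpha * step0, alpha * step)))
      trace <- c(trace, delta)
      if (delta < tol) { converged <- TRUE; break }
    }
    if (!converged)
      stop("Poisson ridge IRLS did not converge in ", max_iter,
           " iterations; max coefficient changes: ",
           paste(signif(utils::tail(trace, 5), 3), collapse = ", "))
  }
  b <- b / cd$s
  structure(list(intercept = b0 - sum(cd$xbar * b), coefficients = b,
                 lambda = lambda, family = "poisson",
                 feature_names = colnames(X), iterations = length(trace)),
            class = "zapforest_ridge")
}

# small pseudo-inverse fallback (avoids a MASS dependency)
MASS_ginv <- function(A, tol = 1e-12) {
  s <- svd(A)
  pos <- s$d > tol * max(s$d)
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' @export
predict.zapforest_ridge <- function(object, newdata, ...) {
  newdata <- as_design(newdata)
  if (ncol(newdata) != length(object$coefficients))
    stop("newdata has ", ncol(newdata), " columns; model has ",
         length(object$coefficients))
  eta <- object$intercept + drop(newdata %*% object$coefficients)
  if (object$family == "poisson") exp(eta) else eta
}

#' @export
print.zapforest_ridge <- function(x, ...) {
  cat("Penalized ", x$family, " regression: p = ", length(x$coefficients),
      ", lambda = ", signif(x$lambda, 4), "\n", sep = "")
  invisible(x)
}

#' Default penalty grid
#'
#' 100 values log-spaced over `[lambda_max * 1e-4, lambda_max]` with
#' `lambda_max = max_j |sum_i x_ij (y_i - ybar)| / n`.
#'
#' @inheritParams fit_ridge
#' @param length Grid size.
#' @return Decreasing numeric vector of penalties.
#' @export
default_lambda_grid <- function(X, y, length = 100) {
  X <- as_design(X)
  lmax <- max(abs(crossprod(X, y - mean(y)))) / nrow(X)
  if (!is.finite(lmax) || lmax <= 0) lmax <- 1
  exp(seq(log(lmax), log(lmax * 1e-4), length.out = length))
}

#' Cross-validated penalty selection
#'
#' k-fold cross-validation on a penalty grid; the selected `lambda`
#' minimizes the mean held-out MAE, with ties broken toward the largest
#' penalty (stronger regularization).
#'
#' @inheritParams fit_ridge
#' @param family `"gaussian"` (ridge regression) or `"poisson"`
#'   (ridge-penalized Poisson regression).
#' @param k_folds Number of folds (the benchmark protocol uses 10).
#' @param grid Penalty grid; default [default_lambda_grid()].
#' @param seed Seed for the fold assignment.
#' @return The selected penalty (scalar); the full CV curve is attached as
#'   attribute `"cv"`.
#' @export
select_lambda <- function(X, y, family = c("gaussian", "poisson"),
                          k_folds = 10, grid = NULL, seed = 1,
                          standardize = FALSE) {
  family <- match.arg(family)
  X <- as_design(X)
  stopifnot(k_folds >= 2)
  if (is.null(grid)) grid <- default_lambda_grid(X, y)
  if (length(grid) == 0) stop("`grid` must be nonempty")
  grid <- sort(grid, decreasing = TRUE)
  folds <- make_folds(nrow(X), k_folds, seed)
  err <- matrix(NA_real_, length(grid), k_folds)
  for (f in seq_len(k_folds)) {
    tr <- folds != f
    if (family == "gaussian") {
      cd <- center_design(X[tr, , drop = FALSE], standardize)
      sv <- svd(cd$Xc)
      yc <- y[tr] - mean(y[tr])
      for (g in seq_along(grid)) {
        b <- ridge_coef_svd(sv, yc, grid[g]) / cd$s
        a <- mean(y[tr]) - sum(cd$xbar * b)
        pred <- a + drop(X[!tr, , drop = FALSE] %*% b)
        err[g, f] <- mae(y[!tr], pred)
      }
    } else {
      for (g in seq_along(grid)) {
        fit <- fit_poisson_ridge(X[tr, , drop = FALSE], y[tr], grid[g],
                                 standardize = standardize)
        err[g, f] <- mae(y[!tr], predict(fit, X[!tr, , drop = FALSE]))
      }
    }
  }
  cv <- rowMeans(err)
  best <- grid[which.min(cv)]  # grid is decreasing: ties pick the largest
  attr(best, "cv") <- data.frame(lambda = grid, mae = cv)
  best
}
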
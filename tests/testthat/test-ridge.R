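test_that("ridge: OLS at lambda 0, closed form, shrinkage limits", {
  set.seed(51)
  X <- matrix(rnorm(20), 10, 2)
  y <- rnorm(10, X[, 1])
  f0 <- fit_ridge(X, y, lambda = 0)
  ols <- lm(y ~ X)
  expect_equal(f0$intercept, unname(coef(ols)[1]), tolerance = 1e-10)
  expect_equal(unname(f0$coefficients), unname(coef(ols)[-1]),
               tolerance = 1e-10)

  # hand-evaluated centered closed form: slope Sxy/(Sxx + lambda)
  fh <- fit_ridge(matrix(c(0, 0, 1, 1)), c(1, 1, 3, 3), lambda = 1)
  expect_equal(unname(fh$coefficients), 1)
  expect_equal(fh$intercept, 1.5)

  fbig <- fit_ridge(X, y, lambda = 1e9)
  expect_lt(max(abs(fbig$coefficients)), 1e-6)
  expect_equal(fbig$intercept, mean(y), tolerance = 1e-6)

  Xdef <- cbind(1:6, (1:6) * 2)  # collinear
  expect_error(fit_ridge(Xdef, rnorm(6), lambda = 0), "lambda > 0")
})

test_that("ridge solution minimizes the printed penalized loss", {
  set.seed(52)
  n <- 8; p <- 3
  X <- matrix(rnorm(n * p), n, p)
  y <- rnorm(n)
  lam <- 0.7
  f <- fit_ridge(X, y, lam)
  loss <- function(b0, b) sum((y - b0 - X %*% b)^2) + lam * sum(b^2)
  opt <- optim(rep(0, p + 1),
               function(par) loss(par[1], par[-1]),
               method = "BFGS", control = list(maxit = 2000, reltol = 1e-14))
  expect_equal(loss(f$intercept, f$coefficients), opt$value,
               tolerance = 1e-6)
  expect_lte(loss(f$intercept, f$coefficients), opt$value + 1e-8)
})

test_that("poisson ridge: intercept limits and local optimality", {
  y <- c(1, 2, 3, 4, 5)
  f0 <- fit_poisson_ridge(matrix(0, 5, 1), y, lambda = 1)
  expect_equal(f0$intercept, log(3), tolerance = 1e-10)
  expect_equal(unname(f0$coefficients), 0)

  set.seed(53)
  X <- matrix(rnorm(20 * 3), 20, 3)
  y2 <- rpois(20, exp(0.5 + 0.4 * X[, 1]))
  fbig <- fit_poisson_ridge(X, y2, lambda = 1e9)
  expect_lt(max(abs(fbig$coefficients)), 1e-5)
  expect_equal(fbig$intercept, log(mean(y2)), tolerance = 1e-4)

  lam <- 0.5
  f <- fit_poisson_ridge(X, y2, lam)
  obj <- function(b0, b) sum(exp(b0 + X %*% b) - y2 * (b0 + X %*% b)) +
    lam * sum(b^2)
  at <- obj(f$intercept, f$coefficients)
  for (i in 1:2000) {
    d <- rnorm(4, sd = 1e-3)
    expect_gte(obj(f$intercept + d[1], f$coefficients + d[-1]) + 1e-12, at)
  }
  expect_true(all(predict(f, X) > 0))

  # all-zero response handled by the intercept limit, not an error
  fz <- fit_poisson_ridge(X, rep(0, 20), lambda = 1)
  expect_lt(max(predict(fz, X)), 1e-6)
})

test_that("coefficient norm is non-increasing in lambda", {
  set.seed(54)
  for (rep in 1:30) {
    n <- sample(8:20, 1); p <- sample(2:6, 1)
    X <- matrix(rnorm(n * p), n, p)
    y <- rnorm(n, X %*% rnorm(p))
    grid <- exp(seq(log(1e-3), log(100), length.out = 20))
    norms <- sapply(grid, function(l)
      sum(fit_ridge(X, y, l)$coefficients^2))
    expect_true(all(diff(norms) <= 1e-10))
  }
})

test_that("lambda selection: contracts and noise behavior", {
  set.seed(55)
  X <- matrix(rnorm(40 * 5), 40, 5)
  y <- rnorm(40, X[, 1])
  expect_equal(as.numeric(select_lambda(X, y, "gaussian", grid = 0.37)),
               0.37)
  a <- select_lambda(X, y, "gaussian", seed = 3)
  b <- select_lambda(X, y, "gaussian", seed = 3)
  expect_identical(as.numeric(a), as.numeric(b))

  # pure noise: shrinkage dominates, lambda lands high in the grid
  hits <- 0
  for (s in 1:25) {
    set.seed(600 + s)
    Xn <- matrix(rnorm(40 * 8), 40, 8)
    yn <- rnorm(40)
    grid <- exp(seq(log(0.01), log(100), length.out = 20))
    lam <- as.numeric(select_lambda(Xn, yn, "gaussian", k_folds = 5,
                                    grid = grid, seed = s))
    if (lam >= sort(grid, decreasing = TRUE)[5]) hits <- hits + 1
  }
  expect_gte(hits, 20)

  # poisson path works end to end
  yp <- rpois(40, 2)
  lam_p <- select_lambda(X, yp, "poisson", k_folds = 4,
                         grid = c(0.1, 1, 10), seed = 1)
  expect_true(as.numeric(lam_p) %in% c(0.1, 1, 10))
})
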
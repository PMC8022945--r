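test_that("hurdle fit guards degenerate responses", {
  X <- matrix(runif(80), 40, 2)
  expect_error(fit_zap(X, rep(0, 40)), "truncated part")
  expect_error(fit_zap(X, 1 + rpois(40, 2)), "zero part")
  expect_error(fit_zap(X, c(rep(0, 37), 1, 1, 2), nodesize = 5),
               "positive")
  expect_error(fit_zap(X, c(rep(0, 20), 1 + rpois(20, 2)), threshold = 1),
               "threshold")
})

test_that("prediction identities: ZAP mean formula and threshold rule", {
  set.seed(41)
  X <- matrix(rbinom(300, 1, 0.5), 100, 3)
  y <- rzap(100, plogis(1.5 * X[, 1] - 0.8), exp(0.7 + 0.8 * X[, 2]))
  m <- fit_zap(X, y, ntree = 40, mtry = 2, nodesize = 4, seed = 6)
  parts <- predict(m, X, type = "parts")
  # exact algebraic identity with the distribution mean
  expect_identical(predict(m, X, type = "mean"),
                   zap_moments(parts$theta, parts$mu)$mean)
  expect_equal(predict(m, X, type = "mean"),
               (1 - parts$theta) * parts$mu / (1 - exp(-parts$mu)),
               tolerance = 1e-14)
  cls <- predict(m, X, type = "class")
  expect_identical(cls, ifelse(parts$theta > 0.5, 0, parts$mu))
  expect_true(any(cls == 0) && any(cls > 0))
})

test_that("theta-hat exactly at the threshold goes to the count branch", {
  # constant feature and no bootstrap: every zero-part tree is a single
  # leaf with class-1 proportion exactly 1/2
  m <- structure(list(
    zero_forest = fit_forest(matrix(0, 4, 1), c(1, 1, 0, 0), "gini",
                             ntree = 3, mtry = 1, nodesize = 1,
                             bootstrap = FALSE, seed = 1),
    pos_forest = fit_forest(matrix(0, 2, 1), c(3, 3), "ztp", ntree = 3,
                            mtry = 1, nodesize = 1, bootstrap = FALSE,
                            seed = 2),
    threshold = 0.5, seed = 1, p = 1L, feature_names = NULL),
    class = "zapforest_zap")
  parts <- predict(m, matrix(0, 1, 1), type = "parts")
  expect_identical(parts$theta, 0.5)
  expect_gt(parts$mu, 1)  # m(mu) = 3
  expect_identical(predict(m, matrix(0, 1, 1), type = "class"), parts$mu)
})

test_that("the hurdle mean is monotone in each part", {
  th <- seq(0, 0.95, by = 0.05)
  expect_true(all(diff(zap_moments(th, 2)$mean) < 0))
  mus <- seq(0.2, 8, by = 0.2)
  expect_true(all(diff(zap_moments(0.3, mus)$mean) > 0))
})

test_that("fits are deterministic and parts live in valid ranges", {
  set.seed(42)
  X <- matrix(rbinom(200, 1, 0.4), 50, 4)
  y <- rzap(50, 0.4, 2)
  a <- predict(fit_zap(X, y, ntree = 10, mtry = 2, nodesize = 3, seed = 3),
               X, type = "parts")
  b <- predict(fit_zap(X, y, ntree = 10, mtry = 2, nodesize = 3, seed = 3),
               X, type = "parts")
  expect_identical(a, b)
  expect_true(all(a$theta >= 0 & a$theta <= 1))
  expect_true(all(a$mu > 0))
})

test_that("constant zero probability is recovered without covariate signal", {
  set.seed(43)
  n_tr <- 600; n_te <- 500
  X <- matrix(rbinom((n_tr + n_te) * 10, 1, 0.5), n_tr + n_te, 10)
  y <- rzap(n_tr + n_te, theta = 0.5, mu = 2)
  m <- fit_zap(X[1:n_tr, ], y[1:n_tr], ntree = 100, mtry = 3,
               nodesize = 10, seed = 7)
  th <- predict(m, X[(n_tr + 1):(n_tr + n_te), ], type = "parts")$theta
  se <- sqrt(0.25 / n_tr)
  expect_lt(abs(mean(th) - 0.5), 3 * se)
})

test_that("marker-driven theta and mu are recovered on the synthetic world", {
  # strong-signal recovery at the stated scale: n = 600 training records,
  # p = 200 markers, 300 trees per part, fresh test lines
  M <- simulate_markers(267, 200, seed = 11)
  eff <- effect_config(200, seed = 12)
  ds <- simulate_zap_phenotypes(M, c("Env1", "Env2", "Env3"), eff, seed = 13)
  X <- build_design(ds)
  y <- ds$records$count
  tr <- ds$records$line %in% rownames(M)[1:200]
  expect_equal(sum(tr), 600)
  m <- fit_zap(X[tr, ], y[tr], ntree = 300, mtry = 50, nodesize = 5,
               seed = 1)
  parts <- predict(m, X[!tr, ], type = "parts")
  expect_gt(cor(parts$theta, ds$truth$theta[!tr], method = "spearman"), 0.6)
  expect_gt(cor(parts$mu, ds$truth$mu[!tr], method = "spearman"), 0.6)
})

test_that("alternative truncated-part aggregation is available and close", {
  set.seed(44)
  X <- matrix(rbinom(200, 1, 0.4), 50, 4)
  y <- rzap(50, 0.3, 2.5)
  m <- fit_zap(X, y, ntree = 20, mtry = 2, nodesize = 3, seed = 2)
  p_mu <- predict(m, X, type = "parts", aggregate = "mu")
  p_mean <- predict(m, X, type = "parts", aggregate = "mean")
  expect_false(identical(p_mu$mu, p_mean$mu))
  expect_equal(p_mu$mu, p_mean$mu, tolerance = 0.5)  # same scale
})
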
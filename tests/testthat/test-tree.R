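test_that("node scores: worked values and criterion/response guards", {
  expect_equal(node_score(c(3, 3, 3), "ls"), 0)
  expect_equal(node_score(c(0, 0, 1, 1), "gini"), 4 * 0.5 * 0.5)
  mu <- ztp_mle(c(1, 2, 3))
  expect_equal(node_score(c(1, 2, 3), "ztp"),
               -3 * log(1 - exp(-mu)) + log(mu) * 6 - 3 * mu -
                 log(2) - log(6),
               tolerance = 1e-10)
  expect_error(node_score(c(0, 2), "gini"), "0/1")
  expect_error(node_score(c(0, 2), "ztp"), ">= 1")
})

test_that("best split: worked ZTP case, constant response, invariances", {
  X <- matrix(c(0, 0, 1, 1))
  s <- best_split(X, c(1, 1, 5, 5), "ztp", nodesize = 1)
  expect_equal(s$feature, 1)
  expect_equal(s$threshold, 0.5)
  # gain equals the partial-LL difference with mu-hat = MU_MIN (left,
  # both counts 1) and mu-hat solving m(mu) = 5 (right)
  pll <- function(y) {
    mu <- oracle_ztp_mu(mean(y)); n <- length(y)
    -n * log(-expm1(-mu)) + log(mu) * sum(y) - n * mu
  }
  expect_equal(s$gain, pll(c(1, 1)) + pll(c(5, 5)) - pll(c(1, 1, 5, 5)),
               tolerance = 1e-9)
  expect_null(best_split(matrix(runif(8), 4, 2), c(2, 2, 2, 2), "ztp"))
  expect_null(best_split(X, c(7, 7, 7, 7), "ls"))
  # row-permutation invariance of the chosen split
  set.seed(10)
  inst <- random_split_instance("ls", 99)
  perm <- sample(nrow(inst$X))
  a <- best_split(inst$X, inst$y, "ls", nodesize = inst$nodesize)
  b <- best_split(inst$X[perm, ], inst$y[perm], "ls",
                  nodesize = inst$nodesize)
  expect_equal(a[c("feature", "threshold")], b[c("feature", "threshold")])
})

test_that("best split matches the exhaustive enumeration oracle", {
  # quick version; the acceptance suite runs the full 200-instance sweep
  for (crit in c("ls", "gini", "ztp")) {
    for (seed in 1:15) {
      inst <- random_split_instance(crit, seed * 31 + match(crit, c("ls", "gini", "ztp")))
      got <- best_split(inst$X, inst$y, crit, nodesize = inst$nodesize)
      exp <- oracle_best_split(inst$X, inst$y, crit, inst$nodesize)
      if (is.null(exp)) {
        expect_null(got)
      } else {
        expect_identical(got$feature, exp$feature)
        expect_identical(got$threshold, exp$threshold)
      }
    }
  }
})

test_that("chosen ZTP split never decreases the children's summed log-likelihood", {
  set.seed(4)
  for (i in 1:25) {
    inst <- random_split_instance("ztp", 1000 + i)
    s <- best_split(inst$X, inst$y, "ztp", nodesize = inst$nodesize)
    if (is.null(s)) next
    l <- inst$X[, s$feature] <= s$threshold
    parent_ll <- ztp_loglik(inst$y, ztp_mle(inst$y))
    child_ll <- ztp_loglik(inst$y[l], ztp_mle(inst$y[l])) +
      ztp_loglik(inst$y[!l], ztp_mle(inst$y[!l]))
    expect_gte(child_ll + 1e-9, parent_ll)
  }
})

test_that("grow_tree: leaves, interpolation, determinism", {
  t1 <- grow_tree(matrix(1.0), 3.2, "ls")
  expect_equal(predict(t1, matrix(c(1, 5), 2, 1)), c(3.2, 3.2))

  set.seed(8)
  X <- matrix(runif(60), 20, 3)
  y <- rnorm(20)
  tr <- grow_tree(X, y, "ls", mtry = 3, nodesize = 1, seed = 2)
  expect_equal(predict(tr, X), y, tolerance = 1e-12)

  tr2 <- grow_tree(X, y, "ls", mtry = 3, nodesize = 1, seed = 2)
  expect_identical(tr$nodes, tr2$nodes)

  # depth-1 tree on a 0/1 marker routes by the 0.5 threshold
  td <- grow_tree(matrix(c(0, 0, 1, 1)), c(1, 1, 4, 4), "ls", nodesize = 1)
  expect_equal(predict(td, matrix(c(0, 1))), c(1, 4))
  expect_error(predict(td, matrix(0, 1, 2)), "columns")

  # mtry restriction is honored under a fixed stream
  tz <- grow_tree(X, 1 + rpois(20, 2), "ztp", mtry = 1, nodesize = 2,
                  seed = 5)
  expect_s3_class(tz, "zapforest_tree")
  expect_true(all(tz$nodes$value[tz$nodes$feature == -1] > 0))
})

test_that("max_depth limits growth", {
  set.seed(9)
  X <- matrix(runif(200), 100, 2)
  y <- rnorm(100)
  t_deep <- grow_tree(X, y, "ls", nodesize = 1, seed = 1)
  t_stump <- grow_tree(X, y, "ls", nodesize = 1, max_depth = 1, seed = 1)
  expect_lte(length(t_stump$nodes$feature), 3)
  expect_gt(length(t_deep$nodes$feature), 3)
})
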
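# Independent oracles used across test files. These re-derive expected
# values by brute force / closed forms and must stay independent of the
# package's code paths they check.

# Invert mean = mu / (1 - exp(-mu)) by stats::uniroot (bisection-based),
# independent of the package's Newton solver.
oracle_ztp_mu <- function(m) {
  if (m <= 1 + 1e-8) return(1e-8)
  stats::uniroot(function(mu) mu / (-expm1(-mu)) - m,
                 c(1e-12, 2 * max(m, 2)), tol = 1e-14)$root
}

# Exhaustive-enumeration best split. For "ztp" the FULL log-likelihood
# (including the log-factorial term) is used, which doubles as the check
# that dropping that term changes no chosen split.
oracle_best_split <- function(X, y, criterion, nodesize = 1) {
  child_obj <- function(yv) {
    if (criterion == "ztp") {
      n1 <- length(yv); S <- sum(yv)
      mu <- oracle_ztp_mu(S / n1)
      -(-n1 * log(-expm1(-mu)) + S * log(mu) - n1 * mu - sum(lgamma(yv + 1)))
    } else {
      sum(yv^2) - sum(yv)^2 / length(yv)
    }
  }
  parent <- child_obj(y)
  # same acceptance rule as the implementation: a candidate (enumerated in
  # ascending feature, then ascending threshold order) replaces the
  # incumbent only when it improves by more than eps, so exact-tie
  # partitions resolve identically
  eps <- 1e-9 * (abs(parent) + 1)
  best <- NULL
  best_obj <- parent
  for (j in seq_len(ncol(X))) {
    xs <- sort(unique(X[, j]))
    if (length(xs) < 2) next
    lo <- xs[-length(xs)]; hi <- xs[-1]
    thr <- (lo + hi) / 2
    thr[thr >= hi] <- lo[thr >= hi]
    for (t in thr) {
      l <- X[, j] <= t
      if (sum(l) < nodesize || sum(!l) < nodesize) next
      obj <- child_obj(y[l]) + child_obj(y[!l])
      if (obj < best_obj - eps) {
        best <- list(feature = j, threshold = t, obj = obj)
        best_obj <- obj
      }
    }
  }
  if (is.null(best)) return(NULL)
  list(feature = best$feature, threshold = best$threshold,
       gain = parent - best$obj)
}

# random small split instances per criterion
random_split_instance <- function(criterion, seed) {
  set.seed(seed)
  n <- sample(5:30, 1)
  p <- sample(1:5, 1)
  X <- matrix(0, n, p)
  for (j in seq_len(p))
    X[, j] <- if (runif(1) < 0.5) rbinom(n, 1, runif(1, 0.2, 0.8))
              else round(runif(n, 0, 4), 2)
  y <- switch(criterion,
    ls = rnorm(n, sd = 2),
    gini = rbinom(n, 1, runif(1, 0.2, 0.8)),
    ztp = 1 + rpois(n, runif(1, 0.5, 4)))
  list(X = X, y = as.numeric(y), nodesize = sample(1:3, 1))
}

# O(n^2) average-rank oracle
naive_ranks <- function(x) {
  sapply(seq_along(x), function(i)
    sum(x < x[i]) + (sum(x == x[i]) + 1) / 2)
}

# small dataset builders
toy_dataset <- function(n_lines = 12, p = 6, envs = c("E1", "E2"),
                        seed = 42) {
  M <- simulate_markers(n_lines, p, seed = seed)
  k <- max(1, min(2, p %/% 2))
  eff <- effect_config(p, n_informative_theta = k,
                       n_informative_mu = min(2, p - k),
                       target_zero_rate = 0.35, target_mu_mean = 2.5,
                       env_effects_theta = c(-0.2, 0.2),
                       env_effects_mu = c(-0.1, 0.1), seed = seed + 1)
  simulate_zap_phenotypes(M, envs, eff, seed = seed + 2)
}
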
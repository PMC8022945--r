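# Synthetic genotype/phenotype worlds. The generator emulates the
# structure the hurdle forest assumes: binary 0/1 SNP markers on a set of
# lines, the same lines replicated across environments, and counts drawn
# from a zero-altered Poisson whose zero probability (logit link) and
# truncated-Poisson rate (log link) are sparse linear functions of the
# markers plus environment offsets.

local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Simulate a binary SNP marker matrix
#'
#' Entry `(i, j)` is Bernoulli with a per-marker presence frequency drawn
#' uniformly from `maf_range` (markers coded 0 = absence, 1 = presence, as
#' in post-QC genotyping panels).
#'
#' @param n_lines Number of lines (rows).
#' @param p Number of markers (columns); `p = 0` gives a valid empty matrix.
#' @param maf_range Lower/upper presence frequency, within `(0, 1)`.
#' @param seed Integer seed.
#' @return `n_lines x p` 0/1 matrix, rows `L001, ...`, columns `V1, ...`.
#' @export
simulate_markers <- function(n_lines, p, maf_range = c(0.1, 0.5), seed = 1) {
  stopifnot(maf_range[1] > 0, maf_range[2] < 1,
            maf_range[1] <= maf_range[2], n_lines >= 1, p >= 0)
  local_seed(seed, {
    maf <- stats::runif(p, maf_range[1], maf_range[2])
    M <- matrix(stats::rbinom(n_lines * p, 1, rep(maf, each = n_lines)),
                nrow = n_lines, ncol = p)
    dimnames(M) <- list(sprintf("L%03d", seq_len(n_lines)),
                        if (p > 0) paste0("V", seq_len(p)))
    M
  })
}

#' Effect architecture for the phenotype simulator
#'
#' Sparse additive linear predictors on the link scales: `n_informative_*`
#' markers receive alternating-sign effects of the given size; the two
#' informative sets are disjoint (different predictors drive each part, as
#' the two-part model allows). Intercepts are calibrated at simulation
#' time so that the mean zero probability and mean rate over the generated
#' records hit `target_zero_rate` and `target_mu_mean`.
#'
#' @param p Number of markers.
#' @param n_informative_theta,n_informative_mu Informative marker counts
#'   for the zero and truncated parts.
#' @param theta_effect_size Logit-scale effect magnitude (zero part).
#' @param mu_effect_size Log-scale effect magnitude (truncated part).
#' @param target_zero_rate Mean structural-zero probability over records.
#' @param target_mu_mean Mean truncated-Poisson rate over records.
#' @param env_effects_theta,env_effects_mu Per-environment offsets
#'   (recycled to the number of environments at simulation time); defaults
#'   are small spreads around 0.
#' @param seed Seed for the choice of informative markers.
#' @return A list of class `zap_effect_config`.
#' @export
effect_config <- function(p, n_informative_theta = 10, n_informative_mu = 10,
                          theta_effect_size = 0.9, mu_effect_size = 0.5,
                          target_zero_rate = 0.35, target_mu_mean = 2.5,
                          env_effects_theta = c(-0.3, 0, 0.3),
                          env_effects_mu = c(-0.2, 0, 0.2),
                          seed = 1) {
  stopifnot(n_informative_theta + n_informative_mu <= p,
            target_zero_rate > 0, target_zero_rate < 1, target_mu_mean > 1)
  idx <- local_seed(seed, sample.int(p, n_informative_theta + n_informative_mu))
  alt <- function(k) rep_len(c(1, -1), k)
  structure(list(
    p = p,
    theta_idx = sort(idx[seq_len(n_informative_theta)]),
    mu_idx = sort(idx[n_informative_theta + seq_len(n_informative_mu)]),
    theta_effects = alt(n_informative_theta) * theta_effect_size,
    mu_effects = alt(n_informative_mu) * mu_effect_size,
    target_zero_rate = target_zero_rate,
    target_mu_mean = target_mu_mean,
    env_effects_theta = env_effects_theta,
    env_effects_mu = env_effects_mu,
    seed = seed
  ), class = "zap_effect_config")
}

#' Simulate zero-altered Poisson phenotypes on a marker matrix
#'
#' For every line x environment record, the structural-zero probability
#' comes from a logit-linear predictor and the truncated-Poisson rate from
#' a log-linear predictor (markers plus environment offsets; intercepts
#' calibrated to the targets in `effects`); the count is then a
#' zero-altered Poisson draw. Under this hurdle construction
#' `P(count = 0) = theta` exactly — sampling zeros cannot arise from the
#' truncated part. The generating `(theta, mu)` per record are returned
#' for parameter-recovery tests.
#'
#' @param markers 0/1 line x marker matrix (rows named by line).
#' @param environments Character vector of environment labels.
#' @param effects A [effect_config()] object with `p = ncol(markers)`.
#' @param seed Seed for the count draws.
#' @return A [genomic_dataset()] whose `truth` element is a data frame
#'   with per-record `theta` and `mu`.
#' @export
simulate_zap_phenotypes <- function(markers, environments, effects,
                                    seed = 1) {
  stopifnot(inherits(effects, "zap_effect_config"),
            ncol(markers) == effects$p)
  lines <- rownames(markers)
  if (is.null(lines)) lines <- sprintf("L%03d", seq_len(nrow(markers)))
  records <- expand.grid(line = lines, environment = environments,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  M <- markers[records$line, , drop = FALSE]
  env_t <- rep_len(effects$env_effects_theta, length(environments))
  env_m <- rep_len(effects$env_effects_mu, length(environments))
  ei <- match(records$environment, environments)

  lp_t <- drop(M[, effects$theta_idx, drop = FALSE] %*% effects$theta_effects) +
    env_t[ei]
  lp_m <- drop(M[, effects$mu_idx, drop = FALSE] %*% effects$mu_effects) +
    env_m[ei]

  # intercept calibration to the stated targets
  a0 <- stats::uniroot(
    function(a) mean(stats::plogis(a + lp_t)) - effects$target_zero_rate,
    c(-50, 50), tol = 1e-12)$root
  c0 <- log(effects$target_mu_mean) - log(mean(exp(lp_m)))

  theta <- pmin(pmax(stats::plogis(a0 + lp_t), 1e-6), 1 - 1e-6)
  mu <- exp(c0 + lp_m)
  counts <- local_seed(seed, rzap(nrow(records), theta, mu))
  records$count <- as.integer(counts)
  ds <- genomic_dataset(lines = lines, environments = environments,
                        markers = markers, records = records)
  ds$truth <- data.frame(theta = theta, mu = mu)
  ds$effects <- effects
  ds
}

#' Preset synthetic worlds
#'
#' `dataset1_like()` mirrors the shape of a small wheat Fusarium-severity
#' panel: 115 lines, 1635 binary markers, 3 environments, about 35%
#' zeros, positive-part rate around 2.5 (`p` can be truncated for
#' desk-scale runs — the informative markers sit inside any truncation of
#' at least 30 columns). `dataset2_like()` mirrors a larger panel: 438
#' lines, 11,617 markers, 6 environments, about 6% zeros and a rate
#' around 6.4.
#'
#' @param seed Master seed (markers, effects and counts derive from it).
#' @param p Number of markers kept.
#' @param n_lines Number of lines.
#' @return A [genomic_dataset()] with `truth` attached.
#' @export
dataset1_like <- function(seed = 1, p = 1635, n_lines = 115) {
  M <- simulate_markers(n_lines, p, maf_range = c(0.1, 0.5), seed = seed)
  k <- min(10, (p + 1) %/% 3)  # scales down for very small p
  eff <- effect_config(p,
                       n_informative_theta = k, n_informative_mu = k,
                       theta_effect_size = 0.9, mu_effect_size = 0.5,
                       target_zero_rate = 0.35, target_mu_mean = 2.5,
                       env_effects_theta = c(-0.3, 0, 0.3),
                       env_effects_mu = c(-0.2, 0, 0.2),
                       seed = seed + 1)
  # keep the informative markers inside desk-scale truncations
  eff$theta_idx <- seq_len(k) * 3 - 2           # V1, V4, ..., V28
  eff$mu_idx <- seq_len(k) * 3 - 1              # V2, V5, ..., V29
  simulate_zap_phenotypes(M, c("Env1", "Env2", "Env3"), eff,
                          seed = seed + 2)
}

#' @rdname dataset1_like
#' @export
dataset2_like <- function(seed = 1, p = 11617, n_lines = 438) {
  M <- simulate_markers(n_lines, p, maf_range = c(0.1, 0.5), seed = seed)
  k <- min(15, (p + 1) %/% 3)
  eff <- effect_config(p,
                       n_informative_theta = k, n_informative_mu = k,
                       theta_effect_size = 0.9, mu_effect_size = 0.4,
                       target_zero_rate = 0.06, target_mu_mean = 6.4,
                       env_effects_theta = seq(-0.3, 0.3, length.out = 6),
                       env_effects_mu = seq(-0.15, 0.15, length.out = 6),
                       seed = seed + 1)
  eff$theta_idx <- seq_len(k) * 3 - 2
  eff$mu_idx <- seq_len(k) * 3 - 1
  simulate_zap_phenotypes(M, paste0("Env", 1:6), eff, seed = seed + 2)
}
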
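#' Random fold assignment
#'
#' Seeded uniform partition of `n` records into `k` folds with sizes
#' differing by at most one (single replication).
#'
#' @param n Number of records.
#' @param k Number of folds.
#' @param seed Integer seed (local to the call; R's RNG state is
#'   restored).
#' @return Integer vector of fold ids in `1..k`, length `n`.
#' @export
make_folds <- function(n, k, seed = 1) {
  if (k > n) stop("more folds than records")
  if (k < 2) stop("need k >= 2")
  local_seed(seed, sample(rep_len(seq_len(k), n)))
}

#' Default forest hyperparameter grids
#'
#' `ntree` (100, 300, 500) and `nodesize` (2, 5, 15) for both scales;
#' `mtry` (30, 50, 100) for the small-panel scale and (150, 230, 320) for
#' the large-panel scale.
#'
#' @param scale `"small"` or `"large"`.
#' @return List with `ntree`, `mtry`, `nodesize` vectors.
#' @export
default_grid <- function(scale = c("small", "large")) {
  scale <- match.arg(scale)
  list(ntree = c(100, 300, 500),
       mtry = if (scale == "small") c(30, 50, 100) else c(150, 230, 320),
       nodesize = c(2, 5, 15))
}

grid_combinations <- function(grid) {
  if (is.data.frame(grid)) {
    stopifnot(all(c("ntree", "mtry", "nodesize") %in% names(grid)))
    return(grid[, c("ntree", "mtry", "nodesize")])
  }
  expand.grid(ntree = grid$ntree, mtry = grid$mtry,
              nodesize = grid$nodesize, KEEP.OUT.ATTRS = FALSE)
}

#' Inner-CV forest hyperparameter tuning
#'
#' Evaluates each `(ntree, mtry, nodesize)` combination by mean held-out
#' MAE over `inner_k` folds of the supplied training data and returns the
#' minimizer. Ties go to the smaller `ntree`, then the larger `nodesize`
#' (the cheaper / smoother model), then the smaller `mtry`. A combination
#' that is unfittable on some inner fold (e.g. no positive counts) is
#' skipped with a warning; if all are skipped this is an error.
#'
#' `grid` is either a list of value vectors (full factorial, the default
#' protocol) or a data frame of explicit `(ntree, mtry, nodesize)` rows
#' for a restricted search.
#'
#' @param X,y Training design and counts (never the outer test fold).
#' @param model `"rf"` (least-squares forest) or `"zap"` (hurdle forest,
#'   scored by its expected-value predictions; both parts share the
#'   candidate hyperparameters).
#' @param grid See above; default [default_grid()].
#' @param inner_k Number of inner folds.
#' @param seed Seed for the inner fold assignment.
#' @return List `ntree`, `mtry`, `nodesize`, `mae`; the full grid curve is
#'   attached as attribute `"results"`.
#' @export
tune_forest <- function(X, y, model = c("rf", "zap"), grid = default_grid(),
                        inner_k = 5, seed = 1) {
  model <- match.arg(model)
  X <- as_design(X)
  combos <- grid_combinations(grid)
  if (nrow(combos) == 0) stop("empty hyperparameter grid")
  folds <- make_folds(nrow(X), inner_k, seed)
  combos$mae <- NA_real_
  for (i in seq_len(nrow(combos))) {
    errs <- numeric(inner_k)
    ok <- TRUE
    for (f in seq_len(inner_k)) {
      tr <- folds != f
      pred <- tryCatch({
        if (model == "rf") {
          fit <- fit_forest(X[tr, , drop = FALSE], y[tr], "ls",
                            ntree = combos$ntree[i], mtry = combos$mtry[i],
                            nodesize = combos$nodesize[i], seed = seed + f)
          predict(fit, X[!tr, , drop = FALSE])
        } else {
          fit <- fit_zap(X[tr, , drop = FALSE], y[tr],
                         ntree = combos$ntree[i], mtry = combos$mtry[i],
                         nodesize = combos$nodesize[i], seed = seed + f)
          predict(fit, X[!tr, , drop = FALSE], type = "mean")
        }
      }, error = function(e) e)
      if (inherits(pred, "error")) {
        warning("skipping (ntree=", combos$ntree[i], ", mtry=",
                combos$mtry[i], ", nodesize=", combos$nodesize[i],
                ") on inner fold ", f, ": ", conditionMessage(pred))
        ok <- FALSE
        break
      }
      errs[f] <- mae(y[!tr], pred)
    }
    if (ok) combos$mae[i] <- mean(errs)
  }
  if (all(is.na(combos$mae)))
    stop("every hyperparameter combination failed during inner tuning")
  ord <- order(combos$mae, combos$ntree, -combos$nodesize, combos$mtry)
  best <- combos[ord[1], ]
  out <- list(ntree = best$ntree, mtry = best$mtry,
              nodesize = best$nodesize, mae = best$mae)
  attr(out, "results") <- combos
  out
}

fit_and_predict <- function(model, X_tr, y_tr, X_te, params, lambda_k,
                            threshold, seed) {
  switch(model,
    RF = {
      fit <- fit_forest(X_tr, y_tr, "ls", ntree = params$ntree,
                        mtry = params$mtry, nodesize = params$nodesize,
                        seed = seed)
      list(fit = fit, pred = predict(fit, X_te))
    },
    ZAP_RF = ,
    ZAPC_RF = {
      fit <- fit_zap(X_tr, y_tr, ntree = params$ntree, mtry = params$mtry,
                     nodesize = params$nodesize, threshold = threshold,
                     seed = seed)
      type <- if (model == "ZAP_RF") "mean" else "class"
      list(fit = fit, pred = predict(fit, X_te, type = type))
    },
    RR = {
      lam <- select_lambda(X_tr, y_tr, "gaussian", k_folds = lambda_k,
                           seed = seed)
      fit <- fit_ridge(X_tr, y_tr, lambda = as.numeric(lam))
      list(fit = fit, pred = predict(fit, X_te))
    },
    GPR = {
      lam <- select_lambda(X_tr, y_tr, "poisson", k_folds = lambda_k,
                           seed = seed)
      fit <- fit_poisson_ridge(X_tr, y_tr, lambda = as.numeric(lam))
      list(fit = fit, pred = predict(fit, X_te))
    },
    stop("unknown model: ", model)
  )
}

metric_row <- function(y, pred) {
  c(SPEARMAN = if (length(y) >= 2) suppressWarnings(spearman_cor(y, pred))
    else NA_real_,
    MAAPE = maape(y, pred),
    MAE = mae(y, pred))
}

#' Nested cross-validation benchmark
#'
#' The full evaluation protocol on one dataset: an outer `k_outer`-fold
#' split of the (line, environment) records; per outer fold, hyperparameter
#' selection on the outer-training data only (inner `inner_k_forest`-fold
#' grid search by MAE for the forests when `tune = TRUE`; inner
#' `inner_k_lambda`-fold penalty selection for the ridge models, always),
#' a refit on the whole outer-training set, and prediction of the held-out
#' fold. Spearman correlation, MAAPE and MAE are reported per environment
#' and across environments as mean and standard error over the outer
#' folds.
#'
#' Across-environment values pool all test records of a fold before
#' computing each metric (`pool = "pool"`); `pool = "average"` instead
#' averages the per-environment values of the fold.
#'
#' The hurdle forest is fit once per fold; `ZAP_RF` (expected value) and
#' `ZAPC_RF` (thresholded) differ only in the prediction rule applied to
#' it.
#'
#' @param dataset A [genomic_dataset()].
#' @param models Subset of `c("RR", "GPR", "RF", "ZAP_RF", "ZAPC_RF")`.
#' @param include_ge Include genotype-by-environment interaction columns
#'   in the design ([build_design()]).
#' @param k_outer Number of outer folds.
#' @param seed Master seed; outer folds, inner folds and forest seeds all
#'   derive from it.
#' @param tune Run the inner grid search for the forest models; otherwise
#'   the fixed `ntree`/`mtry`/`nodesize` below are used.
#' @param grid Forest hyperparameter grid for `tune = TRUE`.
#' @param ntree,mtry,nodesize Fixed forest hyperparameters for
#'   `tune = FALSE` (`mtry = NULL` means `p / 3`).
#' @param threshold ZAPC_RF zero-probability threshold.
#' @param inner_k_forest,inner_k_lambda Inner fold counts (protocol
#'   defaults 5 and 10).
#' @param by_line Partition whole lines instead of records into outer
#'   folds.
#' @param pool Across-environment mode, see above.
#' @param vim Also compute permutation variable importance on each outer
#'   test fold for the forest models and average the tables over folds
#'   (attached as attribute `"vim"`).
#' @param ge_mode Passed to [build_design()].
#' @param hooks Optional list of callbacks; `on_fold(fold, train_idx,
#'   test_idx, params)` is invoked per outer fold (used by tests to audit
#'   train/test isolation).
#' @param verbose Print fold progress.
#' @return Data frame with columns `model`, `environment` (`"all"` = the
#'   across-environment row), `metric`, `mean`, `se`. Attributes:
#'   `"folds"` (the outer fold ids), `"predictions"` (per-record
#'   out-of-fold predictions per model), and `"vim"` when requested.
#' @export
run_benchmark <- function(dataset,
                          models = c("RR", "GPR", "RF", "ZAP_RF", "ZAPC_RF"),
                          include_ge = FALSE, k_outer = 5, seed = 1,
                          tune = FALSE, grid = default_grid(),
                          ntree = 300, mtry = NULL, nodesize = 5,
                          threshold = 0.5, inner_k_forest = 5,
                          inner_k_lambda = 10, by_line = FALSE,
                          pool = c("pool", "average"),
                          vim = FALSE, ge_mode = c("indicator", "product"),
                          hooks = NULL, verbose = FALSE) {
  stopifnot(inherits(dataset, "genomic_dataset"))
  models <- match.arg(models, several.ok = TRUE)
  pool <- match.arg(pool)
  X <- build_design(dataset, include_ge = include_ge,
                    ge_mode = match.arg(ge_mode))
  y <- dataset$records$count
  env <- dataset$records$environment
  n <- nrow(X)
  if (is.null(mtry)) mtry <- max(1, floor(ncol(X) / 3))

  if (by_line) {
    line_fold <- make_folds(length(dataset$lines), k_outer, seed)
    folds <- line_fold[match(dataset$records$line, dataset$lines)]
  } else {
    folds <- make_folds(n, k_outer, seed)
  }

  envs_all <- c(dataset$environments, "all")
  metrics <- c("SPEARMAN", "MAAPE", "MAE")
  vals <- array(NA_real_,
                c(length(models), length(envs_all), 3, k_outer),
                dimnames = list(models, envs_all, metrics, NULL))
  preds <- matrix(NA_real_, n, length(models),
                  dimnames = list(NULL, models))
  vim_tables <- list()

  need_rf_tune <- tune && "RF" %in% models
  need_zap_tune <- tune && any(c("ZAP_RF", "ZAPC_RF") %in% models)

  for (f in seq_len(k_outer)) {
    te <- folds == f
    X_tr <- X[!te, , drop = FALSE]; y_tr <- y[!te]
    X_te <- X[te, , drop = FALSE]; y_te <- y[te]
    fold_seed <- seed * 1000 + f

    params_rf <- params_zap <- list(ntree = ntree, mtry = mtry,
                                    nodesize = nodesize)
    if (need_rf_tune)
      params_rf <- tune_forest(X_tr, y_tr, "rf", grid,
                               inner_k = inner_k_forest, seed = fold_seed)
    if (need_zap_tune)
      params_zap <- tune_forest(X_tr, y_tr, "zap", grid,
                                inner_k = inner_k_forest, seed = fold_seed)
    if (!is.null(hooks$on_fold))
      hooks$on_fold(f, which(!te), which(te),
                    list(rf = params_rf, zap = params_zap))

    zap_fit <- NULL
    for (m in models) {
      if (verbose) message("fold ", f, ": ", m)
      params <- if (m == "RF") params_rf else params_zap
      res <- tryCatch(
        if (m %in% c("ZAP_RF", "ZAPC_RF") && !is.null(zap_fit)) {
          type <- if (m == "ZAP_RF") "mean" else "class"
          list(fit = zap_fit, pred = predict(zap_fit, X_te, type = type))
        } else {
          fit_and_predict(m, X_tr, y_tr, X_te, params, inner_k_lambda,
                          threshold, fold_seed)
        },
        error = function(e)
          stop("model ", m, " failed on outer fold ", f, ": ",
               conditionMessage(e)))
      if (m %in% c("ZAP_RF", "ZAPC_RF")) zap_fit <- res$fit
      preds[te, m] <- res$pred

      for (e in dataset$environments) {
        sel <- env[te] == e
        if (any(sel))
          vals[m, e, , f] <- metric_row(y_te[sel], res$pred[sel])
      }
      vals[m, "all", , f] <- if (pool == "pool") {
        metric_row(y_te, res$pred)
      } else {
        colMeans(vals[m, dataset$environments, , f, drop = FALSE][1, , , 1],
                 na.rm = TRUE)
      }

      if (vim && m %in% c("RF", "ZAP_RF")) {
        tab <- permutation_vim(res$fit, X_te, y_te, n_top = Inf,
                               seed = fold_seed)
        key <- m
        vim_tables[[key]] <- c(vim_tables[[key]], list(tab))
      }
    }
  }

  out <- expand.grid(model = models, environment = envs_all,
                     metric = metrics, KEEP.OUT.ATTRS = FALSE,
                     stringsAsFactors = FALSE)
  out$mean <- NA_real_; out$se <- NA_real_
  for (i in seq_len(nrow(out))) {
    v <- vals[out$model[i], out$environment[i], out$metric[i], ]
    if (sum(!is.na(v)) >= 2) {
      fs <- fold_summary(v)
      out$mean[i] <- fs["mean"]; out$se[i] <- fs["se"]
    }
  }
  attr(out, "folds") <- folds
  attr(out, "predictions") <- preds
  if (vim)
    attr(out, "vim") <- lapply(vim_tables, average_vim)
  out
}

#' Permutation variable importance on a test set
#'
#' For each tree of a fitted forest, the test set is passed through the
#' tree and its prediction error (PE) recorded; each predictor column is
#' then permuted (`n_perm` seeded permutations, averaged) and the PE
#' recomputed. The per-predictor differences are averaged over trees and
#' normalized by their standard deviation across trees (0/0 is reported
#' as 0 — e.g. a predictor never used by any tree). PE is the mean
#' squared error, except for the binary zero-part forest where it is the
#' misclassification rate at 0.5.
#'
#' For a hurdle model two tables are returned: the zero part scored on
#' the indicator `I(y = 0)` over the whole test set, and the truncated
#' part scored on the positive-count subset (squared error of the
#' predicted rate against the positive counts).
#'
#' @param model A `zapforest_forest` or `zapforest_zap`.
#' @param X_test,y_test Held-out test design and counts (for a plain
#'   forest, `y_test` is on the scale of its training response).
#' @param n_top Number of top-ranked predictors returned (`Inf` = all).
#' @param n_perm Permutations per predictor per tree.
#' @param seed Seed of the permutation streams.
#' @return A data frame `feature`, `importance`, `rank`, `part`, sorted by
#'   decreasing importance — or a list of two such tables (`zero`,
#'   `truncated`) for a hurdle model.
#' @export
permutation_vim <- function(model, X_test, y_test, n_top = 30, n_perm = 1,
                            seed = 1) {
  X_test <- as_design(X_test)
  if (inherits(model, "zapforest_zap")) {
    pos <- y_test > 0
    if (!any(pos)) stop("no positive counts in the test set")
    return(list(
      zero = vim_one(model$zero_forest, X_test, as.numeric(y_test == 0),
                     n_top, n_perm, seed, part = "ZERO"),
      truncated = vim_one(model$pos_forest, X_test[pos, , drop = FALSE],
                          y_test[pos], n_top, n_perm, seed,
                          part = "TRUNCATED")))
  }
  if (!inherits(model, "zapforest_forest"))
    stop("`model` must be a forest or hurdle-forest fit")
  vim_one(model, X_test, y_test, n_top, n_perm, seed, part = "SINGLE")
}

vim_one <- function(forest, X, y, n_top, n_perm, seed, part) {
  if (ncol(X) != forest$p)
    stop("test design has ", ncol(X), " columns; model has ", forest$p)
  pe_type <- if (forest$criterion == "gini") 1L else 0L
  D <- cpp_forest_vim(forest$trees, X, as.numeric(y), pe_type,
                      as.integer(n_perm), as.numeric(seed))
  mu <- colMeans(D)
  sdev <- apply(D, 2, stats::sd)
  imp <- ifelse(sdev > 0, mu / sdev, 0)
  nm <- forest$feature_names
  if (is.null(nm)) nm <- paste0("X", seq_len(forest$p))
  tab <- data.frame(feature = nm, importance = imp, part = part,
                    stringsAsFactors = FALSE)
  tab <- tab[order(-tab$importance, tab$feature), ]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  utils::head(tab, n_top)
}

#' Average importance tables over outer folds
#'
#' @param tables List of tables from [permutation_vim()] (or lists of two
#'   tables for hurdle models, averaged part-wise).
#' @return A table (or list of tables) with fold-averaged importance,
#'   re-ranked.
#' @export
average_vim <- function(tables) {
  if (is.data.frame(tables)) return(tables)
  if (!is.data.frame(tables[[1]])) {
    parts <- names(tables[[1]])
    out <- lapply(parts, function(p) average_vim(lapply(tables, `[[`, p)))
    names(out) <- parts
    return(out)
  }
  all_feat <- unique(unlist(lapply(tables, `[[`, "feature")))
  imp <- sapply(tables, function(t)
    t$importance[match(all_feat, t$feature)])
  tab <- data.frame(feature = all_feat,
                    importance = rowMeans(as.matrix(imp), na.rm = TRUE),
                    part = tables[[1]]$part[1], stringsAsFactors = FALSE)
  tab <- tab[order(-tab$importance, tab$feature), ]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  tab
}

#' Bar plot of top-ranked variable importances
#'
#' @param vim A table from [permutation_vim()] (for hurdle models, pass
#'   one part, or the list to get the two panels side by side).
#' @param n_top Number of bars.
#' @param main Title.
#' @return Invisibly, the plotted table(s).
#' @export
plot_vim <- function(vim, n_top = 30, main = NULL) {
  if (!is.data.frame(vim)) {
    op <- graphics::par(mfrow = c(1, length(vim)))
    on.exit(graphics::par(op))
    for (nm in names(vim))
      plot_vim(vim[[nm]], n_top = n_top,
               main = paste(main, nm, "part"))
    return(invisible(vim))
  }
  tab <- utils::head(vim[order(vim$rank), ], n_top)
  graphics::barplot(rev(tab$importance), names.arg = rev(tab$feature),
                    horiz = TRUE, las = 1, cex.names = 0.6,
                    xlab = "permutation importance (mean/sd over trees)",
                    main = if (is.null(main)) tab$part[1] else main)
  invisible(tab)
}
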
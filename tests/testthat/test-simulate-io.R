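test_that("marker simulation: frequencies, determinism, empty case", {
  M <- simulate_markers(1e4, 1, maf_range = c(0.5, 0.5), seed = 1)
  expect_lt(abs(mean(M) - 0.5), 3 * sqrt(0.25 / 1e4))
  expect_identical(simulate_markers(20, 5, seed = 2),
                   simulate_markers(20, 5, seed = 2))
  M0 <- simulate_markers(10, 0, seed = 3)
  expect_equal(dim(M0), c(10, 0))
  expect_true(all(simulate_markers(50, 10, seed = 4) %in% 0:1))
})

test_that("phenotype simulation hits the stated zero fraction", {
  # structural zeros only: P(count = 0) = theta under the hurdle draw
  M <- simulate_markers(2500, 4, seed = 5)
  eff <- effect_config(4, n_informative_theta = 0, n_informative_mu = 0,
                       target_zero_rate = 0.5, target_mu_mean = 2.5,
                       env_effects_theta = c(0, 0, 0, 0),
                       env_effects_mu = c(0, 0, 0, 0), seed = 6)
  ds <- simulate_zap_phenotypes(M, paste0("E", 1:4), eff, seed = 7)
  n <- nrow(ds$records)
  expect_equal(n, 1e4)
  expect_true(all(abs(ds$truth$theta - 0.5) < 1e-9))
  expect_lt(abs(mean(ds$records$count == 0) - 0.5), 3 * sqrt(0.25 / n))

  # near-zero target: counts are essentially pure truncated draws
  eff2 <- effect_config(4, n_informative_theta = 0, n_informative_mu = 0,
                        target_zero_rate = 0.001, target_mu_mean = 2.5,
                        env_effects_theta = 0, env_effects_mu = 0, seed = 8)
  ds2 <- simulate_zap_phenotypes(M[1:1000, ], "E1", eff2, seed = 9)
  expect_lt(mean(ds2$records$count == 0), 0.01)
  expect_gte(min(ds2$records$count[ds2$records$count > 0]), 1)
  # generation is reproducible
  ds3 <- simulate_zap_phenotypes(M[1:1000, ], "E1", eff2, seed = 9)
  expect_identical(ds2$records, ds3$records)
})

test_that("dataset1-like preset has the stated shapes and zero share", {
  ds <- dataset1_like(seed = 3, p = 200)
  expect_length(ds$lines, 115)
  expect_equal(ncol(ds$markers), 200)
  expect_equal(ds$environments, c("Env1", "Env2", "Env3"))
  expect_equal(nrow(ds$records), 345)
  expect_lt(abs(mean(ds$records$count == 0) - 0.35), 0.08)
  expect_lt(abs(mean(ds$truth$theta) - 0.35), 0.01)
  # informative markers survive desk-scale truncation
  expect_true(all(ds$effects$theta_idx <= 30))
  expect_true(all(ds$effects$mu_idx <= 30))
})

test_that("design construction: blocks, one-hot, GE encodings", {
  rec <- expand.grid(line = c("A", "B"), environment = c("E1", "E2"),
                     stringsAsFactors = FALSE)
  rec$count <- c(0, 2, 1, 3)
  M <- matrix(c(0, 1), 2, 1, dimnames = list(c("A", "B"), "V1"))
  ds <- genomic_dataset(c("A", "B"), c("E1", "E2"), M, rec)
  X <- build_design(ds)
  expect_equal(dim(X), c(4, 3))
  expect_equal(colnames(X), c("E1", "E2", "V1"))
  expect_true(all(rowSums(X[, 1:2]) == 1))
  expect_equal(X[, "V1"], c(0, 1, 0, 1))

  Xge <- build_design(ds, include_ge = TRUE)
  expect_equal(colnames(Xge)[4:7],
               c("Z.G1.E1", "Z.G2.E1", "Z.G1.E2", "Z.G2.E2"))
  expect_true(all(rowSums(Xge[, 4:7]) == 1))

  Xpr <- build_design(ds, include_ge = TRUE, ge_mode = "product")
  expect_equal(colnames(Xpr)[4:5], c("V1.E1", "V1.E2"))
  expect_equal(Xpr[, "V1.E1"], X[, "V1"] * X[, "E1"])

  ds$records <- rbind(ds$records, ds$records[1, ])
  expect_error(build_design(ds), "duplicate")
})

test_that("dataset validation rejects malformed inputs", {
  M <- matrix(c(0, 1, 2, 0), 2, 2, dimnames = list(c("A", "B"), NULL))
  rec <- data.frame(line = "A", environment = "E1", count = 1)
  expect_error(genomic_dataset(c("A", "B"), "E1", M, rec), "0.*1|coded")
  M2 <- matrix(0, 2, 2, dimnames = list(c("A", "B"), NULL))
  expect_error(genomic_dataset(c("A", "B"), "E1", M2,
                               data.frame(line = "C", environment = "E1",
                                          count = 1)), "unknown line")
  expect_error(genomic_dataset(c("A", "B"), "E1", M2,
                               data.frame(line = "A", environment = "E1",
                                          count = -1)), "non-negative")
  expect_error(genomic_dataset(c("A", "B"), "E1", M2,
                               data.frame(line = "A", environment = "E1",
                                          count = 1.5)), "non-negative")
})

test_that("CSV round trip is an identity", {
  ds <- toy_dataset(n_lines = 5, p = 3, seed = 101)
  dir <- tempfile("io")
  paths <- write_dataset(ds, dir)
  back <- read_dataset(paths["phenotype"], paths["genotype"])
  expect_equal(back$lines, ds$lines)
  expect_equal(back$environments, ds$environments)
  expect_equal(unname(back$markers), unname(ds$markers))
  expect_equal(back$records, ds$records)
})

test_that("the RData converter emits the CSV formats", {
  # synthetic stand-in for a deposited file, built in a temp dir at test
  # time (the real deposits need a download)
  ds <- toy_dataset(n_lines = 4, p = 3, seed = 102)
  Pheno <- data.frame(GID = ds$records$line, Env = ds$records$environment,
                      Response = ds$records$count)
  Geno <- ds$markers
  rdata <- tempfile(fileext = ".RData")
  save(Pheno, Geno, file = rdata)
  out <- tempfile("conv")
  conv <- convert_rdata(rdata, out, pheno_object = "Pheno",
                        geno_object = "Geno")
  expect_equal(conv$records$count, ds$records$count)
  expect_true(file.exists(file.path(out, "dataset_phenotype.csv")))
  back <- read_dataset(file.path(out, "dataset_phenotype.csv"),
                       file.path(out, "dataset_genotype.csv"))
  expect_equal(unname(back$markers), unname(ds$markers))
  expect_error(convert_rdata(rdata, out, pheno_object = "Nope",
                             geno_object = "Geno"), "contains")
})

test_that("descriptive summaries match base computations", {
  ds <- toy_dataset(n_lines = 10, p = 3, seed = 103)
  s <- dataset_summary(ds)
  y <- ds$records$count
  expect_equal(s$zero_percent, 100 * sum(y == 0) / length(y))
  expect_equal(unname(s$summary),
               unname(c(min(y), quantile(y, 0.25), median(y), mean(y),
                        quantile(y, 0.75), max(y))))
  expect_equal(s$n_lines, 10)
  expect_equal(s$n_markers, 3)

  C <- env_correlations(ds)
  expect_equal(diag(C), setNames(rep(1, 2), ds$environments))
  expect_equal(C, t(C))
  wide <- matrix(y, ncol = 2)  # records are line-major per environment
  expect_equal(C[1, 2], cor(wide[, 1], wide[, 2]))
})

test_that("model serialization round-trips predictions", {
  set.seed(110)
  X <- matrix(rbinom(200, 1, 0.5), 50, 4)
  colnames(X) <- paste0("V", 1:4)
  y <- rzap(50, 0.4, 2)

  f <- fit_forest(X, as.numeric(y), "ls", ntree = 8, mtry = 2, seed = 1)
  pf <- tempfile(fileext = ".json")
  write_model(f, pf)
  # decimal JSON loses at most the final ulp of a leaf value
  expect_equal(predict(read_model(pf), X), predict(f, X),
               tolerance = 1e-12)

  z <- fit_zap(X, y, ntree = 6, mtry = 2, nodesize = 3, seed = 2)
  pz <- tempfile(fileext = ".json")
  write_model(z, pz)
  z2 <- read_model(pz)
  expect_equal(predict(z2, X, type = "mean"),
               predict(z, X, type = "mean"), tolerance = 1e-12)
  expect_identical(z2$threshold, z$threshold)

  r <- fit_ridge(X, as.numeric(y), lambda = 2)
  pr <- tempfile(fileext = ".json")
  write_model(r, pr)
  expect_equal(predict(read_model(pr), X), predict(r, X))

  expect_error(suppressWarnings(read_model(tempfile())), ".")
})

test_that("command-line interface drives the full workflow", {
  dir <- tempfile("cli")
  dir.create(dir)
  expect_message(
    cli_main(c("simulate", "--preset", "dataset1_like", "--p", "12",
               "--n-lines", "12", "--seed", "4", "--out-dir", dir)),
    "wrote")
  ph <- file.path(dir, "dataset_phenotype.csv")
  ge <- file.path(dir, "dataset_genotype.csv")
  expect_true(file.exists(ph) && file.exists(ge))

  model_path <- file.path(dir, "model.json")
  expect_message(
    cli_main(c("fit", "--pheno", ph, "--geno", ge, "--model", "zap",
               "--ntree", "6", "--mtry", "3", "--nodesize", "3",
               "--out", model_path)), "wrote")
  pred_path <- file.path(dir, "pred.csv")
  cli_main(c("predict", "--model", model_path, "--pheno", ph,
             "--geno", ge, "--out", pred_path))
  pred <- read.csv(pred_path)
  expect_equal(nrow(pred), 36)
  expect_true(all(is.finite(pred$prediction)))

  cv_path <- file.path(dir, "cv.csv")
  suppressMessages(
    cli_main(c("cv", "--pheno", ph, "--geno", ge, "--models", "RF",
               "--k-outer", "3", "--ntree", "6", "--mtry", "3",
               "--nodesize", "3", "--out", cv_path)))
  expect_true("MAE" %in% read.csv(cv_path)$metric)

  vim_path <- file.path(dir, "vim.csv")
  plot_path <- file.path(dir, "vim.pdf")
  suppressMessages(
    cli_main(c("vim", "--model", model_path, "--pheno", ph, "--geno", ge,
               "--n-top", "5", "--out", vim_path, "--plot", plot_path)))
  expect_true(file.exists(vim_path) && file.exists(plot_path))

  expect_error(cli_main(c("nonsense")), "unknown subcommand")
  expect_error(cli_main(c("fit", "--pheno", ph)), "--geno")
})
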
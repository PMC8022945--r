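#' Genomic dataset container
#'
#' Joins a long phenotype table (line, environment, non-negative integer
#' count) to a binary line x marker matrix. Every record's line and
#' environment must appear in the registries and marker entries must be
#' 0/1 (markers are coded absence/presence).
#'
#' @param lines Character vector of line IDs.
#' @param environments Character vector of environment IDs.
#' @param markers Numeric 0/1 matrix, one row per line (rownames = lines).
#' @param records Data frame with columns `line`, `environment`, `count`.
#' @return An object of class `genomic_dataset`.
#' @export
genomic_dataset <- function(lines, environments, markers, records) {
  lines <- as.character(lines); environments <- as.character(environments)
  markers <- as.matrix(markers)
  if (nrow(markers) != length(lines))
    stop("`markers` must have one row per line")
  if (length(markers) && !all(markers %in% c(0, 1)))
    stop("marker values must be coded 0 (absence) or 1 (presence)")
  rownames(markers) <- lines
  if (ncol(markers) > 0 && is.null(colnames(markers)))
    colnames(markers) <- paste0("V", seq_len(ncol(markers)))
  req <- c("line", "environment", "count")
  if (!all(req %in% names(records)))
    stop("`records` needs columns line, environment, count")
  records <- data.frame(line = as.character(records$line),
                        environment = as.character(records$environment),
                        count = records$count, stringsAsFactors = FALSE)
  if (!all(records$line %in% lines))
    stop("unknown line in phenotype table: ",
         paste(utils::head(setdiff(records$line, lines)), collapse = ", "))
  if (!all(records$environment %in% environments))
    stop("unknown environment in phenotype table")
  if (any(records$count < 0) || any(records$count != floor(records$count)) ||
      anyNA(records$count))
    stop("counts must be non-negative integers")
  records$count <- as.integer(records$count)
  structure(list(lines = lines, environments = environments,
                 markers = markers, records = records),
            class = "genomic_dataset")
}

#' @export
print.genomic_dataset <- function(x, ...) {
  cat("Genomic dataset: ", length(x$lines), " lines x ", ncol(x$markers),
      " markers, ", length(x$environments), " environments, ",
      nrow(x$records), " records (",
      sprintf("%.1f", 100 * mean(x$records$count == 0)), "% zeros)\n",
      sep = "")
  invisible(x)
}

#' Build the model design matrix for a dataset
#'
#' Column blocks, in deterministic order: one 0/1 indicator per
#' environment, the marker columns replicated to records by line, and
#' optionally genotype-by-environment interaction columns. Two GE
#' encodings are available: `"indicator"` adds one line-within-environment
#' indicator per (line, environment) combination, labeled
#' `Z.G<line#>.Env<env>`; `"product"` adds marker x environment product
#' columns.
#'
#' @param dataset A [genomic_dataset()].
#' @param include_ge Add the GE interaction block?
#' @param ge_mode `"indicator"` (default) or `"product"`.
#' @return Numeric design matrix, one row per record.
#' @export
build_design <- function(dataset, include_ge = FALSE,
                         ge_mode = c("indicator", "product")) {
  stopifnot(inherits(dataset, "genomic_dataset"))
  ge_mode <- match.arg(ge_mode)
  rec <- dataset$records
  if (anyDuplicated(rec[, c("line", "environment")]))
    stop("duplicate (line, environment) records")
  env <- dataset$environments
  E <- matrix(0, nrow(rec), length(env), dimnames = list(NULL, env))
  E[cbind(seq_len(nrow(rec)), match(rec$environment, env))] <- 1
  M <- dataset$markers[rec$line, , drop = FALSE]
  rownames(M) <- NULL
  X <- cbind(E, M)
  if (include_ge) {
    if (ge_mode == "indicator") {
      combos <- unique(rec[, c("line", "environment")])
      combos <- combos[order(match(combos$environment, env),
                             match(combos$line, dataset$lines)), ]
      G <- matrix(0, nrow(rec), nrow(combos))
      key_rec <- paste(rec$line, rec$environment)
      key_combo <- paste(combos$line, combos$environment)
      G[cbind(seq_len(nrow(rec)), match(key_rec, key_combo))] <- 1
      colnames(G) <- paste0("Z.G", match(combos$line, dataset$lines),
                            ".", combos$environment)
    } else {
      blocks <- lapply(env, function(e) {
        B <- M * E[, e]
        colnames(B) <- paste0(colnames(M), ".", e)
        B
      })
      G <- do.call(cbind, blocks)
    }
    X <- cbind(X, G)
  }
  storage.mode(X) <- "double"
  X
}

#' Read / write a dataset as delimited text
#'
#' The phenotype file is a CSV with header `line,environment,count` (long
#' format); the genotype file is a CSV whose first column is `line` and
#' remaining columns are 0/1 markers (wide format). `write_dataset()`
#' followed by `read_dataset()` is an identity.
#'
#' @param phenotype_path,genotype_path CSV paths.
#' @return A [genomic_dataset()].
#' @export
read_dataset <- function(phenotype_path, genotype_path) {
  ph <- utils::read.csv(phenotype_path, stringsAsFactors = FALSE)
  ge <- utils::read.csv(genotype_path, check.names = FALSE,
                        stringsAsFactors = FALSE)
  if (names(ge)[1] != "line") stop("genotype CSV must start with a `line` column")
  markers <- as.matrix(ge[, -1, drop = FALSE])
  rownames(markers) <- ge$line
  genomic_dataset(lines = ge$line,
                  environments = unique(ph$environment),
                  markers = markers, records = ph)
}

#' @rdname read_dataset
#' @param dataset A [genomic_dataset()].
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix.
#' @return (write) Invisibly, the two file paths.
#' @export
write_dataset <- function(dataset, dir, prefix = "dataset") {
  stopifnot(inherits(dataset, "genomic_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  pheno <- file.path(dir, paste0(prefix, "_phenotype.csv"))
  geno <- file.path(dir, paste0(prefix, "_genotype.csv"))
  utils::write.csv(dataset$records, pheno, row.names = FALSE, quote = FALSE)
  gt <- data.frame(line = dataset$lines, dataset$markers,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(gt, geno, row.names = FALSE, quote = FALSE)
  invisible(c(phenotype = pheno, genotype = geno))
}

#' Convert a serialized (.RData) deposit to the CSV formats
#'
#' Ingests an `.RData` file holding a phenotype data frame (columns
#' containing line, environment and one count trait) and a line x marker
#' 0/1 matrix, and writes the package's phenotype/genotype CSVs. The
#' object and column names inside deposited files vary, so they are given
#' explicitly; available objects are listed on error.
#'
#' @param path `.RData` file.
#' @param out_dir Output directory for the CSVs.
#' @param pheno_object,geno_object Names of the phenotype data frame and
#'   marker matrix inside the file.
#' @param line_col,env_col,count_col Column names in the phenotype object.
#' @param prefix File name prefix for [write_dataset()].
#' @return The converted [genomic_dataset()], invisibly.
#' @export
convert_rdata <- function(path, out_dir, pheno_object, geno_object,
                          line_col = "GID", env_col = "Env",
                          count_col = "Response", prefix = "dataset") {
  e <- new.env(parent = emptyenv())
  load(path, envir = e)
  objs <- ls(e)
  for (nm in c(pheno_object, geno_object)) {
    if (!nm %in% objs)
      stop("object `", nm, "` not found; file contains: ",
           paste(objs, collapse = ", "))
  }
  ph <- get(pheno_object, envir = e)
  gm <- as.matrix(get(geno_object, envir = e))
  records <- data.frame(line = as.character(ph[[line_col]]),
                        environment = as.character(ph[[env_col]]),
                        count = ph[[count_col]], stringsAsFactors = FALSE)
  if (is.null(rownames(gm))) rownames(gm) <- unique(records$line)
  ds <- genomic_dataset(lines = rownames(gm),
                        environments = unique(records$environment),
                        markers = gm, records = records)
  write_dataset(ds, out_dir, prefix = prefix)
  invisible(ds)
}

#' Descriptive summary of a dataset
#'
#' The percentage of zeros, the six-number phenotype summary (min,
#' quartiles, median, mean, max) and the dataset dimensions — the
#' quantities usually tabulated when characterizing excess-zero count
#' traits.
#'
#' @param dataset A [genomic_dataset()].
#' @return A list with `zero_percent`, `summary`, `n_lines`, `n_markers`,
#'   `n_environments`, `n_records`.
#' @export
dataset_summary <- function(dataset) {
  stopifnot(inherits(dataset, "genomic_dataset"))
  y <- dataset$records$count
  q <- stats::quantile(y, c(0, 0.25, 0.5, 0.75, 1), names = FALSE)
  list(zero_percent = 100 * mean(y == 0),
       summary = c(min = q[1], q1 = q[2], median = q[3], mean = mean(y),
                   q3 = q[4], max = q[5]),
       n_lines = length(dataset$lines),
       n_markers = ncol(dataset$markers),
       n_environments = length(dataset$environments),
       n_records = nrow(dataset$records))
}

#' Between-environment phenotypic correlations
#'
#' Pearson correlations of the counts between environments, over the
#' lines observed in both (pairwise complete).
#'
#' @param dataset A [genomic_dataset()].
#' @return Symmetric correlation matrix, one row/column per environment.
#' @export
env_correlations <- function(dataset) {
  stopifnot(inherits(dataset, "genomic_dataset"))
  rec <- dataset$records
  W <- matrix(NA_real_, length(dataset$lines), length(dataset$environments),
              dimnames = list(dataset$lines, dataset$environments))
  W[cbind(match(rec$line, dataset$lines),
          match(rec$environment, dataset$environments))] <- rec$count
  stats::cor(W, use = "pairwise.complete.obs")
}
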
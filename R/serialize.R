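# Versioned JSON on-disk format for fitted models, so cross-validation
# runs can be resumed and models exchanged as plain text. Numbers are
# written at full precision; a round-tripped model predicts identically.

SCHEMA_VERSION <- "1.0"

forest_to_list <- function(f) {
  list(type = "forest", criterion = f$criterion, ntree = f$ntree,
       mtry = f$mtry, nodesize = f$nodesize,
       max_depth = if (is.finite(f$max_depth)) f$max_depth else "Inf",
       seed = f$seed, bootstrap = f$bootstrap, p = f$p,
       feature_names = f$feature_names, trees = f$trees)
}

forest_from_list <- function(l) {
  trees <- lapply(l$trees, function(tr) {
    list(feature = as.integer(tr$feature), threshold = as.numeric(tr$threshold),
         left = as.integer(tr$left), right = as.integer(tr$right),
         value = as.numeric(tr$value), n = as.integer(tr$n))
  })
  structure(list(trees = trees, inbag = NULL, criterion = l$criterion,
                 ntree = as.integer(l$ntree), mtry = as.integer(l$mtry),
                 nodesize = as.integer(l$nodesize),
                 max_depth = if (identical(l$max_depth, "Inf")) Inf
                             else as.numeric(l$max_depth),
                 seed = l$seed, bootstrap = isTRUE(l$bootstrap),
                 p = as.integer(l$p),
                 feature_names = unlist(l$feature_names)),
            class = "zapforest_forest")
}

#' Write / read fitted models as JSON
#'
#' Supports plain forests, hurdle (two-forest) models and the penalized
#' regression baselines. The format is self-describing (schema version,
#' model type, criterion, hyperparameters, seeds).
#'
#' @param model A `zapforest_forest`, `zapforest_zap` or
#'   `zapforest_ridge` object.
#' @param path Output file.
#' @return `write_model` the path invisibly; `read_model` the
#'   reconstructed model.
#' @export
write_model <- function(model, path) {
  body <- if (inherits(model, "zapforest_forest")) {
    forest_to_list(model)
  } else if (inherits(model, "zapforest_zap")) {
    list(type = "zap", threshold = model$threshold, seed = model$seed,
         p = model$p, feature_names = model$feature_names,
         zero_forest = forest_to_list(model$zero_forest),
         pos_forest = forest_to_list(model$pos_forest))
  } else if (inherits(model, "zapforest_ridge")) {
    list(type = "ridge", family = model$family, lambda = model$lambda,
         intercept = model$intercept, coefficients = model$coefficients,
         feature_names = model$feature_names)
  } else stop("unsupported model class")
  jsonlite::write_json(c(list(schema = "zapforest-model",
                              version = SCHEMA_VERSION), body),
                       path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  l <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE,
                           simplifyMatrix = FALSE)
  if (!identical(l$schema, "zapforest-model"))
    stop("not a zapforest model file")
  switch(l$type,
    forest = forest_from_list(l),
    zap = structure(list(zero_forest = forest_from_list(l$zero_forest),
                         pos_forest = forest_from_list(l$pos_forest),
                         threshold = l$threshold, seed = l$seed,
                         p = as.integer(l$p),
                         feature_names = unlist(l$feature_names)),
                    class = "zapforest_zap"),
    ridge = structure(list(intercept = l$intercept,
                           coefficients = as.numeric(unlist(l$coefficients)),
                           lambda = l$lambda, family = l$family,
                           feature_names = unlist(l$feature_names)),
                      class = "zapforest_ridge"),
    stop("unknown model type: ", l$type))
}
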
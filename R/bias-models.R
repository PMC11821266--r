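#' Training configuration for bias baseline models
#'
#' @param cv_folds Number of cross-validation folds used for hyperparameter
#'   selection (default 5).
#' @param excluded_ids Complex IDs removed before fold assignment and before
#'   the final refit (e.g. a benchmark core set).
#' @param search_budget Maximum number of hyperparameter configurations
#'   tried from the documented grid (default 4).
#' @param seed Integer seed controlling fold assignment and tree fitting.
#' @return A `train_config` list.
#' @export
train_config <- function(cv_folds = 5, excluded_ids = character(),
                         search_budget = 4, seed = 1) {
  if (cv_folds < 2) abort("cv_folds must be >= 2")
  if (search_budget < 1) abort("search_budget must be >= 1")
  structure(list(cv_folds = as.integer(cv_folds),
                 excluded_ids = as.character(excluded_ids),
                 search_budget = as.integer(search_budget),
                 seed = as.integer(seed)),
            class = "train_config")
}

# The documented hyperparameter grid for the random-forest regressor,
# ordered so that trimming by search_budget keeps the strongest defaults.
bias_model_grid <- function() {
  tibble(
    num_trees = c(500L, 500L, 200L, 500L, 200L, 200L, 500L, 200L),
    mtry_frac = c("sqrt", "third", "sqrt", "sqrt", "third", "sqrt", "third", "third"),
    min_node_size = c(5L, 5L, 5L, 1L, 5L, 1L, 1L, 1L)
  )
}

resolve_mtry <- function(frac, p) {
  switch(frac,
    sqrt = max(1L, floor(sqrt(p))),
    third = max(1L, floor(p / 3)),
    abort(paste0("unknown mtry_frac: ", frac))
  )
}

fit_rf <- function(x, y, num_trees, mtry_frac, min_node_size, seed) {
  ranger::ranger(
    x = x, y = y,
    num.trees = num_trees,
    mtry = resolve_mtry(mtry_frac, ncol(x)),
    min.node.size = min_node_size,
    seed = seed,
    num.threads = 1
  )
}

#' Train a bias baseline model
#'
#' Fits one of the bias-only baseline predictors: a random-forest regressor
#' of pK on a feature view that deliberately contains no 3D interaction
#' information — `"ligand"` (2D ligand descriptors only: the LigandBias
#' model), `"pocket"` (pocket amino-acid composition only: ProteinBias), or
#' `"both"` (their concatenation: BothBias). Hyperparameters are selected by
#' cross-validated RMSE over a small documented grid, then the winning
#' configuration is refit on all non-excluded records.
#'
#' A ligand-view model is protein-blind by construction: two records with
#' the same ligand get bit-identical predictions whatever protein they are
#' bound to. A pocket-view model sees only residue-type counts within the
#' pocket cutoff.
#'
#' @param records Records tibble with `pk` and list-columns `protein`, `ligand`.
#' @param view `"ligand"`, `"pocket"` or `"both"`.
#' @param config A [train_config()].
#' @param schema Optional `descriptor_schema`; built from the training
#'   ligands when missing (ligand/both views).
#' @param threshold_A Pocket distance cutoff in Angstrom (default 15).
#' @return A fitted `bias_model`.
#' @export
train_bias_model <- function(records, view = c("ligand", "pocket", "both"),
                             config = train_config(), schema = NULL,
                             threshold_A = 15) {
  view <- match.arg(view)
  stopifnot(inherits(config, "train_config"))
  records <- records[!records$complex_id %in% config$excluded_ids, , drop = FALSE]
  n <- nrow(records)
  if (n < 10 * config$cv_folds) {
    abort(paste0("too few records to train (", n, " after exclusions; need >= ",
                 10 * config$cv_folds, ")"))
  }
  if (any(!is.finite(records$pk))) abort("non-finite pK labels")
  if (is.null(schema) && view %in% c("ligand", "both")) {
    schema <- build_descriptor_schema(records$ligand)
  }
  x <- feature_matrix(records, view = view, schema = schema,
                      threshold_A = threshold_A)
  if (any(!is.finite(x))) abort("non-finite feature values after imputation")
  y <- records$pk

  grid <- head(bias_model_grid(), config$search_budget)
  folds <- withr::with_seed(config$seed,
    sample(rep(seq_len(config$cv_folds), length.out = n)))
  cv_rmse <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    se <- 0
    for (f in seq_len(config$cv_folds)) {
      tr <- folds != f
      fit <- fit_rf(x[tr, , drop = FALSE], y[tr],
                    grid$num_trees[g], grid$mtry_frac[g],
                    grid$min_node_size[g], config$seed)
      pr <- predict(fit, data = x[!tr, , drop = FALSE])$predictions
      se <- se + sum((pr - y[!tr])^2)
    }
    cv_rmse[g] <- sqrt(se / n)
  }
  best <- which.min(cv_rmse)
  final <- fit_rf(x, y, grid$num_trees[best], grid$mtry_frac[best],
                  grid$min_node_size[best], config$seed)
  structure(
    list(view = view,
         fit = final,
         schema = schema,
         threshold_A = threshold_A,
         feature_names = colnames(x),
         grid_results = dplyr::bind_cols(grid, tibble(cv_rmse = cv_rmse)),
         best = as.list(grid[best, ]),
         config = config,
         n_train = n),
    class = "bias_model"
  )
}

#' @export
print.bias_model <- function(x, ...) {
  cat("<bias_model> view = ", x$view, ", n_train = ", x$n_train, "\n", sep = "")
  cat("  best config: ", x$best$num_trees, " trees, mtry = ", x$best$mtry_frac,
      ", min node ", x$best$min_node_size, " (cv RMSE ",
      sprintf("%.3f", min(x$grid_results$cv_rmse)), " pK)\n", sep = "")
  invisible(x)
}

#' @export
tidy.bias_model <- function(x, ...) {
  x$grid_results
}

#' @export
glance.bias_model <- function(x, ...) {
  tibble(view = x$view, n_train = x$n_train,
         cv_folds = x$config$cv_folds,
         n_excluded = length(x$config$excluded_ids),
         num_trees = x$best$num_trees, mtry_frac = x$best$mtry_frac,
         min_node_size = x$best$min_node_size,
         cv_rmse = min(x$grid_results$cv_rmse),
         seed = x$config$seed)
}

#' Predict pK for complex records
#'
#' One finite prediction per record, in input order. A record that cannot
#' be featurized gets `NaN` with a warning rather than being dropped.
#'
#' @param object A fitted `bias_model`.
#' @param records Records tibble.
#' @param ... Unused.
#' @return Tibble with columns `complex_id`, `pred_pk`.
#' @export
predict.bias_model <- function(object, records, ...) {
  if (nrow(records) == 0) {
    return(tibble(complex_id = character(), pred_pk = numeric()))
  }
  preds <- rep(NaN, nrow(records))
  feats <- vector("list", nrow(records))
  ok <- logical(nrow(records))
  for (i in seq_len(nrow(records))) {
    row <- records[i, , drop = FALSE]
    f <- tryCatch(
      feature_matrix(row, view = object$view, schema = object$schema,
                     threshold_A = object$threshold_A),
      error = function(e) NULL
    )
    if (!is.null(f) && all(is.finite(f))) {
      feats[[i]] <- f
      ok[i] <- TRUE
    }
  }
  if (any(!ok)) {
    warn(paste0("predict: featurization failed for ",
                sum(!ok), " record(s); NaN emitted"))
  }
  if (any(ok)) {
    x <- do.call(rbind, feats[ok])
    preds[ok] <- predict(object$fit, data = x)$predictions
  }
  tibble(complex_id = records$complex_id, pred_pk = preds)
}

#' Ensemble two bias models by averaging their predictions
#'
#' The EnsembleBias construction: the prediction for each record is the
#' (by default unweighted) mean of the two member models' predictions, so
#' the ensemble never sees both feature views at once. `NaN` from either
#' member propagates with a warning.
#'
#' @param model_a,model_b Fitted `bias_model` objects (same label scale).
#' @param records Records tibble.
#' @param weights Two non-negative weights summing to 1 (default equal).
#' @return Tibble with columns `complex_id`, `pred_pk`.
#' @export
ensemble_predict <- function(model_a, model_b, records,
                             weights = c(0.5, 0.5)) {
  stopifnot(inherits(model_a, "bias_model"), inherits(model_b, "bias_model"))
  if (length(weights) != 2 || any(weights < 0) ||
      abs(sum(weights) - 1) > 1e-9) {
    abort("weights must be two non-negative values summing to 1")
  }
  pa <- predict(model_a, records)
  pb <- predict(model_b, records)
  pred <- weights[1] * pa$pred_pk + weights[2] * pb$pred_pk
  if (any(!is.finite(pred)) && nrow(records) > 0) {
    warn("ensemble_predict: NaN member prediction propagated")
  }
  tibble(complex_id = records$complex_id, pred_pk = pred)
}

#' Save / load a bias model archive
#'
#' The archive is a directory holding human-readable metadata
#' (`metadata.json`: view, hyperparameters, schema) alongside the
#' serialized regressor (`model.rds`).
#'
#' @param model A fitted `bias_model`.
#' @param dir Archive directory (created if needed).
#' @return `load_bias_model` returns the restored `bias_model`.
#' @export
save_bias_model <- function(model, dir) {
  stopifnot(inherits(model, "bias_model"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(
    format_version = 1L,
    view = model$view,
    threshold_A = model$threshold_A,
    feature_names = model$feature_names,
    best = model$best,
    grid_results = model$grid_results,
    n_train = model$n_train,
    seed = model$config$seed
  )
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(model$schema)) {
    write_descriptor_schema(model$schema, file.path(dir, "schema.json"))
  }
  saveRDS(model, file.path(dir, "model.rds"))
  invisible(dir)
}

#' @rdname save_bias_model
#' @export
load_bias_model <- function(dir) {
  path <- file.path(dir, "model.rds")
  if (!file.exists(path)) abort(paste0("no model archive at ", dir))
  model <- readRDS(path)
  stopifnot(inherits(model, "bias_model"))
  model
}

#' Write predictions as CSV
#'
#' @param predictions Tibble with `complex_id`, `pred_pk`.
#' @param path Output CSV path.
#' @export
write_predictions <- function(predictions, path) {
  readr::write_csv(predictions, path)
  invisible(path)
}
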
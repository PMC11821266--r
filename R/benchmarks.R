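record_inchikeys <- function(records) {
  vapply(records$ligand, function(m) m$inchikey, character(1))
}

#' Cluster records by identical ligand (InChI-Key)
#'
#' Groups complexes whose ligands are the same molecule, matched on the
#' full 27-character InChI-Key (so stereochemistry and charge state count).
#' Only keys occurring at least twice form clusters; singletons are
#' reported in `attr(, "singletons")`.
#'
#' @param records Records tibble with list-column `ligand` and column `pk`.
#' @return Tibble with one row per cluster: `inchikey`, `n_members`,
#'   `member_ids` (list), `pk_values` (list), `mean_pk`, `var_pk`
#'   (sample variance, n-1 denominator).
#' @export
cluster_by_inchikey <- function(records) {
  keys <- record_inchikeys(records)
  df <- tibble(complex_id = records$complex_id, inchikey = keys,
               pk = records$pk)
  grouped <- df %>%
    group_by(.data$inchikey) %>%
    summarise(
      n_members = dplyr::n(),
      member_ids = list(.data$complex_id),
      pk_values = list(.data$pk),
      mean_pk = mean(.data$pk),
      var_pk = if (dplyr::n() >= 2) var(.data$pk) else NA_real_,
      .groups = "drop"
    ) %>%
    arrange(.data$inchikey)
  clusters <- grouped %>% filter(.data$n_members >= 2)
  singletons <- grouped %>% filter(.data$n_members < 2)
  attr(clusters, "singletons") <- singletons
  clusters
}

new_benchmark_split <- function(name, train_ids, test_ids,
                                excluded_ids = character(), rule = list()) {
  train_ids <- as.character(train_ids)
  test_ids <- as.character(test_ids)
  excluded_ids <- as.character(excluded_ids)
  if (length(intersect(train_ids, test_ids)) > 0) {
    abort("train and test sets must be disjoint")
  }
  structure(
    list(name = name, train_ids = train_ids, test_ids = test_ids,
         excluded_ids = excluded_ids, rule = rule),
    class = "benchmark_split"
  )
}

#' @export
print.benchmark_split <- function(x, ...) {
  cat("<benchmark_split> ", x$name, ": ", length(x$train_ids), " train / ",
      length(x$test_ids), " test",
      if (length(x$excluded_ids)) paste0(" / ", length(x$excluded_ids), " excluded") else "",
      "\n", sep = "")
  invisible(x)
}

#' @export
as_tibble.benchmark_split <- function(x, ...) {
  tibble(
    complex_id = c(x$train_ids, x$test_ids, x$excluded_ids),
    role = c(rep("train", length(x$train_ids)),
             rep("test", length(x$test_ids)),
             rep("excluded", length(x$excluded_ids)))
  )
}

#' Build the zero-ligand-bias benchmark split
#'
#' The test set is the union of identical-ligand clusters whose mean pK
#' lies within `mean_range` (inclusive) and whose sample variance exceeds
#' `var_min` (strict). Centering the cluster means while requiring spread
#' makes per-ligand memorization useless: predicting any one value per
#' ligand cannot correlate with the within-cluster pK variation. Records
#' whose ligand appears in the test set are additionally excluded from the
#' train side so no ligand leaks across the split.
#'
#' @param records Records tibble.
#' @param clusters Optional precomputed [cluster_by_inchikey()] output.
#' @param mean_range Inclusive cluster-mean window (default `c(6, 7)`).
#' @param var_min Strict lower bound on cluster pK variance (default 1).
#' @param exclude_train_leakage Drop train records sharing an InChI-Key with
#'   the test set (default `TRUE`).
#' @return A `benchmark_split` named `"zero_ligand_bias"`.
#' @export
zero_ligand_bias_filter <- function(records, clusters = NULL,
                                    mean_range = c(6, 7), var_min = 1,
                                    exclude_train_leakage = TRUE) {
  if (is.null(clusters)) clusters <- cluster_by_inchikey(records)
  pass <- clusters$mean_pk >= mean_range[1] & clusters$mean_pk <= mean_range[2] &
    clusters$var_pk > var_min
  test_ids <- unlist(clusters$member_ids[pass], use.names = FALSE)
  if (length(test_ids) == 0) {
    warn("zero_ligand_bias_filter: empty test set under the given thresholds")
  }
  keys <- record_inchikeys(records)
  test_keys <- unique(keys[records$complex_id %in% test_ids])
  rest <- records$complex_id[!records$complex_id %in% test_ids]
  leaked <- character()
  if (exclude_train_leakage) {
    leak_mask <- !records$complex_id %in% test_ids & keys %in% test_keys
    leaked <- records$complex_id[leak_mask]
    rest <- setdiff(rest, leaked)
  }
  new_benchmark_split(
    "zero_ligand_bias",
    train_ids = rest, test_ids = test_ids, excluded_ids = leaked,
    rule = list(type = "zero_ligand_bias", mean_range = mean_range,
                var_min = var_min, variance = "sample (n-1)",
                mean_endpoints = "inclusive", var_bound = "strict",
                exclude_train_leakage = exclude_train_leakage)
  )
}

#' Build the peptide holdout split
#'
#' Records whose ligand code contains `code_substring` (case-insensitive)
#' form the test set; in PDBBind-style indices peptide ligands carry codes
#' with the letters "MER" (e.g. "3-MER").
#'
#' @param records Records tibble with column `ligand_code`.
#' @param code_substring Substring matched against the upper-cased ligand
#'   code (default `"MER"`).
#' @return A `benchmark_split` named `"peptide_holdout"`.
#' @export
peptide_holdout <- function(records, code_substring = "MER") {
  code <- toupper(ifelse(is.na(records$ligand_code), "", records$ligand_code))
  is_test <- grepl(toupper(code_substring), code, fixed = TRUE)
  if (!any(is_test)) warn("peptide_holdout: no ligand code matched; empty test set")
  new_benchmark_split(
    "peptide_holdout",
    train_ids = records$complex_id[!is_test],
    test_ids = records$complex_id[is_test],
    rule = list(type = "peptide", code_substring = toupper(code_substring),
                case_insensitive = TRUE)
  )
}

#' Build a deposition-year time split
#'
#' Test set = records with `year >= cutoff_year` ("from `cutoff_year` or
#' later", so the cutoff year itself is test). Records with a missing year
#' are excluded from both sides and reported.
#'
#' @param records Records tibble with column `year`.
#' @param cutoff_year First test-set year (default 2019).
#' @return A `benchmark_split` named `"time_split"`.
#' @export
time_split <- function(records, cutoff_year = 2019) {
  missing <- is.na(records$year)
  is_test <- !missing & records$year >= cutoff_year
  if (!any(is_test)) warn("time_split: empty test set (all records pre-cutoff)")
  new_benchmark_split(
    "time_split",
    train_ids = records$complex_id[!missing & !is_test],
    test_ids = records$complex_id[is_test],
    excluded_ids = records$complex_id[missing],
    rule = list(type = "time", cutoff_year = cutoff_year, inclusive = TRUE)
  )
}

#' Validate a benchmark split against its dataset
#'
#' Generic split validator: checks train/test disjointness, coverage
#' accounting (train + test + excluded = dataset), and that every test
#' member satisfies the split's rule predicate (recomputed from the
#' records, not trusted from the split).
#'
#' @param split A `benchmark_split`.
#' @param records The records tibble it was built from.
#' @return Invisibly `TRUE`; aborts with a description on any violation.
#' @export
validate_split <- function(split, records) {
  stopifnot(inherits(split, "benchmark_split"))
  ids <- records$complex_id
  if (length(intersect(split$train_ids, split$test_ids)) > 0) {
    abort("validate_split: train/test overlap")
  }
  all_ids <- c(split$train_ids, split$test_ids, split$excluded_ids)
  if (anyDuplicated(all_ids)) abort("validate_split: id assigned to two roles")
  if (!setequal(all_ids, ids)) {
    abort("validate_split: coverage accounting failed (train + test + excluded != dataset)")
  }
  rule <- split$rule
  test_rec <- records[match(split$test_ids, ids), , drop = FALSE]
  ok <- switch(rule$type,
    time = !is.na(test_rec$year) & test_rec$year >= rule$cutoff_year,
    peptide = grepl(rule$code_substring,
                    toupper(ifelse(is.na(test_rec$ligand_code), "",
                                   test_rec$ligand_code)), fixed = TRUE),
    zero_ligand_bias = {
      cl <- cluster_by_inchikey(records)
      pass <- cl$mean_pk >= rule$mean_range[1] & cl$mean_pk <= rule$mean_range[2] &
        cl$var_pk > rule$var_min
      split$test_ids %in% unlist(cl$member_ids[pass], use.names = FALSE)
    },
    abort(paste0("validate_split: unknown rule type '", rule$type, "'"))
  )
  if (!all(ok)) {
    abort(paste0("validate_split: ", sum(!ok),
                 " test record(s) violate the '", rule$type, "' rule"))
  }
  if (identical(rule$type, "zero_ligand_bias")) {
    keys <- record_inchikeys(records)
    tr_keys <- keys[ids %in% split$train_ids]
    te_keys <- keys[ids %in% split$test_ids]
    if (length(intersect(tr_keys, te_keys)) > 0) {
      abort("validate_split: ligand InChI-Key occurs in both train and test")
    }
  }
  invisible(TRUE)
}

#' Write a split to disk
#'
#' Two files: a two-column CSV (`complex_id`, `role`) and a JSON rule
#' descriptor.
#'
#' @param split A `benchmark_split`.
#' @param csv_path Output CSV path.
#' @param rule_path Output JSON path (default: CSV path with `.json`).
#' @export
write_split <- function(split, csv_path,
                        rule_path = sub("\\.csv$", ".json", csv_path)) {
  readr::write_csv(as_tibble(split), csv_path)
  jsonlite::write_json(c(list(name = split$name), split$rule), rule_path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(csv_path)
}
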
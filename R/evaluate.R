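#' Accuracy metrics for predicted vs true pK
#'
#' `pearson_r` is the product-moment correlation; `r_squared` is the
#' coefficient of determination 1 - SS_res/SS_tot (not the square of
#' Pearson R: it can be negative for predictions worse than the mean);
#' `rmse` is root-mean-square error in pK units. Zero variance where a
#' metric needs it raises an undefined-metric error rather than silently
#' returning 0.
#'
#' @param y_true,y_pred Equal-length numeric vectors (paired by position).
#' @return A single numeric value.
#' @export
pearson_r <- function(y_true, y_pred) {
  check_pairs(y_true, y_pred, min_n = 3)
  if (near_zero_var(y_true) || near_zero_var(y_pred)) {
    abort("pearson_r undefined: zero variance", class = "sfbias_undefined_metric")
  }
  cor(y_true, y_pred)
}

#' @rdname pearson_r
#' @export
rmse <- function(y_true, y_pred) {
  check_pairs(y_true, y_pred, min_n = 2)
  sqrt(mean((y_true - y_pred)^2))
}

#' @rdname pearson_r
#' @export
r_squared <- function(y_true, y_pred) {
  check_pairs(y_true, y_pred, min_n = 2)
  ss_tot <- sum((y_true - mean(y_true))^2)
  if (ss_tot <= 0) {
    abort("r_squared undefined: zero variance in y_true",
          class = "sfbias_undefined_metric")
  }
  1 - sum((y_true - y_pred)^2) / ss_tot
}

check_pairs <- function(y_true, y_pred, min_n) {
  if (length(y_true) != length(y_pred)) {
    abort("y_true and y_pred must have equal length")
  }
  if (length(y_true) < min_n) {
    abort(paste0("need at least ", min_n, " points"))
  }
  if (any(!is.finite(y_true)) || any(!is.finite(y_pred))) {
    abort("non-finite values in inputs")
  }
  invisible(TRUE)
}

near_zero_var <- function(x) {
  s <- sd(x)
  !is.finite(s) || s < .Machine$double.eps^0.5 * (1 + abs(mean(x)))
}

metric_fun <- function(metric) {
  switch(metric,
    pearson_r = pearson_r,
    r2 = r_squared,
    rmse = rmse,
    abort(paste0("unknown metric: ", metric))
  )
}

# Vectorized metric over index-resampled columns. Returns a numeric vector
# (one value per resample column); NaN marks a degenerate resample.
resample_stats <- function(y_true, y_pred, metric, idx) {
  n <- nrow(idx)
  Y <- matrix(y_true[idx], nrow = n)
  P <- matrix(y_pred[idx], nrow = n)
  eps <- .Machine$double.eps^0.5
  if (metric == "rmse") {
    return(sqrt(colMeans((Y - P)^2)))
  }
  my <- colMeans(Y)
  ss_y <- colSums(Y^2) - n * my^2
  if (metric == "r2") {
    out <- 1 - colSums((Y - P)^2) / ss_y
    out[ss_y <= eps * n * (1 + abs(my))^2] <- NaN
    return(out)
  }
  mp <- colMeans(P)
  ss_p <- colSums(P^2) - n * mp^2
  cov <- colSums(Y * P) - n * my * mp
  den <- ss_y * ss_p
  bad <- ss_y <= eps * n * (1 + abs(my))^2 | ss_p <= eps * n * (1 + abs(mp))^2
  out <- cov / sqrt(pmax(den, .Machine$double.xmin))
  out <- pmin(1, pmax(-1, out))
  out[bad] <- NaN
  out
}

#' Bootstrapped metric with percentile confidence interval
#'
#' Resamples (y_true, y_pred) pairs with replacement `n_boot` times and
#' reports the full-sample point estimate together with the percentile
#' `1 - alpha` confidence interval of the metric over the resamples. The
#' point estimate is the plain metric on the full sample, never the
#' bootstrap mean. Resamples on which the metric is undefined (zero
#' variance) are redrawn, keeping the effective number of resamples at
#' `n_boot`; the redraw count is reported. Fully deterministic under a
#' fixed seed.
#'
#' @param y_true,y_pred Paired numeric vectors.
#' @param metric One of `"pearson_r"`, `"r2"`, `"rmse"`.
#' @param n_boot Number of bootstrap resamples (default 10000).
#' @param alpha CI tail mass (default 0.05 for a 95% interval).
#' @param seed Integer seed.
#' @return One-row tibble of class `metric_result`: `metric`, `point`,
#'   `ci_lo`, `ci_hi`, `n_boot`, `n_points`, `seed`, `n_redraws`.
#' @export
bootstrap_metric <- function(y_true, y_pred,
                             metric = c("pearson_r", "r2", "rmse"),
                             n_boot = 10000, alpha = 0.05, seed = 1) {
  metric <- match.arg(metric)
  min_n <- if (metric == "rmse") 2 else 3
  check_pairs(y_true, y_pred, min_n = max(min_n, 3))
  n <- length(y_true)
  point <- metric_fun(metric)(y_true, y_pred)
  stats <- withr::with_seed(as.integer(seed), {
    # chunked so memory stays ~ a few n x chunk matrices
    chunk <- max(1L, min(n_boot, as.integer(ceiling(2e6 / n))))
    acc <- numeric(0)
    redraws <- 0L
    while (length(acc) < n_boot) {
      b <- min(chunk, n_boot - length(acc))
      idx <- matrix(sample.int(n, n * b, replace = TRUE), nrow = n)
      vals <- resample_stats(y_true, y_pred, metric, idx)
      tries <- 0L
      while (any(!is.finite(vals)) && tries < 1000L) {
        bad <- which(!is.finite(vals))
        redraws <- redraws + length(bad)
        idx2 <- matrix(sample.int(n, n * length(bad), replace = TRUE), nrow = n)
        vals[bad] <- resample_stats(y_true, y_pred, metric, idx2)
        tries <- tries + 1L
      }
      if (any(!is.finite(vals))) {
        abort("bootstrap_metric: could not draw non-degenerate resamples")
      }
      acc <- c(acc, vals)
    }
    list(vals = acc, redraws = redraws)
  })
  ci <- unname(quantile(stats$vals, probs = c(alpha / 2, 1 - alpha / 2)))
  out <- tibble(
    metric = metric, point = point, ci_lo = ci[1], ci_hi = ci[2],
    n_boot = as.integer(n_boot), n_points = n, seed = as.integer(seed),
    n_redraws = stats$redraws
  )
  class(out) <- c("metric_result", class(out))
  out
}

#' @export
glance.metric_result <- function(x, ...) {
  tibble(metric = x$metric, point = x$point,
         half_width = max(x$point - x$ci_lo, x$ci_hi - x$point),
         n_points = x$n_points, n_boot = x$n_boot)
}

format_pm <- function(point, ci_lo, ci_hi) {
  hw <- pmax(point - ci_lo, ci_hi - point)
  sprintf("%.2f ± %.2f", point, hw)
}

#' Cross-model, cross-benchmark accuracy report
#'
#' Joins predictions to labels by `complex_id` (never by row order),
#' bootstraps each requested metric for every (model, benchmark) cell, and
#' flags per benchmark column the best cell plus every cell whose
#' confidence interval overlaps the best cell's interval ("tied"). Higher
#' is better for `pearson_r` and `r2`; lower is better for `rmse`. Cells
#' with fewer than 3 joined pairs, or with an undefined metric, are marked
#' insufficient and carry `NaN`.
#'
#' @param predictions Tibble with columns `model`, `benchmark`,
#'   `complex_id`, `pred_pk` (stack one row per prediction). A single
#'   model/benchmark tibble from [predict.bias_model()] is accepted if
#'   `model`/`benchmark` columns are added by the caller.
#' @param labels Tibble with columns `complex_id`, `pk` (a records tibble
#'   works as is).
#' @param metrics Character subset of `c("pearson_r", "r2", "rmse")`.
#' @param n_boot,alpha,seed Passed to [bootstrap_metric()].
#' @return Tibble of class `bias_report`: one row per (model, benchmark,
#'   metric) with `point`, `ci_lo`, `ci_hi`, `label` ("point +/- half-width"
#'   at 2 decimals), `best`, `tied`, `insufficient`, `n_points`,
#'   `n_unmatched`.
#' @export
build_report <- function(predictions, labels,
                         metrics = "pearson_r",
                         n_boot = 10000, alpha = 0.05, seed = 1) {
  needed <- c("model", "benchmark", "complex_id", "pred_pk")
  if (!all(needed %in% names(predictions))) {
    abort(paste0("predictions must have columns: ",
                 paste(needed, collapse = ", ")))
  }
  stopifnot(all(metrics %in% c("pearson_r", "r2", "rmse")))
  labels <- labels[, c("complex_id", "pk")]
  cells <- predictions %>%
    distinct(.data$model, .data$benchmark)
  rows <- list()
  for (k in seq_len(nrow(cells))) {
    sub <- predictions %>%
      filter(.data$model == cells$model[k],
             .data$benchmark == cells$benchmark[k])
    joined <- dplyr::inner_join(sub, labels, by = "complex_id")
    joined <- joined[is.finite(joined$pred_pk) & is.finite(joined$pk), ,
                     drop = FALSE]
    n_unmatched <- nrow(sub) - nrow(joined)
    for (m in metrics) {
      res <- if (nrow(joined) >= 3) {
        tryCatch(
          bootstrap_metric(joined$pk, joined$pred_pk, metric = m,
                           n_boot = n_boot, alpha = alpha, seed = seed),
          sfbias_undefined_metric = function(e) NULL
        )
      }
      rows[[length(rows) + 1]] <- tibble(
        model = cells$model[k], benchmark = cells$benchmark[k], metric = m,
        point = if (is.null(res)) NaN else res$point,
        ci_lo = if (is.null(res)) NaN else res$ci_lo,
        ci_hi = if (is.null(res)) NaN else res$ci_hi,
        n_points = nrow(joined), n_unmatched = n_unmatched,
        insufficient = is.null(res)
      )
    }
  }
  report <- bind_rows(rows) %>%
    group_by(.data$benchmark, .data$metric) %>%
    mutate(best = best_flag(.data$point, .data$metric[1], .data$insufficient)) %>%
    mutate(tied = !.data$insufficient & !is.na(.data$best) & (
      .data$best |
        (.data$ci_hi >= .data$ci_lo[.data$best][1] &
           .data$ci_lo <= .data$ci_hi[.data$best][1])
    )) %>%
    ungroup() %>%
    mutate(label = ifelse(.data$insufficient, "NA",
                          format_pm(.data$point, .data$ci_lo, .data$ci_hi)))
  class(report) <- c("bias_report", class(report))
  report
}

best_flag <- function(point, metric, insufficient) {
  score <- ifelse(insufficient, NA_real_, point)
  if (all(is.na(score))) return(rep(FALSE, length(point)))
  if (metric == "rmse") score <- -score
  out <- rep(FALSE, length(point))
  out[which.max(score)] <- TRUE
  out
}

#' Write a report as CSV and Markdown
#'
#' @param report A `bias_report` tibble from [build_report()].
#' @param csv_path Output CSV path (`NULL` to skip).
#' @param md_path Output Markdown table path (`NULL` to skip).
#' @export
write_report <- function(report, csv_path = NULL, md_path = NULL) {
  if (!is.null(csv_path)) readr::write_csv(report, csv_path)
  if (!is.null(md_path)) {
    lines <- character()
    for (m in unique(report$metric)) {
      sub <- report[report$metric == m, , drop = FALSE]
      wide <- sub %>%
        mutate(cell = ifelse(.data$best, paste0("**", .data$label, "**"),
                             ifelse(.data$tied, paste0("_", .data$label, "_"),
                                    .data$label))) %>%
        select("model", "benchmark", "cell") %>%
        tidyr::pivot_wider(names_from = "benchmark", values_from = "cell")
      lines <- c(lines, paste0("### ", m), "",
                 paste0("| Method | ", paste(names(wide)[-1], collapse = " | "), " |"),
                 paste0("|", paste(rep("---", ncol(wide)), collapse = "|"), "|"),
                 apply(wide, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |")),
                 "")
    }
    writeLines(lines, md_path)
  }
  invisible(report)
}
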
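test_that("metrics have their defining values", {
  y <- c(2.1, 4.5, 6.7, 5.2, 8.8)
  expect_equal(pearson_r(y, y), 1)
  expect_equal(pearson_r(y, -y), -1)
  # frozen oracle: cov/sd computed by hand for (1..5) vs (2,1,4,3,6)
  expect_equal(pearson_r(1:5, c(2, 1, 4, 3, 6)), 10 / sqrt(10 * 14.8),
               tolerance = 1e-12)
  expect_equal(rmse(y, y), 0)
  expect_equal(rmse(c(1, 2, 3), c(2, 2, 2)), sqrt(2 / 3))
  expect_equal(r_squared(y, y), 1)
  # constant prediction at the mean gives R^2 = 0; below it, negative
  expect_equal(r_squared(y, rep(mean(y), 5)), 0)
  expect_lt(r_squared(y, rep(0, 5)), 0)
})

test_that("r_squared is not pearson_r squared except for affine fits", {
  withr::with_seed(2, {
    y <- rnorm(50)
    p <- y + rnorm(50, sd = 0.5)
    expect_false(isTRUE(all.equal(r_squared(y, p), pearson_r(y, p)^2)))
    fit <- lm(y ~ p)
    p_affine <- unname(fitted(fit))
    expect_equal(r_squared(y, p_affine), pearson_r(y, p_affine)^2,
                 tolerance = 1e-10)
    expect_lte(r_squared(y, p), 1)
  })
})

test_that("zero-variance inputs raise an undefined-metric error", {
  expect_error(pearson_r(c(1, 1, 1), c(1, 2, 3)),
               class = "sfbias_undefined_metric")
  expect_error(r_squared(c(2, 2, 2), c(1, 2, 3)),
               class = "sfbias_undefined_metric")
  expect_error(pearson_r(1:2, 1:2), "at least 3")
})

test_that("bootstrap point estimate is the full-sample metric, not the mean", {
  withr::with_seed(5, {
    y <- rnorm(80); p <- y + rnorm(80, sd = 0.8)
    for (m in c("pearson_r", "r2", "rmse")) {
      b <- bootstrap_metric(y, p, m, n_boot = 500, seed = 11)
      expect_identical(b$point, sfbias:::metric_fun(m)(y, p))
      expect_lte(b$ci_lo, b$point)
      expect_gte(b$ci_hi, b$point)
    }
  })
})

test_that("perfect predictions give R = 1 with a zero-width interval", {
  y <- c(3.2, 5.5, 6.1, 7.8, 4.4, 9.0)
  b <- bootstrap_metric(y, y, "pearson_r", n_boot = 400, seed = 3)
  expect_equal(b$point, 1)
  expect_equal(b$ci_lo, 1)
  expect_equal(b$ci_hi, 1)
})

test_that("bootstrap results are deterministic under a fixed seed", {
  withr::with_seed(9, { y <- rnorm(40); p <- y + rnorm(40) })
  b1 <- bootstrap_metric(y, p, "pearson_r", n_boot = 300, seed = 21)
  b2 <- bootstrap_metric(y, p, "pearson_r", n_boot = 300, seed = 21)
  expect_identical(b1, b2)
  b3 <- bootstrap_metric(y, p, "pearson_r", n_boot = 300, seed = 22)
  expect_false(identical(b1$ci_lo, b3$ci_lo))
})

test_that("degenerate resamples are redrawn, keeping n_boot effective", {
  # tiny n makes all-identical resamples likely, forcing redraws
  y <- c(1, 1, 1, 5); p <- c(1, 1, 2, 4)
  b <- bootstrap_metric(y, p, "pearson_r", n_boot = 500, seed = 13)
  expect_gt(b$n_redraws, 0)
  expect_true(is.finite(b$ci_lo) && is.finite(b$ci_hi))
})

test_that("CI width shrinks with sample size", {
  withr::with_seed(17, {
    widths <- sapply(c(100, 1000), function(n) {
      median(replicate(20, {
        y <- rnorm(n); p <- 0.7 * y + rnorm(n, sd = sqrt(1 - 0.49))
        b <- bootstrap_metric(y, p, "pearson_r", n_boot = 200,
                              seed = sample.int(1e6, 1))
        b$ci_hi - b$ci_lo
      }))
    })
    expect_lt(widths[2], widths[1])
  })
})

test_that("build_report joins on complex_id and flags best and tied cells", {
  withr::with_seed(3, {
    ids <- sprintf("c%03d", 1:60)
    y <- rnorm(60, 6, 1.5)
    labels <- tibble::tibble(complex_id = ids, pk = y)
    preds <- dplyr::bind_rows(
      tibble::tibble(model = "good", benchmark = "bench", complex_id = ids,
                     pred_pk = y + rnorm(60, sd = 0.2)),
      tibble::tibble(model = "bad", benchmark = "bench", complex_id = ids,
                     pred_pk = rnorm(60)),
      tibble::tibble(model = "perfect", benchmark = "bench", complex_id = ids,
                     pred_pk = y)
    )
    # shuffle prediction rows: pairing must come from the join, not order
    preds <- preds[sample(nrow(preds)), ]
    rep <- build_report(preds, labels, metrics = c("pearson_r", "rmse"),
                        n_boot = 300, seed = 5)
    pr <- rep[rep$metric == "pearson_r", ]
    expect_true(pr$best[pr$model == "perfect"])
    expect_false(pr$tied[pr$model == "bad"])
    expect_equal(sum(pr$best), 1)
    # rmse direction: lower is better
    rm <- rep[rep$metric == "rmse", ]
    expect_true(rm$best[rm$model == "perfect"])
    expect_match(rep$label[1], "^-?\\d+\\.\\d{2} ± \\d+\\.\\d{2}$")
    # tied flags equal a brute-force recomputation of the overlap rule
    best_row <- pr[pr$best, ]
    manual <- pr$ci_hi >= best_row$ci_lo & pr$ci_lo <= best_row$ci_hi
    expect_equal(pr$tied, manual & !pr$insufficient)
  })
})

test_that("build_report marks undersized or unmatched cells insufficient", {
  labels <- tibble::tibble(complex_id = c("a", "b"), pk = c(5, 6))
  preds <- tibble::tibble(model = "m", benchmark = "b",
                          complex_id = c("a", "b", "zz"),
                          pred_pk = c(5.1, 6.1, 7))
  rep <- build_report(preds, labels, n_boot = 50, seed = 1)
  expect_true(rep$insufficient)
  expect_true(is.nan(rep$point))
  expect_equal(rep$n_unmatched, 1)
})

test_that("reports render to CSV and Markdown", {
  labels <- tibble::tibble(complex_id = paste0("i", 1:20),
                           pk = rnorm(20, 6))
  preds <- tibble::tibble(model = "m", benchmark = "b",
                          complex_id = labels$complex_id,
                          pred_pk = labels$pk + rnorm(20, sd = 0.3))
  rep <- build_report(preds, labels, n_boot = 100, seed = 2)
  csv <- tempfile(fileext = ".csv"); md <- tempfile(fileext = ".md")
  write_report(rep, csv, md)
  expect_true(file.exists(csv))
  expect_match(paste(readLines(md), collapse = "\n"), "\\| Method \\|")
  p <- ggplot2::autoplot(rep)
  expect_s3_class(p, "ggplot")
})
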
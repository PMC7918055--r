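test_that("NRMSE matches its definition and flags degenerate input", {
  y <- c(0, 1)
  expect_equal(nrmse(y, y), 0)
  expect_equal(nrmse(y, c(1, 2)), 1)
  set.seed(51)
  a <- rnorm(100)
  b <- rnorm(100)
  # independent single-pass loop oracle
  acc <- 0
  for (i in seq_along(a)) acc <- acc + (a[i] - b[i])^2
  oracle <- sqrt(acc / length(a)) / (max(a) - min(a))
  expect_equal(nrmse(a, b), oracle, tolerance = 1e-12)
  expect_error(nrmse(rep(1, 5), rnorm(5)), class = "emgdecode_metric_error")
  expect_error(nrmse(1:4, 1:5), class = "emgdecode_dim_error")
})

test_that("CC is Pearson correlation with affine invariance", {
  y <- c(1, 2, 3, 4)
  expect_equal(cc(y, y), 1, tolerance = 1e-12)
  expect_equal(cc(y, -y), -1, tolerance = 1e-12)
  expect_equal(cc(y, 3 * y + 7), 1, tolerance = 1e-12)
  # hand computation: cov = 6.5, sd product = sqrt(5 * 8.75)
  expect_equal(cc(y, c(1, 2, 3, 5)), 6.5 / sqrt(5 * 8.75),
               tolerance = 1e-12)
  expect_lt(abs(cc(y, c(1, 2, 3, 5)) - 0.9827), 1e-4)
  set.seed(52)
  a <- rnorm(80)
  b <- rnorm(80)
  expect_equal(cc(a, b), cor(a, b), tolerance = 1e-12)
  expect_true(abs(cc(a, b)) <= 1)
  expect_error(cc(rep(2, 5), rnorm(5)), class = "emgdecode_metric_error")
})

test_that("performance reports aggregate per-axis values exactly", {
  rep1 <- performance_report(c(0.7, 0.8, 0.9), c(0.10, 0.12, 0.14),
                             task = "Task_1")
  expect_equal(rep1$cc_mean, 0.8)
  expect_equal(rep1$nrmse_mean, 0.12)
  expect_identical(rep1$task, "Task_1")
  expect_error(performance_report(c(0.7, 0.8), c(0.1, 0.1, 0.1)))
})

test_that("segmentation cuts one fixed-length segment per cycle", {
  segs <- quick_segments()
  expect_length(segs, 5L)
  for (s in segs) {
    expect_identical(nrow(s$envelope), 7000L)
    expect_identical(nrow(s$position_1k), 7000L)
  }
  expect_identical(vapply(segs, function(s) s$metadata$cycle, integer(1)),
                   1:5)
  slow_segs <- segment_cycles(slow_processed())
  expect_identical(nrow(slow_segs[[1]]$envelope), 9000L)
  # non-overlap when cycle spacing (6 s quick) >= segment length
  short <- segment_cycles(quick_processed(), segment_s = 5)
  starts <- vapply(short, function(s) as.numeric(s$metadata$start_sample),
                   numeric(1))
  expect_true(all(diff(starts) >= 5000L))
})

test_that("horizon alignment pairs windows with future positions", {
  t_ms <- seq(100, 1000, by = 50)
  features <- tibble::tibble(t_ms = t_ms, f1 = seq_along(t_ms))
  pos <- cbind(1:1000, 1001:2000, 2001:3000)
  d0 <- align_for_horizon(features, pos, 0)
  expect_equal(d0$Y[, 1], t_ms)
  d50 <- align_for_horizon(features, pos, 50)
  expect_equal(d50$Y[, 1], t_ms[t_ms + 50 <= 1000] + 50)
  # rows whose target time falls beyond the series are dropped
  expect_identical(nrow(d50$X), sum(t_ms + 50 <= 1000))
  d300 <- align_for_horizon(features, pos, 300)
  expect_identical(nrow(d300$X), sum(t_ms + 300 <= 1000))
  expect_error(align_for_horizon(features, pos, -10),
               class = "emgdecode_horizon_error")
  expect_error(align_for_horizon(features, pos, 1e6),
               class = "emgdecode_horizon_error")
})

test_that("evaluating perfect predictions gives CC 1 and NRMSE 0", {
  set.seed(53)
  X <- matrix(runif(150), 50, 3)
  Y <- matrix(runif(150), 50, 3)
  model <- rfnn_fit(X, Y, rfnn_config(n_rules = 4L, epochs = 5L))
  X_test <- matrix(runif(90), 30, 3)
  preds <- forward_sequence(model, X_test)
  d <- structure(list(X = X_test, Y = preds[, , drop = FALSE],
                      t_ms = seq_len(30), horizon_ms = 0),
                 class = "aligned_dataset")
  report <- evaluate_fold(model, d)
  expect_equal(report$cc_mean, 1, tolerance = 1e-10)
  expect_equal(report$nrmse_mean, 0, tolerance = 1e-10)
  expect_error(evaluate_fold(model, list()),
               class = "emgdecode_input_error")
})

test_that("fold plans partition the cycles reproducibly", {
  plan <- emgdecode:::make_cv_plan(45L, 5L, seed = 3L)
  expect_length(plan, 45L)
  expect_identical(sort(unique(plan)), 1:5)
  expect_true(all(table(plan) == 9L))
  expect_identical(plan, emgdecode:::make_cv_plan(45L, 5L, seed = 3L))
  expect_false(identical(plan, emgdecode:::make_cv_plan(45L, 5L, seed = 4L)))
})

test_that("cross-validation is seeded, exhaustive and shape-stable", {
  segs <- quick_segments()
  cfg <- rfnn_config(n_rules = 5L, epochs = 10L, patience = 5L, seed = 2L)
  cv1 <- cross_validate(segs, feature_spec(), cfg, horizon_ms = 250,
                        seed = 6L)
  cv2 <- cross_validate(segs, feature_spec(), cfg, horizon_ms = 250,
                        seed = 6L)
  expect_identical(nrow(cv1), 5L)
  expect_equal(as.data.frame(cv1), as.data.frame(cv2))
  plan <- attr(cv1, "cv_plan")
  expect_identical(sort(unique(plan)), 1:5)
  g <- glance(cv1)
  expect_identical(nrow(g), 1L)
  expect_equal(g$cc_mean, mean(cv1$cc_mean))
  expect_error(cross_validate(segs[1:3], feature_spec(), cfg),
               class = "emgdecode_input_error")
})

test_that("condition comparison reproduces the pooled t formula", {
  a <- c(1, 2, 3)
  ident <- compare_conditions(a, a)
  expect_equal(ident$t, 0, tolerance = 1e-12)
  expect_equal(ident$p_value, 1, tolerance = 1e-12)
  set.seed(54)
  x <- rnorm(8, mean = 1)
  y <- rnorm(10, mean = 0.5)
  res <- compare_conditions(x, y)
  # textbook pooled-variance oracle
  sp2 <- ((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) /
    (length(x) + length(y) - 2)
  t_oracle <- (mean(x) - mean(y)) /
    sqrt(sp2 * (1 / length(x) + 1 / length(y)))
  df <- length(x) + length(y) - 2
  p_oracle <- 2 * pt(-abs(t_oracle), df)
  expect_equal(res$t, t_oracle, tolerance = 1e-10)
  expect_equal(res$p_value, p_oracle, tolerance = 1e-10)
  expect_equal(res$df, df)
  swapped <- compare_conditions(y, x)
  expect_equal(swapped$t, -res$t, tolerance = 1e-12)
  expect_equal(swapped$p_value, res$p_value, tolerance = 1e-12)
  expect_error(compare_conditions(rep(1, 3), rep(2, 3)),
               class = "emgdecode_metric_error")
  expect_error(compare_conditions(1, 1:3), class = "emgdecode_input_error")
})

test_that("the horizon sweep tables one row per horizon and degrades far out", {
  segs <- quick_segments()
  cfg <- rfnn_config(n_rules = 5L, epochs = 20L, patience = 10L, seed = 2L)
  sweep <- horizon_sweep(segs, feature_spec(), cfg,
                         horizons = c(300, 600), seed = 6L)
  expect_s3_class(sweep, "horizon_sweep")
  expect_identical(nrow(sweep), 2L)
  expect_identical(sweep$horizon_ms, c(300, 600))
  # far beyond the generative lead, accuracy decays
  expect_gte(sweep$nrmse_mean[sweep$horizon_ms == 600],
             sweep$nrmse_mean[sweep$horizon_ms == 300])
})
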
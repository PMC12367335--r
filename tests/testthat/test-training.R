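test_that("training configuration is validated", {
  expect_error(train_config(split_fractions = c(0.5, 0.5)), "summing to 1")
  expect_error(train_config(lr_grid = numeric(0)), "non-empty")
  expect_error(train_config(batch_size = 0), "batch_size")
  expect_error(improvement_pct(0, 1), "mse_base")
})

test_that("the stratified hold-out split has the printed sizes and composition", {
  co <- toy_cohort(n = 1600, seed = 83)
  cfg <- train_config(seed = 11)
  sp <- split_holdout(co, cfg)
  expect_equal(length(sp$train), 900)
  expect_equal(length(sp$validation), 300)
  expect_equal(length(sp$test), 400)
  # disjoint and exhaustive
  ids <- c(names(sp$train$records), names(sp$validation$records), names(sp$test$records))
  expect_equal(sort(ids), sort(names(co$records)))
  # per-stratum composition matches the pool: each split holds one quarter
  # of its records in each LOS quartile (+/- rounding)
  qs <- stats::quantile(cohort_los(co), c(0.25, 0.5, 0.75))
  for (s in sp) {
    bins <- table(cut(cohort_los(s), c(-Inf, qs, Inf)))
    expect_lt(max(abs(bins - length(s) / 4)), 4)
  }
  # same seed -> identical assignment; different seed -> different
  sp2 <- split_holdout(co, cfg)
  expect_identical(names(sp$train$records), names(sp2$train$records))
  sp3 <- split_holdout(co, cfg, seed = 12)
  expect_false(identical(names(sp$train$records), names(sp3$train$records)))
  expect_equal(length(sp3$train), 900)
  expect_error(split_holdout(toy_cohort(n = 8), train_config(stratify_bins = 4)),
               "fewer stratify_bins")
})

test_that("evaluation metrics follow their definitions", {
  r <- eval_report(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$mse, 0); expect_equal(r$r2, 1)
  truth <- c(1, 2, 3, 6)
  r2 <- eval_report(rep(mean(truth), 4), truth)
  expect_equal(r2$r2, 0)
  expect_equal(r2$mse, mean((truth - mean(truth))^2))
  r3 <- eval_report(c(1, 2, 5), c(1, 2, 3))
  expect_equal(r3$mse, 4 / 3)
  expect_equal(r3$rmse, sqrt(r3$mse), tolerance = 1e-12)
  rneg <- eval_report(c(-2, 4), c(1, 3))
  expect_equal(rneg$n_negative, 1L)
  expect_gte(min(rneg$prediction_quantiles), 0)
})

test_that("improvement_pct is the signed relative MSE change", {
  expect_equal(improvement_pct(10, 8), 20)
  expect_equal(improvement_pct(8, 10), -25)
  expect_equal(improvement_pct(3.7, 3.7), 0)
})

test_that("training converges to the constant on degenerate data", {
  set.seed(91)
  records <- lapply(1:40, function(i) toy_stay(sprintf("d%02d", i), n = 40, los = 3))
  co <- cohort_table(records)
  cfg <- train_config(model_kind = "lstm", window_hours = 3, hidden_dim = 4L,
                      lr_grid = 0.1, max_epochs = 60L, stratify_bins = 1L, seed = 3L)
  sp <- split_holdout(co, cfg)
  fit <- suppressWarnings(train_model(sp$train, sp$validation, cfg))
  expect_lt(fit$best_val, 0.05)
  preds <- predict(fit, sp$test)
  expect_lt(max(abs(preds - 3)), 0.5)
})

test_that("early stopping halts patience+1 epochs after the last improvement", {
  # all-zero inputs and zero targets: loss is exactly zero from epoch 1
  X <- lapply(1:8, function(i) matrix(0, 6, 3))
  y <- rep(0, 8)
  th0 <- wtlstm:::weights_to_theta(lstm_weights(3, 2, init = "zero", bias_enabled = TRUE))
  res <- wtlstm:::cpp_train(X, y, X, y, th0, 3L, 2L, FALSE, 0.1, 4L, 100L, 3L, 1L)
  expect_equal(res$epochs_run, 4L)  # epoch 1 improves, then patience 3
  expect_equal(res$best_epoch, 1L)
})

test_that("identically seeded fits are bit-identical and the checkpoint is the grid winner", {
  co <- toy_cohort(n = 120, seed = 13)
  cfg <- train_config(model_kind = "lstm", window_hours = 3, hidden_dim = 6L,
                      lr_grid = c(0.08, 0.12), max_epochs = 15L, seed = 21L)
  sp <- split_holdout(co, cfg)
  f1 <- train_model(sp$train, sp$validation, cfg)
  f2 <- train_model(sp$train, sp$validation, cfg)
  expect_identical(f1$theta, f2$theta)
  expect_identical(f1$best_val, f2$best_val)
  expect_true(f1$best_lr %in% cfg$lr_grid)
  # the reported best_val is the minimum validation loss in the history
  expect_equal(f1$best_val, min(f1$history$val_loss[f1$history$lr == f1$best_lr]))
})

test_that("the linear-regression baseline recovers a linear LOS signal", {
  set.seed(97)
  records <- lapply(1:80, function(i) {
    los <- runif(1, 1, 8)
    n <- 40
    stay_record(sprintf("l%02d", i), rep(60 + 4 * los, n), rep(18, n),
                rep(96, n), los = los)
  })
  co <- cohort_table(records)
  cfg <- train_config(model_kind = "linreg", window_hours = 3, seed = 7L,
                      stratify_bins = 2L)
  sp <- split_holdout(co, cfg)
  fit <- train_model(sp$train, sp$validation, cfg)
  rep_ <- evaluate_model(fit, sp$test)
  expect_lt(rep_$mse, 1e-10)
  expect_equal(rep_$r2, 1, tolerance = 1e-8)
})

test_that("run_experiment emits one cell per model/window with repeat summaries", {
  co <- toy_cohort(n = 90, seed = 37)
  cfg <- train_config(hidden_dim = 4L, lr_grid = 0.1, max_epochs = 8L,
                      n_repeats = 2L, seed = 17L)
  ex <- run_experiment(co, cfg, model_kinds = c("lstm", "linreg"), windows = 3)
  expect_s3_class(ex, "wt_experiment")
  expect_equal(nrow(ex$runs), 4)           # 2 models x 1 window x 2 repeats
  expect_equal(nrow(ex$summary), 2)
  expect_null(ex$improvement)              # no wtlstm/lstm pair
  expect_true(all(ex$summary$sd_mse >= 0))
})

test_that("level-0 denoising reproduces the plain LSTM cell exactly", {
  co <- toy_cohort(n = 90, seed = 41)
  cfg <- train_config(hidden_dim = 4L, lr_grid = c(0.1), max_epochs = 8L,
                      n_repeats = 2L, seed = 19L,
                      denoise = denoise_config(level = 0))
  ex <- run_experiment(co, cfg, model_kinds = c("wtlstm", "lstm"), windows = 3)
  wt <- ex$runs[ex$runs$model == "wtlstm", ]
  plain <- ex$runs[ex$runs$model == "lstm", ]
  expect_identical(wt$mse, plain$mse)
  expect_equal(ex$improvement$improvement_pct, 0)
})
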
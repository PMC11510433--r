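test_that("registry exposes the expected families, all instantiable on a toy", {
  reg <- registry()
  expect_true(all(c("nusvr", "svr", "random_forest", "gradient_boosting",
                    "knn", "ridge", "lasso", "linear", "mlp") %in% names(reg)))
  toy <- make_linear_toy(n = 10, p = 3, noise_sd = 0.1, seed = 1)
  for (nm in names(reg)) {
    fit <- reg_fit(reg[[nm]], toy$X, toy$y, seed = 2)
    pred <- reg_predict(fit, toy$X)
    expect_length(pred, 10)
    expect_true(all(is.finite(pred)), info = nm)
  }
  expect_error(registry("not_a_model"), "unknown regressor")
})

test_that("reg_predict enforces the training feature count", {
  toy <- make_linear_toy(n = 15, p = 4, seed = 1)
  fit <- reg_fit(registry("linear")[[1]], toy$X, toy$y)
  expect_error(reg_predict(fit, toy$X[, 1:3]), "mismatch")
})

test_that("tune returns the sampled point for a single trial and is deterministic", {
  toy <- make_linear_toy(n = 50, noise_sd = 0.2, seed = 4)
  cfg1 <- tuning_config("knn", n_trials = 1, seed = 11)
  r1 <- tune(cfg1, toy$X, toy$y)
  expect_equal(nrow(r1$knn$trace), 1)
  expect_false(r1$knn$failed)
  expect_equal(r1$knn$sampler, "tpe")

  cfg <- tuning_config(c("knn", "ridge"), n_trials = 15, seed = 11)
  a <- tune(cfg, toy$X, toy$y)
  b <- tune(cfg, toy$X, toy$y)
  expect_identical(a$knn$best_params, b$knn$best_params)
  expect_identical(a$ridge$trace, b$ridge$trace)
})

test_that("tuned linear regression beats the intercept-only baseline", {
  toy <- make_linear_toy(n = 80, noise_sd = 0.1, seed = 6)
  sp <- train_test_split(seq_len(80), 0.25, seed = 3)
  tr <- setdiff(1:80, sp$test_idx); te <- sp$test_idx
  cfg <- tuning_config("linear", n_trials = 1, seed = 1)
  res <- tune(cfg, toy$X[tr, ], toy$y[tr])
  rep <- model_report(res$linear, toy$X[tr, ], toy$y[tr],
                      toy$X[te, , drop = FALSE], toy$y[te], seed = 1)
  # closed-form least-squares oracle: the intercept-only model predicts the
  # training mean, with test RMSD equal to the RMS deviation around it
  baseline <- rmsd(rep(mean(toy$y[tr]), length(te)), toy$y[te])
  expect_lt(rep$test$rmsd, baseline)
})

test_that("a regressor whose trials all fail is reported failed, run continues", {
  toy <- make_linear_toy(n = 40, p = 1, noise_sd = 0.1, seed = 2)
  # glmnet requires >= 2 feature columns, so ridge fails on p = 1
  cfg <- tuning_config(c("ridge", "knn"), n_trials = 2, seed = 5)
  res <- suppressWarnings(tune(cfg, toy$X, toy$y))
  expect_true(res$ridge$failed)
  expect_false(res$knn$failed)
})

test_that("evaluate computes held-out metrics consistent with scoring", {
  toy <- make_linear_toy(n = 50, noise_sd = 0, seed = 8)
  fit <- reg_fit(registry("linear")[[1]], toy$X, toy$y)
  ev <- evaluate(fit, toy$X, toy$y)
  expect_equal(ev$rmsd, 0, tolerance = 1e-10)
  expect_equal(ev$mape, 0, tolerance = 1e-9)
  expect_equal(ev$outlier_percent, 0)

  noisy <- make_linear_toy(n = 50, noise_sd = 0.5, seed = 9)
  fit2 <- reg_fit(registry("knn")[[1]], noisy$X, noisy$y, list(k = 3))
  pred <- reg_predict(fit2, noisy$X)
  ev2 <- evaluate(fit2, noisy$X, noisy$y)
  expect_equal(ev2$rmsd, rmsd(pred, noisy$y), tolerance = 1e-12)
  expect_equal(ev2$mape, mape(pred, noisy$y), tolerance = 1e-12)

  # constant predictor on centered targets: RMSD equals the population SD
  y_ctr <- noisy$y - mean(noisy$y)
  cfit <- reg_fit(constant_regressor(0), noisy$X, y_ctr)
  expect_equal(evaluate(cfit, noisy$X, y_ctr - 1)$rmsd,
               sqrt(mean((y_ctr - 1 - 0)^2)), tolerance = 1e-12)
})

test_that("the published nu-SVR preset is stored verbatim and usable", {
  ps <- nusvr_preset()
  expect_equal(ps$nu, 0.4754)
  expect_equal(ps$gamma, 0.8358)
  expect_equal(ps$C, 6.8251)
  expect_equal(ps$degree, 8)
  expect_equal(ps$max_iter, 61378442)
  expect_gt(ps$nu, 0)
  expect_lt(ps$nu, 1)
  toy <- make_linear_toy(n = 30, noise_sd = 0.1, seed = 3)
  fit <- fit_nusvr_preset(toy$X, toy$y)
  expect_length(reg_predict(fit, toy$X), 30)
})

test_that("overfitting_screen drops high test/train ratios and ranks survivors", {
  mk <- function(name, train_mape, test_mape) {
    structure(list(regressor_name = name,
                   train = list(mape = train_mape),
                   test = list(mape = test_mape)),
              class = "model_report")
  }
  reports <- list(mk("overfit", 5, 50), mk("ok2", 10, 12), mk("ok1", 10, 10))
  kept <- overfitting_screen(reports, threshold = 2)
  expect_equal(vapply(kept, `[[`, "", "regressor_name"), c("ok1", "ok2"))
  expect_length(overfitting_screen(list()), 0)
  expect_length(overfitting_screen(list(mk("equal", 8, 8))), 1)
})

test_that("nu-SVR solver respects nu as a support-vector budget and fits signal", {
  toy <- make_linear_toy(n = 60, p = 2, noise_sd = 0.05, seed = 12)
  fit <- reg_fit(registry("nusvr")[[1]], toy$X, toy$y,
                 list(C = 10, nu = 0.5, gamma = 0.5))
  pred <- reg_predict(fit, toy$X)
  expect_lt(rmsd(pred, toy$y), 0.5 * sd(toy$y))
  # epsilon-SVR with epsilon = 0 approaches kernel-ridge-like interpolation
  fit2 <- reg_fit(registry("svr")[[1]], toy$X, toy$y,
                  list(C = 100, epsilon = 0.001, gamma = 0.5))
  expect_lt(mae(reg_predict(fit2, toy$X), toy$y), 0.05)
})

test_that("pure-noise descriptor columns do not lower the loss beyond its CV floor", {
  toy <- make_linear_toy(n = 60, noise_sd = 0.2, seed = 15)
  toy$y <- toy$y - 2
  lin <- registry("linear")[[1]]
  clean <- vapply(1:3, function(s)
    custom_loss(lin, list(), toy$X, toy$y, seed = s)$total, 0)
  floor <- max(stats::sd(clean), 1e-3)
  noise_cols <- dessol:::with_local_seed(99, matrix(rnorm(60 * 5), 60, 5))
  aug <- custom_loss(lin, list(), cbind(toy$X, noise_cols), toy$y, seed = 1)$total
  expect_gte(aug, min(clean) - 3 * floor)
})
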
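# Ten-line brute-force oracles for the metrics.
rmsd_oracle <- function(pred, obs) {
  s <- 0
  for (i in seq_along(pred)) s <- s + (obs[i] - pred[i])^2
  sqrt(s / length(pred))
}
mape_oracle <- function(pred, obs) {
  s <- 0
  for (i in seq_along(pred)) s <- s + abs((obs[i] - pred[i]) / obs[i])
  100 * s / length(pred)
}

test_that("rmsd and mape match their examples and oracles", {
  expect_equal(rmsd(c(-2, -3), c(-2, -3)), 0)
  expect_equal(rmsd(-1, -2), 1)
  expect_equal(mape(-1, -2), 50)
  expect_equal(mape(c(-1, -2), c(-2, -4)), 50)
  expect_equal(mape(c(-2, -4), c(-2, -4)), 0)
  for (s in 1:20) {
    v <- dessol:::with_local_seed(s, list(p = rnorm(50), o = rnorm(50) - 3))
    expect_equal(rmsd(v$p, v$o), rmsd_oracle(v$p, v$o), tolerance = 1e-12)
    expect_equal(mape(v$p, v$o), mape_oracle(v$p, v$o), tolerance = 1e-12)
    # permutation invariance
    perm <- dessol:::with_local_seed(s + 100, sample.int(50))
    expect_equal(rmsd(v$p[perm], v$o[perm]), rmsd(v$p, v$o), tolerance = 1e-12)
  }
  expect_error(rmsd(1:3, 1:2), "mismatch")
  expect_error(rmsd(numeric(0), numeric(0)), "empty")
  expect_error(mape(c(1, 2), c(0, 2)), "zero")
})

test_that("rmsd dominates mae on any error vector", {
  for (s in 1:10) {
    v <- dessol:::with_local_seed(s, list(p = rnorm(30), o = rnorm(30)))
    expect_gte(rmsd(v$p, v$o), mae(v$p, v$o))
  }
})

test_that("outlier_fraction flags 3-sigma deviations with population SD", {
  # all equal errors: SD = 0, nothing is an outlier
  expect_equal(outlier_fraction(rep(-2, 5), rep(-2.5, 5))$percent, 0)
  # 99 zero errors + one error of 10: population SD = sqrt(100/100 - 0.01),
  # 3*SD ~ 2.985 < 10, so only that point is flagged
  pred <- rep(-3, 100)
  obs <- rep(-3, 100); obs[40] <- -3 + 10
  of <- outlier_fraction(pred, obs)
  expect_equal(of$percent, 1)
  expect_identical(which(of$mask), 40L)
  # scale invariance of the flagged set
  of2 <- outlier_fraction(pred, -3 + 2 * (obs + 3))
  expect_identical(of2$mask, of$mask)
  expect_error(outlier_fraction(1, 1), "at least 2")
})

test_that("learning_curve returns five deterministic points and exposes memorization", {
  toy <- make_linear_toy(n = 60, noise_sd = 0.3, seed = 3)
  knn <- registry("knn")[[1]]
  lc <- learning_curve(knn, list(k = 1), toy$X, toy$y, seed = 5)
  expect_equal(nrow(lc), 5)
  expect_equal(lc$fraction, c(0.5, 0.625, 0.75, 0.875, 1))
  expect_true(all(diff(lc$n) >= 0))
  # 1-NN memorizes: zero train error, positive validation error
  expect_lt(mean(lc$train_mae), 1e-10)
  expect_gt(mean(lc$test_mae), 0.1)
  lc2 <- learning_curve(knn, list(k = 1), toy$X, toy$y, seed = 5)
  expect_identical(lc, lc2)
  expect_error(learning_curve(knn, list(k = 1), toy$X[1:10, ], toy$y[1:10]),
               "at least")
})

test_that("custom_loss is near zero for a perfect generalizing model", {
  toy <- make_linear_toy(n = 60, noise_sd = 0, seed = 2)
  toy$y <- toy$y - 3  # keep every target (and perfect prediction) negative
  lin <- registry("linear")[[1]]
  sb <- custom_loss(lin, list(), toy$X, toy$y, seed = 1)
  expect_lt(sb$total, 1e-8)
  expect_equal(sb$positive_fraction, 0)
  expect_equal(sb$outlier_percent, 0)
})

test_that("custom_loss penalizes positive predictions and the LCA gap", {
  toy <- make_linear_toy(n = 60, noise_sd = 0.3, seed = 7)
  # a constant positive predictor: positive_fraction = 1 contributes w_pos
  pos <- constant_regressor(0.1)
  sb <- custom_loss(pos, list(), toy$X, toy$y, seed = 1)
  expect_equal(sb$positive_fraction, 1)
  expect_gte(sb$total, 1)
  # increasing w_lca with a positive gap strictly increases the total
  knn <- registry("knn")[[1]]
  s1 <- custom_loss(knn, list(k = 1), toy$X, toy$y, seed = 3,
                    weights = c(lca = 1))
  s2 <- custom_loss(knn, list(k = 1), toy$X, toy$y, seed = 3,
                    weights = c(lca = 5))
  expect_gt(s1$lca_gap, 0)
  expect_gt(s2$total, s1$total)
  # total is the declared weighted sum of its parts
  expect_equal(s1$total,
               s1$base_error + s1$weights[["pos"]] * s1$positive_fraction +
                 s1$weights[["out"]] * s1$outlier_percent / 100 +
                 s1$weights[["lca"]] * max(s1$lca_gap, 0),
               tolerance = 1e-12)
})

test_that("custom_loss supports the MSE base metric", {
  toy <- make_linear_toy(n = 60, noise_sd = 0.2, seed = 9)
  lin <- registry("linear")[[1]]
  s_mae <- custom_loss(lin, list(), toy$X, toy$y, seed = 1, base_metric = "mae")
  s_mse <- custom_loss(lin, list(), toy$X, toy$y, seed = 1, base_metric = "mse")
  fit <- reg_fit(lin, toy$X, toy$y)
  pred <- reg_predict(fit, toy$X)
  expect_equal(s_mae$base_error, mae(pred, toy$y), tolerance = 1e-12)
  expect_equal(s_mse$base_error, mean((toy$y - pred)^2), tolerance = 1e-12)
})
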
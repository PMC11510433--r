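# Evaluation metrics and the custom composite loss.
#
# The loss combines the in-sample base error with three penalties aimed at
# generalization rather than fit: the frequency of physically inadmissible
# positive predictions (log10 of a mole fraction must be negative), the
# share of 3-sigma outliers, and the mean train/validation gap of a
# five-point learning curve (cross-validated MAE at increasing training
# sizes) -- a model that memorizes shows a large gap and is penalized even
# if its in-sample error is tiny.

check_pair <- function(pred, obs) {
  assert_that(is.numeric(pred) && is.numeric(obs), "pred and obs must be numeric")
  assert_that(length(pred) == length(obs),
              "length mismatch: %d predictions vs %d observations",
              length(pred), length(obs))
  assert_that(length(pred) >= 1L, "empty input")
  invisible(TRUE)
}

#' Root-mean-square deviation
#'
#' `sqrt(mean((obs - pred)^2))` on the decadal-log solubility scale.
#'
#' @param pred,obs numeric vectors of equal nonzero length.
#' @return non-negative number.
#' @export
rmsd <- function(pred, obs) {
  check_pair(pred, obs)
  sqrt(mean((obs - pred)^2))
}

#' Mean absolute percentage error
#'
#' `100/n * sum(|(obs - pred)/obs|)`; every observation must be nonzero.
#'
#' @inheritParams rmsd
#' @return percentage (>= 0).
#' @export
mape <- function(pred, obs) {
  check_pair(pred, obs)
  if (any(obs == 0)) stop_f("mape undefined: observation(s) equal to zero")
  100 * mean(abs((obs - pred) / obs))
}

#' Mean absolute error
#'
#' @inheritParams rmsd
#' @return non-negative number.
#' @export
mae <- function(pred, obs) {
  check_pair(pred, obs)
  mean(abs(obs - pred))
}

#' Three-sigma outlier fraction
#'
#' Flags predictions whose error exceeds `k` times the population standard
#' deviation (ddof 0) of the errors of the same prediction set. When all
#' errors are identical the SD is zero and no point is an outlier.
#'
#' @inheritParams rmsd
#' @param k sigma multiplier, default 3.
#' @return list with `percent` (100 * flagged / n) and logical `mask`.
#' @export
outlier_fraction <- function(pred, obs, k = 3) {
  check_pair(pred, obs)
  n <- length(pred)
  assert_that(n >= 2L, "outlier_fraction needs at least 2 points")
  e <- obs - pred
  sd_pop <- sqrt(mean((e - mean(e))^2))
  # an SD at floating-point-noise scale counts as zero (all-identical errors)
  degenerate <- sd_pop <= 1e-12 * max(1, max(abs(e)))
  mask <- if (degenerate) rep(FALSE, n) else abs(e) > k * sd_pop
  list(percent = 100 * sum(mask) / n, mask = mask)
}

#' Five-point learning curve by cross-validated MAE
#'
#' For each training fraction in `fractions` (default five points evenly
#' spaced from 50% to 100% of the data), a seeded subsample is evaluated by
#' 5-fold cross-validation: the model is fitted on four folds and its MAE
#' recorded on both the fitting folds (train) and the held-out fold
#' (validation), averaged over folds.
#'
#' @param reg a regressor from [registry()].
#' @param params hyperparameter list for the regressor.
#' @param X numeric feature matrix (n >= 25).
#' @param y numeric targets.
#' @param seed integer seed (subsampling and fold assignment).
#' @param fractions increasing fractions in (0, 1], default
#'   `c(0.5, 0.625, 0.75, 0.875, 1)`.
#' @param folds number of CV folds, default 5.
#' @return object of class `learning_curve`: data frame with columns
#'   `fraction`, `n`, `train_mae`, `test_mae`.
#' @export
learning_curve <- function(reg, params, X, y, seed = 1L,
                           fractions = c(0.5, 0.625, 0.75, 0.875, 1), folds = 5L) {
  assert_that(is.matrix(X) && is.numeric(y) && nrow(X) == length(y),
              "X must be a matrix with one row per target")
  n <- nrow(X)
  assert_that(n >= folds * 5L, "learning curve needs at least %d samples, got %d",
              folds * 5L, n)
  assert_that(all(diff(fractions) > 0) && all(fractions > 0) && all(fractions <= 1),
              "fractions must be increasing in (0, 1]")
  perm <- with_local_seed(derive_seed(seed, "lc_perm"), sample.int(n))
  out <- data.frame(fraction = fractions, n = NA_integer_,
                    train_mae = NA_real_, test_mae = NA_real_)
  for (j in seq_along(fractions)) {
    m <- max(folds * 2L, floor(n * fractions[j]))
    idx <- perm[seq_len(m)]
    Xs <- X[idx, , drop = FALSE]; ys <- y[idx]
    fold_id <- with_local_seed(derive_seed(seed, paste0("lc_folds", j)),
                               sample(rep_len(seq_len(folds), m)))
    tr_err <- te_err <- numeric(folds)
    for (f in seq_len(folds)) {
      hold <- fold_id == f
      if (sum(hold) < 1L || sum(!hold) < 2L) stop_f("degenerate CV fold (size %d)", sum(hold))
      fit <- reg_fit(reg, Xs[!hold, , drop = FALSE], ys[!hold], params,
                     seed = derive_seed(seed, paste0("lc_fit", j, "_", f)))
      tr_err[f] <- mae(reg_predict(fit, Xs[!hold, , drop = FALSE]), ys[!hold])
      te_err[f] <- mae(reg_predict(fit, Xs[hold, , drop = FALSE]), ys[hold])
    }
    out$n[j] <- m
    out$train_mae[j] <- mean(tr_err)
    out$test_mae[j] <- mean(te_err)
  }
  class(out) <- c("learning_curve", class(out))
  out
}

#' Custom composite loss with learning-curve penalty
#'
#' `total = base_error + w_pos * positive_fraction +
#'  w_out * outlier_percent/100 + w_lca * max(lca_gap, 0)` where the base
#' error (MAE by default, MSE available) and the positive/outlier penalties
#' are computed on the training-set predictions of the model fitted on all
#' of `X`, and `lca_gap` is the mean validation-minus-train MAE over the
#' five learning-curve points.
#'
#' @inheritParams learning_curve
#' @param weights named numeric, penalty weights `pos`, `out`, `lca`
#'   (default all 1).
#' @param base_metric `"mae"` (default) or `"mse"`.
#' @return object of class `score_breakdown` with fields `base_error`,
#'   `positive_fraction`, `outlier_percent`, `lca_gap`, `weights`,
#'   `base_metric` and `total`.
#' @export
custom_loss <- function(reg, params, X, y, seed = 1L,
                        weights = c(pos = 1, out = 1, lca = 1),
                        base_metric = c("mae", "mse")) {
  base_metric <- match.arg(base_metric)
  w <- c(pos = 1, out = 1, lca = 1)
  w[names(weights)] <- weights
  fit <- reg_fit(reg, X, y, params, seed = derive_seed(seed, "loss_fit"))
  pred <- reg_predict(fit, X)
  base <- if (base_metric == "mae") mae(pred, y) else mean((y - pred)^2)
  pos_frac <- mean(pred >= 0)
  out_pct <- outlier_fraction(pred, y)$percent
  lc <- learning_curve(reg, params, X, y, seed = seed)
  gap <- mean(lc$test_mae - lc$train_mae)
  total <- base + w[["pos"]] * pos_frac + w[["out"]] * out_pct / 100 +
    w[["lca"]] * max(gap, 0)
  structure(
    list(base_error = base, positive_fraction = pos_frac,
         outlier_percent = out_pct, lca_gap = gap, weights = w,
         base_metric = base_metric, total = total,
         learning_curve = lc),
    class = "score_breakdown"
  )
}

#' @export
print.score_breakdown <- function(x, ...) {
  cat(sprintf(paste0("<score_breakdown> total = %.6g\n",
                     "  base_error (%s)   = %.6g\n",
                     "  positive_fraction = %.6g\n",
                     "  outlier_percent   = %.6g\n",
                     "  lca_gap           = %.6g\n"),
              x$total, x$base_metric, x$base_error, x$positive_fraction,
              x$outlier_percent, x$lca_gap))
  invisible(x)
}
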
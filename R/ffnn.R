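#' Specification of a single-hidden-layer network
#'
#' The calibration network has exactly one hidden layer of `n_hidden` tanh
#' units (the searched range in this design is 5-20) and a linear output
#' for regression or a softmax output for classification. Regression
#' networks train by Levenberg-Marquardt (damped Gauss-Newton on the sum of
#' squared errors) or scaled conjugate gradient; classification uses scaled
#' conjugate gradient on the cross-entropy.
#'
#' @param n_hidden Hidden units (default 8).
#' @param trainer `"levenberg_marquardt"` or `"scaled_conjugate_gradient"`.
#' @param max_epochs Training epoch cap (default 100).
#' @param patience Early-stopping patience in validation checks (default 6).
#' @param seed Integer seed for weight initialization and the validation
#'   split.
#' @return A list of class `ffnn_spec`.
#' @export
ffnn_spec <- function(n_hidden = 8L,
                      trainer = c("levenberg_marquardt",
                                  "scaled_conjugate_gradient"),
                      max_epochs = 100L, patience = 6L, seed = 1L) {
  if (n_hidden < 1) stop("n_hidden must be >= 1")
  structure(list(n_hidden = as.integer(n_hidden),
                 trainer = match.arg(trainer),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 seed = as.integer(seed)),
            class = "ffnn_spec")
}

# ---- parameter packing -----------------------------------------------------

ffnn_init <- function(p, H, K = 1L, seed = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  s <- 1 / sqrt(p + 1)
  list(W1 = matrix(stats::runif(H * p, -s, s), H, p),
       b1 = stats::runif(H, -s, s),
       W2 = matrix(stats::runif(K * H, -0.5, 0.5), K, H),
       b2 = stats::runif(K, -0.5, 0.5))
}

ffnn_pack <- function(w) c(as.numeric(w$W1), w$b1, as.numeric(w$W2), w$b2)

ffnn_unpack <- function(theta, p, H, K = 1L) {
  i <- 0L
  W1 <- matrix(theta[seq_len(H * p)], H, p); i <- H * p
  b1 <- theta[i + seq_len(H)]; i <- i + H
  W2 <- matrix(theta[i + seq_len(K * H)], K, H); i <- i + K * H
  b2 <- theta[i + seq_len(K)]
  list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
}

ffnn_forward <- function(w, X) {
  A <- tanh(sweep(X %*% t(w$W1), 2, w$b1, `+`))
  list(A = A, out = sweep(A %*% t(w$W2), 2, w$b2, `+`))
}

# ---- Levenberg-Marquardt for the regression net ---------------------------

# Damped Gauss-Newton on SSE. On a rejected step the damping is multiplied
# by 10 and the weights untouched; on acceptance it is divided by 10. Stops
# when damping exceeds 1e10, the epoch cap is hit, or validation patience
# runs out.
lm_train <- function(X, y, theta, p, H, max_epochs, val, patience) {
  lambda <- 1e-3
  sse_of <- function(th) {
    w <- ffnn_unpack(th, p, H)
    r <- drop(ffnn_forward(w, X)$out) - y
    sum(r * r)
  }
  val_rmse <- function(th) {
    w <- ffnn_unpack(th, p, H)
    sqrt(mean((drop(ffnn_forward(w, val$X)$out) - val$y)^2))
  }
  sse <- sse_of(theta)
  best_val <- if (!is.null(val)) val_rmse(theta) else Inf
  best_theta <- theta
  bad <- 0L
  trace <- numeric(0)
  for (epoch in seq_len(max_epochs)) {
    w <- ffnn_unpack(theta, p, H)
    fw <- ffnn_forward(w, X)
    r <- drop(fw$out) - y
    S <- fw$A                                   # n x H
    D <- (1 - S^2) * matrix(w$W2[1, ], nrow(X), H, byrow = TRUE)
    J <- cbind(X[, rep(seq_len(p), each = H), drop = FALSE] *
                 D[, rep(seq_len(H), p), drop = FALSE],   # dW1
               D,                                          # db1
               S,                                          # dW2
               1)                                          # db2
    g <- drop(crossprod(J, r))
    A <- crossprod(J)
    accepted <- FALSE
    while (!accepted && lambda <= 1e10) {
      step <- tryCatch(
        solve(A + lambda * diag(nrow(A)), g),
        error = function(e) NULL
      )
      if (!is.null(step)) {
        cand <- theta - step
        sse_new <- sse_of(cand)
        if (is.finite(sse_new) && sse_new <= sse) {
          theta <- cand
          sse <- sse_new
          lambda <- lambda / 10
          accepted <- TRUE
        } else {
          lambda <- lambda * 10
        }
      } else {
        lambda <- lambda * 10
      }
    }
    trace <- c(trace, sse)
    if (!accepted) break                       # damping exhausted
    if (!is.null(val)) {
      v <- val_rmse(theta)
      if (v < best_val) {
        best_val <- v
        best_theta <- theta
        bad <- 0L
      } else {
        bad <- bad + 1L
        if (bad >= patience) break
      }
    } else {
      best_theta <- theta
    }
    if (sse < 1e-14) break
  }
  list(theta = if (is.null(val)) theta else best_theta,
       sse_trace = trace, final_sse = sse)
}

# ---- scaled conjugate gradient (Moller 1993) ------------------------------

# Generic SCG on f(theta) -> list(loss, grad); deterministic.
scg_optimize <- function(fg, theta, max_iter = 200L,
                         monitor = NULL, patience = Inf) {
  sigma0 <- 1e-5
  lambda <- 1e-6
  lambda_bar <- 0
  fv <- fg(theta)
  f <- fv$loss
  r <- -fv$grad
  d <- r
  success <- TRUE
  best_mon <- Inf
  best_theta <- theta
  bad <- 0L
  delta <- 0
  for (it in seq_len(max_iter)) {
    if (success) {
      d2 <- sum(d * d)
      if (d2 < 1e-30) break
      sigma <- sigma0 / sqrt(d2)
      g2 <- fg(theta + sigma * d)$grad
      s <- (g2 - (-r)) / sigma
      delta <- sum(d * s)
    }
    delta_reg <- delta + (lambda - lambda_bar) * sum(d * d)
    if (delta_reg <= 0) {
      lambda_bar <- 2 * (lambda - delta_reg / sum(d * d))
      delta_reg <- -delta + lambda_bar * sum(d * d)
      lambda <- lambda_bar
    }
    mu <- sum(d * r)
    alpha <- mu / delta_reg
    theta_new <- theta + alpha * d
    f_new <- fg(theta_new)$loss
    Delta <- 2 * delta_reg * (f - f_new) / (mu * mu)
    if (is.finite(Delta) && Delta >= 0) {
      theta <- theta_new
      fv <- fg(theta)
      f <- fv$loss
      r_new <- -fv$grad
      lambda_bar <- 0
      success <- TRUE
      beta <- (sum(r_new * r_new) - sum(r_new * r)) / mu
      d <- r_new + beta * d
      r <- r_new
      if (Delta >= 0.75) lambda <- lambda / 4
      if (!is.null(monitor)) {
        mv <- monitor(theta)
        if (mv < best_mon) {
          best_mon <- mv
          best_theta <- theta
          bad <- 0L
        } else {
          bad <- bad + 1L
          if (bad >= patience) break
        }
      } else {
        best_theta <- theta
      }
      if (f < 1e-14) break
    } else {
      lambda_bar <- lambda
      success <- FALSE
    }
    if (is.finite(Delta) && Delta < 0.25) lambda <- lambda * 4
    if (lambda > 1e15) break
  }
  if (is.null(monitor)) best_theta <- theta
  list(theta = best_theta, loss = f)
}

scg_train_reg <- function(X, y, theta, p, H, max_epochs, val, patience) {
  fg <- function(th) {
    w <- ffnn_unpack(th, p, H)
    fw <- ffnn_forward(w, X)
    r <- drop(fw$out) - y
    S <- fw$A
    dA <- (r %o% w$W2[1, ]) * (1 - S^2)          # n x H
    list(loss = 0.5 * sum(r * r),
         grad = c(as.numeric(crossprod(dA, X)),  # dW1 (H x p, col-major)
                  colSums(dA),                   # db1
                  drop(crossprod(S, r)),         # dW2
                  sum(r)))
  }
  monitor <- if (is.null(val)) NULL else function(th) {
    w <- ffnn_unpack(th, p, H)
    sqrt(mean((drop(ffnn_forward(w, val$X)$out) - val$y)^2))
  }
  res <- scg_optimize(fg, theta, max_iter = max_epochs,
                      monitor = monitor,
                      patience = if (is.null(val)) Inf else patience)
  list(theta = res$theta, final_sse = 2 * res$loss)
}

# cross-entropy softmax classifier gradient; Y is an n x K indicator matrix
scg_train_cls <- function(X, Y, theta, p, H, K, max_epochs, val, patience) {
  fg <- function(th) {
    w <- ffnn_unpack(th, p, H, K)
    fw <- ffnn_forward(w, X)
    Z <- fw$out - apply(fw$out, 1, max)
    P_mat <- exp(Z) / rowSums(exp(Z))
    E <- P_mat - Y                              # n x K
    S <- fw$A
    dA <- (E %*% w$W2) * (1 - S^2)
    list(loss = -sum(Y * log(pmax(P_mat, 1e-12))),
         grad = c(as.numeric(crossprod(dA, X)),
                  colSums(dA),
                  as.numeric(t(crossprod(S, E))),
                  colSums(E)))
  }
  monitor <- if (is.null(val)) NULL else function(th) {
    w <- ffnn_unpack(th, p, H, K)
    fw <- ffnn_forward(w, val$X)
    Z <- fw$out - apply(fw$out, 1, max)
    P_mat <- exp(Z) / rowSums(exp(Z))
    -sum(val$Y * log(pmax(P_mat, 1e-12)))
  }
  res <- scg_optimize(fg, theta, max_iter = max_epochs,
                      monitor = monitor,
                      patience = if (is.null(val)) Inf else patience)
  res
}

# ---- user-facing training -------------------------------------------------

# learn per-feature min-max scaling to [-1, 1] from training data
fit_scaling <- function(X) {
  lo <- apply(X, 2, min)
  hi <- apply(X, 2, max)
  span <- hi - lo
  span[span == 0] <- 1
  list(lo = lo, span = span)
}

apply_scaling <- function(sc, X) {
  sweep(sweep(X, 2, sc$lo), 2, sc$span, "/") * 2 - 1
}

#' Train the regression calibration network
#'
#' Inputs are min-max scaled to [-1, 1] and the target standardized, both
#' from the training portion only. A validation fraction is carved out for
#' early stopping (patience from the spec); with `val_fraction = 0` the
#' network trains on everything to the epoch cap. Training is deterministic
#' given `spec$seed`.
#'
#' @param X Sample-by-feature matrix.
#' @param y Numeric response.
#' @param spec An [ffnn_spec()].
#' @param val_fraction Fraction held out for early stopping (default 0.15).
#' @return A `calibration_model` (kind `"ffnn"`).
#' @export
ffnn_train <- function(X, y, spec = ffnn_spec(), val_fraction = 0.15) {
  X <- as.matrix(X)
  if (any(!is.finite(X)) || any(!is.finite(y))) {
    stop("non-finite values in training data")
  }
  n <- nrow(X)
  p <- ncol(X)
  H <- spec$n_hidden
  sc <- fit_scaling(X)
  y_mean <- mean(y)
  y_sd <- stats::sd(y)
  if (!is.finite(y_sd) || y_sd == 0) y_sd <- 1
  Xs <- apply_scaling(sc, X)
  ys <- (y - y_mean) / y_sd

  val <- NULL
  tr_idx <- seq_len(n)
  if (val_fraction > 0 && n >= 10) {
    old <- .Random.seed_save()
    n_val <- max(1L, round(val_fraction * n))
    set.seed(spec$seed)
    v_idx <- sample.int(n, n_val)
    .Random.seed_restore(old)
    tr_idx <- setdiff(seq_len(n), v_idx)
    val <- list(X = Xs[v_idx, , drop = FALSE], y = ys[v_idx])
  }
  theta0 <- ffnn_pack(ffnn_init(p, H, 1L, seed = spec$seed))
  fit <- if (spec$trainer == "levenberg_marquardt") {
    lm_train(Xs[tr_idx, , drop = FALSE], ys[tr_idx], theta0, p, H,
             spec$max_epochs, val, spec$patience)
  } else {
    scg_train_reg(Xs[tr_idx, , drop = FALSE], ys[tr_idx], theta0, p, H,
                  spec$max_epochs, val, spec$patience)
  }
  structure(list(kind = "ffnn", spec = spec, p = p,
                 scaling = sc, y_mean = y_mean, y_sd = y_sd,
                 theta = fit$theta,
                 history = fit[setdiff(names(fit), "theta")]),
            class = "calibration_model")
}

#' Predict from a calibration model
#'
#' Applies the frozen scaling then the trained predictor; regression output
#' is clipped below at zero (concentrations cannot be negative). Inputs
#' outside the training min-max range are extrapolated with a warning.
#'
#' @param object A `calibration_model`.
#' @param newdata Sample-by-feature matrix with the training feature count.
#' @param ... Unused.
#' @return Numeric predictions.
#' @export
predict.calibration_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (ncol(X) != object$p) stop("feature count does not match the model")
  hi <- object$scaling$lo + object$scaling$span
  if (any(t(X) < object$scaling$lo - 1e-9) ||
      any(t(X) > hi + 1e-9)) {
    warning("inputs outside the training range; extrapolating")
  }
  Xs <- apply_scaling(object$scaling, X)
  raw <- switch(
    object$kind,
    ffnn = {
      w <- ffnn_unpack(object$theta, object$p, object$spec$n_hidden)
      drop(ffnn_forward(w, Xs)$out)
    },
    linear = drop(cbind(1, Xs) %*% object$coefficients),
    pls = drop(sweep(Xs, 2, object$x_center) %*% object$coefficients) +
      object$y_center_raw,
    svm = svm_rbf_predict(object, Xs),
    stop("unknown model kind ", object$kind)
  )
  pmax(raw * object$y_sd + object$y_mean, 0)
}

#' Search the hidden-layer size
#'
#' Trains one network per candidate size and scores it by k-fold
#' cross-validated RMSE; returns the spec of the size with the smallest
#' mean validation RMSE, ties going to the smaller network. The full search
#' table is attached.
#'
#' @param X,y Training data.
#' @param hidden Candidate sizes (default 5:20).
#' @param folds CV folds (default 3).
#' @param trainer Trainer passed to [ffnn_spec()].
#' @param max_epochs,seed Passed through.
#' @return The winning `ffnn_spec`, with the search table in
#'   `attr(, "search")`.
#' @export
ffnn_hidden_search <- function(X, y, hidden = 5:20, folds = 3L,
                               trainer = "levenberg_marquardt",
                               max_epochs = 60L, seed = 1L) {
  if (!length(hidden)) stop("empty hidden-size range")
  rmse <- vapply(hidden, function(H) {
    spec <- ffnn_spec(n_hidden = H, trainer = trainer,
                      max_epochs = max_epochs, seed = seed)
    rep_ <- kfold_rmsecv(X, y, function(Xtr, ytr) ffnn_train(Xtr, ytr, spec),
                         k = folds, seed = seed)
    rep_$rmse_cv
  }, numeric(1))
  best <- hidden[which.min(rmse)]   # which.min takes the first = smallest
  out <- ffnn_spec(n_hidden = best, trainer = trainer,
                   max_epochs = max_epochs, seed = seed)
  attr(out, "search") <- data.frame(n_hidden = hidden, rmse_cv = rmse)
  out
}

#' Save a calibration model as versioned JSON
#'
#' Weights and scaling are written at full precision so that a loaded model
#' reproduces predictions bitwise.
#'
#' @param model A `calibration_model`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
model_save <- function(model, path) {
  obj <- unclass(model)
  obj$format_version <- 1L
  obj$spec <- unclass(obj$spec)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = 17)
  invisible(path)
}

#' Load a calibration model saved by [model_save()]
#'
#' @param path JSON file path.
#' @return A `calibration_model`.
#' @export
model_load <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$format_version <- NULL
  if (!is.null(obj$spec)) {
    obj$spec <- structure(obj$spec, class = "ffnn_spec")
  }
  for (fld in c("theta", "coefficients", "y_mean", "y_sd")) {
    if (!is.null(obj[[fld]])) obj[[fld]] <- as.numeric(obj[[fld]])
  }
  if (!is.null(obj$sv)) obj$sv <- as.matrix(obj$sv)
  structure(obj, class = "calibration_model")
}
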
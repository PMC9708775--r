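# Independent oracles, kept deliberately naive and separate from the
# package implementations they check.

# Straight-from-the-formulas RReliefF: explicit double loop over sampled
# instances, neighbors and features.
rrelieff_bruteforce <- function(X, y, k, sigma = 20) {
  n <- nrow(X)
  p <- ncol(X)
  mins <- apply(X, 2, min)
  rngs <- apply(X, 2, max) - mins
  rngs[rngs == 0] <- 1
  Xs <- sweep(sweep(X, 2, mins), 2, rngs, "/")
  yr <- diff(range(y))
  w1 <- exp(-((1:k) / sigma)^2)
  w1 <- w1 / sum(w1)
  NdY <- 0
  NdA <- numeric(p)
  NdYdA <- numeric(p)
  for (i in 1:n) {
    d <- sqrt(colSums((t(Xs) - Xs[i, ])^2))
    d[i] <- Inf
    nb <- order(d)[1:k]
    for (r in 1:k) {
      j <- nb[r]
      dy <- abs(y[i] - y[j]) / yr
      NdY <- NdY + w1[r] * dy
      for (f in 1:p) {
        da <- abs(Xs[i, f] - Xs[j, f])
        NdA[f] <- NdA[f] + w1[r] * da
        NdYdA[f] <- NdYdA[f] + w1[r] * dy * da
      }
    }
  }
  NdYdA / NdY - (NdA - NdYdA) / (n - NdY)
}

# Direct (non-GA) minimizer of the asymmetric baseline cost on a given
# basis, by iteratively reweighted least squares; the cost is convex so
# this converges to the global optimum.
asymmetric_ls <- function(B, y, beta = 10, max_iter = 200) {
  c_est <- qr.coef(qr(B), y)
  c_est[is.na(c_est)] <- 0
  for (it in seq_len(max_iter)) {
    r <- drop(B %*% c_est) - y
    w <- ifelse(r > 0, beta, 1)
    c_new <- solve(crossprod(B, w * B), crossprod(B, w * y))
    if (max(abs(c_new - c_est)) < 1e-12) break
    c_est <- drop(c_new)
  }
  drop(B %*% c_est)
}

# Tiny valid cohort built by hand (2 subjects, 1 site, 2 replicates each).
make_tiny_cohort <- function(n_wn = 12) {
  wn <- seq(400, 1700, length.out = n_wn)
  set.seed(42)
  inten <- matrix(abs(rnorm(4 * n_wn, 100, 10)), 4, n_wn)
  meta <- data.frame(
    subject_id = c("A", "A", "B", "B"),
    site = "wrist",
    replicate = c(1L, 2L, 1L, 2L),
    stringsAsFactors = FALSE
  )
  refs <- data.frame(
    subject_id = c("A", "B"),
    hba1c_pct = c(5.5, 8.0),
    glucose_mgdl = c(90, 220),
    dx_class = c("healthy", "t2d"),
    stringsAsFactors = FALSE
  )
  raman_cohort(wn, inten, meta, refs)
}

# constant-mean predictor usable through stats::predict
fit_mean_model <- function(X, y) structure(list(mu = mean(y)), class = "mean_model")
predict.mean_model <- function(object, newdata, ...) rep(object$mu, nrow(newdata))
registerS3method("predict", "mean_model", predict.mean_model,
                 envir = asNamespace("stats"))

# exact-oracle predictor: memorizes rows of X -> y (for CV plumbing tests)
fit_oracle_model <- function(lookup_X, lookup_y) {
  function(X, y) structure(list(X = lookup_X, y = lookup_y), class = "oracle_model")
}
predict.oracle_model <- function(object, newdata, ...) {
  idx <- apply(newdata, 1, function(r) {
    which.min(colSums((t(object$X) - r)^2))
  })
  object$y[idx]
}
registerS3method("predict", "oracle_model", predict.oracle_model,
                 envir = asNamespace("stats"))
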
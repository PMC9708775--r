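#' Fit a self-organizing map by batch training
#'
#' Prototypes on a rows x cols grid are initialized from a random draw of
#' input samples and updated in batch mode: every epoch assigns each sample
#' to its best-matching unit (BMU, Euclidean distance) and moves every
#' prototype to the Gaussian-neighborhood-weighted mean of the samples, with
#' the neighborhood radius decaying exponentially across epochs. An epoch
#' whose update would increase the quantization error is rolled back, so the
#' recorded error trace is non-increasing.
#'
#' @param X Numeric sample-by-feature matrix.
#' @param grid_shape Integer c(rows, cols) of the map (default c(8, 8)).
#' @param epochs Training epochs (default 100).
#' @param radius0 Initial neighborhood radius; default `max(grid_shape)/2`.
#' @param radius_end Final radius (default 0.5).
#' @param seed Integer seed (initialization draw).
#' @return A list of class `som_grid`: `prototypes` (units x features),
#'   `grid_shape`, unit coordinates, `qe_trace` (quantization error per
#'   epoch, non-increasing), schedule settings.
#' @export
som_fit <- function(X, grid_shape = c(8L, 8L), epochs = 100L,
                    radius0 = NULL, radius_end = 0.5, seed = 1L) {
  X <- as.matrix(X)
  if (nrow(X) < 1) stop("som_fit needs at least one sample")
  if (any(grid_shape < 1)) stop("grid_shape must be >= (1,1)")
  if (is.null(radius0)) radius0 <- max(grid_shape) / 2
  n_units <- prod(grid_shape)
  coords <- cbind(rep(seq_len(grid_shape[1]), times = grid_shape[2]),
                  rep(seq_len(grid_shape[2]), each = grid_shape[1]))
  unit_d2 <- as.matrix(stats::dist(coords))^2

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  W <- X[sample.int(nrow(X), n_units, replace = nrow(X) < n_units), ,
         drop = FALSE]

  x_sq <- rowSums(X^2)
  bmu_of <- function(W) {
    d2 <- outer(x_sq, rowSums(W^2), `+`) - 2 * X %*% t(W)
    bmu <- max.col(-d2, ties.method = "first")
    qe <- mean(sqrt(pmax(d2[cbind(seq_len(nrow(X)), bmu)], 0)))
    list(bmu = bmu, qe = qe)
  }

  qe_trace <- numeric(epochs)
  ass <- bmu_of(W)
  qe <- ass$qe
  for (e in seq_len(epochs)) {
    radius <- if (epochs == 1) radius_end else
      radius0 * (radius_end / radius0)^((e - 1) / (epochs - 1))
    H <- exp(-unit_d2 / (2 * radius^2))        # units x units
    S <- H[, ass$bmu, drop = FALSE]            # units x samples
    denom <- rowSums(S)
    W_new <- (S %*% X) / denom
    keep <- denom <= 0 | !is.finite(denom)
    if (any(keep)) W_new[keep, ] <- W[keep, , drop = FALSE]
    ass_new <- bmu_of(W_new)
    if (ass_new$qe <= qe) {                    # monotone safeguard
      W <- W_new
      ass <- ass_new
      qe <- ass_new$qe
    }
    qe_trace[e] <- qe
  }
  structure(list(prototypes = W, grid_shape = grid_shape, coords = coords,
                 qe_trace = qe_trace, epochs = epochs, radius0 = radius0,
                 radius_end = radius_end, seed = seed),
            class = "som_grid")
}

#' Vector-quantize samples through a fitted SOM
#'
#' Replaces every sample by the prototype vector of its best-matching unit.
#' The representation keeps the full feature dimension (output shape equals
#' input shape) while collapsing near-duplicate acquisitions onto shared
#' prototypes, which is what makes it useful as a denoising front end.
#'
#' @param grid A fitted `som_grid`.
#' @param X Sample-by-feature matrix; feature count must match the
#'   prototypes.
#' @return Matrix of the same shape as `X`, each row one of the prototypes.
#' @export
som_encode <- function(grid, X) {
  X <- as.matrix(X)
  W <- grid$prototypes
  if (ncol(X) != ncol(W)) stop("feature dimension mismatch with SOM grid")
  d2 <- outer(rowSums(X^2), rowSums(W^2), `+`) - 2 * X %*% t(W)
  bmu <- max.col(-d2, ties.method = "first")
  W[bmu, , drop = FALSE]
}

#' RReliefF feature weighting for regression
#'
#' Estimates per-feature relevance for a continuous response: features
#' whose value differences track response differences among near neighbors
#' are rewarded, features that differ between neighbors with similar
#' responses are penalized. Implements the standard regression ReliefF
#' accumulation: over `m` sampled instances and their `k` nearest neighbors
#' (Euclidean in features min-max scaled to [0, 1]), with
#' exponentially-decaying distance-rank weights (sigma = 20 ranks),
#' accumulate `NdY`, `NdA[f]`, `NdYdA[f]` and set
#' `W[f] = NdYdA[f]/NdY - (NdA[f] - NdYdA[f])/(m - NdY)`.
#'
#' With `m = n` (the default) every instance is visited in index order and
#' the result is deterministic without a seed; `m < n` samples instances
#' with the given seed.
#'
#' @param X Sample-by-feature matrix.
#' @param y Numeric response vector.
#' @param k Number of nearest neighbors, `2 <= k < n`.
#' @param m Number of sampled instances (default `nrow(X)`).
#' @param sigma Rank-decay scale (default 20).
#' @param seed Seed used only when `m < n`.
#' @return A list of class `feature_weights`: `weights` (in [-1, 1]),
#'   `k`, `m`, `sigma`.
#' @export
rrelieff <- function(X, y, k, m = nrow(X), sigma = 20, seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  if (k >= n) stop("k must be < number of samples")
  if (k < 2) stop("k must be >= 2")
  if (m < 1 || m > n) stop("m must be in [1, n]")
  y_range <- diff(range(y))
  if (y_range == 0) {
    warning("constant response: all RReliefF weights are 0")
    return(structure(list(weights = rep(0, p), k = k, m = m, sigma = sigma),
                     class = "feature_weights"))
  }
  # min-max scale features to [0, 1]; constant features stay 0
  mins <- apply(X, 2, min)
  rngs <- apply(X, 2, max) - mins
  rngs[rngs == 0] <- 1
  Xs <- sweep(sweep(X, 2, mins), 2, rngs, "/")
  dy_all <- abs(outer(y, y, "-")) / y_range

  idx <- if (m == n) seq_len(n) else {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
    sample.int(n, m)
  }
  # distance-rank weights, shared by every instance
  w_rank <- exp(-(seq_len(k) / sigma)^2)
  w_rank <- w_rank / sum(w_rank)

  xs_sq <- rowSums(Xs^2)
  NdY <- 0
  NdA <- numeric(p)
  NdYdA <- numeric(p)
  for (i in idx) {
    d2 <- xs_sq + xs_sq[i] - 2 * drop(Xs %*% Xs[i, ])
    d2[i] <- Inf
    nb <- order(d2)[seq_len(k)]
    Df <- abs(sweep(Xs[nb, , drop = FALSE], 2, Xs[i, ]))
    dy <- dy_all[i, nb]
    NdY <- NdY + sum(w_rank * dy)
    NdA <- NdA + colSums(w_rank * Df)
    NdYdA <- NdYdA + colSums((w_rank * dy) * Df)
  }
  W <- NdYdA / NdY - (NdA - NdYdA) / (m - NdY)
  structure(list(weights = W, k = k, m = m, sigma = sigma),
            class = "feature_weights")
}

#' Select the highest-weighted features
#'
#' Returns the indices of the `count` largest weights; ties are broken in
#' favor of the lower wavenumber (lower column index, since features are
#' stored in increasing wavenumber order). The study design searched counts
#' in {50, 100, 150, 200, 512}, but any count up to the feature number is
#' allowed.
#'
#' @param weights A `feature_weights` object or bare numeric vector.
#' @param count Number of features to keep, `1 <= count <= p`.
#' @return Integer indices ordered by descending weight (ties: ascending
#'   index).
#' @export
select_top <- function(weights, count) {
  w <- if (inherits(weights, "feature_weights")) weights$weights else
    as.numeric(weights)
  if (count <= 0) stop("count must be positive")
  if (count > length(w)) stop("count exceeds number of features")
  ord <- order(-w, seq_along(w))
  ord[seq_len(count)]
}

#' SOM-then-RReliefF feature engineering
#'
#' The combined recipe: fit a SOM on the spectra, replace each spectrum by
#' its prototype (same dimensionality), weight the encoded features with
#' RReliefF against the response, and keep the top `count`. Returns
#' everything needed to apply the identical transform to new data.
#'
#' @param X Sample-by-feature matrix (preprocessed spectra).
#' @param y Response vector.
#' @param count Number of features to keep.
#' @param k RReliefF neighbor count.
#' @param grid_shape,epochs SOM settings.
#' @param seed Seed for the SOM initialization.
#' @return List of class `rrelieff_som`: `som`, `weights`, `selected`
#'   (indices), plus the settings.
#' @export
rrelieff_som <- function(X, y, count, k, grid_shape = c(8L, 8L),
                         epochs = 100L, seed = 1L) {
  som <- som_fit(X, grid_shape = grid_shape, epochs = epochs, seed = seed)
  enc <- som_encode(som, X)
  fw <- rrelieff(enc, y, k = k)
  sel <- select_top(fw, count)
  structure(list(som = som, weights = fw, selected = sel, count = count,
                 k = k),
            class = "rrelieff_som")
}

#' Per-site best feature-selection settings
#'
#' The reported best (feature count, k-nearest-neighbors) combinations per
#' body site and analyte from the in vivo grid search, shipped as a named
#' preset for convenience; any other combination can be configured freely.
#'
#' @return Data frame with columns `site`, `analyte`, `count`, `k`.
#' @export
featsel_presets <- function() {
  data.frame(
    site = rep(c("forearm", "wrist", "index_finger"), 2),
    analyte = rep(c("hba1c", "glucose"), each = 3),
    count = c(100L, 512L, 50L, 200L, 150L, 150L),
    k = c(13L, 26L, 23L, 9L, 7L, 38L),
    stringsAsFactors = FALSE
  )
}

#' Apply a fitted SOM + RReliefF recipe to new spectra
#'
#' @param recipe An `rrelieff_som` object.
#' @param X New sample-by-feature matrix on the same grid.
#' @return Encoded matrix restricted to the selected features.
#' @export
apply_recipe <- function(recipe, X) {
  enc <- som_encode(recipe$som, X)
  enc[, recipe$selected, drop = FALSE]
}
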
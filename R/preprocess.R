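#' Radial polynomial basis on a normalized axis
#'
#' Zernike polynomials are natively two-dimensional; for one-dimensional
#' spectra this package uses their radial parts R_n^m(r) with m = n mod 2
#' (the lowest azimuthal order for which R_n^m is defined), n = 0..max_order,
#' evaluated on the wavenumber axis mapped affinely to [0, 1]. The first few
#' members are 1, r, 2r^2 - 1, 3r^3 - 2r, 6r^4 - 6r^2 + 1, ...
#'
#' @param wavenumbers Grid the basis is evaluated on.
#' @param max_order Highest radial order n (>= 1).
#' @return Matrix with `length(wavenumbers)` rows and `max_order + 1`
#'   columns (orders 0..max_order).
#' @export
zernike_basis <- function(wavenumbers, max_order = 6L) {
  if (max_order < 1) stop("max_order must be >= 1")
  r <- (wavenumbers - min(wavenumbers)) /
    (max(wavenumbers) - min(wavenumbers))
  vapply(0:max_order, function(n) {
    m <- n %% 2L
    k <- 0:((n - m) / 2)
    coef <- (-1)^k * factorial(n - k) /
      (factorial(k) * factorial((n + m) / 2 - k) * factorial((n - m) / 2 - k))
    pow <- n - 2 * k
    drop(outer(r, pow, `^`) %*% coef)
  }, numeric(length(r)))
}

#' Genetic-algorithm settings for the baseline fit
#'
#' @param population Population size (default 60).
#' @param generations Number of generations (default 150).
#' @param p_crossover Single-point crossover probability (default 0.8).
#' @param p_mutation Per-gene Gaussian mutation probability (default 0.1).
#' @param tournament Tournament selection size (default 3).
#' @param elitism Number of elites carried over unchanged (default 1).
#' @param seed Integer seed for the GA's randomness.
#' @return A list of class `ga_settings`.
#' @export
ga_settings <- function(population = 60L, generations = 150L,
                        p_crossover = 0.8, p_mutation = 0.1,
                        tournament = 3L, elitism = 1L, seed = 1L) {
  structure(list(population = as.integer(population),
                 generations = as.integer(generations),
                 p_crossover = p_crossover, p_mutation = p_mutation,
                 tournament = as.integer(tournament),
                 elitism = as.integer(elitism),
                 seed = as.integer(seed)),
            class = "ga_settings")
}

#' Fluorescence baseline removal by GA-fitted radial polynomial expansion
#'
#' Fits a smooth baseline as an expansion over the radial polynomial basis
#' ([zernike_basis()]), with coefficients chosen by a real-coded genetic
#' algorithm minimizing an asymmetric squared cost: residuals where the
#' baseline lies ABOVE the spectrum are weighted `beta` times more than
#' residuals below, so the fit hugs the lower envelope that tissue
#' autofluorescence forms beneath the Raman bands. The population is seeded
#' around the ordinary least-squares expansion; elitism makes the best
#' fitness non-increasing across generations.
#'
#' @param s A `raman_spectrum`, or a bare numeric intensity vector (then
#'   `wavenumbers` must be given).
#' @param max_order Highest radial order of the basis (default 6).
#' @param ga A [ga_settings()] list.
#' @param beta Asymmetry factor penalizing baseline > spectrum (default 10).
#' @param wavenumbers Grid when `s` is a bare vector.
#' @return A list of class `baseline_fit`: `coefficients`, `baseline`,
#'   `corrected` (original minus baseline, clipped at 0), `fitness`,
#'   `trace` (best fitness per generation, non-increasing).
#' @export
zernike_baseline <- function(s, max_order = 6L, ga = ga_settings(),
                             beta = 10, wavenumbers = NULL) {
  if (inherits(s, "raman_spectrum")) {
    y <- s$intensities
    wavenumbers <- s$wavenumbers
  } else {
    y <- as.numeric(s)
    if (is.null(wavenumbers)) stop("wavenumbers required for a bare vector")
  }
  if (length(y) < max_order + 1) stop("spectrum shorter than basis size")
  B <- zernike_basis(wavenumbers, max_order)
  nb <- ncol(B)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(ga$seed)

  # The raw radial-polynomial columns are strongly collinear, which would
  # leave the GA searching a needle-shaped valley; the chromosome therefore
  # lives in the orthonormalized (QR) span of the same basis and the
  # coefficients are mapped back afterwards. The fitted baselines are
  # identical in either parameterization.
  qrB <- qr(B)
  Q <- qr.Q(qrB)

  cost_of <- function(C) {
    # C: nb x P chromosome matrix; returns P costs
    R <- Q %*% C - y
    w <- ifelse(R > 0, beta, 1)
    colMeans(w * R * R)
  }

  # seed the population around the ordinary least-squares expansion
  c0 <- drop(crossprod(Q, y))
  scale <- pmax(abs(c0), stats::sd(y), 1e-8)
  P <- ga$population
  # diverse seeds: the OLS expansion, shrunk variants of it (the lower
  # envelope lies below the OLS curve when bands sit on the baseline), and
  # Gaussian scatter around them
  shrink <- rep(c(1, 0.7, 0.4, 0), length.out = P)
  pop <- matrix(c0, nb, P) * matrix(shrink, nb, P, byrow = TRUE) +
    matrix(stats::rnorm(nb * P, 0, 0.2 * scale), nb, P)
  pop[, 1] <- c0
  cost <- cost_of(pop)

  trace <- numeric(ga$generations)
  for (g in seq_len(ga$generations)) {
    ord <- order(cost)
    elite <- pop[, ord[seq_len(ga$elitism)], drop = FALSE]
    # tournament selection of parents
    pick <- function(n) {
      idx <- matrix(sample.int(P, n * ga$tournament, replace = TRUE),
                    ga$tournament)
      cm <- matrix(cost[idx], ga$tournament)
      idx[cbind(max.col(t(-cm), ties.method = "first"), seq_len(n))]
    }
    pa <- pop[, pick(P), drop = FALSE]
    pb <- pop[, pick(P), drop = FALSE]
    # single-point crossover on the coefficient vector
    cross <- stats::runif(P) < ga$p_crossover
    cut <- sample.int(nb - 1, P, replace = TRUE)
    child <- pa
    for (j in which(cross)) {
      child[(cut[j] + 1):nb, j] <- pb[(cut[j] + 1):nb, j]
    }
    # Gaussian mutation, s.d. annealed exponentially over generations so
    # early search is broad and late generations fine-tune
    msd <- 0.3 * scale * (1e-3)^(g / ga$generations)
    mut <- matrix(stats::runif(nb * P) < ga$p_mutation, nb, P)
    child <- child + mut * matrix(stats::rnorm(nb * P, 0, msd), nb, P)
    child[, seq_len(ga$elitism)] <- elite
    # creep offspring of the elite: hill-climbing at the current scale
    n_creep <- min(5L, P - ga$elitism)
    creep_cols <- ga$elitism + seq_len(n_creep)
    child[, creep_cols] <- elite[, 1] +
      matrix(stats::rnorm(nb * n_creep, 0, msd / 5), nb, n_creep)
    pop <- child
    cost <- cost_of(pop)
    trace[g] <- min(cost)
    if (g > 1 && trace[g] > trace[g - 1]) {
      # elitism guarantees monotonicity; numerical safety net
      trace[g] <- trace[g - 1]
    }
  }
  best <- pop[, which.min(cost)]
  baseline <- drop(Q %*% best)
  coefs <- backsolve(qr.R(qrB), best)     # back to the radial-poly basis
  corrected <- pmax(y - baseline, 0)
  structure(list(coefficients = coefs, baseline = baseline,
                 corrected = corrected, fitness = min(cost),
                 trace = trace),
            class = "baseline_fit")
}

#' Whittaker-Eilers penalized smoother
#'
#' Returns the exact minimizer of `sum((y - z)^2) + lam * sum(diff(z,
#' differences = d)^2)`, solved through the sparse banded system
#' `(I + lam * D'D) z = y`. With `lam = 0` the output equals the input;
#' polynomial sequences of degree < d are fixed points; as `lam -> Inf` the
#' output approaches the least-squares polynomial of degree d - 1.
#'
#' @param y Numeric vector (or matrix with one series per row).
#' @param lam Penalty weight, >= 0 (default 10).
#' @param d Difference order (default 2).
#' @return Smoothed vector (or matrix) of the same shape.
#' @export
whittaker_smooth <- function(y, lam = 10, d = 2L) {
  if (lam < 0) stop("lam must be >= 0")
  is_mat <- is.matrix(y)
  n <- if (is_mat) ncol(y) else length(y)
  if (n <= d) stop("series length must exceed difference order d")
  if (lam == 0) return(y)
  D <- Matrix::diff(Matrix::Diagonal(n), differences = d)
  A <- Matrix::Diagonal(n) + lam * Matrix::crossprod(D)
  if (is_mat) {
    t(as.matrix(Matrix::solve(A, t(y))))
  } else {
    as.numeric(Matrix::solve(A, y))
  }
}

#' Replicate signal-to-noise ratio at a band
#'
#' SNR is the ratio of the mean intensity across replicate acquisitions at
#' the grid point nearest to `peak_center` to the sample standard deviation
#' (n - 1 denominator) at that same point. Identical replicates give a zero
#' standard deviation; the result is then flagged infinite.
#'
#' @param replicates Numeric matrix of replicate spectra (one row each) or a
#'   `raman_cohort` (then `subject_id` and `site` select the replicates).
#' @param peak_center Band position in cm^-1 (nearest-grid-point lookup);
#'   the study design evaluates HbA1c at 1230 cm^-1 and glucose at
#'   1106 cm^-1.
#' @param wavenumbers Grid when `replicates` is a bare matrix.
#' @param subject_id,site Selection when `replicates` is a cohort.
#' @return A list of class `snr_result`: `peak_center` (requested),
#'   `grid_point` (used), `s_bar`, `sigma_y`, `snr`, `infinite` flag.
#' @export
snr <- function(replicates, peak_center, wavenumbers = NULL,
                subject_id = NULL, site = NULL) {
  if (inherits(replicates, "raman_cohort")) {
    keep <- replicates$meta$subject_id == subject_id &
      replicates$meta$site == site
    wavenumbers <- replicates$wavenumbers
    replicates <- replicates$intensities[keep, , drop = FALSE]
  }
  if (is.null(wavenumbers)) stop("wavenumbers required for a bare matrix")
  if (nrow(replicates) < 2) stop("snr needs at least 2 replicates")
  j <- which.min(abs(wavenumbers - peak_center))
  v <- replicates[, j]
  s_bar <- mean(v)
  sigma_y <- stats::sd(v)
  structure(list(peak_center = peak_center, grid_point = wavenumbers[j],
                 s_bar = s_bar, sigma_y = sigma_y,
                 snr = if (sigma_y == 0) Inf else s_bar / sigma_y,
                 infinite = sigma_y == 0),
            class = "snr_result")
}

#' Per-site SNR summary of a cohort
#'
#' Computes the replicate SNR for every (subject, site) group at a band and
#' summarizes mean and s.d. per site.
#'
#' @param cohort A `raman_cohort`.
#' @param peak_center Band position in cm^-1.
#' @return Data frame with one row per site: `site`, `mean_snr`, `sd_snr`,
#'   `n_subjects`.
#' @export
snr_summary <- function(cohort, peak_center) {
  groups <- unique(cohort$meta[, c("subject_id", "site")])
  vals <- mapply(function(sid, st) {
    snr(cohort, peak_center, subject_id = sid, site = st)$snr
  }, groups$subject_id, groups$site)
  out <- do.call(rbind, lapply(split(vals, groups$site), function(v) {
    v <- v[is.finite(v)]
    data.frame(mean_snr = mean(v), sd_snr = stats::sd(v),
               n_subjects = length(v))
  }))
  out$site <- rownames(out)
  rownames(out) <- NULL
  out[, c("site", "mean_snr", "sd_snr", "n_subjects")]
}

#' Full spectral preprocessing of a cohort
#'
#' Removes the fluorescence baseline from every acquisition with
#' [zernike_baseline()] (GA seeds derived deterministically from `ga$seed`
#' and the acquisition index) and then smooths shot noise with
#' [whittaker_smooth()].
#'
#' @param cohort A `raman_cohort`.
#' @param max_order Radial basis order for the baseline fit.
#' @param ga [ga_settings()] used per spectrum.
#' @param beta Baseline cost asymmetry.
#' @param lam,d Whittaker smoothing parameters.
#' @return The cohort with corrected, smoothed intensities; provenance is
#'   extended with the preprocessing settings.
#' @export
preprocess_cohort <- function(cohort, max_order = 6L, ga = ga_settings(),
                              beta = 10, lam = 10, d = 2L) {
  validate_cohort(cohort)
  out <- cohort$intensities
  for (i in seq_len(nrow(out))) {
    ga_i <- ga
    ga_i$seed <- ga$seed + i
    fit <- zernike_baseline(out[i, ], max_order = max_order, ga = ga_i,
                            beta = beta, wavenumbers = cohort$wavenumbers)
    out[i, ] <- fit$corrected
  }
  out <- whittaker_smooth(out, lam = lam, d = d)
  out <- pmax(out, 0)
  prov <- cohort$provenance
  prov$preprocess <- list(max_order = max_order, beta = beta,
                          lam = lam, d = d, ga_seed = ga$seed)
  raman_cohort(cohort$wavenumbers, out, cohort$meta, cohort$references,
               prov)
}
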
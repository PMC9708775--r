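#' Default wavenumber grid of the synthetic generator
#'
#' Piecewise-uniform 788-point grid over 200-1800 cm^-1, built so that the
#' two spectral windows used throughout the analysis have exactly the sizes
#' the instrument configuration yields: 788 points in [200, 1800] and 512 in
#' [600, 1600]. Concretely: 512 evenly spaced points cover [600, 1600], 184
#' fill [200, 600) and 92 fill (1600, 1800], with the outer fill spacing
#' equal on both flanks.
#'
#' @return Strictly increasing numeric vector of length 788, first point
#'   200, last point 1800.
#' @export
make_grid <- function() {
  mid <- seq(600, 1600, length.out = 512)
  left <- 200 + (0:183) * (400 / 184)
  right <- 1600 + (1:92) * (200 / 92)
  c(left, mid, right)
}

#' Specification of a synthetic cohort
#'
#' Bundles every knob of the generator. The defaults emulate the study
#' design: 46 subjects measured at three body sites with nine replicates
#' each, HbA1c spanning 5.2-14 %, glucose 56-400 mg/dL, a class mix of 32
#' T2D / 10 prediabetes / 4 healthy, analyte-coupled Raman bands at the
#' assigned wavenumbers riding on a dominant smooth fluorescence background
#' with shot noise.
#'
#' @param n_subjects Number of volunteers (default 46).
#' @param replicates_per_site Replicate acquisitions per subject and site
#'   (default 9).
#' @param sites Character vector of body sites (default all three).
#' @param class_counts Named integer vector `c(t2d=, prediabetes=, healthy=)`
#'   summing to `n_subjects`.
#' @param hba1c_range,glucose_range Numeric length-2 ranges (% and mg/dL).
#' @param glucose_hba1c_cor Target rank correlation between glucose and
#'   HbA1c draws (Gaussian copula, default 0.7).
#' @param peak_table Data frame with columns `center` (cm^-1), `width`
#'   (Gaussian sigma, cm^-1), `analyte` (`"hba1c"`, `"glucose"`,
#'   `"background"`), `slope` (counts per unit concentration; for
#'   background bands the slope is the amplitude itself, at unit nominal
#'   concentration). Defaults to [default_peak_table()].
#' @param site_factors Named multiplicative response factors per site.
#' @param baseline_amplitude Length-2 range of the fluorescence amplitude
#'   as a multiple of a nominal 100-count band (default `c(5, 20)`); the
#'   index finger baseline is doubled to mimic its collagen-rich tissue.
#' @param noise_scale Shot-noise scale: intensity s.d. is
#'   `noise_scale * sqrt(signal)` (default 2; 0 disables noise).
#' @param seed Integer seed; all generator randomness flows from it.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 46L,
                        replicates_per_site = 9L,
                        sites = RAMAN_SITES,
                        class_counts = c(t2d = 32L, prediabetes = 10L,
                                         healthy = 4L),
                        hba1c_range = c(5.2, 14),
                        glucose_range = c(56, 400),
                        glucose_hba1c_cor = 0.7,
                        peak_table = default_peak_table(),
                        site_factors = c(forearm = 1.0, wrist = 1.1,
                                         index_finger = 0.8),
                        baseline_amplitude = c(5, 20),
                        noise_scale = 2,
                        seed = 1L) {
  spec <- list(
    n_subjects = as.integer(n_subjects),
    replicates_per_site = as.integer(replicates_per_site),
    sites = match.arg(sites, RAMAN_SITES, several.ok = TRUE),
    class_counts = class_counts,
    hba1c_range = hba1c_range,
    glucose_range = glucose_range,
    glucose_hba1c_cor = glucose_hba1c_cor,
    peak_table = peak_table,
    site_factors = site_factors,
    baseline_amplitude = baseline_amplitude,
    noise_scale = noise_scale,
    seed = as.integer(seed)
  )
  class(spec) <- "cohort_spec"
  validate_cohort_spec(spec)
  spec
}

validate_cohort_spec <- function(spec) {
  if (sum(spec$class_counts) != spec$n_subjects) {
    stop("class_counts must sum to n_subjects")
  }
  pt <- spec$peak_table
  stopifnot(all(c("center", "width", "analyte", "slope") %in% names(pt)))
  if (any(pt$center < 200 | pt$center > 1800)) {
    stop("all peak centers must lie inside [200, 1800] cm^-1")
  }
  if (any(pt$slope < 0)) stop("response slopes must be >= 0")
  if (any(pt$width <= 0)) stop("peak widths must be > 0")
  if (any(spec$noise_scale < 0)) stop("noise_scale must be >= 0")
  invisible(spec)
}

#' Default synthetic band assignments
#'
#' HbA1c-coupled bands at 1536, 1230, 1114, 969, 665 and 1308 cm^-1;
#' glucose-coupled bands at 544, 837, 1060 and 1106 cm^-1; six
#' concentration-independent skin/collagen background bands at
#' non-overlapping centers. Widths are a uniform 12 cm^-1 (Gaussian sigma),
#' typical of tissue Raman bands. Slopes are counts per % HbA1c, counts per
#' mg/dL glucose, or (for background) counts outright.
#'
#' @return Data frame with columns `center`, `width`, `analyte`, `slope`.
#' @export
default_peak_table <- function() {
  data.frame(
    center = c(1536, 1230, 1114, 969, 665, 1308,
               544, 837, 1060, 1106,
               340, 450, 720, 900, 1004, 1655),
    width = 12,
    analyte = c(rep("hba1c", 6), rep("glucose", 4), rep("background", 6)),
    slope = c(10, 8, 6, 6, 5, 7,
              0.20, 0.25, 0.30, 0.25,
              60, 50, 70, 80, 120, 90),
    stringsAsFactors = FALSE
  )
}

#' Draw per-subject reference values
#'
#' HbA1c is drawn uniformly inside each diagnostic class band (healthy
#' < 5.7 %, prediabetes 5.7-6.4 %, T2D >= 6.5 %) intersected with the
#' spec's overall HbA1c range; glucose is coupled to HbA1c through a
#' Gaussian copula with the configured correlation and a uniform margin on
#' the glucose range.
#'
#' @param spec A `cohort_spec`.
#' @return Data frame of `subject_id`, `hba1c_pct`, `glucose_mgdl`,
#'   `dx_class` with exactly the configured class counts.
#' @export
sample_references <- function(spec) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  bands <- list(healthy = c(-Inf, 5.7), prediabetes = c(5.7, 6.5),
                t2d = c(6.5, Inf))
  rng <- spec$hba1c_range
  cls <- rep(names(spec$class_counts), times = spec$class_counts)
  hba1c <- numeric(length(cls))
  for (cl in unique(cls)) {
    band <- bands[[cl]]
    lo <- max(band[1], rng[1])
    hi <- min(band[2], rng[2])
    if (!(lo < hi || (is.finite(lo) && lo == hi))) {
      stop("infeasible HbA1c band for class ", cl,
           ": empty intersection with hba1c_range")
    }
    idx <- which(cls == cl)
    # open upper ends of the healthy/prediabetes bands: draw strictly below
    hba1c[idx] <- lo + stats::runif(length(idx)) * (hi - lo) *
      (1 - 1e-9)
  }
  # copula coupling: HbA1c quantile -> correlated normal -> glucose quantile
  u_h <- (hba1c - rng[1]) / (rng[2] - rng[1])
  z_h <- stats::qnorm(pmin(pmax(u_h, 1e-9), 1 - 1e-9))
  r <- spec$glucose_hba1c_cor
  z_g <- r * z_h + sqrt(1 - r^2) * stats::rnorm(length(z_h))
  g_rng <- spec$glucose_range
  glucose <- g_rng[1] + stats::pnorm(z_g) * (g_rng[2] - g_rng[1])
  ord <- sample(seq_along(cls))   # de-correlate subject index from class
  data.frame(
    subject_id = sprintf("S%02d", seq_along(cls)),
    hba1c_pct = hba1c[ord],
    glucose_mgdl = glucose[ord],
    dx_class = class_from_hba1c(hba1c[ord]),
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic cohort with ground truth
#'
#' Each acquisition is built as
#' `baseline + sum of Gaussian bands + shot noise`, clipped at zero.
#' Analyte-coupled band amplitudes are `slope * concentration *
#' site_factor`; background bands have concentration-independent
#' amplitudes. The fluorescence baseline is a smooth positive random
#' Chebyshev-basis curve (degree 5), 5-20x the nominal band amplitude,
#' drawn per subject and site and jittered per replicate. Shot noise is
#' Poisson-like: s.d. proportional to the square root of the noise-free
#' signal.
#'
#' @param spec A `cohort_spec`.
#' @param wavenumbers Grid to synthesize on (default [make_grid()]).
#' @return A list with elements `cohort` (a `raman_cohort`) and
#'   `ground_truth` (list: `references`, `baselines` matrix, `peak_amplitudes`
#'   per subject/site/peak, `clean` noise-free spectra matrix).
#' @export
generate_cohort <- function(spec = cohort_spec(), wavenumbers = make_grid()) {
  validate_cohort_spec(spec)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  refs <- sample_references(spec)
  set.seed(spec$seed + 1L)

  pt <- spec$peak_table
  n_wn <- length(wavenumbers)
  # Gaussian band shapes, one column per peak
  shapes <- vapply(seq_len(nrow(pt)), function(j) {
    exp(-0.5 * ((wavenumbers - pt$center[j]) / pt$width[j])^2)
  }, numeric(n_wn))

  n_rep <- spec$replicates_per_site
  n_total <- spec$n_subjects * length(spec$sites) * n_rep
  inten <- matrix(0, n_total, n_wn)
  clean <- matrix(0, n_total, n_wn)
  baselines <- matrix(0, n_total, n_wn)
  meta <- data.frame(subject_id = character(n_total),
                     site = character(n_total),
                     replicate = integer(n_total),
                     stringsAsFactors = FALSE)
  amp_rows <- list()

  u <- 2 * (wavenumbers - min(wavenumbers)) /
    (max(wavenumbers) - min(wavenumbers)) - 1
  cheb <- cbind(1.5, u, 2 * u^2 - 1, 4 * u^3 - 3 * u,
                8 * u^4 - 8 * u^2 + 1, 16 * u^5 - 20 * u^3 + 5 * u)

  row <- 0L
  for (si in seq_len(nrow(refs))) {
    conc <- c(hba1c = refs$hba1c_pct[si], glucose = refs$glucose_mgdl[si],
              background = 1)
    for (site in spec$sites) {
      sf <- spec$site_factors[[site]]
      amps <- pt$slope * conc[pt$analyte] * sf
      peak_sum <- drop(shapes %*% amps)
      amp_rows[[length(amp_rows) + 1L]] <- data.frame(
        subject_id = refs$subject_id[si], site = site,
        center = pt$center, analyte = pt$analyte, amplitude = amps,
        stringsAsFactors = FALSE)
      # subject/site fluorescence curve, doubled on the finger
      b_amp <- stats::runif(1, spec$baseline_amplitude[1],
                            spec$baseline_amplitude[2]) * 100 *
        if (site == "index_finger") 2 else 1
      b_coef <- c(1, stats::runif(5, -0.2, 0.2))
      for (rep_i in seq_len(n_rep)) {
        row <- row + 1L
        coef_r <- b_coef + c(0, stats::rnorm(5, 0, 0.02))
        amp_r <- b_amp * (1 + stats::rnorm(1, 0, 0.03))
        base <- amp_r * pmax(drop(cheb %*% coef_r), 0.05) / 2.5
        signal <- base + peak_sum
        # noise draws happen at every noise_scale (including 0) so that
        # cohorts at different noise levels share common random numbers
        eps <- stats::rnorm(n_wn)
        y <- signal + spec$noise_scale * sqrt(pmax(signal, 0)) * eps
        inten[row, ] <- pmax(y, 0)
        clean[row, ] <- signal
        baselines[row, ] <- base
        meta$subject_id[row] <- refs$subject_id[si]
        meta$site[row] <- site
        meta$replicate[row] <- rep_i
      }
    }
  }

  cohort <- raman_cohort(
    wavenumbers, inten, meta, refs,
    provenance = list(generator = "ramanquant synthetic cohort",
                      seed = spec$seed)
  )
  list(
    cohort = cohort,
    ground_truth = list(
      references = refs,
      baselines = baselines,
      clean = clean,
      peak_amplitudes = do.call(rbind, amp_rows)
    )
  )
}

# save/restore the global RNG state so seeded generators do not clobber
# the caller's stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
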
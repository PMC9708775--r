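wn_full <- make_grid()

test_that("whittaker smoother has its closed-form limits", {
  y <- c(5, 1, 9, 4)
  expect_identical(whittaker_smooth(y, lam = 0), y)
  expect_equal(whittaker_smooth(c(1, 2, 3, 4), lam = 1e6, d = 2),
               c(1, 2, 3, 4), tolerance = 1e-9)
  expect_equal(whittaker_smooth(c(0, 1, 0), lam = 1e9, d = 2),
               rep(1 / 3, 3), tolerance = 1e-6)
  expect_error(whittaker_smooth(y, lam = -1), ">= 0")
  expect_error(whittaker_smooth(c(1, 2), lam = 1, d = 2), "length")
})

test_that("whittaker smoother shrinks roughness and fixes constants", {
  set.seed(7)
  y <- cumsum(rnorm(200)) + rnorm(200)
  rough <- function(z, d) sum(diff(z, differences = d)^2)
  for (lam in c(0.1, 10, 1e4)) {
    z <- whittaker_smooth(y, lam = lam, d = 2)
    expect_lte(rough(z, 2), rough(y, 2))
  }
  expect_equal(whittaker_smooth(rep(4.2, 50), lam = 100), rep(4.2, 50),
               tolerance = 1e-10)
})

test_that("GA baseline recovers a known radial-polynomial curve", {
  B <- ramanquant:::zernike_basis(wn_full, 4)
  truth <- drop(B %*% c(800, 50, -120, 30, 60))
  expect_true(all(truth > 0))
  fit <- zernike_baseline(truth, max_order = 4, wavenumbers = wn_full)
  rel_rms <- sqrt(mean((fit$baseline - truth)^2)) / sqrt(mean(truth^2))
  expect_lt(rel_rms, 0.01)
  expect_lt(max(abs(fit$corrected)), 0.01 * max(truth))
  # GA fitness matches the direct asymmetric-least-squares optimum
  direct <- asymmetric_ls(B, truth)
  expect_equal(fit$baseline, direct, tolerance = 1e-3)
})

test_that("GA baseline hugs the lower envelope under pure band signals", {
  peaks <- 300 * exp(-0.5 * ((wn_full - 700) / 12)^2) +
    200 * exp(-0.5 * ((wn_full - 1100) / 12)^2) +
    250 * exp(-0.5 * ((wn_full - 1500) / 12)^2)
  fit <- zernike_baseline(peaks, max_order = 6, wavenumbers = wn_full)
  expect_lt(max(abs(fit$corrected - peaks)), 0.05 * max(peaks))
  # close to the convex optimum found by direct solve
  B <- ramanquant:::zernike_basis(wn_full, 6)
  direct <- asymmetric_ls(B, peaks)
  cost <- function(b) {
    r <- b - peaks
    mean(ifelse(r > 0, 10, 1) * r^2)
  }
  expect_lt(cost(fit$baseline), cost(direct) * 1.05)
})

test_that("baseline removal preserves band positions on baseline + peaks", {
  B <- ramanquant:::zernike_basis(wn_full, 4)
  base <- drop(B %*% c(1500, -100, -200, 50, 80))
  peaks <- 300 * exp(-0.5 * ((wn_full - 700) / 12)^2) +
    200 * exp(-0.5 * ((wn_full - 1100) / 12)^2) +
    250 * exp(-0.5 * ((wn_full - 1500) / 12)^2)
  fit <- zernike_baseline(base + peaks, max_order = 6,
                          wavenumbers = wn_full)
  step <- max(diff(wn_full))
  for (ctr in c(700, 1100, 1500)) {
    win <- which(abs(wn_full - ctr) < 40)
    found <- wn_full[win[which.max(fit$corrected[win])]]
    expect_lt(abs(found - ctr), step + 1e-9)
  }
  # contract: corrected is non-negative and trace is monotone
  expect_true(all(fit$corrected >= 0))
  expect_true(all(diff(fit$trace) <= 1e-12))
})

test_that("GA runs are seed-reproducible and never worsen with budget", {
  y <- 500 + wn_full / 10 + 100 * exp(-0.5 * ((wn_full - 900) / 15)^2)
  f1 <- zernike_baseline(y, ga = ga_settings(seed = 7), wavenumbers = wn_full)
  f2 <- zernike_baseline(y, ga = ga_settings(seed = 7), wavenumbers = wn_full)
  expect_identical(f1$coefficients, f2$coefficients)
  f_short <- zernike_baseline(y, ga = ga_settings(generations = 40, seed = 7),
                              wavenumbers = wn_full)
  f_long <- zernike_baseline(y, ga = ga_settings(generations = 80, seed = 7),
                             wavenumbers = wn_full)
  expect_lte(f_long$fitness, f_short$fitness)
})

test_that("snr matches independent two-pass arithmetic and flags degeneracy", {
  wn <- c(500, 600)
  r <- snr(rbind(c(9, 1), c(11, 1)), peak_center = 500, wavenumbers = wn)
  expect_equal(r$s_bar, 10)
  expect_equal(r$sigma_y, sqrt(2))
  expect_equal(r$snr, 10 / sqrt(2))

  same <- snr(rbind(c(7, 1), c(7, 1)), peak_center = 500, wavenumbers = wn)
  expect_true(same$infinite)
  expect_identical(same$snr, Inf)
  expect_error(snr(rbind(c(1, 2)), peak_center = 500, wavenumbers = wn),
               "at least 2")

  set.seed(10)
  reps <- matrix(100 + rnorm(9 * 3, 0, 10), 9, 3)
  got <- snr(reps, peak_center = 840, wavenumbers = c(800, 840, 900))
  v <- reps[, 2]
  m1 <- sum(v) / length(v)
  s1 <- sqrt(sum((v - m1)^2) / (length(v) - 1))
  expect_equal(got$snr, m1 / s1, tolerance = 1e-12)
})

test_that("full preprocessing keeps amplitude ratios of noise-free band spectra", {
  sp <- cohort_spec(n_subjects = 2,
                    class_counts = c(t2d = 1, prediabetes = 0, healthy = 1),
                    sites = "forearm", replicates_per_site = 2,
                    noise_scale = 0, baseline_amplitude = c(0, 0), seed = 14)
  sim <- generate_cohort(sp)
  pp <- preprocess_cohort(sim$cohort, ga = ga_settings(seed = 3))
  wn <- pp$wavenumbers
  # band amplitude measured the spectroscopist's way: height above the
  # local background in a +-40 cm^-1 window; the ratio compared is the
  # strongest analyte band (1536) against the 1004 reference band
  amp <- function(v, ctr) {
    win <- abs(wn - ctr) <= 40
    v[which.min(abs(wn - ctr))] - min(v[win])
  }
  for (i in seq_len(n_spectra(pp))) {
    raw <- sim$cohort$intensities[i, ]
    ratio_true <- amp(raw, 1536) / amp(raw, 1004)
    ratio_got <- amp(pp$intensities[i, ], 1536) / amp(pp$intensities[i, ], 1004)
    expect_equal(ratio_got, ratio_true, tolerance = 0.02)
  }
})
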
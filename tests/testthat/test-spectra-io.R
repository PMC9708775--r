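test_that("spectrum constructor enforces its invariants", {
  wn <- seq(200, 1800, length.out = 10)
  s <- raman_spectrum("S1", "wrist", 1, wn, rep(5, 10))
  expect_s3_class(s, "raman_spectrum")
  expect_error(raman_spectrum("S1", "wrist", 1, rev(wn), rep(5, 10)),
               "strictly increasing")
  expect_error(raman_spectrum("S1", "wrist", 1, wn, rep(5, 9)),
               "equal length")
  expect_error(raman_spectrum("S1", "elbow", 1, wn, rep(5, 10)))
})

test_that("cohort validation is total: missing references and class mismatches are hard errors", {
  co <- make_tiny_cohort()
  expect_silent(validate_cohort(co))

  bad <- co
  bad$references <- bad$references[1, , drop = FALSE]
  expect_error(validate_cohort(bad), "missing reference.*B")

  bad2 <- co
  bad2$references$dx_class[1] <- "t2d"   # hba1c 5.5 implies healthy
  expect_error(validate_cohort(bad2), "inconsistent")
})

test_that("CSV cohort round-trip is the identity", {
  co <- generate_cohort(cohort_spec(
    n_subjects = 3, class_counts = c(t2d = 1, prediabetes = 1, healthy = 1),
    sites = "forearm", seed = 8))$cohort
  d <- withr::local_tempdir()
  write_cohort(co, d)
  back <- read_cohort(d)
  expect_identical(back$wavenumbers, co$wavenumbers)
  expect_identical(back$intensities, co$intensities)
  expect_identical(back$meta, co$meta)
  expect_identical(back$references, co$references)
})

test_that("JCAMP-DX round-trip preserves grid and intensities", {
  co <- make_tiny_cohort()
  d <- withr::local_tempdir()
  write_cohort(co, d, format = "jcampdx")
  back <- read_cohort(d, format = "jcampdx")
  expect_identical(back$wavenumbers, co$wavenumbers)
  # file order is alphabetical; compare per (subject, replicate)
  key <- function(x) paste(x$meta$subject_id, x$meta$replicate)
  expect_identical(back$intensities[order(key(back)), ],
                   co$intensities[order(key(co)), ])
})

test_that("single-spectrum JCAMP-DX write/read is exact", {
  s <- raman_spectrum("X9", "index_finger", 3,
                      c(500.25, 733.125, 1209.8), c(12.5, 0, 991.25))
  f <- withr::local_tempfile(fileext = ".jdx")
  write_jcampdx(s, f)
  back <- read_jcampdx(f)
  expect_identical(back$wavenumbers, s$wavenumbers)
  expect_identical(back$intensities, s$intensities)
  expect_identical(back$subject_id, s$subject_id)
  expect_identical(back$replicate, s$replicate)
})

test_that("reading rejects corrupt tables with located errors", {
  co <- make_tiny_cohort()
  d <- withr::local_tempdir()
  write_cohort(co, d)
  # break one intensity cell
  lines <- readLines(file.path(d, "spectra.csv"))
  lines[3] <- sub("^([^,]*,[^,]*,[^,]*,)[^,]*", "\\1oops", lines[3])
  writeLines(lines, file.path(d, "spectra.csv"))
  expect_error(read_cohort(d), "non-numeric intensity")
  # remove the reference file entirely
  file.remove(file.path(d, "references.csv"))
  expect_error(read_cohort(d), "references")
})

test_that("long-format CSV parses to the same cohort as wide", {
  co <- make_tiny_cohort()
  d <- withr::local_tempdir()
  write_cohort(co, d)
  long <- do.call(rbind, lapply(seq_len(n_spectra(co)), function(i) {
    data.frame(subject_id = co$meta$subject_id[i], site = co$meta$site[i],
               replicate = co$meta$replicate[i],
               wavenumber = co$wavenumbers, intensity = co$intensities[i, ])
  }))
  utils::write.csv(format(long, digits = 17, trim = TRUE, scientific = FALSE),
                   file.path(d, "spectra.csv"), row.names = FALSE,
                   quote = FALSE)
  back <- read_cohort(d)
  ord <- order(back$meta$subject_id, back$meta$replicate)
  expect_equal(back$intensities[ord, ], co$intensities, tolerance = 1e-12)
})

test_that("empty cohort writes with a warning and reads back", {
  co <- make_tiny_cohort()
  empty <- raman_cohort(co$wavenumbers,
                        co$intensities[integer(0), , drop = FALSE],
                        co$meta[integer(0), ],
                        co$references[integer(0), ])
  d <- withr::local_tempdir()
  expect_warning(write_cohort(empty, d), "empty")
  back <- read_cohort(d)
  expect_equal(n_spectra(back), 0L)
})

test_that("restrict_interval keeps the closed interval and is idempotent", {
  co <- generate_cohort(cohort_spec(
    n_subjects = 2, class_counts = c(t2d = 1, prediabetes = 1, healthy = 0),
    sites = "wrist", replicates_per_site = 2, seed = 3))$cohort
  expect_identical(restrict_interval(co, 200, 1800)$intensities,
                   co$intensities)
  mid <- restrict_interval(co, 600, 1600)
  expect_equal(length(mid$wavenumbers), 512L)
  twice <- restrict_interval(mid, 600, 1600)
  expect_identical(twice$intensities, mid$intensities)

  s <- get_spectrum(co, 1)
  p <- s$wavenumbers[17]
  one <- restrict_interval(s, p, p)
  expect_equal(length(one$wavenumbers), 1L)
  expect_error(restrict_interval(s, 5000, 6000), "no grid points")
})
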
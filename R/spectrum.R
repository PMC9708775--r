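#' Construct a single Raman spectrum
#'
#' A `raman_spectrum` bundles one acquisition: the wavenumber grid, the
#' measured intensities, and the acquisition metadata (subject, body site,
#' replicate index).
#'
#' @param subject_id Character scalar identifying the volunteer.
#' @param site Body site, one of `"forearm"`, `"wrist"`, `"index_finger"`.
#' @param replicate Integer replicate index (1-based; complete cohorts carry
#'   nine replicates per subject and site).
#' @param wavenumbers Strictly increasing numeric vector of Raman shifts
#'   (cm^-1).
#' @param intensities Numeric vector of non-negative counts, same length as
#'   `wavenumbers`.
#' @return An object of class `raman_spectrum`.
#' @export
raman_spectrum <- function(subject_id, site, replicate, wavenumbers,
                           intensities) {
  site <- match.arg(site, RAMAN_SITES)
  wavenumbers <- as.numeric(wavenumbers)
  intensities <- as.numeric(intensities)
  if (length(wavenumbers) != length(intensities)) {
    stop("wavenumbers and intensities must have equal length")
  }
  if (length(wavenumbers) == 0L) stop("empty spectrum")
  if (any(diff(wavenumbers) <= 0)) {
    stop("wavenumbers must be strictly increasing")
  }
  if (any(!is.finite(intensities))) stop("non-finite intensities")
  structure(
    list(
      subject_id = as.character(subject_id),
      site = site,
      replicate = as.integer(replicate),
      wavenumbers = wavenumbers,
      intensities = intensities
    ),
    class = "raman_spectrum"
  )
}

#' Body sites measured in the study design
#' @export
RAMAN_SITES <- c("forearm", "wrist", "index_finger")

#' Diagnostic classes used throughout the package
#' @export
DX_CLASSES <- c("healthy", "prediabetes", "t2d")

#' @export
print.raman_spectrum <- function(x, ...) {
  cat(sprintf(
    "<raman_spectrum> subject %s, %s, replicate %d: %d points, %.1f-%.1f cm^-1\n",
    x$subject_id, x$site, x$replicate, length(x$wavenumbers),
    min(x$wavenumbers), max(x$wavenumbers)
  ))
  invisible(x)
}

#' Construct a cohort of spectra with subject reference values
#'
#' A `raman_cohort` holds all acquisitions on a shared wavenumber grid
#' (intensities as a spectra-by-wavenumber matrix, metadata as a data frame)
#' together with the per-subject laboratory reference values.
#'
#' @param wavenumbers Shared strictly increasing grid (cm^-1).
#' @param intensities Numeric matrix, one row per acquisition, `ncol ==
#'   length(wavenumbers)`.
#' @param meta Data frame with columns `subject_id`, `site`, `replicate`,
#'   one row per acquisition (row order matches `intensities`).
#' @param references Data frame with columns `subject_id`, `hba1c_pct`,
#'   `glucose_mgdl`, `dx_class`, one row per subject.
#' @param provenance Optional list recording how the cohort was produced
#'   (free text, seed).
#' @return An object of class `raman_cohort`.
#' @export
raman_cohort <- function(wavenumbers, intensities, meta, references,
                         provenance = list()) {
  intensities <- as.matrix(intensities)
  obj <- structure(
    list(
      wavenumbers = as.numeric(wavenumbers),
      intensities = intensities,
      meta = as.data.frame(meta),
      references = as.data.frame(references),
      provenance = provenance
    ),
    class = "raman_cohort"
  )
  validate_cohort(obj)
  obj
}

#' Validate a cohort's structural invariants
#'
#' Checks grid monotonicity, dimension agreement, that every spectrum's
#' subject has exactly one reference row, that reference values are positive,
#' and that the recorded diagnostic class agrees with [class_from_hba1c()].
#'
#' @param cohort A `raman_cohort`.
#' @return The cohort, invisibly; errors on any violation.
#' @export
validate_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "raman_cohort"))
  wn <- cohort$wavenumbers
  if (length(wn) && any(diff(wn) <= 0)) {
    stop("cohort wavenumber grid must be strictly increasing")
  }
  if (ncol(cohort$intensities) != length(wn)) {
    stop("intensity matrix width does not match grid length")
  }
  if (nrow(cohort$intensities) != nrow(cohort$meta)) {
    stop("metadata rows do not match spectra rows")
  }
  need <- c("subject_id", "site", "replicate")
  if (!all(need %in% names(cohort$meta))) {
    stop("meta must have columns subject_id, site, replicate")
  }
  if (nrow(cohort$meta) && !all(cohort$meta$site %in% RAMAN_SITES)) {
    stop("unknown body site in metadata")
  }
  refs <- cohort$references
  need_ref <- c("subject_id", "hba1c_pct", "glucose_mgdl", "dx_class")
  if (!all(need_ref %in% names(refs))) {
    stop("references must have columns subject_id, hba1c_pct, glucose_mgdl, dx_class")
  }
  if (anyDuplicated(refs$subject_id)) {
    stop("duplicate subject_id in references: ",
         paste(unique(refs$subject_id[duplicated(refs$subject_id)]),
               collapse = ", "))
  }
  missing_ref <- setdiff(unique(cohort$meta$subject_id), refs$subject_id)
  if (length(missing_ref)) {
    stop("missing reference for subject(s): ",
         paste(missing_ref, collapse = ", "))
  }
  if (nrow(refs)) {
    if (any(refs$hba1c_pct <= 0) || any(refs$glucose_mgdl <= 0)) {
      stop("reference values must be positive")
    }
    implied <- class_from_hba1c(refs$hba1c_pct)
    if (!all(as.character(refs$dx_class) == implied)) {
      bad <- refs$subject_id[as.character(refs$dx_class) != implied]
      stop("dx_class inconsistent with HbA1c cut-offs for subject(s): ",
           paste(bad, collapse = ", "))
    }
  }
  invisible(cohort)
}

#' @export
print.raman_cohort <- function(x, ...) {
  cat(sprintf(
    "<raman_cohort> %d spectra, %d subjects, %d grid points (%.1f-%.1f cm^-1)\n",
    nrow(x$intensities), nrow(x$references), length(x$wavenumbers),
    if (length(x$wavenumbers)) min(x$wavenumbers) else NA,
    if (length(x$wavenumbers)) max(x$wavenumbers) else NA
  ))
  if (nrow(x$meta)) {
    print(table(site = x$meta$site))
  }
  invisible(x)
}

#' Number of spectra in a cohort
#' @param cohort A `raman_cohort`.
#' @export
n_spectra <- function(cohort) nrow(cohort$intensities)

#' Extract one acquisition from a cohort as a `raman_spectrum`
#'
#' @param cohort A `raman_cohort`.
#' @param i Row index of the acquisition.
#' @export
get_spectrum <- function(cohort, i) {
  m <- cohort$meta[i, ]
  raman_spectrum(m$subject_id, m$site, m$replicate,
                 cohort$wavenumbers, cohort$intensities[i, ])
}

#' Subset a cohort by acquisition rows
#'
#' Keeps only the selected acquisitions; reference rows for subjects no
#' longer present are dropped.
#'
#' @param cohort A `raman_cohort`.
#' @param rows Integer or logical index into the acquisitions.
#' @export
subset_cohort <- function(cohort, rows) {
  meta <- cohort$meta[rows, , drop = FALSE]
  refs <- cohort$references[
    cohort$references$subject_id %in% unique(meta$subject_id), , drop = FALSE]
  raman_cohort(cohort$wavenumbers,
               cohort$intensities[rows, , drop = FALSE],
               meta, refs, cohort$provenance)
}

#' Restrict a spectrum or cohort to a closed wavenumber interval
#'
#' Keeps every grid point p with `lo <= p <= hi` (both ends inclusive).
#' The study design uses two such views: the full 200-1800 cm^-1 window
#' (788 points) and the restricted 600-1600 cm^-1 window (512 points).
#'
#' @param x A `raman_spectrum` or `raman_cohort`.
#' @param lo,hi Interval bounds in cm^-1, `lo <= hi` (a degenerate
#'   `lo == hi` interval selects a single on-grid point).
#' @return Object of the same class on the restricted grid.
#' @export
restrict_interval <- function(x, lo, hi) {
  UseMethod("restrict_interval")
}

#' @export
restrict_interval.raman_spectrum <- function(x, lo, hi) {
  keep <- interval_keep(x$wavenumbers, lo, hi)
  raman_spectrum(x$subject_id, x$site, x$replicate,
                 x$wavenumbers[keep], x$intensities[keep])
}

#' @export
restrict_interval.raman_cohort <- function(x, lo, hi) {
  keep <- interval_keep(x$wavenumbers, lo, hi)
  raman_cohort(x$wavenumbers[keep],
               x$intensities[, keep, drop = FALSE],
               x$meta, x$references, x$provenance)
}

interval_keep <- function(wn, lo, hi) {
  if (lo > hi) stop("restrict_interval requires lo <= hi")
  keep <- wn >= lo & wn <= hi
  if (!any(keep)) stop("no grid points in [", lo, ", ", hi, "]")
  keep
}
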
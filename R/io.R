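#' Write a cohort to disk
#'
#' CSV is the primary interchange format: a directory holding `spectra.csv`
#' (wide form: `subject_id`, `site`, `replicate`, then one column per
#' wavenumber, headers at full precision so the grid round-trips exactly)
#' and `references.csv`.
#' `format = "jcampdx"` writes one JCAMP-DX 4.24 file per acquisition plus
#' the same `references.csv` sidecar.
#'
#' @param cohort A valid `raman_cohort`.
#' @param path Output directory (created if absent).
#' @param format `"csv"` (default) or `"jcampdx"`.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, format = c("csv", "jcampdx")) {
  format <- match.arg(format)
  validate_cohort(cohort)
  if (n_spectra(cohort) == 0L) {
    warning("writing an empty cohort")
  }
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) stop("cannot create output directory ", path)
  utils::write.csv(format(cohort$references, digits = 17, trim = TRUE,
                          scientific = FALSE),
                   file.path(path, "references.csv"), row.names = FALSE,
                   quote = FALSE)
  if (format == "csv") {
    wide <- cbind(
      cohort$meta[, c("subject_id", "site", "replicate")],
      as.data.frame(cohort$intensities)
    )
    names(wide) <- c("subject_id", "site", "replicate",
                     sprintf("%.17g", cohort$wavenumbers))
    # full decimal precision so the round-trip is exact
    utils::write.csv(format(wide, digits = 17, trim = TRUE, scientific = FALSE),
                     file.path(path, "spectra.csv"),
                     row.names = FALSE, quote = FALSE)
  } else {
    for (i in seq_len(n_spectra(cohort))) {
      s <- get_spectrum(cohort, i)
      fn <- sprintf("%s_%s_r%02d.jdx", s$subject_id, s$site, s$replicate)
      write_jcampdx(s, file.path(path, fn))
    }
  }
  if (length(cohort$provenance)) {
    jsonlite::write_json(cohort$provenance,
                         file.path(path, "provenance.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a cohort from disk
#'
#' Accepts the layouts produced by [write_cohort()]: a directory with a
#' references table plus either a wide/long spectra CSV or a set of JCAMP-DX
#' files. Wavenumber grids are checked for strict monotonicity and
#' cross-spectrum consistency (grids must agree within 1e-6 cm^-1).
#'
#' @param path Directory locator.
#' @param format `"csv"` or `"jcampdx"`.
#' @return A validated `raman_cohort`.
#' @export
read_cohort <- function(path, format = c("csv", "jcampdx")) {
  format <- match.arg(format)
  if (!dir.exists(path)) stop("no such directory: ", path)
  ref_path <- file.path(path, "references.csv")
  if (!file.exists(ref_path)) stop("missing references.csv in ", path)
  refs <- utils::read.csv(ref_path, stringsAsFactors = FALSE)
  prov <- list()
  prov_path <- file.path(path, "provenance.json")
  if (file.exists(prov_path)) prov <- jsonlite::read_json(prov_path)

  if (format == "csv") {
    sp_path <- file.path(path, "spectra.csv")
    if (!file.exists(sp_path)) stop("missing spectra.csv in ", path)
    tab <- utils::read.csv(sp_path, check.names = FALSE,
                           stringsAsFactors = FALSE)
    parsed <- parse_spectra_table(tab)
    wn <- parsed$wavenumbers
    inten <- parsed$intensities
    meta <- parsed$meta
  } else {
    files <- sort(list.files(path, pattern = "\\.jdx$", full.names = TRUE))
    if (!length(files)) stop("no .jdx files in ", path)
    specs <- lapply(files, read_jcampdx)
    wn <- specs[[1]]$wavenumbers
    for (s in specs[-1]) {
      if (length(s$wavenumbers) != length(wn) ||
          max(abs(s$wavenumbers - wn)) > 1e-6) {
        stop("inconsistent wavenumber grids across JCAMP-DX files")
      }
    }
    inten <- do.call(rbind, lapply(specs, function(s) s$intensities))
    meta <- data.frame(
      subject_id = vapply(specs, function(s) s$subject_id, ""),
      site = vapply(specs, function(s) s$site, ""),
      replicate = vapply(specs, function(s) s$replicate, 1L),
      stringsAsFactors = FALSE
    )
  }
  raman_cohort(wn, inten, meta, refs, prov)
}

# Accepts wide form (one column per wavenumber) or long form
# (subject_id, site, replicate, wavenumber, intensity).
parse_spectra_table <- function(tab) {
  long_cols <- c("subject_id", "site", "replicate", "wavenumber", "intensity")
  if (all(long_cols %in% names(tab)) && ncol(tab) == 5L) {
    wn <- sort(unique(tab$wavenumber))
    key <- interaction(tab$subject_id, tab$site, tab$replicate, drop = TRUE)
    rows <- split(seq_len(nrow(tab)), key)
    inten <- matrix(NA_real_, length(rows), length(wn))
    meta <- data.frame(subject_id = character(length(rows)),
                       site = character(length(rows)),
                       replicate = integer(length(rows)),
                       stringsAsFactors = FALSE)
    for (i in seq_along(rows)) {
      idx <- rows[[i]]
      ord <- order(tab$wavenumber[idx])
      idx <- idx[ord]
      if (length(idx) != length(wn) ||
          max(abs(tab$wavenumber[idx] - wn)) > 1e-6) {
        stop("inconsistent wavenumber grids in long-format table")
      }
      vals <- tab$intensity[idx]
      if (any(!is.finite(vals))) {
        stop("non-numeric intensity near table row ", idx[which(!is.finite(vals))[1]])
      }
      inten[i, ] <- vals
      meta$subject_id[i] <- as.character(tab$subject_id[idx[1]])
      meta$site[i] <- as.character(tab$site[idx[1]])
      meta$replicate[i] <- as.integer(tab$replicate[idx[1]])
    }
    return(list(wavenumbers = wn, intensities = inten, meta = meta))
  }
  # wide form
  id_cols <- c("subject_id", "site", "replicate")
  if (!all(id_cols %in% names(tab))) {
    stop("spectra table is neither recognized wide nor long format")
  }
  wn_cols <- setdiff(names(tab), id_cols)
  wn <- suppressWarnings(as.numeric(wn_cols))
  if (any(is.na(wn))) stop("non-numeric wavenumber column header(s)")
  ord <- order(wn)
  inten <- as.matrix(tab[, wn_cols[ord], drop = FALSE])
  suppressWarnings(storage.mode(inten) <- "double")
  if (any(!is.finite(inten))) {
    bad <- which(!is.finite(inten), arr.ind = TRUE)[1, ]
    stop("non-numeric intensity at table row ", bad[1],
         ", wavenumber column ", wn_cols[ord][bad[2]])
  }
  dimnames(inten) <- NULL
  meta <- data.frame(subject_id = as.character(tab$subject_id),
                     site = as.character(tab$site),
                     replicate = as.integer(tab$replicate),
                     stringsAsFactors = FALSE)
  list(wavenumbers = wn[ord], intensities = inten, meta = meta)
}

#' Write one spectrum as a JCAMP-DX 4.24 file
#'
#' Uses an `##XYDATA=(XY..XY)` table in AFFN (plain decimal) form, one
#' `x, y` pair per line, full precision. Acquisition metadata travels in
#' `##TITLE=` and custom `##$` labels.
#'
#' @param s A `raman_spectrum`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_jcampdx <- function(s, path) {
  stopifnot(inherits(s, "raman_spectrum"))
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- c(
    sprintf("##TITLE=%s %s replicate %d", s$subject_id, s$site, s$replicate),
    "##JCAMP-DX=4.24",
    "##DATA TYPE=RAMAN SPECTRUM",
    "##XUNITS=1/CM",
    "##YUNITS=ARBITRARY UNITS",
    sprintf("##$SUBJECTID=%s", s$subject_id),
    sprintf("##$SITE=%s", s$site),
    sprintf("##$REPLICATE=%d", s$replicate),
    sprintf("##FIRSTX=%.10g", s$wavenumbers[1]),
    sprintf("##LASTX=%.10g", s$wavenumbers[length(s$wavenumbers)]),
    sprintf("##NPOINTS=%d", length(s$wavenumbers)),
    "##XYDATA=(XY..XY)"
  )
  writeLines(hdr, con)
  writeLines(sprintf("%.17g, %.17g", s$wavenumbers, s$intensities), con)
  writeLines("##END=", con)
  invisible(path)
}

#' Read a JCAMP-DX file written by [write_jcampdx()]
#'
#' @param path File path.
#' @return A `raman_spectrum`.
#' @export
read_jcampdx <- function(path) {
  lines <- readLines(path)
  get_label <- function(label) {
    hit <- grep(paste0("^", label, "="), lines, value = TRUE)
    if (!length(hit)) return(NA_character_)
    sub(paste0("^", label, "="), "", hit[1])
  }
  subject_id <- get_label("##\\$SUBJECTID")
  site <- get_label("##\\$SITE")
  replicate <- as.integer(get_label("##\\$REPLICATE"))
  start <- grep("^##XYDATA", lines)
  if (!length(start)) stop("no XYDATA block in ", path)
  end <- grep("^##END", lines)
  end <- end[end > start[1]][1]
  body <- lines[(start[1] + 1):(end - 1)]
  parts <- strsplit(body, "[,;[:space:]]+")
  xy <- vapply(parts, function(p) as.numeric(p[p != ""][1:2]), numeric(2))
  raman_spectrum(subject_id, site, replicate, xy[1, ], xy[2, ])
}
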
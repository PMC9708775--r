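#' Cross-validated RMSE of a model recipe
#'
#' Randomly partitions the samples into `k` near-equal folds (sizes differ
#' by at most 1; with 414 spectra and k = 3 every training set holds 276
#' samples and every test fold 138), trains the supplied recipe on the
#' complement of each fold, and reports the per-fold test RMSE, their mean
#' (RMSE-CV) and the between-fold standard deviation. Folds are drawn at
#' the sample (replicate) level by default; passing per-sample `groups`
#' (e.g. subject ids) keeps whole groups inside one fold, which avoids
#' subject identity leaking across folds at the cost of the exact 276/138
#' arithmetic.
#'
#' @param X Sample-by-feature matrix.
#' @param y Numeric response.
#' @param fit_fun Function `(X_train, y_train) -> model`, where the model
#'   answers to [predict()].
#' @param k Number of folds (default 3, must be >= 2).
#' @param seed Seed of the random partition.
#' @param groups Optional per-sample grouping vector for grouped folds.
#' @return List of class `cv_report`: `fold_rmse`, `rmse_cv`, `sd`,
#'   `fold_assignment`.
#' @export
kfold_rmsecv <- function(X, y, fit_fun, k = 3L, seed = 1L, groups = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (k < 2) stop("k must be >= 2")
  if (n < k) stop("more folds than samples")
  old <- .Random.seed_save()
  set.seed(seed)
  if (is.null(groups)) {
    fold <- sample(rep_len(seq_len(k), n))
  } else {
    g <- unique(groups)
    gf <- sample(rep_len(seq_len(k), length(g)))
    fold <- gf[match(groups, g)]
  }
  .Random.seed_restore(old)
  oof <- rep(NA_real_, n)
  fold_rmse <- vapply(seq_len(k), function(f) {
    te <- fold == f
    model <- fit_fun(X[!te, , drop = FALSE], y[!te])
    pred <- stats::predict(model, X[te, , drop = FALSE])
    oof[te] <<- pred
    sqrt(mean((pred - y[te])^2))
  }, numeric(1))
  structure(list(fold_rmse = fold_rmse,
                 rmse_cv = mean(fold_rmse),
                 sd = stats::sd(fold_rmse),
                 fold_assignment = fold,
                 predictions = oof),
            class = "cv_report")
}

#' Clarke error grid zone of glucose predictions
#'
#' Assigns each (reference, predicted) pair in mg/dL to one of the five
#' clinical-accuracy zones of the Clarke error grid, using the canonical
#' published boundaries evaluated in the order A, E, C, D, else B:
#' \itemize{
#'   \item A: both values <= 70, or relative error <= 20 %.
#'   \item E: reference >= 180 with prediction <= 70, or reference <= 70
#'     with prediction >= 180.
#'   \item C: 70 <= reference <= 290 with prediction >= reference + 110, or
#'     130 <= reference <= 180 with prediction <= (7/5) reference - 182.
#'   \item D: reference >= 240 with prediction in [70, 180], or reference
#'     <= 175/3 with prediction in [70, 180], or 175/3 <= reference <= 70
#'     with prediction >= (6/5) reference.
#'   \item B: everything else.
#' }
#' The diagonal is always zone A, and every point in the positive quadrant
#' receives exactly one zone.
#'
#' @param reference True glucose, mg/dL, > 0 (vectorized).
#' @param predicted Predicted glucose, mg/dL, >= 0.
#' @return Character vector of zones `"A"`..`"E"`.
#' @export
clarke_zone <- function(reference, predicted) {
  if (any(reference <= 0)) stop("reference glucose must be positive")
  if (any(predicted < 0)) stop("predicted glucose must be >= 0")
  r <- reference
  p <- predicted
  zone <- rep(NA_character_, length(r))
  a <- (p <= 70 & r <= 70) | (abs(p - r) <= 0.2 * r)
  e <- !a & ((r >= 180 & p <= 70) | (r <= 70 & p >= 180))
  c_ <- !a & !e & ((r >= 70 & r <= 290 & p >= r + 110) |
                     (r >= 130 & r <= 180 & p <= (7 / 5) * r - 182))
  d <- !a & !e & !c_ &
    ((r >= 240 & p >= 70 & p <= 180) |
       (r <= 175 / 3 & p >= 70 & p <= 180) |
       (r >= 175 / 3 & r <= 70 & p >= (6 / 5) * r))
  zone[a] <- "A"
  zone[e] <- "E"
  zone[c_] <- "C"
  zone[d] <- "D"
  zone[is.na(zone)] <- "B"
  zone
}

#' Clarke error grid summary
#'
#' Zone percentages (2 decimals) over a set of (reference, predicted)
#' pairs, with the per-point zones and pairs retained for plotting.
#'
#' @param reference,predicted Glucose pairs in mg/dL.
#' @return List of class `clarke_report`: `zones` (per point),
#'   `percentages` (named A-E, summing to 100 within rounding), `pairs`.
#' @export
clarke_summary <- function(reference, predicted) {
  if (!length(reference)) stop("at least one pair required")
  z <- clarke_zone(reference, predicted)
  counts <- table(factor(z, levels = c("A", "B", "C", "D", "E")))
  pct <- round(100 * as.numeric(counts) / length(z), 2)
  names(pct) <- names(counts)
  structure(list(zones = z, percentages = pct,
                 pairs = data.frame(reference = reference,
                                    predicted = predicted, zone = z)),
            class = "clarke_report")
}

#' Plot a Clarke error grid
#'
#' Draws the classic grid with zone boundaries derived from the same
#' inequality set as [clarke_zone()] (the zone of every plotted point and
#' the background labels share one source of truth). Requires ggplot2.
#'
#' @param report A `clarke_report` from [clarke_summary()].
#' @param max_glucose Axis limit in mg/dL (default 450).
#' @return A ggplot object.
#' @export
clarke_plot <- function(report, max_glucose = 450) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for clarke_plot")
  }
  gg <- seq(1, max_glucose, by = 2)
  bg <- expand.grid(reference = gg, predicted = gg)
  bg$zone <- clarke_zone(bg$reference, bg$predicted)
  ggplot2::ggplot() +
    ggplot2::geom_raster(data = bg,
                         ggplot2::aes(x = .data$reference,
                                      y = .data$predicted,
                                      fill = .data$zone),
                         alpha = 0.25) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::geom_point(data = report$pairs,
                        ggplot2::aes(x = .data$reference,
                                     y = .data$predicted),
                        size = 0.8) +
    ggplot2::labs(x = "Reference glucose (mg/dL)",
                  y = "Predicted glucose (mg/dL)", fill = "Zone") +
    ggplot2::coord_equal(xlim = c(0, max_glucose),
                         ylim = c(0, max_glucose), expand = FALSE)
}

#' Diagnostic class from an HbA1c percentage
#'
#' ADA-convention cut-offs: below 5.7 % healthy, 5.7 % to below 6.5 %
#' prediabetes, 6.5 % and above T2D.
#'
#' @param hba1c_pct HbA1c in %, > 0 (vectorized).
#' @return Character vector over `c("healthy", "prediabetes", "t2d")`.
#' @export
class_from_hba1c <- function(hba1c_pct) {
  if (any(hba1c_pct <= 0)) stop("HbA1c must be positive")
  ifelse(hba1c_pct < 5.7, "healthy",
         ifelse(hba1c_pct < 6.5, "prediabetes", "t2d"))
}

#' Multiclass diagnostic metrics
#'
#' Confusion matrix over the three diagnostic classes with one-vs-rest
#' sensitivity and specificity per class and overall accuracy, all in
#' percent. A class absent from the truth (sensitivity) or whose rest-set
#' is empty (specificity) yields `NA`, reported as undefined rather than 0.
#'
#' @param truth,predicted Label vectors over
#'   `c("healthy", "prediabetes", "t2d")`, equal length.
#' @return List of class `dx_metrics`: `confusion` (rows = truth),
#'   `sensitivity`, `specificity` (named, %), `accuracy` (%).
#' @export
dx_metrics <- function(truth, predicted) {
  if (length(truth) != length(predicted)) {
    stop("truth and predicted must have equal length")
  }
  truth <- factor(as.character(truth), levels = DX_CLASSES)
  predicted <- factor(as.character(predicted), levels = DX_CLASSES)
  if (anyNA(truth) || anyNA(predicted)) stop("labels outside the 3-class enum")
  cm <- table(truth = truth, predicted = predicted)
  total <- sum(cm)
  sens <- spec <- stats::setNames(numeric(3), DX_CLASSES)
  for (cl in DX_CLASSES) {
    tp <- cm[cl, cl]
    fn <- sum(cm[cl, ]) - tp
    fp <- sum(cm[, cl]) - tp
    tn <- total - tp - fn - fp
    sens[cl] <- if (tp + fn == 0) NA_real_ else 100 * tp / (tp + fn)
    spec[cl] <- if (tn + fp == 0) NA_real_ else 100 * tn / (tn + fp)
  }
  structure(list(confusion = unclass(cm),
                 sensitivity = sens, specificity = spec,
                 accuracy = 100 * sum(diag(cm)) / total),
            class = "dx_metrics")
}

#' Diagnostic metrics of regression-predicted HbA1c
#'
#' Converts predicted HbA1c percentages to diagnostic classes through the
#' cut-offs of [class_from_hba1c()] and scores them against the true
#' labels — the protocol for judging a regression calibration as a
#' diagnostic instrument.
#'
#' @param predicted_hba1c Predicted HbA1c values in %.
#' @param truth True diagnostic labels.
#' @return A `dx_metrics` list.
#' @export
regression_to_dx <- function(predicted_hba1c, truth) {
  dx_metrics(truth, class_from_hba1c(pmax(predicted_hba1c, 1e-9)))
}
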
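#' Per-class confusion counts of two label masks
#'
#' @param pred,truth [label_mask()]s with identical dimensions.
#' @param cls class name treated as positive.
#' @return list with nonnegative pixel counts `TP`, `FP`, `FN`, `TN` summing
#'   to the raster size.
#' @export
confusion_counts <- function(pred, truth, cls) {
  if (pred$width != truth$width || pred$height != truth$height)
    stop("confusion_counts: mask dimensions differ")
  p <- class_raster(pred, cls)
  t <- class_raster(truth, cls)
  list(TP = sum(p & t), FP = sum(p & !t), FN = sum(!p & t), TN = sum(!p & !t))
}

#' Intersection over union of one class
#'
#' `IoU = TP / (TP + FP + FN)`. Returns `NA` (undefined metric) when the
#' class is absent from both masks.
#'
#' @inheritParams confusion_counts
#' @return proportion in `[0, 1]`, or `NA`.
#' @export
iou <- function(pred, truth, cls) {
  cc <- confusion_counts(pred, truth, cls)
  den <- cc$TP + cc$FP + cc$FN
  if (den == 0) return(NA_real_)
  cc$TP / den
}

#' Pixel accuracy of one class
#'
#' `PA = (TP + TN) / (TP + TN + FP + FN)`.
#'
#' @inheritParams confusion_counts
#' @return proportion in `[0, 1]`, or `NA` when the class is absent from
#'   both masks.
#' @export
pixel_accuracy <- function(pred, truth, cls) {
  cc <- confusion_counts(pred, truth, cls)
  if (cc$TP + cc$FP + cc$FN == 0) return(NA_real_)
  (cc$TP + cc$TN) / (cc$TP + cc$TN + cc$FP + cc$FN)
}

#' Mean of a per-class metric over the palette classes
#'
#' The per-class mean (as in MIoU / MPA); undefined classes are dropped.
#'
#' @param pred,truth [label_mask()]s.
#' @param metric a function `(pred, truth, cls) -> proportion`, e.g. [iou()].
#' @return proportion in `[0, 1]`.
#' @export
mean_over_classes <- function(pred, truth, metric = iou) {
  vals <- vapply(rownames(label_palette()),
                 function(cl) metric(pred, truth, cl), numeric(1))
  mean(vals, na.rm = TRUE)
}

#' Absolute measurement-error summary
#'
#' @param measured,actual equal-length numeric vectors (mm).
#' @param thresholds numeric vector of error thresholds (mm) at which to
#'   count exceedances.
#' @return list with `abs_errors`, `max_error`, and `count_exceeding` (named
#'   by threshold).
#' @export
error_summary <- function(measured, actual, thresholds = 1) {
  if (length(measured) != length(actual) || length(measured) < 1)
    stop("error_summary: measured and actual must have equal length >= 1")
  err <- abs(measured - actual)
  counts <- vapply(thresholds, function(th) sum(err > th), numeric(1))
  names(counts) <- paste0(">", thresholds, "mm")
  list(abs_errors = err, max_error = max(err), count_exceeding = counts)
}

#' Ordinary least squares agreement report
#'
#' Regresses the measured values on the actual values with `lm` and reports
#' the agreement statistics: `R^2` (the squared Pearson correlation),
#' `adj.R^2 = 1 - (1 - R^2)(n - 1)/(n - 2)`, and the regression F statistic
#' `F = R^2 (n - 2)/(1 - R^2)`.
#'
#' @param actual,measured numeric vectors (mm), `n >= 3`, `actual` not
#'   constant.
#' @return object of class `regression_report`: slope, intercept,
#'   `r_squared`, `adj_r_squared`, `f_statistic`, `n`, `per_sample_errors`
#'   (absolute measured-vs-actual errors), and the underlying `lm` fit.
#' @export
ols_report <- function(actual, measured) {
  if (length(actual) != length(measured))
    stop("ols_report: input lengths differ")
  n <- length(actual)
  if (n < 3) stop("ols_report: need at least 3 samples")
  if (stats::sd(actual) < 1e-12)
    stop("ols_report: actual values are constant (degenerate regression)")
  fit <- stats::lm(measured ~ actual)
  sm <- summary(fit)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = sm$r.squared,
                 adj_r_squared = sm$adj.r.squared,
                 f_statistic = unname(sm$fstatistic[1]),
                 n = n,
                 per_sample_errors = abs(measured - actual),
                 fit = fit),
            class = "regression_report")
}

#' @export
print.regression_report <- function(x, digits = 4, ...) {
  cat("<regression_report>\n")
  cat(sprintf("  n = %d; measured = %.4g + %.4g * actual\n",
              x$n, x$intercept, x$slope))
  cat(sprintf("  R^2 = %.*f; adj.R^2 = %.*f; F = %.3f\n",
              digits, x$r_squared, digits, x$adj_r_squared, x$f_statistic))
  cat(sprintf("  max |error| = %.3f mm\n", max(x$per_sample_errors)))
  invisible(x)
}

#' Load the shipped 15-egg measurement table
#'
#' The packaged fixture of measured vs caliper-actual axis lengths (mm) for
#' 15 eggs, with the printed per-sample absolute errors. On load, every
#' printed error cell is checked against `|measured - actual|` of its row to
#' 0.001 mm; a mismatch signals fixture corruption.
#'
#' @return data frame with columns `sample_id`, `minor_measured`,
#'   `minor_actual`, `minor_error`, `major_measured`, `major_actual`,
#'   `major_error`.
#' @export
load_egg_measurements <- function() {
  path <- system.file("extdata", "egg_measurements_15.csv",
                      package = "ovometry", mustWork = TRUE)
  df <- utils::read.csv(path)
  if (nrow(df) != 15)
    stop("load_egg_measurements: fixture corrupted (expected 15 rows, got ", nrow(df), ")")
  for (ax in c("minor", "major")) {
    rec <- abs(df[[paste0(ax, "_measured")]] - df[[paste0(ax, "_actual")]])
    if (any(abs(rec - df[[paste0(ax, "_error")]]) > 0.001 + 1e-9))
      stop("load_egg_measurements: fixture corrupted (", ax,
           " error column does not match |measured - actual|)")
  }
  df
}

#' Reproduce the fixture's accuracy statistics
#'
#' Runs [ols_report()] and [error_summary()] on both axes of the shipped
#' measurement table and prints the headline agreement statistics.
#'
#' @param quiet suppress printing.
#' @return list with `major` and `minor`, each holding the
#'   `regression_report` and error summary, invisibly when printing.
#' @export
repro_measurement_table <- function(quiet = FALSE) {
  df <- load_egg_measurements()
  out <- list()
  for (ax in c("major", "minor")) {
    rep_ <- ols_report(df[[paste0(ax, "_actual")]],
                       df[[paste0(ax, "_measured")]])
    es <- error_summary(df[[paste0(ax, "_measured")]],
                        df[[paste0(ax, "_actual")]], thresholds = c(1, 2))
    out[[ax]] <- list(ols = rep_, errors = es)
    if (!quiet) {
      cat(sprintf("%s axis: adj.R^2 = %.4f, F = %.3f, max |error| = %.3f mm, errors > 1 mm: %d\n",
                  ax, rep_$adj_r_squared, rep_$f_statistic,
                  es$max_error, es$count_exceeding[[">1mm"]]))
    }
  }
  invisible(out)
}
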
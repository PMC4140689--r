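#' Confusion matrix for symmetry verdicts
#'
#' A "positive" is a symmetric verdict. `tp`: symmetric verdict on a truly
#' symmetric case; `fn`: non-symmetric verdict (asymmetric or undetermined)
#' on a symmetric case; `fp` / `tn`: the same on truly asymmetric cases.
#'
#' @param tp,fn,fp,tn Nonnegative integer counts.
#' @return List (class `symaxis_confusion`).
#' @export
confusion_matrix <- function(tp, fn, fp, tn) {
  counts <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  if (any(counts < 0)) stop("counts must be >= 0", call. = FALSE)
  structure(as.list(counts), class = "symaxis_confusion")
}

#' Sensitivity and specificity in percent
#'
#' `sensitivity = 100 * tp / (tp + fn)` over truly symmetric cases;
#' `specificity = 100 * tn / (tn + fp)` over truly asymmetric ones. A zero
#' denominator yields `NA` (the rate is absent, not zero).
#'
#' @param cm `symaxis_confusion`.
#' @return Percentage, or `NA_real_`.
#' @export
sensitivity <- function(cm) {
  if (cm$tp + cm$fn == 0) NA_real_ else 100 * cm$tp / (cm$tp + cm$fn)
}

#' @rdname sensitivity
#' @export
specificity <- function(cm) {
  if (cm$tn + cm$fp == 0) NA_real_ else 100 * cm$tn / (cm$tn + cm$fp)
}

#' @export
print.symaxis_confusion <- function(x, ...) {
  cat(sprintf("confusion matrix: tp=%d fn=%d fp=%d tn=%d\n",
              x$tp, x$fn, x$fp, x$tn))
  cat(sprintf("  sensitivity %s  specificity %s\n",
              fmt_pct(sensitivity(x)), fmt_pct(specificity(x))))
  invisible(x)
}

fmt_pct <- function(p) if (is.na(p)) "absent" else sprintf("%.2f%%", p)

#' Score detection reports against ground truth
#'
#' Builds the confusion matrix, sensitivity and specificity (Eq. 1 / Eq. 2
#' style percentages), the mean angular axis error over true positives
#' (circular distance on undirected axes, `min(|d|, 180 - |d|)`), and an
#' ROC trace over the vote threshold via [roc_sweep()]. An `undetermined`
#' verdict counts as a non-detection.
#'
#' @param reports List of `symaxis_report`.
#' @param truths List of ground-truth records (each with `symmetric` and
#'   `true_alpha`), e.g. the `truth` element of a fixture.
#' @param axis_tol Angular tolerance in degrees for the secondary
#'   "correct axis" rate (default `2 * delta_alpha` of the first report,
#'   or 2).
#' @return List (class `symaxis_eval`) with `matrix`, `sensitivity`,
#'   `specificity`, `mean_axis_error`, `axis_correct_rate`, `roc_points`.
#' @export
score_detections <- function(reports, truths, axis_tol = NULL) {
  if (length(reports) == 0L || length(reports) != length(truths)) {
    stop("invalid input: need a nonempty 1:1 pairing of reports and truths",
         call. = FALSE)
  }
  if (is.null(axis_tol)) {
    da <- reports[[1]]$parameters$config$delta_alpha %||% 1
    axis_tol <- 2 * da
  }
  truth_sym <- vapply(truths, function(t) isTRUE(t$symmetric), TRUE)
  verdict_sym <- vapply(reports, function(r) r$verdict == "symmetric", TRUE)
  cm <- confusion_matrix(tp = sum(truth_sym & verdict_sym),
                         fn = sum(truth_sym & !verdict_sym),
                         fp = sum(!truth_sym & verdict_sym),
                         tn = sum(!truth_sym & !verdict_sym))
  errs <- numeric()
  for (k in which(truth_sym & verdict_sym)) {
    ta <- truths[[k]]$true_alpha
    if (!is.null(ta) && !is.na(ta)) {
      errs <- c(errs, axis_error(reports[[k]]$best_axis$alpha, ta))
    }
  }
  structure(list(matrix = cm,
                 sensitivity = sensitivity(cm),
                 specificity = specificity(cm),
                 mean_axis_error = if (length(errs)) mean(errs) else NA_real_,
                 axis_correct_rate = if (sum(truth_sym) > 0)
                   100 * sum(errs <= axis_tol) / sum(truth_sym)
                 else NA_real_,
                 axis_tol = axis_tol,
                 roc_points = roc_sweep(reports, truths)),
            class = "symaxis_eval")
}

#' @export
print.symaxis_eval <- function(x, ...) {
  print(x$matrix)
  cat(sprintf("  mean axis error (tp): %s\n",
              if (is.na(x$mean_axis_error)) "absent"
              else sprintf("%.2f deg", x$mean_axis_error)))
  cat(sprintf("  correct-axis rate (<= %g deg): %s\n",
              x$axis_tol, fmt_pct(x$axis_correct_rate)))
  invisible(x)
}

#' ROC trace over the vote threshold
#'
#' Re-thresholds stored vote tables without re-running detection: a case is
#' called symmetric at threshold `t` when its maximum candidate vote count
#' is at least `t`. Reports without a vote table (undetermined) count zero
#' votes. TPR and FPR are non-increasing in the threshold.
#'
#' @param reports List of `symaxis_report` (vote tables required).
#' @param truths Matching ground-truth records.
#' @param thresholds Integer thresholds; default `0:(max votes + 1)`.
#' @return `data.frame` with `threshold`, `fpr`, `tpr`.
#' @export
roc_sweep <- function(reports, truths, thresholds = NULL) {
  max_votes <- vapply(reports, function(r) {
    if (is.null(r$vote_table)) 0L else as.integer(max(r$vote_table$votes))
  }, 0L)
  truth_sym <- vapply(truths, function(t) isTRUE(t$symmetric), TRUE)
  if (is.null(thresholds)) thresholds <- 0:(max(max_votes) + 1L)
  n_pos <- sum(truth_sym); n_neg <- sum(!truth_sym)
  tpr <- vapply(thresholds, function(t) {
    if (n_pos == 0) NA_real_ else sum(truth_sym & max_votes >= t) / n_pos
  }, 0)
  fpr <- vapply(thresholds, function(t) {
    if (n_neg == 0) NA_real_ else sum(!truth_sym & max_votes >= t) / n_neg
  }, 0)
  data.frame(threshold = thresholds, fpr = fpr, tpr = tpr)
}

#' Area under an ROC trace
#'
#' Trapezoidal area over the (FPR, TPR) points, endpoints extended to
#' (0,0) and (1,1).
#'
#' @param roc_points `data.frame` from [roc_sweep()].
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(roc_points) {
  ok <- stats::complete.cases(roc_points[, c("fpr", "tpr")])
  x <- c(0, sort(roc_points$fpr[ok]), 1)
  y <- c(0, sort(roc_points$tpr[ok]), 1)
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Write an evaluation report and its ROC trace
#'
#' @param eval `symaxis_eval`.
#' @param path JSON output path for the report.
#' @param roc_path Optional CSV path for the ROC points.
#' @return `path`, invisibly.
#' @export
write_eval <- function(eval, path, roc_path = NULL) {
  x <- unclass(eval)
  x$matrix <- unclass(x$matrix)
  jsonlite::write_json(x, path, dataframe = "columns", auto_unbox = TRUE,
                       digits = NA, na = "null")
  if (!is.null(roc_path)) {
    utils::write.csv(eval$roc_points, roc_path, row.names = FALSE)
  }
  invisible(path)
}
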
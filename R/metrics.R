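# Evaluation metrics: confusion-matrix summaries, multi-rater agreement,
# and side-by-side predictor comparisons.

#' Confusion-matrix metrics
#'
#' Accuracy, positive/negative predictive value, sensitivity and
#' specificity as percentages, kept at full precision internally and
#' rounded to whole percent for display. Ratios with an empty denominator
#' are reported as `NA` (flagged, never silently zeroed).
#'
#' @param predicted,actual Logical vectors, or pass counts via `tp`, `fp`,
#'   `tn`, `fn` directly.
#' @param tp,fp,tn,fn Confusion counts (used when `predicted` is missing).
#' @return Object of class `confusion_metrics`: counts plus `acc`, `ppv`,
#'   `npv`, `sen`, `spe` in percent.
#' @export
#' @examples
#' confusion_metrics(tp = 8, fp = 2, tn = 6, fn = 4)
confusion_metrics <- function(predicted = NULL, actual = NULL,
                              tp = NULL, fp = NULL, tn = NULL, fn = NULL) {
  if (!is.null(predicted)) {
    predicted <- as.logical(predicted); actual <- as.logical(actual)
    stopifnot(length(predicted) == length(actual))
    tp <- sum(predicted & actual); fp <- sum(predicted & !actual)
    tn <- sum(!predicted & !actual); fn <- sum(!predicted & actual)
  }
  n <- tp + fp + tn + fn
  if (n == 0L) stop_oomech("no observations", "oomech_invalid_input")
  pct <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  structure(
    list(tp = tp, fp = fp, tn = tn, fn = fn,
         acc = pct(tp + tn, n), ppv = pct(tp, tp + fp),
         npv = pct(tn, tn + fn), sen = pct(tp, tp + fn),
         spe = pct(tn, tn + fp)),
    class = "confusion_metrics")
}

#' @export
print.confusion_metrics <- function(x, ...) {
  cat(sprintf("n=%d  TP=%d FP=%d TN=%d FN=%d\n",
              x$tp + x$fp + x$tn + x$fn, x$tp, x$fp, x$tn, x$fn))
  fmt <- function(v) if (is.na(v)) "NA" else sprintf("%.0f%%", v)
  cat(sprintf("ACC %s  PPV %s  NPV %s  SEN %s  SPE %s\n",
              fmt(x$acc), fmt(x$ppv), fmt(x$npv), fmt(x$sen), fmt(x$spe)))
  invisible(x)
}

#' @export
as.data.frame.confusion_metrics <- function(x, ...) {
  data.frame(tp = x$tp, fp = x$fp, tn = x$tn, fn = x$fn, acc = x$acc,
             ppv = x$ppv, npv = x$npv, sen = x$sen, spe = x$spe)
}

#' Fleiss' kappa for multiple raters
#'
#' Chance-corrected agreement for `n` raters assigning categorical labels
#' to `N` subjects: \eqn{\kappa = (\bar P - \bar P_e) / (1 - \bar P_e)},
#' where \eqn{\bar P} averages the subject-wise pairwise agreement
#' proportions and \eqn{\bar P_e} sums the squared marginal category
#' proportions.
#'
#' @param ratings Matrix or data frame, subjects in rows and raters in
#'   columns, each cell a category label; no missing cells, at least 2
#'   raters and 2 subjects.
#' @return Kappa (length-1 numeric).
#' @export
fleiss_kappa <- function(ratings) {
  ratings <- as.matrix(ratings)
  if (anyNA(ratings)) stop_oomech("ratings must be complete", "oomech_invalid_input")
  N <- nrow(ratings); n <- ncol(ratings)
  if (N < 2L || n < 2L) {
    stop_oomech("need at least 2 subjects and 2 raters", "oomech_invalid_input")
  }
  cats <- sort(unique(as.vector(ratings)))
  counts <- vapply(cats, function(cat) rowSums(ratings == cat),
                   numeric(N))
  if (N == 1L) counts <- matrix(counts, nrow = 1)
  P_i <- (rowSums(counts^2) - n) / (n * (n - 1))
  p_j <- colSums(counts) / (N * n)
  Pe <- sum(p_j^2)
  if (1 - Pe < 1e-12) {
    stop_oomech("all ratings fall in one category; kappa is undefined",
                "oomech_degenerate_agreement")
  }
  (mean(P_i) - Pe) / (1 - Pe)
}

#' Compare predictor variants and embryologist ratings on one test set
#'
#' Computes one [confusion_metrics()] row per classifier variant and per
#' rater, all against the same true labels, plus the mean rater accuracy.
#'
#' @param truth Logical vector of true usable-blastocyst labels on the test
#'   rows.
#' @param predictions Named list of logical prediction vectors (e.g.
#'   `mechanical`, `maternal`, `mixed`), each the same length as `truth`.
#' @param rater_predictions Optional matrix/data frame of per-rater logical
#'   predictions (rows = the same test subjects, one column per rater).
#' @return List with `table` (`data.frame`, one metrics row per predictor)
#'   and `mean_rater_acc` (percent, `NA` without raters).
#' @export
compare_predictors <- function(truth, predictions, rater_predictions = NULL) {
  truth <- as.logical(truth)
  lens <- vapply(predictions, length, integer(1))
  if (any(lens != length(truth))) {
    stop_oomech("all predictions must cover the same test rows",
                "oomech_comparison_error")
  }
  rows <- lapply(names(predictions), function(nm) {
    cbind(predictor = nm,
          as.data.frame(confusion_metrics(predictions[[nm]], truth)))
  })
  mean_rater_acc <- NA_real_
  if (!is.null(rater_predictions)) {
    rater_predictions <- as.data.frame(rater_predictions)
    if (nrow(rater_predictions) != length(truth)) {
      stop_oomech("rater predictions must cover the same test rows",
                  "oomech_comparison_error")
    }
    accs <- numeric(0)
    for (nm in names(rater_predictions)) {
      cm <- confusion_metrics(rater_predictions[[nm]], truth)
      accs <- c(accs, cm$acc)
      rows[[length(rows) + 1L]] <- cbind(predictor = nm, as.data.frame(cm))
    }
    mean_rater_acc <- mean(accs)
  }
  list(table = do.call(rbind, rows), mean_rater_acc = mean_rater_acc)
}

#' Mean rater accuracy from reported per-rater accuracies
#'
#' @param accuracies Numeric vector of per-rater accuracies in percent.
#' @return List with `mean` (full precision) and `display` (rounded to
#'   whole percent, the convention used in reported tables).
#' @export
mean_rater_accuracy <- function(accuracies) {
  m <- mean(accuracies)
  list(mean = m, display = round(m))
}
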
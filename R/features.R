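# Feature assembly and patient-grouped splitting for the
# usable-blastocyst classifier.

MECHANICAL_FEATURES <- c("k0", "k1", "eta0", "eta1", "tau")
MATERNAL_FEATURES <- c("patient_age", "mii_count")

#' Collect per-oocyte fits into a data frame
#'
#' @param fits Named list of [zener_params()] keyed by oocyte id.
#' @return `data.frame` with one row per oocyte: parameters, `tau`, `sse`,
#'   `converged`.
#' @export
fits_table <- function(fits) {
  stopifnot(is.list(fits), !is.null(names(fits)))
  do.call(rbind, lapply(names(fits), function(id) {
    f <- fits[[id]]
    data.frame(oocyte_id = id, k0 = f$k0, k1 = f$k1, eta0 = f$eta0,
               eta1 = f$eta1, tau = f$tau, sse = f$sse,
               converged = isTRUE(f$converged), stringsAsFactors = FALSE)
  }))
}

#' Assemble the classifier feature table
#'
#' Joins fitted mechanics onto the cohort, keeps measured oocytes with a
#' converged fit (others are excluded with a logged reason, mirroring
#' exclusion for poor video quality), optionally restricts to fertilized
#' oocytes, log2-transforms every feature and standardizes to zero mean and
#' unit variance. Standardization parameters are learned on training rows
#' only when a split is supplied, and applied to all rows; zero-variance
#' columns are dropped with a warning.
#'
#' @param cohort A `cohort_table`.
#' @param fits `data.frame` from [fits_table()], or a named list of
#'   [zener_params()].
#' @param feature_set One of `"mechanical"` (k0, k1, eta0, eta1, tau),
#'   `"maternal"` (patient age, MII count) or `"mixed"` (both).
#' @param fertilized_only Keep only fertilized oocytes.
#' @param split Optional [split_by_patient()] result; standardization is
#'   then fit on its training rows only.
#' @return `data.frame` of class `feature_table` with standardized feature
#'   columns, `oocyte_id`, `patient_id` and logical `label`
#'   (usable blastocyst); attributes `transform` (centers/scales),
#'   `feature_set` and `exclusions`.
#' @export
assemble_features <- function(cohort, fits,
                              feature_set = c("mechanical", "maternal", "mixed"),
                              fertilized_only = FALSE, split = NULL) {
  feature_set <- match.arg(feature_set)
  stopifnot(inherits(cohort, "cohort_table") || is.data.frame(cohort))
  if (is.list(fits) && !is.data.frame(fits)) fits <- fits_table(fits)

  meas <- cohort[cohort$arm == "measured", , drop = FALSE]
  df <- merge(meas, fits, by = "oocyte_id", all.x = TRUE, sort = FALSE)
  excl <- character(0)
  bad <- is.na(df$k0) | !df$converged
  if (any(bad)) {
    excl <- df$oocyte_id[bad]
    df <- df[!bad, , drop = FALSE]
  }
  if (fertilized_only) df <- df[df$fertilized, , drop = FALSE]

  cols <- switch(feature_set,
                 mechanical = MECHANICAL_FEATURES,
                 maternal = MATERNAL_FEATURES,
                 mixed = c(MECHANICAL_FEATURES, MATERNAL_FEATURES))
  X <- df[, cols, drop = FALSE]
  if (anyNA(X)) {
    stop_oomech("missing feature values after assembly", "oomech_data_error")
  }
  nonpos <- vapply(X, function(v) any(v <= 0), logical(1))
  if (any(nonpos)) {
    bad_row <- df$oocyte_id[which(X[[which(nonpos)[1]]] <= 0)[1]]
    stop_oomech(sprintf("non-positive feature before log2 (oocyte %s)", bad_row),
                "oomech_data_error")
  }
  X <- log2(X)

  train_rows <- if (is.null(split)) rep(TRUE, nrow(X)) else
    df$patient_id %in% split$train_patients
  ctr <- vapply(X[train_rows, , drop = FALSE], mean, numeric(1))
  scl <- vapply(X[train_rows, , drop = FALSE], stats::sd, numeric(1))
  drop_cols <- !is.finite(scl) | scl < 1e-12
  if (any(drop_cols)) {
    warning(sprintf("dropping zero-variance feature(s): %s",
                    paste(names(X)[drop_cols], collapse = ", ")))
    X <- X[, !drop_cols, drop = FALSE]
    ctr <- ctr[!drop_cols]; scl <- scl[!drop_cols]
  }
  X <- as.data.frame(scale(X, center = ctr, scale = scl))

  out <- cbind(
    data.frame(oocyte_id = df$oocyte_id, patient_id = df$patient_id,
               label = df$usable_blastocyst, stringsAsFactors = FALSE),
    X)
  class(out) <- c("feature_table", "data.frame")
  attr(out, "transform") <- list(center = ctr, scale = scl)
  attr(out, "feature_set") <- feature_set
  attr(out, "exclusions") <- excl
  out
}

#' Split a cohort into training and test patients
#'
#' Whole patients are assigned to the training set, in an order randomized
#' by `seed`, until the training oocyte count is as close as possible to
#' `round(train_fraction * n_oocytes)`; the split therefore never separates
#' a patient's oocytes.
#'
#' @param cohort A `cohort_table` or any `data.frame` with `patient_id` and
#'   `oocyte_id` columns (typically already restricted to the oocytes being
#'   modelled).
#' @param train_fraction Target fraction of oocytes in training.
#' @param seed Integer seed.
#' @return List with `train_patients`, `test_patients` and `assignment`
#'   (`data.frame` of `oocyte_id`, `patient_id`, `role`).
#' @export
split_by_patient <- function(cohort, train_fraction = 0.7, seed = 1L) {
  check_probability(train_fraction, "train_fraction")
  patients <- unique(cohort$patient_id)
  if (length(patients) < 2L) {
    stop_oomech("need at least 2 patients to split", "oomech_split_error")
  }
  counts <- table(cohort$patient_id)
  target <- round(train_fraction * nrow(cohort))
  ord <- with_seed(seed, sample(patients))
  cum <- cumsum(as.numeric(counts[ord]))
  # take patients while they bring the train count closer to the target
  k <- which.min(abs(cum - target))
  k <- min(k, length(patients) - 1L)  # keep the test set non-empty
  train <- ord[seq_len(k)]
  test <- setdiff(patients, train)
  list(train_patients = train, test_patients = test,
       assignment = data.frame(
         oocyte_id = cohort$oocyte_id, patient_id = cohort$patient_id,
         role = ifelse(cohort$patient_id %in% train, "train", "test"),
         stringsAsFactors = FALSE))
}

#' Training/test sizes under oocyte-count rounding
#'
#' @param n_oocytes Total number of oocytes.
#' @param train_fraction Fraction assigned to training.
#' @return Named vector `c(train, test)`.
#' @export
#' @examples
#' train_test_sizes(209) # 146 train, 63 test
train_test_sizes <- function(n_oocytes, train_fraction = 0.7) {
  tr <- round(train_fraction * n_oocytes)
  c(train = tr, test = n_oocytes - tr)
}
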
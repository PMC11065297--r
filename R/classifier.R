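# Usable-blastocyst classifier: patient-grouped cross-validated SVM with
# greedy forward feature selection maximizing ROC AUC.

# Assign training patients to CV folds (round-robin over a seeded shuffle)
# so no patient straddles folds.
patient_folds <- function(patient_ids, n_folds = 10L, seed = 1L) {
  patients <- unique(patient_ids)
  n_folds <- min(n_folds, length(patients))
  ord <- with_seed(seed, sample(patients))
  fold_of <- stats::setNames(rep(seq_len(n_folds), length.out = length(ord)), ord)
  unname(fold_of[patient_ids])
}

svm_fit <- function(X, y, cost, gamma) {
  e1071::svm(x = as.matrix(X), y = factor(y, levels = c(FALSE, TRUE)),
             type = "C-classification", kernel = "radial",
             cost = cost, gamma = gamma, scale = FALSE)
}

# Decision values oriented so larger means more likely positive (TRUE).
svm_decision <- function(model, X) {
  pr <- stats::predict(model, as.matrix(X), decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  if (startsWith(colnames(dv)[1], "TRUE")) dv[, 1] else -dv[, 1]
}

auc_score <- function(labels, scores) {
  if (length(unique(labels)) < 2L) return(NA_real_)
  as.numeric(pROC::auc(pROC::roc(
    response = labels, predictor = scores,
    levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)))
}

# Mean held-out-fold AUC and hard-label accuracy for one feature subset
# and hyperparameter pair.
cv_metrics <- function(X, y, folds, cost, gamma) {
  res <- vapply(sort(unique(folds)), function(f) {
    tr <- folds != f
    if (length(unique(y[tr])) < 2L || !any(!tr)) return(c(NA_real_, NA_real_))
    m <- svm_fit(X[tr, , drop = FALSE], y[tr], cost, gamma)
    Xte <- X[!tr, , drop = FALSE]
    c(auc_score(y[!tr], svm_decision(m, Xte)),
      mean(as.logical(stats::predict(m, as.matrix(Xte))) == y[!tr]))
  }, numeric(2))
  c(auc = mean(res[1, ], na.rm = TRUE), acc = mean(res[2, ], na.rm = TRUE))
}

cv_auc <- function(X, y, folds, cost, gamma) {
  unname(cv_metrics(X, y, folds, cost, gamma)["auc"])
}

#' Forward feature selection and SVM training
#'
#' Greedy forward selection on the training rows: at each step the feature
#' whose addition maximizes the mean patient-grouped 10-fold
#' cross-validated AUC is added, with RBF-SVM hyperparameters chosen by
#' grid search inside the same cross-validation; selection stops at the
#' first addition that does not improve the AUC (tolerance 1e-6). The final
#' model is refit on all training rows with the selected features and best
#' hyperparameters. Everything—folds, selection, hyperparameters—depends on
#' training rows only.
#'
#' @param features A [assemble_features()] table.
#' @param split A [split_by_patient()] result.
#' @param seed Integer seed (fold shuffling).
#' @param cost_grid Candidate SVM costs.
#' @param gamma_grid Candidate RBF widths; default is `1/n_features` scaled
#'   by 0.1, 1 and 10.
#' @param n_folds Cross-validation folds (capped at the number of training
#'   patients).
#' @return Object of class `oomech_classifier`: the fitted `e1071::svm`
#'   model, `selected` features, `cost`, `gamma`, `cv_auc`, and a
#'   step-by-step `cv_report`.
#' @export
forward_select_and_train <- function(features, split, seed = 1L,
                                     cost_grid = c(0.1, 1, 10, 100),
                                     gamma_grid = NULL, n_folds = 10L) {
  stopifnot(inherits(features, "feature_table"))
  feat_cols <- setdiff(names(features), c("oocyte_id", "patient_id", "label"))
  tr <- features$patient_id %in% split$train_patients
  X <- features[tr, feat_cols, drop = FALSE]
  y <- features$label[tr]
  if (length(unique(y)) < 2L) {
    stop_oomech("training rows contain a single class", "oomech_training_error")
  }
  if (is.null(gamma_grid)) gamma_grid <- (1 / length(feat_cols)) * c(0.1, 1, 10)
  folds <- patient_folds(features$patient_id[tr], n_folds = n_folds, seed = seed)

  grid <- expand.grid(cost = cost_grid, gamma = gamma_grid)
  best_over_grid <- function(cols) {
    cv <- vapply(seq_len(nrow(grid)), function(i) {
      cv_metrics(X[, cols, drop = FALSE], y, folds, grid$cost[i], grid$gamma[i])
    }, numeric(2))
    # primary criterion is the AUC; ties (common when ranking is easy) are
    # broken by the hard-label CV accuracy so a degenerate majority-class
    # threshold never wins over an equally ranked calibrated one
    top <- which(cv["auc", ] > max(cv["auc", ]) - 1e-9)
    i <- top[which.max(cv["acc", top])]
    list(auc = cv["auc", i], cost = grid$cost[i], gamma = grid$gamma[i])
  }

  selected <- character(0)
  best_auc <- -Inf
  best_hp <- list(cost = 1, gamma = gamma_grid[2])
  report <- list()
  remaining <- feat_cols
  while (length(remaining) > 0L) {
    trial <- lapply(remaining, function(f) best_over_grid(c(selected, f)))
    aucs <- vapply(trial, `[[`, numeric(1), "auc")
    j <- which.max(aucs)
    if (aucs[j] > best_auc + 1e-6) {
      selected <- c(selected, remaining[j])
      best_auc <- aucs[j]
      best_hp <- trial[[j]]
      report[[length(report) + 1L]] <- data.frame(
        step = length(selected), added = remaining[j], cv_auc = best_auc,
        cost = best_hp$cost, gamma = best_hp$gamma)
      remaining <- setdiff(remaining, remaining[j])
    } else break
  }
  if (length(selected) == 0L) {  # no feature beats chance; keep the best single
    j <- which.max(aucs)
    selected <- remaining[j]
    best_auc <- aucs[j]
    best_hp <- trial[[j]]
    report[[1L]] <- data.frame(step = 1L, added = selected, cv_auc = best_auc,
                               cost = best_hp$cost, gamma = best_hp$gamma)
  }

  model <- svm_fit(X[, selected, drop = FALSE], y, best_hp$cost, best_hp$gamma)
  structure(
    list(model = model, selected = selected, cost = best_hp$cost,
         gamma = best_hp$gamma, cv_auc = best_auc,
         cv_report = do.call(rbind, report),
         transform = attr(features, "transform"),
         feature_set = attr(features, "feature_set"), seed = seed),
    class = "oomech_classifier")
}

#' @export
print.oomech_classifier <- function(x, ...) {
  cat(sprintf("Usable-blastocyst SVM (%s features)\n", x$feature_set))
  cat(sprintf("  selected: %s\n", paste(x$selected, collapse = ", ")))
  cat(sprintf("  CV AUC %.3f (cost %g, gamma %g)\n", x$cv_auc, x$cost, x$gamma))
  invisible(x)
}

#' Predict usable-blastocyst labels
#'
#' @param object An `oomech_classifier`.
#' @param features A [assemble_features()] table (standardized with the same
#'   transform as the training table).
#' @param ... Unused.
#' @return Logical vector of predictions.
#' @export
predict.oomech_classifier <- function(object, features, ...) {
  X <- features[, object$selected, drop = FALSE]
  as.logical(stats::predict(object$model, as.matrix(X)))
}

#' Permutation-null cross-validated AUC
#'
#' Calibration check of the cross-validation machinery: labels of the
#' training rows are permuted and the patient-grouped CV AUC recomputed at
#' fixed hyperparameters (no selection, so the null is unbiased). Over many
#' permutations the mean AUC should sit at 0.5 within Monte-Carlo noise.
#'
#' @param features A [assemble_features()] table.
#' @param split A [split_by_patient()] result.
#' @param n_perm Number of label permutations.
#' @param seed Integer seed.
#' @param cost,gamma Fixed SVM hyperparameters.
#' @return Numeric vector of per-permutation mean CV AUCs.
#' @export
permutation_null_auc <- function(features, split, n_perm = 100L, seed = 1L,
                                 cost = 1, gamma = NULL) {
  feat_cols <- setdiff(names(features), c("oocyte_id", "patient_id", "label"))
  if (is.null(gamma)) gamma <- 1 / length(feat_cols)
  tr <- features$patient_id %in% split$train_patients
  X <- features[tr, feat_cols, drop = FALSE]
  y <- features$label[tr]
  folds <- patient_folds(features$patient_id[tr], seed = seed)
  with_seed(seed, vapply(seq_len(n_perm), function(i) {
    cv_auc(X, sample(y), folds, cost, gamma)
  }, numeric(1)))
}

#' Evaluate a classifier on the held-out test patients
#'
#' @param classifier An `oomech_classifier`.
#' @param features The feature table.
#' @param split The [split_by_patient()] result used for training.
#' @return A [confusion_metrics()] object.
#' @export
evaluate_classifier <- function(classifier, features, split) {
  te <- features$patient_id %in% split$test_patients
  if (!any(te)) stop_oomech("test rows are empty", "oomech_invalid_input")
  pred <- predict(classifier, features[te, , drop = FALSE])
  confusion_metrics(pred, features$label[te])
}
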
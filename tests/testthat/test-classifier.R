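# Feature assembly, patient-grouped splitting, forward selection, and
# leakage guarantees.

classifier_fixture <- function(seed = 31, class_effect = 2.0, n_patients = 20) {
  cached(sprintf("cohort_%d_%g_%d", seed, class_effect, n_patients), {
    cfg <- sim_config(seed = seed, class_effect = class_effect,
                      n_patients = n_patients)
    co <- generate_cohort(cfg)
    list(cohort = co, fits = true_fits(co), config = cfg)
  })
}

test_that("feature sets select the documented columns", {
  fx <- classifier_fixture()
  feat_cols <- function(ft) setdiff(names(ft), c("oocyte_id", "patient_id", "label"))
  ft_mat <- assemble_features(fx$cohort, fx$fits, "maternal")
  expect_identical(feat_cols(ft_mat), c("patient_age", "mii_count"))
  ft_mech <- assemble_features(fx$cohort, fx$fits, "mechanical")
  expect_identical(feat_cols(ft_mech), c("k0", "k1", "eta0", "eta1", "tau"))
  ft_mix <- assemble_features(fx$cohort, fx$fits, "mixed")
  expect_length(feat_cols(ft_mix), 7L)
  # fertilized_only filters rows
  ft_f <- assemble_features(fx$cohort, fx$fits, "mechanical",
                            fertilized_only = TRUE)
  expect_lt(nrow(ft_f), nrow(ft_mech))
  expect_equal(nrow(ft_f),
               sum(fx$cohort$arm == "measured" & fx$cohort$fertilized))
})

test_that("standardization is learned on training rows only", {
  fx <- classifier_fixture()
  ft0 <- assemble_features(fx$cohort, fx$fits, "mechanical")
  sp <- split_by_patient(ft0, 0.7, seed = 2)
  ft <- assemble_features(fx$cohort, fx$fits, "mechanical", split = sp)
  tr <- ft$patient_id %in% sp$train_patients
  for (cl in c("k0", "k1", "eta0")) {
    expect_equal(mean(ft[[cl]][tr]), 0, tolerance = 1e-10)
    expect_equal(stats::sd(ft[[cl]][tr]), 1, tolerance = 1e-10)
  }
  # test rows are standardized with the training parameters, so in general
  # they are not exactly centred
  expect_false(isTRUE(all.equal(mean(ft$k0[!tr]), 0, tolerance = 1e-6)))
})

test_that("zero-variance features are dropped with a warning", {
  fx <- classifier_fixture()
  co <- fx$cohort
  co$patient_age <- 30L  # constant maternal feature
  expect_warning(ft <- assemble_features(co, fx$fits, "maternal"),
                 "zero-variance")
  expect_identical(setdiff(names(ft), c("oocyte_id", "patient_id", "label")),
                   "mii_count")
})

test_that("patient splits are disjoint and hit the oocyte-count target", {
  co <- data.frame(
    patient_id = rep(sprintf("P%02d", 1:10), each = 10),
    oocyte_id = sprintf("O%03d", 1:100))
  for (seed in 1:5) {
    sp <- split_by_patient(co, 0.7, seed = seed)
    expect_length(intersect(sp$train_patients, sp$test_patients), 0L)
    expect_equal(sum(sp$assignment$role == "train"), 70L)
    expect_length(sp$train_patients, 7L)
  }
  expect_error(split_by_patient(co[co$patient_id == "P01", ], 0.7, 1),
               class = "oomech_split_error")
})

test_that("oocyte-count rounding reproduces the canonical split sizes", {
  expect_equal(unname(train_test_sizes(209)), c(146, 63))
  expect_equal(unname(train_test_sizes(160)), c(112, 48))
})

test_that("forward selection finds a perfectly separating feature first", {
  ft <- separable_feature_table()
  sp <- split_by_patient(ft, 0.7, seed = 1)
  clf <- forward_select_and_train(ft, sp, seed = 1,
                                  cost_grid = c(1, 10), n_folds = 5)
  expect_identical(clf$selected[1], "good")
  expect_gt(clf$cv_auc, 0.95)
  m <- evaluate_classifier(clf, ft, sp)
  expect_gt(m$acc, 90)
})

test_that("selection on mechanical features stays within the mechanical set", {
  fx <- classifier_fixture()
  ft0 <- assemble_features(fx$cohort, fx$fits, "mechanical",
                           fertilized_only = TRUE)
  sp <- split_by_patient(ft0, 0.7, seed = 31)
  ft <- assemble_features(fx$cohort, fx$fits, "mechanical",
                          fertilized_only = TRUE, split = sp)
  clf <- forward_select_and_train(ft, sp, seed = 31,
                                  cost_grid = c(1, 10), n_folds = 5)
  expect_true(all(clf$selected %in% c("k0", "k1", "eta0", "eta1", "tau")))
  expect_gte(evaluate_classifier(clf, ft, sp)$acc, 90)
})

test_that("training artifacts never depend on test rows", {
  ft <- separable_feature_table()
  sp <- split_by_patient(ft, 0.7, seed = 3)
  clf1 <- forward_select_and_train(ft, sp, seed = 3,
                                   cost_grid = c(1, 10), n_folds = 5)
  ft_flip <- ft
  te <- ft_flip$patient_id %in% sp$test_patients
  ft_flip$label[te] <- !ft_flip$label[te]
  clf2 <- forward_select_and_train(ft_flip, sp, seed = 3,
                                   cost_grid = c(1, 10), n_folds = 5)
  expect_identical(clf1$selected, clf2$selected)
  expect_identical(clf1$cost, clf2$cost)
  expect_identical(clf1$gamma, clf2$gamma)
  expect_equal(clf1$cv_auc, clf2$cv_auc)
  expect_identical(predict(clf1, ft), predict(clf2, ft))
})

test_that("no patient straddles cross-validation folds", {
  pid <- rep(sprintf("P%02d", 1:15), times = sample(3:8, 15, replace = TRUE))
  folds <- oomech:::patient_folds(pid, n_folds = 10, seed = 4)
  per_patient <- tapply(folds, pid, function(x) length(unique(x)))
  expect_true(all(per_patient == 1))
})

test_that("label permutation yields chance-level cross-validated AUC", {
  ft <- separable_feature_table()
  sp <- split_by_patient(ft, 0.7, seed = 5)
  aucs <- permutation_null_auc(ft, sp, n_perm = 30, seed = 5)
  se <- stats::sd(aucs) / sqrt(length(aucs))
  expect_lt(abs(mean(aucs) - 0.5), 0.5 * 0.1 + 3 * se)
})

test_that("single-class training data is a training error", {
  ft <- separable_feature_table()
  ft$label <- TRUE
  sp <- split_by_patient(ft, 0.7, seed = 1)
  expect_error(forward_select_and_train(ft, sp, seed = 1),
               class = "oomech_training_error")
})
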
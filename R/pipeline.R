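# End-to-end orchestration: simulate -> (render/track) -> fit -> classify
# -> safety, with a run manifest for reproducibility bookkeeping.

#' Fit the Zener model to every curve, logging exclusions
#'
#' Tracking or fitting failures become logged exclusions rather than
#' errors, mirroring how unanalysable recordings are excluded for poor
#' video quality.
#'
#' @param curves Named list of [aspiration_curve()]s.
#' @param F0 Applied force in newtons.
#' @return List with `fits` (named list of [zener_params()]) and
#'   `exclusions` (`data.frame` of oocyte id and reason).
#' @export
fit_cohort_curves <- function(curves, F0) {
  fits <- list()
  excl <- list()
  for (id in names(curves)) {
    res <- tryCatch(fit_zener(curves[[id]], F0),
                    oomech_error = function(e) conditionMessage(e))
    if (inherits(res, "zener_params")) fits[[id]] <- res
    else excl[[id]] <- res
  }
  list(fits = fits,
       exclusions = data.frame(
         oocyte_id = names(excl),
         reason = unlist(excl, use.names = FALSE),
         stringsAsFactors = FALSE))
}

#' Run the full synthetic pipeline
#'
#' Generates a cohort, obtains an aspiration curve per measured oocyte
#' (directly from the generator, or by rendering and re-tracking frame
#' stacks when `use_rendered_video = TRUE`), fits the Zener model, trains
#' and evaluates the usable-blastocyst classifier for each requested
#' feature set, runs the safety comparison, and returns everything with a
#' manifest (config hash, seeds, per-stage counts and exclusions). Rerun
#' with the same config reproduces all outputs.
#'
#' @param config A [sim_config()].
#' @param feature_sets Feature sets to train.
#' @param fertilized_only Restrict the classifier to fertilized oocytes.
#' @param use_rendered_video Route curves through the renderer and tracker
#'   (slower; exercises the full video chain).
#' @param train_fraction Oocyte fraction in the training split.
#' @param out_dir Optional directory to write CSV/JSON artifacts to.
#' @return List of class `oomech_run`: `cohort`, `fits`, `metrics` (one
#'   [confusion_metrics()] per feature set), `classifiers`, `safety`,
#'   `manifest`.
#' @export
run_pipeline <- function(config = sim_config(),
                         feature_sets = c("mechanical", "maternal", "mixed"),
                         fertilized_only = FALSE,
                         use_rendered_video = FALSE,
                         train_fraction = 0.7, out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  cohort <- generate_cohort(config)
  F0 <- applied_force(config$suction, config$pipette_inner_diameter)

  curves <- generate_cohort_curves(cohort, config)
  if (use_rendered_video) {
    ids <- names(curves)
    curves <- lapply(seq_along(curves), function(i) {
      stack <- render_frame_stack(curves[[i]], seed = config$seed + 10000L + i)
      track_stack(stack,
                  pipette_inner_diameter_um = config$pipette_inner_diameter)
    })
    names(curves) <- ids
  }

  fitres <- fit_cohort_curves(curves, F0)

  metrics <- list(); classifiers <- list()
  ft0 <- assemble_features(cohort, fitres$fits, "mixed",
                           fertilized_only = fertilized_only)
  split <- split_by_patient(ft0, train_fraction = train_fraction,
                            seed = config$seed)
  for (fs in feature_sets) {
    ft <- assemble_features(cohort, fitres$fits, fs,
                            fertilized_only = fertilized_only, split = split)
    clf <- forward_select_and_train(ft, split, seed = config$seed)
    metrics[[fs]] <- evaluate_classifier(clf, ft, split)
    classifiers[[fs]] <- clf
  }

  safety <- safety_analysis(cohort)

  n_measured <- sum(cohort$arm == "measured")
  manifest <- list(
    package_version = as.character(utils::packageVersion("oomech")),
    seed = config$seed,
    config_hash = rlang::hash(config),
    n_patients = config$n_patients,
    n_oocytes = nrow(cohort),
    n_measured = n_measured,
    n_control = sum(cohort$arm == "control"),
    n_fitted = length(fitres$fits),
    n_excluded = nrow(fitres$exclusions),
    exclusions = fitres$exclusions,
    counts_reconcile = n_measured == length(fitres$fits) +
      nrow(fitres$exclusions),
    train_patients = length(split$train_patients),
    test_patients = length(split$test_patients),
    fertilized_only = fertilized_only,
    use_rendered_video = use_rendered_video)

  run <- structure(
    list(cohort = cohort, curves = curves, fits = fitres$fits,
         split = split, classifiers = classifiers, metrics = metrics,
         safety = safety, manifest = manifest),
    class = "oomech_run")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_cohort_csv(cohort, file.path(out_dir, "cohort.csv"))
    write_curves_csv(curves, file.path(out_dir, "curves.csv"))
    ftab <- fits_table(fitres$fits)
    ftab$F0 <- F0
    utils::write.csv(ftab, file.path(out_dir, "fits.csv"), row.names = FALSE)
    utils::write.csv(safety, file.path(out_dir, "safety.csv"),
                     row.names = FALSE)
    mtab <- do.call(rbind, lapply(names(metrics), function(nm) {
      cbind(feature_set = nm, as.data.frame(metrics[[nm]]))
    }))
    utils::write.csv(mtab, file.path(out_dir, "metrics.csv"),
                     row.names = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  run
}

#' @export
print.oomech_run <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("Pipeline run (seed %d, config %s)\n", m$seed, m$config_hash))
  cat(sprintf("  %d oocytes from %d patients; %d measured (%d fitted, %d excluded)\n",
              m$n_oocytes, m$n_patients, m$n_measured, m$n_fitted, m$n_excluded))
  for (nm in names(x$metrics)) {
    cat(sprintf("  %s features: ACC %.0f%%\n", nm, x$metrics[[nm]]$acc))
  }
  cat(sprintf("  safety p-values: %s\n",
              paste(sprintf("%s=%.3f", x$safety$outcome, x$safety$p_value),
                    collapse = ", ")))
  invisible(x)
}
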
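# Shared fixture builders. Heavy objects are memoised per session so the
# classifier tests do not regenerate cohorts repeatedly.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, .fixture_cache)) assign(key, force(expr), .fixture_cache)
  get(key, .fixture_cache)
}

F0_DEFAULT <- applied_force(0.1, 50)

ref_params <- function() zener_params(0.2, 0.1, 0.01, 0.5)

# "Fits" taken directly from the cohort's ground-truth parameters; exercises
# classifier logic without paying for per-curve optimisation.
true_fits <- function(cohort) {
  meas <- cohort[cohort$arm == "measured", ]
  fits <- lapply(seq_len(nrow(meas)), function(i) {
    zener_params(meas$true_k0[i], meas$true_k1[i], meas$true_eta0[i],
                 meas$true_eta1[i], sse = 0, converged = TRUE)
  })
  names(fits) <- meas$oocyte_id
  fits
}

# A feature table built by hand: one feature separates the classes, the
# rest are noise. 20 patients x 6 oocytes.
separable_feature_table <- function(seed = 7) {
  set.seed(seed)
  n_pat <- 20L
  df <- do.call(rbind, lapply(seq_len(n_pat), function(i) {
    n <- 6L
    lab <- stats::runif(n) < 0.5
    data.frame(
      oocyte_id = sprintf("P%02d-O%d", i, seq_len(n)),
      patient_id = sprintf("P%02d", i),
      label = lab,
      good = ifelse(lab, 2, -2) + stats::rnorm(n, 0, 0.3),
      noise1 = stats::rnorm(n), noise2 = stats::rnorm(n),
      stringsAsFactors = FALSE)
  }))
  class(df) <- c("feature_table", "data.frame")
  attr(df, "feature_set") <- "mechanical"
  attr(df, "transform") <- list(center = c(good = 0, noise1 = 0, noise2 = 0),
                                scale = c(good = 1, noise1 = 1, noise2 = 1))
  df
}

# Fixed 12-subject x 4-rater table with its longhand Fleiss' kappa
# (computed independently from the agreement/marginal definitions).
kappa_fixture <- function() {
  m <- matrix(c(1, 1, 1, 1,
                1, 1, 1, 0,
                0, 0, 0, 0,
                1, 0, 1, 0,
                0, 0, 1, 0,
                1, 1, 0, 1,
                0, 1, 0, 0,
                1, 1, 1, 1,
                0, 0, 0, 1,
                1, 0, 0, 0,
                0, 1, 1, 1,
                0, 0, 0, 0), ncol = 4, byrow = TRUE)
  list(ratings = m, kappa = 0.3043478260869565,
       p_bar = 0.6527777777777778, p_e = 0.5008680555555556)
}
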
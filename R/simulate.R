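# Synthetic-data generator: creep curves, pressure traces and
# patient-structured outcome cohorts with known ground truth.

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulation configuration
#'
#' Bundles every knob of the synthetic cohort generator. Defaults mirror the
#' measurement set-up the pipeline is built for: a ~110 um human oocyte
#' aspirated into a 50 um inner-diameter pipette at 0.1 p.s.i. suction,
#' recorded at 70 frames per second and analysed over a 0.5 s window, in a
#' cohort of 22 patients each contributing at least 10 mature (MII) oocytes
#' of which about half are measured.
#'
#' @param seed Integer seed; every draw is reproducible from it.
#' @param n_patients Number of patients.
#' @param oocytes_per_patient Single count or inclusive range `c(lo, hi)` of
#'   oocytes retrieved per patient (also the patient's MII count).
#' @param frame_rate Camera frame rate in Hz.
#' @param window Analysis window in seconds.
#' @param suction Suction magnitude in p.s.i.
#' @param pipette_inner_diameter Pipette inner diameter in micrometers.
#' @param noise_sd Additive Gaussian depth noise, micrometers (sub-pixel
#'   tracking error scale).
#' @param class_effect Multiplicative shift applied to the mechanical
#'   parameters of the unusable class relative to the usable class; 1 means
#'   no signal.
#' @param usable_fraction Probability that an oocyte carries the
#'   usable-class mechanics.
#' @param fert_rate Fertilization probability, independent of mechanics by
#'   default (fertilization depends on sperm and injection factors the
#'   mechanics cannot see).
#' @param day3_rate P(grade-A day-3 embryo | fertilized).
#' @param blast_bg_rate P(blastocyst | fertilized, unusable class); the
#'   usable class always reaches blastocyst when fertilized so that the
#'   usable => blastocyst => fertilized label hierarchy holds.
#' @param fert_depends_on_class If `TRUE`, fertilization probability is also
#'   shifted by class (off by default).
#' @param param_medians Named medians of the log-normal parameter priors, SI
#'   units, for the usable class.
#' @param param_sdlog Log-scale standard deviation of the parameter priors.
#' @param clinic_id Clinic label stamped on every record.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_patients = 22L,
                       oocytes_per_patient = c(16L, 28L),
                       frame_rate = 70, window = 0.5, suction = 0.1,
                       pipette_inner_diameter = 50, noise_sd = 0.2,
                       class_effect = 1.5, usable_fraction = 0.4,
                       fert_rate = 0.766, day3_rate = 0.5,
                       blast_bg_rate = 0.35, fert_depends_on_class = FALSE,
                       param_medians = c(k0 = 0.2, k1 = 0.1,
                                         eta0 = 0.01, eta1 = 0.5),
                       param_sdlog = 0.25, clinic_id = "A") {
  if (n_patients < 1L) stop_oomech("n_patients must be >= 1", "oomech_invalid_input")
  rng <- range(oocytes_per_patient)
  if (rng[1] < 1L) stop_oomech("oocytes_per_patient must be >= 1", "oomech_invalid_input")
  check_positive(frame_rate, "frame_rate")
  check_positive(window, "window")
  check_positive(suction, "suction")
  check_positive(pipette_inner_diameter, "pipette_inner_diameter")
  if (noise_sd < 0) stop_oomech("noise_sd must be >= 0", "oomech_invalid_input")
  check_positive(class_effect, "class_effect")
  check_probability(usable_fraction, "usable_fraction")
  check_probability(fert_rate, "fert_rate")
  check_probability(day3_rate, "day3_rate")
  check_probability(blast_bg_rate, "blast_bg_rate")
  stopifnot(all(c("k0", "k1", "eta0", "eta1") %in% names(param_medians)))
  structure(
    list(seed = as.integer(seed), n_patients = as.integer(n_patients),
         oocytes_per_patient = as.integer(round(rng)),
         frame_rate = frame_rate, window = window, suction = suction,
         pipette_inner_diameter = pipette_inner_diameter,
         noise_sd = noise_sd, class_effect = class_effect,
         usable_fraction = usable_fraction, fert_rate = fert_rate,
         day3_rate = day3_rate, blast_bg_rate = blast_bg_rate,
         fert_depends_on_class = isTRUE(fert_depends_on_class),
         param_medians = param_medians, param_sdlog = param_sdlog,
         clinic_id = clinic_id),
    class = "sim_config"
  )
}

#' Simulate one aspiration curve from known Zener parameters
#'
#' Evaluates the creep model on the camera time grid
#' `t = k / frame_rate, k = 0 .. floor(window * frame_rate)` (t = 0 is the
#' first frame after suction onset, carrying the instantaneous elastic jump)
#' and adds independent Gaussian measurement noise per sample.
#'
#' @param params Ground-truth [zener_params()].
#' @param force Applied force in newtons.
#' @param frame_rate Frames per second.
#' @param window Clip length in seconds.
#' @param noise_sd Gaussian noise standard deviation in micrometers.
#' @param seed Optional seed; identical seeds give identical curves.
#' @return An [aspiration_curve()].
#' @export
generate_curve <- function(params, force, frame_rate = 70, window = 0.5,
                           noise_sd = 0.2, seed = NULL) {
  stopifnot(inherits(params, "zener_params"))
  check_positive(force, "force")
  check_positive(frame_rate, "frame_rate")
  check_positive(window, "window")
  if (noise_sd < 0) stop_oomech("noise_sd must be >= 0", "oomech_invalid_input")
  times <- (0:floor(window * frame_rate)) / frame_rate
  depths <- zener_depth(times, params, force)
  noise <- with_seed(seed, stats::rnorm(length(times), 0, noise_sd))
  if (noise_sd == 0) noise <- 0
  aspiration_curve(times, pmax(depths + noise, 0), frame_rate = frame_rate)
}

#' Simulate a suction pressure log
#'
#' A trace at the balance pressure before suction onset, stepping to
#' `balance - suction` for the measurement, with small sensor noise.
#'
#' @param suction Suction magnitude in p.s.i.
#' @param duration Total log length in seconds.
#' @param onset Suction onset time in seconds.
#' @param balance Balance pressure in p.s.i.
#' @param sample_rate Logger rate in Hz.
#' @param noise_sd Sensor noise in p.s.i.
#' @param seed Optional seed.
#' @return A [pressure_trace()].
#' @export
generate_pressure_trace <- function(suction = 0.1, duration = 2, onset = 0.25,
                                    balance = 0, sample_rate = 70,
                                    noise_sd = 0.001, seed = NULL) {
  check_positive(suction, "suction")
  times <- seq(0, duration, by = 1 / sample_rate)
  p <- ifelse(times >= onset, balance - suction, balance)
  p <- p + with_seed(seed, stats::rnorm(length(p), 0, noise_sd))
  # keep the suction window unambiguous despite sensor noise
  p[times >= onset] <- pmin(p[times >= onset], balance - suction / 2)
  pressure_trace(times, p, balance_pressure = balance)
}

draw_params <- function(n, medians, sdlog, shift = 1) {
  m <- vapply(c("k0", "k1", "eta0", "eta1"), function(nm) {
    stats::rlnorm(n, meanlog = log(medians[[nm]] * shift), sdlog = sdlog)
  }, numeric(n))
  if (n == 1L) m <- matrix(m, nrow = 1, dimnames = list(NULL, c("k0", "k1", "eta0", "eta1")))
  m
}

#' Simulate a patient-structured outcome cohort
#'
#' Generates one record per oocyte: patient membership, measured/control arm
#' (about half of each patient's oocytes are measured), maternal factors
#' (age uniform on 21-45 years; MII count equal to the number of retrieved
#' oocytes, at least 10), ground-truth Zener parameters for measured oocytes
#' drawn log-normally with a class-dependent location, and the outcome
#' cascade. Fertilization is drawn independently of the mechanics by
#' default; a usable-class oocyte that fertilizes always forms a blastocyst
#' and is labelled usable, so the label hierarchy
#' usable => blastocyst => fertilized holds by construction.
#'
#' @param config A [sim_config()].
#' @return A `data.frame` of class `cohort_table` with one row per oocyte
#'   and columns `patient_id`, `clinic_id`, `oocyte_id`, `arm`,
#'   `patient_age`, `mii_count`, `fertilized`, `day3_grade_a`, `blastocyst`,
#'   `usable_blastocyst`, `latent_usable` and `true_k0` .. `true_tau`
#'   (`NA` on control rows).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    rng <- config$oocytes_per_patient
    n_oo <- if (rng[1] == rng[2]) rep(rng[1], config$n_patients) else
      sample(rng[1]:rng[2], config$n_patients, replace = TRUE)
    ages <- sample(21:45, config$n_patients, replace = TRUE)

    rows <- lapply(seq_len(config$n_patients), function(i) {
      n <- n_oo[i]
      pid <- sprintf("P%03d", i)
      measured <- rep("control", n)
      measured[sample.int(n, n %/% 2)] <- "measured"
      data.frame(
        patient_id = pid, clinic_id = config$clinic_id,
        oocyte_id = sprintf("%s-O%03d", pid, seq_len(n)),
        arm = measured, patient_age = ages[i], mii_count = n,
        stringsAsFactors = FALSE)
    })
    co <- do.call(rbind, rows)
    n <- nrow(co)

    co$latent_usable <- stats::runif(n) < config$usable_fraction
    fert_p <- rep(config$fert_rate, n)
    if (config$fert_depends_on_class) {
      fert_p <- ifelse(co$latent_usable, pmin(1, fert_p * 1.25), fert_p * 0.75)
    }
    co$fertilized <- stats::runif(n) < fert_p
    co$day3_grade_a <- co$fertilized & (stats::runif(n) < config$day3_rate)
    co$blastocyst <- co$fertilized &
      (co$latent_usable | stats::runif(n) < config$blast_bg_rate)
    co$usable_blastocyst <- co$fertilized & co$latent_usable

    # ground-truth mechanics for measured oocytes; the unusable class is
    # shifted multiplicatively by class_effect
    pm <- matrix(NA_real_, n, 4, dimnames = list(NULL, c("k0", "k1", "eta0", "eta1")))
    meas <- co$arm == "measured"
    shift <- ifelse(co$latent_usable[meas], 1, config$class_effect)
    base <- draw_params(sum(meas), config$param_medians, config$param_sdlog)
    pm[meas, ] <- base * shift
    co$true_k0 <- pm[, "k0"]; co$true_k1 <- pm[, "k1"]
    co$true_eta0 <- pm[, "eta0"]; co$true_eta1 <- pm[, "eta1"]
    co$true_tau <- co$true_eta0 * (co$true_k0 + co$true_k1) /
      (co$true_k0 * co$true_k1)

    class(co) <- c("cohort_table", "data.frame")
    attr(co, "config") <- config
    co
  })
}

#' Simulate aspiration curves for the measured oocytes of a cohort
#'
#' @param cohort A [generate_cohort()] table.
#' @param config The [sim_config()] used to generate it.
#' @return Named list of [aspiration_curve()]s keyed by oocyte id.
#' @export
generate_cohort_curves <- function(cohort, config = attr(cohort, "config")) {
  stopifnot(inherits(cohort, "cohort_table"), inherits(config, "sim_config"))
  F0 <- applied_force(config$suction, config$pipette_inner_diameter)
  meas <- cohort[cohort$arm == "measured", ]
  curves <- lapply(seq_len(nrow(meas)), function(i) {
    p <- zener_params(meas$true_k0[i], meas$true_k1[i],
                      meas$true_eta0[i], meas$true_eta1[i])
    generate_curve(p, F0, frame_rate = config$frame_rate,
                   window = config$window, noise_sd = config$noise_sd,
                   seed = config$seed + i)
  })
  names(curves) <- meas$oocyte_id
  curves
}

#' Write / read cohort tables as CSV
#'
#' Logical outcome columns are stored as `yes`/`no`. The schema is this
#' package's own (no public per-oocyte schema exists for such studies) and
#' is documented in [generate_cohort()].
#'
#' @param cohort A `cohort_table`.
#' @param path CSV file path.
#' @export
write_cohort_csv <- function(cohort, path) {
  out <- as.data.frame(cohort)
  for (cl in c("fertilized", "day3_grade_a", "blastocyst",
               "usable_blastocyst", "latent_usable")) {
    if (cl %in% names(out)) out[[cl]] <- ifelse(out[[cl]], "yes", "no")
  }
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  co <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (cl in c("fertilized", "day3_grade_a", "blastocyst",
               "usable_blastocyst", "latent_usable")) {
    if (cl %in% names(co)) co[[cl]] <- co[[cl]] == "yes"
  }
  class(co) <- c("cohort_table", "data.frame")
  co
}
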
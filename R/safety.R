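# Safety comparison of measured vs control oocytes: 2x2 contingency
# tables and Pearson chi-square tests for fertilization, good day-3 and
# blastocyst formation rates.

#' Build a measured-vs-control contingency table
#'
#' Rows are the study arms (measured, control), columns the outcome
#' (yes, no). Fertilization is always counted out of all oocytes; day-3 and
#' blastocyst outcomes default to fertilized oocytes as the denominator
#' (both conventions are available via `denominator`).
#'
#' @param cohort A `cohort_table`.
#' @param outcome One of `"fertilized"`, `"day3_grade_a"`, `"blastocyst"`.
#' @param clinic Clinic label to restrict to, or `"all"`.
#' @param denominator `"fertilized"` (default for embryo outcomes) or
#'   `"all"`.
#' @return 2x2 integer matrix of class `contingency_table` with attributes
#'   `outcome`, `clinic`, `denominator`.
#' @export
build_table <- function(cohort,
                        outcome = c("fertilized", "day3_grade_a", "blastocyst"),
                        clinic = "all", denominator = NULL) {
  outcome <- match.arg(outcome)
  if (!identical(clinic, "all")) {
    cohort <- cohort[cohort$clinic_id == clinic, , drop = FALSE]
  }
  if (is.null(denominator)) {
    denominator <- if (outcome == "fertilized") "all" else "fertilized"
  }
  denominator <- match.arg(denominator, c("all", "fertilized"))
  if (denominator == "fertilized" && outcome != "fertilized") {
    cohort <- cohort[cohort$fertilized, , drop = FALSE]
  }
  arms <- c("measured", "control")
  if (!all(arms %in% cohort$arm)) {
    stop_oomech("cohort must contain both a measured and a control arm",
                "oomech_construction_error")
  }
  y <- cohort[[outcome]]
  tab <- rbind(
    measured = c(yes = sum(y[cohort$arm == "measured"]),
                 no = sum(!y[cohort$arm == "measured"])),
    control = c(yes = sum(y[cohort$arm == "control"]),
                no = sum(!y[cohort$arm == "control"])))
  structure(tab, class = c("contingency_table", class(tab)),
            outcome = outcome, clinic = clinic, denominator = denominator)
}

#' Pearson chi-square test on a 2x2 table
#'
#' @param table 2x2 count matrix (e.g. from [build_table()]).
#' @param continuity_correction Apply the Yates continuity correction
#'   (off by default; recorded in the result).
#' @return List with `statistic`, `p_value`, `df`, `continuity_correction`.
#' @export
#' @examples
#' chi_square(matrix(c(30, 10, 10, 30), 2, byrow = TRUE)) # statistic 20
chi_square <- function(table, continuity_correction = FALSE) {
  m <- unclass(as.matrix(table))
  if (!all(dim(m) == c(2L, 2L)) || any(m < 0)) {
    stop_oomech("need a 2x2 table of non-negative counts", "oomech_invalid_input")
  }
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stop_oomech("zero marginal total; chi-square test undefined",
                "oomech_test_error")
  }
  ht <- suppressWarnings(
    stats::chisq.test(m, correct = continuity_correction))
  list(statistic = unname(ht$statistic), p_value = unname(ht$p.value),
       df = unname(ht$parameter),
       continuity_correction = continuity_correction)
}

#' Run the full safety comparison
#'
#' One chi-square row per outcome; the fertilization test uses all oocytes,
#' the embryo-development tests use the configured denominator.
#'
#' @inheritParams build_table
#' @param outcomes Outcomes to test.
#' @param continuity_correction Passed to [chi_square()].
#' @return `data.frame` with outcome, per-arm counts and rates, statistic,
#'   p-value and the denominator convention used.
#' @export
safety_analysis <- function(cohort, clinic = "all",
                            outcomes = c("fertilized", "day3_grade_a",
                                         "blastocyst"),
                            denominator = NULL,
                            continuity_correction = FALSE) {
  rows <- lapply(outcomes, function(oc) {
    tab <- build_table(cohort, oc, clinic = clinic, denominator = denominator)
    ht <- chi_square(tab, continuity_correction)
    data.frame(
      outcome = oc, clinic = clinic,
      measured_yes = tab["measured", "yes"],
      measured_n = sum(tab["measured", ]),
      control_yes = tab["control", "yes"],
      control_n = sum(tab["control", ]),
      measured_rate = tab["measured", "yes"] / sum(tab["measured", ]),
      control_rate = tab["control", "yes"] / sum(tab["control", ]),
      statistic = ht$statistic, p_value = ht$p_value,
      denominator = attr(tab, "denominator"),
      continuity_correction = continuity_correction,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
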
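#' Synthetic cohort configuration
#'
#' Defaults emulate the design of a 21-patient retrospective methotrexate
#' cohort: 7 good and 14 poor responders, monthly visits over months 0-12,
#' baseline DAS28-CRP drawn near 4.0 and truncated to the observed 2.31-6.66
#' range, constant weekly doses from {6, 8, 10} mg/week (0-3-month
#' cumulative doses of 72-120 mg), and per-SNP carrier-group frequencies
#' matching the reported genotype margins out of 21.
#'
#' @param n_patients Cohort size.
#' @param n_good Number of good responders; `0 < n_good < n_patients`.
#' @param visit_times Months of scheduled visits, sorted, starting at 0.
#' @param baseline_das28_mean,baseline_das28_sd Baseline DAS28 distribution
#'   (truncated to `baseline_das28_range`).
#' @param baseline_das28_range Truncation bounds for the baseline draw.
#' @param good_decline_rate,poor_decline_rate Expected DAS28 decline per
#'   month for each responder group, both `>= 0`.
#' @param measurement_noise_sd Per-visit Gaussian noise on the DAS28 target,
#'   in score units.
#' @param weekly_dose_levels Candidate constant weekly doses (mg/week).
#' @param genotype_group_probabilities Named per-SNP probability of the
#'   comparison (variant-carrier-defined) group; names as in
#'   [snp_groupings()].
#' @param genotype_effect_on_R Multiplier applied to the decline rate of
#'   carriers of the RFC1 comparison group; 1 means no genotype effect (the
#'   null used for type-I-error studies).
#' @param seed Integer seed; all cohort randomness flows from it.
#'
#' @return A validated `cohort_config` list.
#' @export
cohort_config <- function(n_patients = 21L,
                          n_good = 7L,
                          visit_times = 0:12,
                          baseline_das28_mean = 4.0,
                          baseline_das28_sd = 1.0,
                          baseline_das28_range = c(2.31, 6.66),
                          good_decline_rate = 0.5,
                          poor_decline_rate = 0.15,
                          measurement_noise_sd = 0.3,
                          weekly_dose_levels = c(6, 8, 10),
                          genotype_group_probabilities = c(
                            rfc1_80 = 15 / 21, fpgs_1994 = 4 / 21,
                            ggh_401 = 10 / 21, mthfr_1298 = 2 / 21,
                            tyms_utr = 13 / 21),
                          genotype_effect_on_R = 1,
                          seed = 1L) {
  cfg <- list(n_patients = as.integer(n_patients), n_good = as.integer(n_good),
              visit_times = as.numeric(visit_times),
              baseline_das28_mean = baseline_das28_mean,
              baseline_das28_sd = baseline_das28_sd,
              baseline_das28_range = as.numeric(baseline_das28_range),
              good_decline_rate = good_decline_rate,
              poor_decline_rate = poor_decline_rate,
              measurement_noise_sd = measurement_noise_sd,
              weekly_dose_levels = as.numeric(weekly_dose_levels),
              genotype_group_probabilities = genotype_group_probabilities,
              genotype_effect_on_R = genotype_effect_on_R,
              seed = as.integer(seed))
  validate_cohort_config(cfg)
}

validate_cohort_config <- function(cfg) {
  fail <- function(field, msg) {
    stop(sprintf("invalid cohort config: field '%s' %s", field, msg),
         call. = FALSE)
  }
  if (is.na(cfg$n_patients) || cfg$n_patients < 2L) {
    fail("n_patients", "must be at least 2")
  }
  if (is.na(cfg$n_good) || cfg$n_good <= 0L || cfg$n_good >= cfg$n_patients) {
    fail("n_good", "must satisfy 0 < n_good < n_patients")
  }
  vt <- cfg$visit_times
  if (length(vt) < 2L || anyNA(vt) || is.unsorted(vt, strictly = TRUE)) {
    fail("visit_times", "must be >= 2 strictly increasing values")
  }
  if (vt[1] != 0) fail("visit_times", "must start at month 0 (baseline)")
  if (any(vt < 0) || any(vt > 12)) fail("visit_times", "must lie in [0, 12]")
  for (f in c("good_decline_rate", "poor_decline_rate")) {
    if (is.na(cfg[[f]]) || cfg[[f]] < 0) fail(f, "must be >= 0")
  }
  for (f in c("baseline_das28_sd", "measurement_noise_sd")) {
    if (is.na(cfg[[f]]) || cfg[[f]] < 0) fail(f, "must be >= 0")
  }
  p <- cfg$genotype_group_probabilities
  if (is.null(names(p)) || !all(names(p) %in% snp_groupings()$snp)) {
    fail("genotype_group_probabilities",
         sprintf("must be named by SNP (%s)",
                 paste(snp_groupings()$snp, collapse = ", ")))
  }
  if (any(p < 0 | p > 1)) {
    fail("genotype_group_probabilities", "must lie in [0, 1]")
  }
  if (any(cfg$weekly_dose_levels <= 0)) {
    fail("weekly_dose_levels", "must be positive (index R needs dose > 0)")
  }
  if (is.na(cfg$genotype_effect_on_R) || cfg$genotype_effect_on_R <= 0) {
    fail("genotype_effect_on_R", "must be a positive multiplier")
  }
  if (is.na(cfg$seed)) fail("seed", "must be an integer")
  structure(cfg, class = "cohort_config")
}
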
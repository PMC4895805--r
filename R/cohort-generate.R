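#' Generate a synthetic methotrexate-response cohort
#'
#' Simulates patients whose DAS28 trajectories decline linearly from a
#' baseline at a responder-group-specific rate (floored at zero), with
#' i.i.d. Gaussian measurement noise per visit on the target score.  The
#' noisy target is then back-filled into score components — VAS and CRP as
#' deterministic functions of the target, tender/swollen joint counts
#' solving the remaining formula terms, rounded to integers in [0, 28] —
#' and the DAS28 recomputed from the rounded components is the ground-truth
#' score, so the scoring formula remains the single source of truth.
#'
#' Each patient receives a constant weekly methotrexate dose drawn from the
#' configured levels, as a single interval covering months 0-12.  Genotypes
#' are sampled independently per SNP at the two-group (carrier vs
#' non-carrier) level; members of a SNP's comparison group are recorded as
#' heterozygous carriers (homozygous where the group itself is homozygous).
#'
#' @param config A [cohort_config()].
#'
#' @return An `mtx_cohort`: `patients` (list of `mtx_patient`), `true_labels`
#'   (`"good"`/`"poor"` per patient), `config` (the echoed configuration).
#'   Deterministic given `config$seed`; the caller's RNG state is restored.
#' @export
generate_cohort <- function(config) {
  config <- validate_cohort_config(unclass(config))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(config$seed)

  n <- config$n_patients
  ids <- sprintf("P%02d", seq_len(n))
  labels <- rep(c("good", "poor"), c(config$n_good, n - config$n_good))
  rates <- ifelse(labels == "good", config$good_decline_rate,
                  config$poor_decline_rate)
  baseline <- pmin(pmax(
    stats::rnorm(n, config$baseline_das28_mean, config$baseline_das28_sd),
    config$baseline_das28_range[1]), config$baseline_das28_range[2])

  # genotypes: per-SNP Bernoulli membership in the comparison group
  defs <- snp_groupings()
  probs <- config$genotype_group_probabilities
  geno <- matrix(NA_character_, nrow = n, ncol = length(probs),
                 dimnames = list(NULL, names(probs)))
  member <- matrix(FALSE, nrow = n, ncol = length(probs),
                   dimnames = list(NULL, names(probs)))
  for (s in names(probs)) {
    i <- match(s, defs$snp)
    member[, s] <- stats::runif(n) < probs[[s]]
    geno[, s] <- ifelse(member[, s],
                        comparison_genotype(defs, i),
                        reference_genotype(defs, i))
  }
  if ("rfc1_80" %in% colnames(member)) {
    rates <- rates * ifelse(member[, "rfc1_80"], config$genotype_effect_on_R, 1)
  }

  dose_mg <- config$weekly_dose_levels[
    sample.int(length(config$weekly_dose_levels), n, replace = TRUE)]

  vt <- config$visit_times
  patients <- vector("list", n)
  for (i in seq_len(n)) {
    target <- pmax(0, baseline[i] - rates[i] * vt +
                     stats::rnorm(length(vt), 0, config$measurement_noise_sd))
    comp <- backfill_components(target)
    visits <- tibble::new_tibble(
      list(month = vt, t28 = comp$t28, s28 = comp$s28,
           vas = comp$vas, crp = comp$crp,
           das28 = das28_crp(comp$t28, comp$s28, comp$vas, comp$crp)),
      nrow = length(vt))
    doses <- tibble::new_tibble(
      list(start_month = 0, end_month = 12, weekly_dose_mg = dose_mg[i]),
      nrow = 1L)
    patients[[i]] <- new_patient(ids[i], visits, doses, geno[i, ])
  }
  structure(list(patients = patients, true_labels = labels, config = config),
            class = "mtx_cohort")
}

# representative diploid calls for the two groups of a SNP
comparison_genotype <- function(defs, i) {
  al <- defs$alleles[[i]]
  grp <- defs$comparison_group[i]
  if (grepl("/", grp, fixed = TRUE)) grp else paste(al[1], al[2], sep = "/")
}

reference_genotype <- function(defs, i) {
  al <- defs$alleles[[i]]
  grp <- defs$reference_group[i]
  if (grepl("/", grp, fixed = TRUE)) grp else paste(al[1], al[2], sep = "/")
}

# Solve score components so the recomputed DAS28 tracks the target score.
# VAS and CRP are deterministic in the target (noise enters once, upstream);
# the joint-count terms absorb the residual with T28 = S28.
backfill_components <- function(target) {
  vas <- pmin(100, pmax(0, round(10 * target)))
  crp <- pmax(0, 0.35 * (exp(target / 2.8) - 1))
  resid <- target - 0.36 * log(crp + 1) - 0.014 * vas - 0.96
  counts <- pmin(28L, pmax(0L, as.integer(round((pmax(0, resid) / 0.84)^2))))
  list(t28 = counts, s28 = counts, vas = vas, crp = crp)
}

#' @export
print.mtx_cohort <- function(x, ...) {
  cat(sprintf("<mtx_cohort: %d patients (%d good / %d poor), %d visits each>\n",
              length(x$patients), sum(x$true_labels == "good"),
              sum(x$true_labels == "poor"),
              length(x$config$visit_times)))
  invisible(x)
}
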
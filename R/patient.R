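#' Construct a patient record
#'
#' Bundles one patient's longitudinal visits, methotrexate dose schedule and
#' genotype calls.  Visits must be strictly time-sorted and include a
#' baseline visit at month 0; the DAS28 score is computed from the components
#' if not supplied.
#'
#' @param patient_id Identifier (coerced to character).
#' @param visits Data frame with `month` and either `das28` or the four
#'   components `t28`, `s28`, `vas`, `crp`.
#' @param doses Data frame with `start_month`, `end_month`, `weekly_dose_mg`;
#'   non-overlapping intervals.
#' @param genotypes Named character vector or list of genotype calls keyed by
#'   SNP name (see [snp_groupings()]), e.g.
#'   `c(rfc1_80 = "G/A", tyms_utr = "-6/-6")`.  May be empty.
#'
#' @return An object of class `mtx_patient`.
#' @export
new_patient <- function(patient_id, visits, doses,
                        genotypes = character()) {
  visits <- as_visit_frame(visits)
  if (visits$month[1] != 0) {
    stop(sprintf("patient '%s': first visit must be the baseline at month 0",
                 patient_id), call. = FALSE)
  }
  doses <- as_dose_frame(doses)
  genotypes <- unlist(genotypes)
  if (length(genotypes) && is.null(names(genotypes))) {
    stop("genotypes must be named by SNP", call. = FALSE)
  }
  structure(
    list(patient_id = as.character(patient_id),
         visits = visits, doses = doses,
         genotypes = genotypes),
    class = "mtx_patient")
}

#' @export
print.mtx_patient <- function(x, ...) {
  cat(sprintf("<mtx_patient %s: %d visits over months %s-%s, %d dose interval(s), %d genotype(s)>\n",
              x$patient_id, nrow(x$visits),
              format(min(x$visits$month)), format(max(x$visits$month)),
              nrow(x$doses), length(x$genotypes)))
  invisible(x)
}

as_patient_list <- function(patients) {
  if (inherits(patients, "mtx_cohort")) return(patients$patients)
  if (inherits(patients, "mtx_patient")) return(list(patients))
  if (is.list(patients) && all(vapply(patients, inherits, logical(1), "mtx_patient"))) {
    return(patients)
  }
  stop("expected a cohort, a patient, or a list of patients", call. = FALSE)
}
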
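#' Disease-control criteria
#'
#' Control status is judged over months 6-12 after the start of methotrexate.
#' A patient is in good control when the weekly dose stayed fixed throughout
#' the window and DAS28 scores above the threshold were recorded at clinic
#' visits less than once per month on average; every other case is poor
#' control.
#'
#' The "less than once per month" rule admits two readings, both provided:
#' the default counts exceedances across the whole window and requires the
#' count to be strictly below the window length in months (an average below
#' one per month); `strict_mode` allows no exceedance at all, i.e. DAS28
#' held at or under the threshold for the entire window.
#'
#' @param window Numeric `c(start, end)` in months; default `c(6, 12)`.
#' @param das28_threshold Score above which a visit counts as an exceedance;
#'   default 2.
#' @param require_fixed_dose Must the weekly dose be constant over the
#'   window?  Default `TRUE`.
#' @param strict_mode If `TRUE`, zero exceedances are allowed.
#'
#' @return A `control_criteria` list.
#' @export
control_criteria <- function(window = c(6, 12), das28_threshold = 2,
                             require_fixed_dose = TRUE, strict_mode = FALSE) {
  window <- check_window(window)
  if (!is.numeric(das28_threshold) || das28_threshold <= 0) {
    stop("das28_threshold must be positive", call. = FALSE)
  }
  structure(list(window = window, das28_threshold = das28_threshold,
                 require_fixed_dose = isTRUE(require_fixed_dose),
                 strict_mode = isTRUE(strict_mode)),
            class = "control_criteria")
}

#' Classify a patient's disease-control status
#'
#' @param patient An `mtx_patient`.
#' @param criteria A [control_criteria()] object.
#'
#' @return List with `status` (`"good"` or `"poor"`), `reasons` (character,
#'   empty for good), `n_exceedances`, `n_visits` (visits inside the window,
#'   inclusive of both edges), and `dose_levels` seen in the window.
#'   A patient with no visits inside the window raises an indeterminate
#'   error rather than being labelled silently.
#' @export
classify_control <- function(patient, criteria = control_criteria()) {
  stopifnot(inherits(patient, "mtx_patient"))
  w <- criteria$window
  v <- as_visit_frame(patient$visits)
  inw <- v$month >= w[1] & v$month <= w[2]
  if (!any(inw)) {
    stop(sprintf("patient '%s': no visits in the control window [%s, %s]; status indeterminate",
                 patient$patient_id, format(w[1]), format(w[2])),
         call. = FALSE)
  }
  n_exc <- sum(v$das28[inw] > criteria$das28_threshold)
  allowed <- if (criteria$strict_mode) 0 else (w[2] - w[1])
  exc_ok <- if (criteria$strict_mode) n_exc == 0 else n_exc < allowed
  reasons <- character()
  if (!exc_ok) {
    reasons <- c(reasons, sprintf(
      "DAS28 > %s at %d visit(s) in months %s-%s (allowed: %s)",
      format(criteria$das28_threshold), n_exc, format(w[1]), format(w[2]),
      if (criteria$strict_mode) "none" else
        sprintf("fewer than %d", as.integer(allowed))))
  }
  d <- as_dose_frame(patient$doses)
  in_dose <- d$start_month < w[2] & d$end_month > w[1]
  levels <- unique(d$weekly_dose_mg[in_dose])
  if (criteria$require_fixed_dose && length(levels) > 1L) {
    reasons <- c(reasons, sprintf("dose change within months %s-%s (%s mg/week)",
                                  format(w[1]), format(w[2]),
                                  paste(format(levels), collapse = " -> ")))
  }
  list(status = if (length(reasons)) "poor" else "good",
       reasons = reasons,
       n_exceedances = n_exc,
       n_visits = sum(inw),
       dose_levels = levels)
}

#' Classify every patient in a cohort
#'
#' @param patients Cohort or list of patients.
#' @param criteria A [control_criteria()] object.
#'
#' @return Tibble with `patient_id`, `control_status`, `reasons`
#'   (semicolon-joined), `n_exceedances`.
#' @export
classify_cohort <- function(patients, criteria = control_criteria()) {
  pl <- as_patient_list(patients)
  rows <- lapply(pl, function(p) {
    cl <- classify_control(p, criteria)
    tibble::tibble(patient_id = p$patient_id,
                   control_status = cl$status,
                   reasons = paste(cl$reasons, collapse = "; "),
                   n_exceedances = cl$n_exceedances)
  })
  do.call(rbind, rows)
}
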
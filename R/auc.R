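#' Trapezoidal area under a DAS28 trajectory
#'
#' Integrates the piecewise-linear interpolant of a patient's DAS28 values
#' over a time window, i.e. the trapezoidal rule on the visit grid.  If no
#' visit falls exactly on a window edge, the trajectory value there is
#' linearly interpolated between the bracketing visits.
#'
#' @param visits A data frame with a `month` column and either a `das28`
#'   column or the four score components (`t28`, `s28`, `vas`, `crp`), from
#'   which DAS28 is computed via [das28_crp()].  May also be a patient
#'   object, in which case its visit table is used.
#' @param window Numeric length-2 vector `c(t0, t1)` in months, `t0 < t1`.
#'
#' @return The integral in DAS28 x months (score-months).
#'
#' @details The window must be covered by the visit grid
#'   (`min(month) <= t0` and `max(month) >= t1`); otherwise a coverage error
#'   is raised rather than extrapolating.  A trajectory held constant at the
#'   reference score of 10 gives exactly 30 over months 0-3 and 60 over
#'   months 0-6.
#'
#' @examples
#' v <- data.frame(month = 0:3, das28 = 10)
#' das28_auc(v, c(0, 3))   # 30
#' @export
das28_auc <- function(visits, window) {
  visits <- as_visit_frame(visits)
  window <- check_window(window)
  m <- visits$month
  d <- visits$das28
  if (length(m) < 2L) {
    stop("need at least 2 visits to integrate a trajectory", call. = FALSE)
  }
  if (min(m) > window[1] || max(m) < window[2]) {
    stop(sprintf(
      "visits cover [%s, %s] but window [%s, %s] was requested; refusing to extrapolate",
      format(min(m)), format(max(m)), format(window[1]), format(window[2])),
      call. = FALSE)
  }
  inner <- m[m > window[1] & m < window[2]]
  knots <- sort(unique(c(window, inner)))
  vals <- stats::approx(m, d, xout = knots, ties = "ordered")$y
  sum(diff(knots) * (vals[-length(vals)] + vals[-1]) / 2)
}

#' Improved DAS28 area over a window
#'
#' The reference area — a DAS28 score of 10 sustained over the whole window
#' (30 score-months for 0-3 months, 60 for 0-6 months) — minus the patient's
#' actual trapezoidal DAS28 area.  Larger values mean more improvement
#' relative to maximal disease burden; the reference anchors all patients to
#' a common ceiling regardless of their baseline score.
#'
#' @inheritParams das28_auc
#' @param reference_das28 Score assumed sustained for the reference area
#'   (default 10, the ceiling used to normalise across baselines).
#'
#' @return Improved area in score-months.  A negative value (trajectory
#'   above the reference) is reported with a warning, not clipped.
#'
#' @examples
#' v <- data.frame(month = 0:6, das28 = 0)
#' improved_area(v, c(0, 6))   # 60
#' @export
improved_area <- function(visits, window, reference_das28 = 10) {
  window <- check_window(window)
  ref <- reference_das28 * (window[2] - window[1])
  out <- ref - das28_auc(visits, window)
  if (out < 0) {
    warning("improved area is negative: trajectory exceeds the reference score",
            call. = FALSE)
  }
  out
}

as_visit_frame <- function(visits) {
  if (inherits(visits, "mtx_patient")) visits <- visits$visits
  if (!is.data.frame(visits) || !"month" %in% names(visits)) {
    stop("visits must be a data frame with a 'month' column", call. = FALSE)
  }
  if (is.unsorted(visits$month, strictly = TRUE)) {
    stop("visit months must be strictly increasing", call. = FALSE)
  }
  if (!"das28" %in% names(visits)) {
    comp <- c("t28", "s28", "vas", "crp")
    if (!all(comp %in% names(visits))) {
      stop("visits need either a 'das28' column or all of t28, s28, vas, crp",
           call. = FALSE)
    }
    visits$das28 <- das28_crp(visits$t28, visits$s28, visits$vas, visits$crp)
  }
  visits
}

check_window <- function(window) {
  if (!is.numeric(window) || length(window) != 2L || anyNA(window) ||
      window[1] >= window[2]) {
    stop("window must be c(t0, t1) with t0 < t1", call. = FALSE)
  }
  as.numeric(window)
}

window_label <- function(window) {
  paste0(format(window[1], trim = TRUE), "-", format(window[2], trim = TRUE))
}
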
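#' Cumulative methotrexate dose over a window
#'
#' Sums weekly doses over the overlap of each dosing interval with the
#' analysis window.  Dosing is represented as piecewise-constant weekly doses
#' on half-open month intervals `[start_month, end_month)`.
#'
#' @param doses Data frame with columns `start_month`, `end_month`,
#'   `weekly_dose_mg`, or a patient object.  Intervals must be
#'   non-overlapping and jointly cover the window.
#' @param window Numeric `c(t0, t1)` in months.
#' @param weeks_per_month Months-to-weeks conversion factor.  The default, 4
#'   exactly, makes a 0-3-month window hold 12 weekly doses (so 8 mg/week
#'   gives 96 mg); pass `365.25 / 12 / 7` (about 4.348) for calendar-exact
#'   weeks per month.
#'
#' @return Cumulative dose in mg.
#'
#' @examples
#' d <- data.frame(start_month = 0, end_month = 12, weekly_dose_mg = 8)
#' cumulative_dose(d, c(0, 3))   # 96
#' @export
cumulative_dose <- function(doses, window, weeks_per_month = 4) {
  doses <- as_dose_frame(doses)
  window <- check_window(window)
  ord <- order(doses$start_month)
  doses <- doses[ord, , drop = FALSE]
  check_dose_coverage(doses, window)
  ov <- pmax(0, pmin(doses$end_month, window[2]) -
                pmax(doses$start_month, window[1]))
  sum(doses$weekly_dose_mg * weeks_per_month * ov)
}

as_dose_frame <- function(doses) {
  if (inherits(doses, "mtx_patient")) doses <- doses$doses
  need <- c("start_month", "end_month", "weekly_dose_mg")
  if (!is.data.frame(doses) || !all(need %in% names(doses))) {
    stop("doses must be a data frame with start_month, end_month, weekly_dose_mg",
         call. = FALSE)
  }
  if (any(doses$start_month >= doses$end_month)) {
    stop("dose intervals must have start_month < end_month", call. = FALSE)
  }
  if (any(doses$weekly_dose_mg < 0)) {
    stop("weekly_dose_mg must be non-negative", call. = FALSE)
  }
  doses
}

check_dose_coverage <- function(doses, window) {
  # doses sorted by start; intervals must tile the window without gaps
  if (nrow(doses) == 0L || doses$start_month[1] > window[1] ||
      max(doses$end_month) < window[2]) {
    stop(sprintf("dose intervals do not cover the window [%s, %s]",
                 format(window[1]), format(window[2])), call. = FALSE)
  }
  if (nrow(doses) > 1L) {
    gap <- doses$start_month[-1] - doses$end_month[-nrow(doses)]
    if (any(gap > 1e-9 & doses$start_month[-1] < window[2])) {
      stop("dose intervals leave a gap inside the window", call. = FALSE)
    }
    if (any(gap < -1e-9)) {
      stop("dose intervals overlap", call. = FALSE)
    }
  }
  invisible(doses)
}
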
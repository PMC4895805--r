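#' DAS28-CRP composite disease-activity score
#'
#' Computes the 28-joint Disease Activity Score with C-reactive protein from
#' its four components:
#'
#' \deqn{DAS28 = 0.56\sqrt{T28} + 0.28\sqrt{S28} + 0.36\ln(CRP + 1)
#'   + 0.014 \times VAS + 0.96}
#'
#' CRP is consumed on the scale it is supplied (no unit conversion is applied
#' silently); declare the unit at the study level.  All arguments are
#' vectorized and recycled to a common length.
#'
#' @param t28 Tender-joint count out of 28 assessed joints (integer 0-28).
#' @param s28 Swollen-joint count out of 28 assessed joints (integer 0-28).
#' @param vas Patient global assessment on a 0-100 visual analogue scale.
#' @param crp C-reactive protein concentration (non-negative).
#'
#' @return Numeric vector of DAS28-CRP scores.  The score is strictly
#'   increasing in every component; its minimum, at all-zero components, is
#'   the additive constant 0.96.
#'
#' @examples
#' das28_crp(0, 0, 0, 0)        # 0.96
#' das28_crp(4, 4, 50, 1.26)    # moderate activity
#' @export
das28_crp <- function(t28, s28, vas, crp) {
  check_component(t28, "t28", 0, 28)
  check_component(s28, "s28", 0, 28)
  check_component(vas, "vas", 0, 100)
  check_component(crp, "crp", 0, Inf)
  0.56 * sqrt(t28) + 0.28 * sqrt(s28) + 0.36 * log(crp + 1) +
    0.014 * vas + 0.96
}

check_component <- function(x, name, lo, hi) {
  if (!is.numeric(x)) {
    stop(sprintf("component '%s' must be numeric", name), call. = FALSE)
  }
  if (anyNA(x)) {
    stop(sprintf("component '%s' contains missing values", name),
         call. = FALSE)
  }
  if (any(x < lo) || any(x > hi)) {
    stop(sprintf("component '%s' out of range [%s, %s]: %s",
                 name, format(lo), format(hi),
                 paste(format(x[x < lo | x > hi]), collapse = ", ")),
         call. = FALSE)
  }
  invisible(x)
}
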
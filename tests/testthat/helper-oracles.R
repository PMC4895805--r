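# Independent oracles used across the suite.  These deliberately take a
# different computational route from the package implementation.

# Two-sided Mann-Whitney p by complete enumeration of all assignments of the
# pooled values to the two groups.  U is computed directly from pairwise
# comparisons (with half-credit for ties), not from ranks.
bruteforce_mw_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  n <- length(pooled)
  u_stat <- function(a, b) {
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  center <- n1 * (n - n1) / 2
  dev_obs <- abs(u_stat(x, y) - center)
  idx <- utils::combn(n, n1)
  devs <- apply(idx, 2, function(i) {
    abs(u_stat(pooled[i], pooled[-i]) - center)
  })
  mean(devs >= dev_obs - 1e-9)
}

# Fine-grid Riemann (midpoint) sum of the piecewise-linear interpolant,
# over exactly n_cells equal cells tiling the window.
riemann_auc <- function(month, das28, window, n_cells = 2e5) {
  h <- (window[2] - window[1]) / n_cells
  mid <- window[1] + (seq_len(n_cells) - 0.5) * h
  vals <- stats::approx(month, das28, xout = mid, ties = "ordered")$y
  sum(vals) * h
}

# Quick builders for hand-made patients.
make_visits <- function(month, das28) {
  data.frame(month = month, das28 = das28)
}

make_doses <- function(weekly = 8, start = 0, end = 12) {
  data.frame(start_month = start, end_month = end, weekly_dose_mg = weekly)
}

# A patient whose DAS28 trajectory is given directly (components omitted).
make_patient <- function(id = "P1", month = 0:12, das28 = 4,
                         weekly = 8, genotypes = character()) {
  das28 <- rep_len(das28, length(month))
  new_patient(id, make_visits(month, das28), make_doses(weekly), genotypes)
}
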
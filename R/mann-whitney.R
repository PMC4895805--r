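#' Mann-Whitney U test for two independent samples
#'
#' Rank-based two-sample test with mid-rank tie handling and a two-sided
#' p-value throughout.  The exact method computes the full null distribution
#' of the rank sum under random group assignment — ties included — by a
#' dynamic-programming count over subsets, which is equivalent to complete
#' enumeration of all `choose(n1+n2, n1)` assignments but runs in polynomial
#' time.  The approximate method uses the normal approximation with
#' tie-corrected variance and a 0.5 continuity correction.
#'
#' @param x,y Numeric samples, both non-empty.
#' @param method `"auto"` (exact when `n1+n2 <= exact_cap`, else
#'   approximate), `"exact"`, or `"approx"`.
#' @param exact_cap Largest combined sample size for which `"auto"` picks the
#'   exact distribution (default 40).
#'
#' @return An object of class `mw_test`: `u` (U statistic for `x`), `n1`,
#'   `n2`, `p_value` (two-sided, in (0, 1]), `method_used`, and `note`
#'   (non-empty when all values are identical across both groups, where
#'   p = 1 by convention).  `U` is in `[0, n1*n2]` and the U statistics of
#'   the two orderings sum to `n1*n2`.
#'
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))$p_value  # exact two-sided 0.1
#' @export
mann_whitney <- function(x, y, method = c("auto", "exact", "approx"),
                         exact_cap = 40) {
  method <- match.arg(method)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) == 0L || length(y) == 0L) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  if (anyNA(x) || anyNA(y)) stop("samples contain missing values", call. = FALSE)
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))
  w <- sum(r[seq_len(n1)])              # rank sum of x
  u <- w - n1 * (n1 + 1) / 2            # U statistic for x

  if (length(unique(c(x, y))) == 1L) {
    return(new_mw_test(u, n1, n2, 1, "degenerate",
                       note = "all values identical across both groups"))
  }
  use_exact <- switch(method,
                      exact = TRUE,
                      approx = FALSE,
                      auto = n <= exact_cap)
  if (use_exact) {
    p <- mw_exact_p(r, n1)
    new_mw_test(u, n1, n2, p, "exact-permutation")
  } else {
    p <- mw_approx_p(u, r, n1, n2)
    new_mw_test(u, n1, n2, p, "normal-approx-tie-corrected")
  }
}

new_mw_test <- function(u, n1, n2, p, method_used, note = "") {
  structure(list(u = u, n1 = n1, n2 = n2, p_value = p,
                 method_used = method_used, note = note),
            class = "mw_test")
}

#' @export
print.mw_test <- function(x, ...) {
  cat(sprintf("Mann-Whitney U test (%s)\nU = %g (n1 = %d, n2 = %d), two-sided p = %.4g\n",
              x$method_used, x$u, x$n1, x$n2, x$p_value))
  if (nzchar(x$note)) cat("note:", x$note, "\n")
  invisible(x)
}

# Exact two-sided p from the permutation distribution of the rank sum.
# Mid-ranks are multiples of 1/2, so doubled ranks are integers; count the
# number of n1-subsets attaining each doubled rank sum with a subset-sum DP.
# Counts stay below choose(40, 20) < 2^53, so double-precision counting is
# exact.
mw_exact_p <- function(r, n1) {
  w2 <- as.integer(round(2 * r))
  n <- length(r)
  total <- sum(w2)                       # = n * (n + 1)
  cnt <- matrix(0, nrow = n1 + 1L, ncol = total + 1L)
  cnt[1L, 1L] <- 1
  kmax <- 0L
  for (wi in w2) {
    kmax <- min(kmax + 1L, n1)
    for (k in kmax:1L) {
      idx <- seq_len(total + 1L - wi)
      cnt[k + 1L, idx + wi] <- cnt[k + 1L, idx + wi] + cnt[k, idx]
    }
  }
  dist <- cnt[n1 + 1L, ]
  s2 <- which(dist > 0) - 1L             # attainable doubled rank sums
  e2 <- n1 * (n + 1L)                    # doubled null mean of the rank sum
  obs <- sum(w2[seq_len(n1)])
  dev <- abs(obs - e2)
  extreme <- abs(s2 - e2) >= dev
  sum(dist[s2[extreme] + 1L]) / choose(n, n1)
}

mw_approx_p <- function(u, r, n1, n2) {
  n <- n1 + n2
  mu <- n1 * n2 / 2
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
  if (sigma2 <= 0) return(1)
  z <- (abs(u - mu) - 0.5) / sqrt(sigma2)
  z <- max(z, 0)
  min(1, 2 * stats::pnorm(-z))
}

#' Median and quartiles of a sample
#'
#' Summaries use linear interpolation between order statistics at positions
#' `1 + (n - 1) * q` (R's quantile type 7), the convention recorded in the
#' pipeline manifest so the choice is auditable.
#'
#' @param values Non-empty numeric sample.
#' @return Named list: `median`, `q25`, `q75`, `n`.
#' @examples
#' summarize_quartiles(c(1, 2, 3, 4, 5))
#' @export
summarize_quartiles <- function(values) {
  values <- as.numeric(values)
  if (length(values) == 0L || anyNA(values)) {
    stop("values must be non-empty with no missing entries", call. = FALSE)
  }
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  list(median = q[2], q25 = q[1], q75 = q[3], n = length(values))
}

#' Two-group comparison with medians, quartiles, and Mann-Whitney p
#'
#' @param values Numeric vector of the analysed variable.
#' @param groups Vector of group labels aligned with `values`; exactly two
#'   distinct labels after dropping `NA`.
#' @param variable Name recorded in the output row.
#' @param group_order Optional length-2 character giving the reporting order
#'   (first group is "group1").
#' @inheritParams mann_whitney
#'
#' @return One-row tibble: variable, each group's label/n/median/quartiles,
#'   `u` (U statistic of group1), two-sided `p_value`, `method`.
#' @export
compare_groups <- function(values, groups, variable = "value",
                           group_order = NULL,
                           method = c("auto", "exact", "approx"),
                           exact_cap = 40) {
  keep <- !is.na(groups)
  values <- values[keep]; groups <- as.character(groups[keep])
  labs <- if (is.null(group_order)) sort(unique(groups)) else group_order
  if (length(unique(groups)) != 2L || !setequal(labs, unique(groups))) {
    stop("compare_groups needs exactly two non-empty groups; got: ",
         paste(unique(groups), collapse = ", "), call. = FALSE)
  }
  g1 <- values[groups == labs[1]]
  g2 <- values[groups == labs[2]]
  s1 <- summarize_quartiles(g1)
  s2 <- summarize_quartiles(g2)
  mw <- mann_whitney(g1, g2, method = method, exact_cap = exact_cap)
  tibble::tibble(
    variable = variable,
    group1 = labs[1], n1 = s1$n, median1 = s1$median,
    q25_1 = s1$q25, q75_1 = s1$q75,
    group2 = labs[2], n2 = s2$n, median2 = s2$median,
    q25_2 = s2$q25, q75_2 = s2$q75,
    u = mw$u, p_value = mw$p_value, method = mw$method_used)
}
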
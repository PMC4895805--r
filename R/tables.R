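#' Compare response measures between disease-control groups
#'
#' Builds the six comparisons of the main response report: cumulative dose,
#' improved DAS28 area, and index R, each over the 0-3 and 0-6 month
#' windows, contrasted between patients in good versus poor disease control
#' during months 6-12.  Each row carries both groups' median (25th-75th
#' percentile) and the two-sided Mann-Whitney p-value.
#'
#' @param summaries Tibble from [response_summaries()] with both windows.
#' @param labels Tibble with `patient_id` and `control_status`
#'   (from [classify_cohort()]).
#' @inheritParams mann_whitney
#'
#' @return Tibble with 6 rows (3 variables x 2 windows), columns as in
#'   [compare_groups()] plus `window`.
#' @export
build_table2 <- function(summaries, labels, method = "auto", exact_cap = 40) {
  missing_lab <- setdiff(unique(summaries$patient_id), labels$patient_id)
  if (length(missing_lab)) {
    stop("no control label for patient(s): ",
         paste(missing_lab, collapse = ", "), call. = FALSE)
  }
  vars <- c(`Cumulative dose of MTX (mg)` = "cumulative_dose_mg",
            `Improved DAS28 area` = "improved_area",
            `Index R (1/mg)` = "index_r")
  rows <- list()
  for (w in unique(summaries$window)) {
    sw <- summaries[summaries$window == w, , drop = FALSE]
    status <- labels$control_status[match(sw$patient_id, labels$patient_id)]
    for (j in seq_along(vars)) {
      row <- compare_groups(sw[[vars[j]]], status, variable = names(vars)[j],
                            group_order = c("good", "poor"),
                            method = method, exact_cap = exact_cap)
      rows[[length(rows) + 1L]] <- cbind(tibble::tibble(window = w), row)
    }
  }
  tibble::as_tibble(do.call(rbind, rows))
}

#' Compare index R between genotype groups
#'
#' One comparison per SNP: index R over the 0-6-month window, contrasted
#' between the SNP's two genotype groups (homozygous reference vs variant
#' carriers, or the reverse, per the grouping rules in [snp_groupings()]).
#' A SNP with an empty group is skipped with a warning rather than failing
#' the whole report.
#'
#' @param summaries Tibble from [response_summaries()].
#' @param groups Long tibble from [genotype_groups()] (`patient_id`, `snp`,
#'   `group`).
#' @param window Window label analysed, default `"0-6"`.
#' @inheritParams mann_whitney
#'
#' @return Tibble with one row per comparable SNP, columns as in
#'   [compare_groups()] plus `snp`.
#' @export
build_table3 <- function(summaries, groups, window = "0-6",
                         method = "auto", exact_cap = 40) {
  sw <- summaries[summaries$window == window, , drop = FALSE]
  if (nrow(sw) == 0L) {
    stop("no response summaries for window ", window, call. = FALSE)
  }
  defs <- snp_groupings()
  rows <- list()
  for (i in seq_len(nrow(defs))) {
    s <- defs$snp[i]
    gs <- groups[groups$snp == s, , drop = FALSE]
    grp <- gs$group[match(sw$patient_id, gs$patient_id)]
    order2 <- c(defs$reference_group[i], defs$comparison_group[i])
    sizes <- table(factor(grp, levels = order2))
    if (any(sizes == 0L)) {
      warning(sprintf("SNP %s: group '%s' is empty; comparison skipped",
                      s, order2[sizes == 0L][1]), call. = FALSE)
      next
    }
    row <- compare_groups(sw$index_r, grp, variable = "index_r",
                          group_order = order2,
                          method = method, exact_cap = exact_cap)
    rows[[length(rows) + 1L]] <- cbind(tibble::tibble(snp = s), row)
  }
  if (!length(rows)) {
    return(tibble::tibble(snp = character()))
  }
  tibble::as_tibble(do.call(rbind, rows))
}
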
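#' Folate-pathway SNP grouping rules
#'
#' The five SNPs compared in the genotype analysis, each collapsed from three
#' genotypes to the two groups actually contrasted: homozygous for one allele
#' versus any carrier of the other.  The contrasts are
#' RFC1 80G>A (rs1051266): G/G vs A-allele carriers;
#' FPGS 1994G>A (rs10106): G-allele carriers vs A/A;
#' GGH -401C>T (rs3758149): C/C vs T-allele carriers;
#' MTHFR 1298A>C (rs1801131): A-allele carriers vs C/C;
#' TYMS 3'-UTR 6-bp ins/del (rs16430): -6/-6 vs +6-allele carriers.
#'
#' @return Tibble with one row per SNP: `snp`, `alleles` (list of the two
#'   allele symbols), `reference_group`, `comparison_group`, and
#'   `carrier_allele` — the allele whose presence assigns the carrier-defined
#'   group.
#' @export
snp_groupings <- function() {
  if (is.null(.mtx_cache$snp_defs)) .mtx_cache$snp_defs <- make_snp_defs()
  .mtx_cache$snp_defs
}

.mtx_cache <- new.env(parent = emptyenv())

make_snp_defs <- function() {
  tibble::tibble(
    snp = c("rfc1_80", "fpgs_1994", "ggh_401", "mthfr_1298", "tyms_utr"),
    alleles = list(c("G", "A"), c("G", "A"), c("C", "T"),
                   c("A", "C"), c("-6", "+6")),
    # group listed first in the report; the comparison group is the one whose
    # simulated frequency is configured in cohort_config()
    reference_group = c("G/G", "G allele", "C/C", "A allele", "-6/-6"),
    comparison_group = c("A allele", "A/A", "T allele", "C/C", "+6 allele"),
    carrier_allele = c("A", "G", "T", "A", "+6"),
    carrier_is_reference = c(FALSE, TRUE, FALSE, TRUE, FALSE)
  )
}

#' Map a genotype call to its comparison group
#'
#' Normalizes allele order (`"A/G"` and `"G/A"` are the same call; a Unicode
#' minus in TYMS calls is accepted) and applies the SNP's carrier rule.
#'
#' @param snp_name One of `"rfc1_80"`, `"fpgs_1994"`, `"ggh_401"`,
#'   `"mthfr_1298"`, `"tyms_utr"` (case-insensitive).
#' @param genotype_string A diploid call such as `"G/A"` or `"+6/-6"`.
#'
#' @return The group label, e.g. `"A allele"` or `"G/G"`.
#'
#' @examples
#' group_genotype("rfc1_80", "G/A")    # "A allele"
#' group_genotype("tyms_utr", "+6/-6") # "+6 allele"
#' @export
group_genotype <- function(snp_name, genotype_string) {
  defs <- snp_groupings()
  key <- tolower(as.character(snp_name))
  i <- match(key, defs$snp)
  if (is.na(i)) {
    stop(sprintf("unknown SNP '%s'; expected one of: %s", snp_name,
                 paste(defs$snp, collapse = ", ")), call. = FALSE)
  }
  alleles <- normalize_call(genotype_string, defs$alleles[[i]], snp_name)
  carrier <- defs$carrier_allele[i]
  has_carrier <- carrier %in% alleles
  if (defs$carrier_is_reference[i]) {
    if (has_carrier) defs$reference_group[i] else defs$comparison_group[i]
  } else {
    if (has_carrier) defs$comparison_group[i] else defs$reference_group[i]
  }
}

normalize_call <- function(genotype_string, valid_alleles, snp_name) {
  g <- as.character(genotype_string)
  if (length(g) != 1L || is.na(g)) {
    stop(sprintf("malformed genotype call for %s: %s", snp_name,
                 deparse(genotype_string)), call. = FALSE)
  }
  g <- gsub("−", "-", trimws(g))  # Unicode minus -> hyphen
  parts <- strsplit(g, "/", fixed = TRUE)[[1]]
  if (length(parts) != 2L || !all(parts %in% valid_alleles)) {
    stop(sprintf("malformed genotype call for %s: '%s' (valid alleles: %s)",
                 snp_name, genotype_string,
                 paste(valid_alleles, collapse = ", ")), call. = FALSE)
  }
  sort(parts)
}

#' Assign every patient to a genotype group for every SNP
#'
#' @param patients A cohort, patient list, or a genotype table (data frame
#'   with `patient_id` plus one column per SNP).
#'
#' @return Long tibble with `patient_id`, `snp`, `genotype`, `group`.  SNPs
#'   missing for a patient are omitted.
#' @export
genotype_groups <- function(patients) {
  geno <- if (is.data.frame(patients)) {
    patients
  } else {
    pl <- as_patient_list(patients)
    ids <- vapply(pl, function(p) p$patient_id, character(1))
    rows <- lapply(pl, function(p) as.list(p$genotypes))
    snps <- unique(unlist(lapply(rows, names)))
    out <- tibble::tibble(patient_id = ids)
    for (s in snps) {
      out[[s]] <- vapply(rows, function(r) {
        v <- r[[s]]
        if (is.null(v)) NA_character_ else as.character(v)
      }, character(1))
    }
    out
  }
  snp_cols <- setdiff(names(geno), "patient_id")
  pieces <- lapply(snp_cols, function(s) {
    keep <- !is.na(geno[[s]])
    calls <- as.character(geno[[s]][keep])
    # map unique calls only: a SNP has at most three distinct genotypes
    uniq <- unique(calls)
    lut <- vapply(uniq, function(g) group_genotype(s, g), character(1))
    tibble::tibble(
      patient_id = as.character(geno$patient_id[keep]),
      snp = tolower(s),
      genotype = calls,
      group = unname(lut[calls]))
  })
  do.call(rbind, pieces)
}
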
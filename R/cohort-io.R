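#' Write a cohort to the three pipeline CSV inputs
#'
#' Emits `visits.csv` (patient_id, month, t28, s28, vas, crp), `doses.csv`
#' (patient_id, start_month, end_month, weekly_dose_mg) and `genotypes.csv`
#' (patient_id plus one column per SNP holding calls such as `"G/A"`), in
#' the dialect the readers consume.  Doubles are written losslessly, so a
#' write/read round trip reproduces the numeric content exactly.
#'
#' @param cohort An `mtx_cohort` or list of `mtx_patient`.
#' @param dir Destination directory (created if missing).
#'
#' @return Invisibly, the three file paths.
#' @export
write_cohort <- function(cohort, dir) {
  pl <- as_patient_list(cohort)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  snps <- snp_groupings()$snp

  visits <- do.call(rbind, lapply(pl, function(p) {
    v <- p$visits
    tibble::tibble(patient_id = p$patient_id, month = v$month, t28 = v$t28,
                   s28 = v$s28, vas = v$vas, crp = v$crp)
  }))
  if (is.null(visits)) {
    visits <- tibble::tibble(patient_id = character(), month = numeric(),
                             t28 = integer(), s28 = integer(),
                             vas = numeric(), crp = numeric())
  }
  doses <- do.call(rbind, lapply(pl, function(p) {
    d <- p$doses
    tibble::tibble(patient_id = p$patient_id, start_month = d$start_month,
                   end_month = d$end_month, weekly_dose_mg = d$weekly_dose_mg)
  }))
  if (is.null(doses)) {
    doses <- tibble::tibble(patient_id = character(), start_month = numeric(),
                            end_month = numeric(), weekly_dose_mg = numeric())
  }
  geno <- tibble::tibble(patient_id = vapply(pl, function(p) p$patient_id,
                                             character(1)))
  for (s in snps) {
    geno[[s]] <- vapply(pl, function(p) {
      v <- unname(p$genotypes[s])
      if (length(v) != 1L || is.na(v)) NA_character_ else as.character(v)
    }, character(1))
  }
  if (length(pl) == 0L) geno <- geno[0, c("patient_id", snps)]

  paths <- file.path(dir, c("visits.csv", "doses.csv", "genotypes.csv"))
  readr::write_csv(visits, paths[1])
  readr::write_csv(doses, paths[2])
  readr::write_csv(geno, paths[3])
  invisible(paths)
}

#' Read the pipeline input tables
#'
#' @param path Path to the CSV file.
#' @return A tibble; `read_visits()` adds the derived `das28` column.
#' @export
read_visits <- function(path) {
  v <- read_pipeline_csv(path, c("patient_id", "month", "t28", "s28",
                                 "vas", "crp"),
                         readr::cols(patient_id = "c", .default = "d"))
  v$das28 <- das28_crp(v$t28, v$s28, v$vas, v$crp)
  v
}

#' @rdname read_visits
#' @export
read_doses <- function(path) {
  read_pipeline_csv(path, c("patient_id", "start_month", "end_month",
                            "weekly_dose_mg"),
                    readr::cols(patient_id = "c", .default = "d"))
}

#' @rdname read_visits
#' @export
read_genotypes <- function(path) {
  read_pipeline_csv(path, "patient_id", readr::cols(.default = "c"))
}

read_pipeline_csv <- function(path, required, col_types = NULL) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  x <- readr::read_csv(path, col_types = col_types, progress = FALSE)
  missing <- setdiff(required, names(x))
  if (length(missing)) {
    stop(sprintf("%s: missing required column(s): %s", basename(path),
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  x$patient_id <- as.character(x$patient_id)
  x
}

#' Assemble patient objects from the three input tables
#'
#' @param visits,doses,genotypes Tibbles as returned by [read_visits()],
#'   [read_doses()], [read_genotypes()], or paths to a directory's
#'   `visits.csv`, `doses.csv`, `genotypes.csv` via [read_cohort()].
#'
#' @return List of `mtx_patient`, ordered by first appearance in the visit
#'   table.  Patients lacking a baseline (month 0) visit are dropped with a
#'   warning naming them.
#' @export
assemble_patients <- function(visits, doses, genotypes = NULL) {
  ids <- unique(visits$patient_id)
  out <- list()
  dropped <- character()
  for (id in ids) {
    v <- visits[visits$patient_id == id, , drop = FALSE]
    v <- v[order(v$month), setdiff(names(v), "patient_id"), drop = FALSE]
    d <- doses[doses$patient_id == id,
               c("start_month", "end_month", "weekly_dose_mg"), drop = FALSE]
    g <- character()
    if (!is.null(genotypes) && id %in% genotypes$patient_id) {
      row <- genotypes[genotypes$patient_id == id, , drop = FALSE]
      snps <- setdiff(names(row), "patient_id")
      g <- stats::setNames(as.character(unlist(row[1, snps])), tolower(snps))
      g <- g[!is.na(g)]
    }
    p <- tryCatch(new_patient(id, v, d, g), error = function(e) {
      dropped <<- c(dropped, sprintf("%s (%s)", id, conditionMessage(e)))
      NULL
    })
    if (!is.null(p)) out[[length(out) + 1L]] <- p
  }
  if (length(dropped)) {
    warning("patients excluded while assembling cohort: ",
            paste(dropped, collapse = "; "), call. = FALSE)
  }
  out
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir Directory containing `visits.csv`, `doses.csv`,
#'   `genotypes.csv`.
#' @return List of `mtx_patient`.
#' @export
read_cohort <- function(dir) {
  assemble_patients(read_visits(file.path(dir, "visits.csv")),
                    read_doses(file.path(dir, "doses.csv")),
                    read_genotypes(file.path(dir, "genotypes.csv")))
}
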
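#' Pipeline run configuration
#'
#' Collects everything one end-to-end run needs: the input mode (simulate a
#' cohort, or read the three CSV inputs), the control criteria, the analysis
#' windows, the statistics options, and the output directory.  Exactly one
#' input mode is active.
#'
#' @param mode `"simulate"` or `"csv"`.
#' @param cohort A [cohort_config()] (simulate mode).
#' @param csv_dir Directory holding `visits.csv`, `doses.csv`,
#'   `genotypes.csv` (csv mode).
#' @param criteria A [control_criteria()].
#' @param windows Analysis windows for the response measures.
#' @param weeks_per_month See [cumulative_dose()].
#' @param stats_method,exact_cap Mann-Whitney options (see [mann_whitney()]).
#' @param out_dir Output directory for the report bundle; `NULL` for none.
#' @param seed Integer; overrides the cohort config seed so that all
#'   randomness in a run flows from one number.
#'
#' @return A `run_config` list.
#' @export
run_config <- function(mode = c("simulate", "csv"),
                       cohort = cohort_config(),
                       csv_dir = NULL,
                       criteria = control_criteria(),
                       windows = list(c(0, 3), c(0, 6)),
                       weeks_per_month = 4,
                       stats_method = "auto",
                       exact_cap = 40,
                       out_dir = NULL,
                       seed = NULL) {
  mode <- match.arg(mode)
  if (mode == "csv" && (is.null(csv_dir) || !dir.exists(csv_dir))) {
    stop("csv mode requires an existing csv_dir", call. = FALSE)
  }
  if (!is.null(seed)) cohort$seed <- as.integer(seed)
  structure(list(mode = mode, cohort = cohort, csv_dir = csv_dir,
                 criteria = criteria, windows = windows,
                 weeks_per_month = weeks_per_month,
                 stats_method = stats_method, exact_cap = exact_cap,
                 out_dir = out_dir),
            class = "run_config")
}

#' Run the full response analysis
#'
#' Simulates or ingests a cohort, computes per-patient response summaries
#' (cumulative dose, improved DAS28 area, index R over each window),
#' classifies disease control over months 6-12, assigns genotype groups,
#' builds the control-status and genotype comparison reports, and — when an
#' output directory is configured — writes the bundle:
#' `summaries.csv`, `labels.csv`, `groups.csv`, `table2.csv`, `table3.csv`
#' and `manifest.json`, the last recording every analysis convention
#' (quartile rule, months-to-weeks factor, control-rule mode, sidedness,
#' test method) alongside the configuration, for reproducibility.
#'
#' @param config A [run_config()].
#'
#' @return Invisibly, a list: `patients`, `true_labels` (simulate mode),
#'   `summaries`, `labels`, `groups`, `table2`, `table3`, `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (config$mode == "simulate") {
    cohort <- generate_cohort(config$cohort)
    patients <- cohort$patients
    true_labels <- cohort$true_labels
  } else {
    patients <- read_cohort(config$csv_dir)
    true_labels <- NULL
  }
  summaries <- response_summaries(patients, windows = config$windows,
                                  weeks_per_month = config$weeks_per_month)
  labels <- classify_cohort(patients, config$criteria)
  groups <- genotype_groups(patients)
  table2 <- build_table2(summaries, labels, method = config$stats_method,
                         exact_cap = config$exact_cap)
  table3 <- build_table3(summaries, groups, method = config$stats_method,
                         exact_cap = config$exact_cap)
  manifest <- build_manifest(config)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_csv(summaries, file.path(config$out_dir, "summaries.csv"))
    readr::write_csv(labels, file.path(config$out_dir, "labels.csv"))
    readr::write_csv(groups, file.path(config$out_dir, "groups.csv"))
    readr::write_csv(table2, file.path(config$out_dir, "table2.csv"))
    readr::write_csv(table3, file.path(config$out_dir, "table3.csv"))
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(list(patients = patients, true_labels = true_labels,
                 summaries = summaries, labels = labels, groups = groups,
                 table2 = table2, table3 = table3, manifest = manifest))
}

build_manifest <- function(config) {
  list(
    package = "mtxresponse",
    version = as.character(utils::packageVersion("mtxresponse")),
    mode = config$mode,
    seed = if (config$mode == "simulate") config$cohort$seed else NULL,
    conventions = list(
      quartile_rule = "linear interpolation at 1 + (n - 1) * q (quantile type 7)",
      weeks_per_month = config$weeks_per_month,
      control_rule = if (config$criteria$strict_mode)
        "strict: zero DAS28 exceedances allowed in the control window"
      else
        "average: fewer exceedances than the control-window length in months",
      das28_threshold = config$criteria$das28_threshold,
      control_window = config$criteria$window,
      require_fixed_dose = config$criteria$require_fixed_dose,
      sidedness = "two-sided",
      mw_method = config$stats_method,
      mw_exact_cap = config$exact_cap,
      reference_das28 = 10
    ),
    windows = lapply(config$windows, window_label),
    cohort_config = if (config$mode == "simulate")
      unclass(config$cohort) else NULL,
    csv_dir = config$csv_dir
  )
}

#' Read a pipeline configuration from a YAML file
#'
#' Flat keys mirror the arguments of [run_config()], [cohort_config()] and
#' [control_criteria()]; unknown keys are rejected.  See the packaged
#' example `system.file("extdata", "example-config.yaml",
#' package = "mtxresponse")`.
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- c("mode", "csv_dir", "out_dir", "seed", "weeks_per_month",
             "stats_method", "exact_cap", "strict_control", "cohort",
             "control")
  bad <- setdiff(names(y), known)
  if (length(bad)) {
    stop("unknown config key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  cohort <- do.call(cohort_config, as.list(y$cohort %||% list()))
  crit_args <- as.list(y$control %||% list())
  if (isTRUE(y$strict_control)) crit_args$strict_mode <- TRUE
  criteria <- do.call(control_criteria, crit_args)
  run_config(mode = y$mode %||% "simulate",
             cohort = cohort,
             csv_dir = y$csv_dir,
             criteria = criteria,
             weeks_per_month = y$weeks_per_month %||% 4,
             stats_method = y$stats_method %||% "auto",
             exact_cap = y$exact_cap %||% 40,
             out_dir = y$out_dir,
             seed = y$seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
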
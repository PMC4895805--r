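test_that("generation is deterministic given the seed and leaves the caller's
           RNG untouched", {
  cfg <- cohort_config(seed = 123)
  set.seed(99)
  a <- generate_cohort(cfg)
  nxt <- runif(1)
  set.seed(99)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  expect_identical(runif(1), nxt)   # RNG state restored after generation
  # a different seed changes the cohort
  c2 <- generate_cohort(cohort_config(seed = 124))
  expect_false(identical(a$patients, c2$patients))
})

test_that("cohort structure matches the configuration", {
  cfg <- cohort_config()
  co <- generate_cohort(cfg)
  expect_s3_class(co, "mtx_cohort")
  expect_length(co$patients, 21L)
  expect_equal(sum(co$true_labels == "good"), 7L)
  for (p in co$patients) {
    expect_equal(p$visits$month, as.numeric(0:12))
    expect_equal(p$visits$month[1], 0)
    expect_true(all(p$visits$t28 >= 0 & p$visits$t28 <= 28))
    expect_true(all(p$visits$vas >= 0 & p$visits$vas <= 100))
    expect_true(all(p$visits$crp >= 0))
    expect_equal(nrow(p$doses), 1L)
    expect_true(p$doses$weekly_dose_mg %in% cfg$weekly_dose_levels)
    expect_setequal(names(p$genotypes), snp_groupings()$snp)
  }
})

test_that("the stored DAS28 is exactly the formula applied to the stored
           components", {
  co <- generate_cohort(cohort_config(seed = 2))
  for (p in co$patients) {
    expect_equal(p$visits$das28,
                 das28_crp(p$visits$t28, p$visits$s28,
                           p$visits$vas, p$visits$crp))
  }
})

test_that("zero noise and zero decline give constant trajectories at
           baseline", {
  cfg <- cohort_config(measurement_noise_sd = 0, good_decline_rate = 0,
                       poor_decline_rate = 0, seed = 3)
  co <- generate_cohort(cfg)
  for (p in co$patients) {
    expect_equal(diff(range(p$visits$das28)), 0)
    # the constant sits near the intended baseline (rounding of the counts
    # moves it by at most one joint-count step)
    expect_lt(abs(p$visits$das28[1] - cfg$baseline_das28_mean), 1.5)
  }
})

test_that("invalid configurations are rejected with the offending field", {
  expect_error(cohort_config(n_good = 0), "n_good")
  expect_error(cohort_config(n_good = 21), "n_good")
  expect_error(cohort_config(visit_times = c(1, 2)), "visit_times")
  expect_error(cohort_config(visit_times = c(0, 2, 2)), "visit_times")
  expect_error(cohort_config(good_decline_rate = -1), "good_decline_rate")
  expect_error(cohort_config(measurement_noise_sd = -0.1),
               "measurement_noise_sd")
  expect_error(cohort_config(genotype_group_probabilities = c(rfc1_80 = 1.2)),
               "genotype_group_probabilities")
  expect_error(cohort_config(genotype_group_probabilities = c(bad_snp = 0.5)),
               "genotype_group_probabilities")
  expect_error(cohort_config(weekly_dose_levels = c(0, 8)),
               "weekly_dose_levels")
})

test_that("carrier-group frequency matches the configured probability over
           replicates", {
  # Monte-Carlo check of the binomial sampling against the 15/21 margin
  p_cfg <- 15 / 21
  frac <- vapply(1:500, function(r) {
    co <- generate_cohort(cohort_config(seed = r, visit_times = c(0, 1)))
    gg <- genotype_groups(co)
    mean(gg$group[gg$snp == "rfc1_80"] == "A allele")
  }, numeric(1))
  mc_se <- sqrt(p_cfg * (1 - p_cfg) / (500 * 21))
  expect_lt(abs(mean(frac) - p_cfg), 4 * mc_se)
})

test_that("a faster good-group decline raises the good group's index R", {
  mean_good_r <- function(rate) {
    rs <- vapply(1:30, function(r) {
      co <- generate_cohort(cohort_config(seed = r, good_decline_rate = rate))
      su <- response_summaries(co, windows = list(c(0, 6)))
      good <- co$true_labels == "good"
      ids <- vapply(co$patients[good], function(p) p$patient_id, character(1))
      mean(su$index_r[su$patient_id %in% ids])
    }, numeric(1))
    mean(rs)
  }
  expect_gt(mean_good_r(0.8), mean_good_r(0.4))
})

test_that("write_cohort round-trips through the readers losslessly", {
  dir <- withr::local_tempdir()
  co <- generate_cohort(cohort_config(seed = 7))
  paths <- write_cohort(co, dir)
  expect_true(all(file.exists(paths)))
  # visit row count: patients x scheduled visits
  visits <- read_visits(file.path(dir, "visits.csv"))
  expect_equal(nrow(visits), 21L * 13L)
  back <- read_cohort(dir)
  expect_length(back, 21L)
  for (i in seq_along(back)) {
    orig <- co$patients[[i]]
    expect_identical(back[[i]]$patient_id, orig$patient_id)
    expect_equal(back[[i]]$visits$das28, orig$visits$das28)
    expect_equal(back[[i]]$visits$crp, orig$visits$crp)
    expect_equal(back[[i]]$doses$weekly_dose_mg, orig$doses$weekly_dose_mg)
    expect_identical(sort(unname(back[[i]]$genotypes)),
                     sort(unname(orig$genotypes)))
  }
})

test_that("an empty patient list writes headers-only files", {
  dir <- withr::local_tempdir()
  write_cohort(list(), dir)
  expect_equal(nrow(read_visits(file.path(dir, "visits.csv"))), 0L)
  expect_equal(nrow(read_doses(file.path(dir, "doses.csv"))), 0L)
  expect_equal(nrow(read_genotypes(file.path(dir, "genotypes.csv"))), 0L)
})

test_that("patients without a baseline visit are dropped on assembly with a
           warning", {
  visits <- tibble::tibble(patient_id = c("A", "A", "B", "B"),
                           month = c(0, 3, 1, 3),
                           t28 = 4L, s28 = 4L, vas = 40, crp = 1)
  doses <- tibble::tibble(patient_id = c("A", "B"), start_month = 0,
                          end_month = 12, weekly_dose_mg = 8)
  expect_warning(pl <- assemble_patients(visits, doses), "B")
  expect_length(pl, 1L)
  expect_equal(pl[[1]]$patient_id, "A")
})
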
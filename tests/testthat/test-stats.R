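test_that("exact Mann-Whitney matches hand-enumerated separated samples", {
  mw <- mann_whitney(c(1, 2, 3), c(4, 5, 6), method = "exact")
  expect_equal(mw$u, 0)
  # 2 of the 20 equally likely assignments are at least as extreme
  expect_equal(mw$p_value, 0.1)
  # identical multisets: complete overlap
  expect_equal(mann_whitney(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  # all values identical: p = 1 by convention, flagged
  deg <- mann_whitney(c(2, 2), c(2, 2, 2))
  expect_equal(deg$p_value, 1)
  expect_match(deg$note, "identical")
})

test_that("exact p equals brute-force enumeration on a randomized battery", {
  set.seed(41)
  for (i in 1:60) {
    n1 <- sample(2:5, 1)
    n2 <- sample(2:5, 1)
    vals <- if (i %% 2 == 0) {
      round(runif(n1 + n2, 0, 4))          # heavy ties
    } else {
      rnorm(n1 + n2)                       # tie-free
    }
    x <- vals[seq_len(n1)]
    y <- vals[-seq_len(n1)]
    expect_equal(mann_whitney(x, y, method = "exact")$p_value,
                 bruteforce_mw_p(x, y), tolerance = 1e-12,
                 info = sprintf("case %d", i))
  }
})

test_that("exact method agrees with the classical exact distribution on
           tie-free samples", {
  set.seed(42)
  for (i in 1:20) {
    x <- rnorm(sample(3:8, 1))
    y <- rnorm(sample(3:8, 1))
    expect_equal(mann_whitney(x, y, method = "exact")$p_value,
                 stats::wilcox.test(x, y, exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
})

test_that("U statistics are symmetric and complementary", {
  set.seed(43)
  for (i in 1:20) {
    x <- round(rnorm(7), 1)
    y <- round(rnorm(9), 1)
    a <- mann_whitney(x, y)
    b <- mann_whitney(y, x)
    expect_equal(a$p_value, b$p_value, tolerance = 1e-12)
    expect_equal(a$u + b$u, a$n1 * a$n2)
    expect_gte(a$u, 0)
    expect_lte(a$u, a$n1 * a$n2)
  }
})

test_that("exact and approximate p agree on tie-free moderate samples", {
  set.seed(44)
  for (i in 1:10) {
    x <- rnorm(20)
    y <- rnorm(20, mean = runif(1, 0, 1))
    pe <- mann_whitney(x, y, method = "exact")$p_value
    pa <- mann_whitney(x, y, method = "approx")$p_value
    expect_lt(abs(pe - pa), 0.01)
  }
  # auto switches to the approximation above the cap
  big <- mann_whitney(rnorm(30), rnorm(30), method = "auto", exact_cap = 40)
  expect_equal(big$method_used, "normal-approx-tie-corrected")
})

test_that("rejection rate grows with the location shift", {
  set.seed(45)
  rate <- function(shift) {
    mean(replicate(150, {
      mann_whitney(rnorm(10), rnorm(10, shift))$p_value < 0.05
    }))
  }
  rates <- vapply(c(0, 1, 2.5), rate, numeric(1))
  expect_true(all(diff(rates) > 0))
  expect_lt(rates[1], 0.12)
  expect_gt(rates[3], 0.9)
})

test_that("quartile summaries use linear interpolation between order
           statistics", {
  s <- summarize_quartiles(1:5)
  expect_equal(s$median, 3)
  expect_equal(summarize_quartiles(c(0.22, 0.25, 0.27))$median, 0.25)
  # hand evaluation at positions 1 + (n - 1) q for n = 4: 1.75 and 3.25
  s4 <- summarize_quartiles(1:4)
  expect_equal(s4$q25, 1.75)
  expect_equal(s4$q75, 3.25)
  expect_equal(s4$median, 2.5)
  expect_error(summarize_quartiles(numeric()), "non-empty")
})

test_that("empty groups and mismatched labels are rejected", {
  expect_error(compare_groups(1:4, c("a", "a", "a", "a")), "two")
  expect_error(mann_whitney(numeric(), 1:3), "non-empty")
})

test_that("the control-status report has six comparisons with the expected
           structure", {
  co <- generate_cohort(cohort_config(seed = 9))
  su <- response_summaries(co)
  labs <- classify_cohort(co)
  t2 <- build_table2(su, labs)
  expect_equal(nrow(t2), 6L)
  expect_setequal(unique(t2$window), c("0-3", "0-6"))
  expect_equal(sum(t2$variable == "Index R (1/mg)"), 2L)
  expect_true(all(t2$p_value > 0 & t2$p_value <= 1))
  expect_true(all(t2$group1 == "good" & t2$group2 == "poor"))
  # missing label -> join error listing the id
  expect_error(build_table2(su, labs[-1, ]),
               labs$patient_id[1])
})

test_that("identical trajectories and doses give p = 1 everywhere", {
  pats <- lapply(1:8, function(i) {
    make_patient(sprintf("P%d", i), 0:12, seq(5, 2, length.out = 13))
  })
  su <- response_summaries(pats)
  labs <- tibble::tibble(patient_id = sprintf("P%d", 1:8),
                         control_status = rep(c("good", "poor"), 4))
  t2 <- build_table2(su, labs)
  expect_true(all(t2$p_value == 1))
})

test_that("the genotype report has one row per comparable SNP and skips
           empty groups with a warning", {
  co <- generate_cohort(cohort_config(seed = 9))
  su <- response_summaries(co)
  gg <- genotype_groups(co)
  t3 <- build_table3(su, gg)
  expect_equal(nrow(t3), 5L)
  expect_setequal(t3$snp, snp_groupings()$snp)
  # deterministic: same cohort, same report
  expect_identical(t3, build_table3(su, gg))
  # force one group empty
  gg2 <- gg
  gg2$group[gg2$snp == "mthfr_1298"] <- "A allele"
  expect_warning(t3b <- build_table3(su, gg2), "mthfr_1298")
  expect_equal(nrow(t3b), 4L)
})
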
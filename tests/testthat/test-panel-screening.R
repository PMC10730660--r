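test_that("panel coverage metrics follow the closed forms", {
  afs <- tibble::tibble(hgvs_c = c("a", "b"), af = c(0.003, 0.001))
  p1 <- design_panel(afs, k = 1)
  expect_equal(attr(p1, "allele_coverage"), 0.75)
  expect_equal(attr(p1, "patient_two_allele_coverage"), 0.5625)
  expect_equal(attr(p1, "patient_one_allele_coverage"), 1 - 0.25^2)
  expect_equal(p1$hgvs_c, "a")

  full <- design_panel(afs, k = 2)
  expect_equal(attr(full, "allele_coverage"), 1)
  expect_equal(attr(full, "patient_one_allele_coverage"), 1)
  expect_equal(attr(full, "patient_two_allele_coverage"), 1)

  expect_error(design_panel(afs, k = 3), "exceeds")
})

test_that("sites are ordered by descending AF with lexicographic ties", {
  afs <- tibble::tibble(
    hgvs_c = c("c.9G>A", "c.1A>G", "c.5C>T"), af = c(0.001, 0.002, 0.001)
  )
  p <- design_panel(afs, k = 3)
  expect_equal(p$hgvs_c, c("c.1A>G", "c.5C>T", "c.9G>A"))
})

test_that("a CNGP-style panel holding 90% of the AF mass covers ~81%/99% of patients", {
  sites <- cngp_panel_sites()
  afs <- tibble::tibble(
    hgvs_c = c(sites, sprintf("rare%02d", 1:20)),
    af = c(rep(0.9 * 0.0076 / 10, 10), rep(0.1 * 0.0076 / 20, 20))
  )
  p <- design_panel(afs, k = 10)
  expect_equal(attr(p, "allele_coverage"), 0.9, tolerance = 1e-9)
  expect_equal(attr(p, "patient_two_allele_coverage"), 0.81, tolerance = 1e-9)
  expect_equal(attr(p, "patient_one_allele_coverage"), 0.99, tolerance = 1e-9)
  expect_setequal(p$hgvs_c, sites)
})

test_that("coverage is non-decreasing in k and top-k maximizes it over all k-subsets", {
  afs <- withr::with_seed(13, tibble::tibble(
    hgvs_c = sprintf("v%02d", 1:9), af = runif(9, 1e-5, 5e-3)
  ))
  covs <- sapply(1:9, function(k) attr(design_panel(afs, k), "allele_coverage"))
  expect_true(all(diff(covs) > 0))
  for (k in c(2, 3, 4)) {
    best <- max(combn(afs$af, k, sum)) / sum(afs$af)
    expect_equal(attr(design_panel(afs, k), "allele_coverage"), best)
  }
})

test_that("the first-tier classifier implements the decision rules", {
  mk <- function(c0, hits, total = 2) {
    tibble::tibble(id = "x", c0_initial = c0, panel_hits = hits, total_plp_alleles = total)
  }
  expect_equal(classify_newborns(mk(4.0, 2))$tier1, "diagnosed_patient")
  expect_equal(classify_newborns(mk(12.0, 0, 0))$tier1, "negative")
  expect_equal(classify_newborns(mk(12.0, 1, 1))$tier1, "suspected_carrier")
  expect_equal(classify_newborns(mk(12.0, 2))$tier1, "suspected_patient")
  expect_equal(classify_newborns(mk(4.0, 1, 1))$tier1, "retest")
  expect_equal(classify_newborns(mk(4.0, 0, 0))$tier1, "retest")
  # boundary: C0 exactly at the cutoff takes the "higher" branch
  expect_equal(classify_newborns(mk(10.0, 0, 0))$tier1, "negative")

  expect_error(classify_newborns(mk(-1, 0, 0)), "positive")
  expect_error(classify_newborns(mk(5, 2, 1)), "panel_hits")
})

test_that("classification is total: every (C0, hits) pair maps to one tier", {
  grid <- tidyr::expand_grid(
    c0_initial = c(0.5, 5, 9.99, 10, 15, 40),
    panel_hits = 0:2
  ) |>
    dplyr::mutate(id = as.character(dplyr::row_number()), total_plp_alleles = 2L)
  out <- classify_newborns(grid)
  expect_true(all(out$tier1 %in% c(
    "diagnosed_patient", "suspected_patient", "suspected_carrier", "negative", "retest"
  )))
  expect_equal(nrow(out), nrow(grid))
})

test_that("second tier resolves suspected carriers and retests", {
  rec <- tibble::tibble(
    id = c("s_low2", "s_low1", "s_high", "r_low2", "r_high1", "r_na"),
    c0_initial = c(15, 15, 15, 4, 4, 4),
    c0_second = c(5, 5, 12, 5, 12, NA),
    panel_hits = c(1L, 1L, 1L, 1L, 1L, 0L),
    total_plp_alleles = c(2L, 1L, 1L, 2L, 1L, 0L)
  )
  out <- classify_newborns(rec)
  expect_equal(out$final[out$id == "s_low2"], "patient") # rescued at second tier
  expect_equal(out$final[out$id == "s_low1"], "carrier")
  expect_equal(out$final[out$id == "s_high"], "carrier")
  expect_equal(out$final[out$id == "r_low2"], "patient")
  expect_equal(out$final[out$id == "r_high1"], "carrier")
  expect_equal(out$final[out$id == "r_na"], "unresolved")
})

test_that("the 17-patient fixture reproduces the published screening metrics", {
  fix <- cngp_patient_fixture()
  comb <- screen_cohort(fix, cutoff = 10, mode = "combined")
  expect_equal(comb$tier1_positive_patients, 15)
  expect_equal(comb$tier1_positive_percent, 88.2)
  expect_equal(comb$suspected_carriers, 2)

  msms <- screen_cohort(fix, cutoff = 10, mode = "msms_only")
  expect_equal(msms$detected_patients, 15)
  expect_equal(msms$missed_patients, 2)
  expect_equal(round(100 * msms$missed_patients / msms$n_patients, 1), 11.8)

  # the combined algorithm rescues one MS/MS-missed patient at second tier
  expect_equal(comb$rescued, 1)
})

test_that("an all-negative cohort yields zero positives in both modes", {
  neg <- tibble::tibble(
    id = sprintf("n%02d", 1:20), true_status = "negative",
    c0_initial = seq(20, 40, length.out = 20),
    panel_hits = 0L, total_plp_alleles = 0L
  )
  expect_equal(screen_cohort(neg, mode = "combined")$tier1_positive_patients, 0)
  expect_equal(screen_cohort(neg, mode = "msms_only")$detected_patients, 0)
})

test_that("combined-mode detection is a superset of MS/MS-only detection", {
  for (seed in c(3, 4, 5)) {
    cfg <- sim_config(
      n_newborns = 4000, seed = seed,
      variant_afs = c("c.1400C>G" = 0.04, "c.760C>T" = 0.03)
    )
    cohort <- simulate_cohort(cfg)
    comb <- screen_cohort(cohort, mode = "combined")
    msms <- screen_cohort(cohort, mode = "msms_only")
    expect_gte(comb$detected_patients, msms$detected_patients)
    # no low-C0 patient is lost by adding genotype information
    out <- attr(comb, "outcomes")
    low_pat <- out$true_status == "patient" & out$c0_initial < 10
    expect_true(all(out$tier1[low_pat] == "diagnosed_patient"))
  }
})

test_that("rank-sum comparison: identical groups, enumeration oracle, small groups", {
  same <- compare_c0_groups(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p_value, 1)

  far <- compare_c0_groups(c(1, 2, 3), c(10, 11, 12))
  expect_equal(far$p_value, oracle_ranksum_p(c(1, 2, 3), c(10, 11, 12)))
  expect_equal(far$p_value, 0.1)

  tiny <- compare_c0_groups(c(5), c(1, 2))
  expect_true(is.na(tiny$p_value))
  expect_equal(tiny$mean_carriers, 5)
  expect_equal(tiny$mean_patients, 1.5)

  for (seed in 1:6) {
    withr::with_seed(seed, {
      x <- round(rlnorm(sample(2:6, 1), log(9), 0.3), 3)
      y <- round(rlnorm(sample(2:6, 1), log(4.3), 0.3), 3)
    })
    expect_equal(compare_c0_groups(x, y)$p_value, oracle_ranksum_p(x, y))
  }
})

test_that("second-tier C0 separation is detected in most simulated replicates", {
  # second-tier group sizes and centres as published: carriers n=3 at 9.01,
  # patients n=9 at 4.28 umol/L
  hits <- sapply(1:200, function(s) {
    withr::with_seed(s, {
      carriers <- rlnorm(3, log(9.01), 0.25)
      patients <- rlnorm(9, log(4.28), 0.25)
    })
    compare_c0_groups(carriers, patients)$p_value < 0.05
  })
  expect_gt(mean(hits), 0.5)
})
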
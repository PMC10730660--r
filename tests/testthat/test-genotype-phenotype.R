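mini_patients <- function() {
  tibble::tribble(
    ~id, ~age_group, ~allele1_hgvs, ~allele1_type, ~allele2_hgvs, ~allele2_type, ~phenotypes,
    "p1", "infant_child", "c.760C>T", "nonsense", "c.760C>T", "nonsense", "cardiomyopathy",
    "p2", "infant_child", "c.760C>T", "nonsense", "c.760C>T", "nonsense", "cardiomyopathy;hypoglycemia",
    "p3", "infant_child", "c.760C>T", "nonsense", "c.1400C>G", "missense", "",
    "p4", "adult", "c.1400C>G", "missense", "c.1400C>G", "missense", "asymptomatic",
    "p5", "adult", "c.1400C>G", "missense", "c.51C>G", "missense", "fatigue"
  )
}

test_that("validation derives zygosity and parses phenotype lists", {
  rec <- validate_patient_table(mini_patients())
  expect_equal(rec$zygosity, c(
    "homozygous", "homozygous", "compound_het", "homozygous", "compound_het"
  ))
  expect_equal(rec$phenotype_list[[2]], c("cardiomyopathy", "hypoglycemia"))
  expect_equal(rec$phenotype_list[[3]], character(0))

  dup <- mini_patients()
  dup$id[2] <- "p1"
  expect_error(validate_patient_table(dup), "Duplicate")
  bad <- mini_patients()
  bad$allele1_type[1] <- "weird"
  expect_error(validate_patient_table(bad), "mutation type")
})

test_that("grouping schemes partition patients as constructed", {
  rec <- validate_patient_table(mini_patients())
  hom760 <- group_patients(rec, "variant_homozygous", site = "c.760C>T")
  expect_equal(sum(hom760$in_group), 2)

  mm <- group_patients(rec, "type_combination", type_pair = c("missense", "missense"))
  expect_equal(sum(mm$in_group), 2)
  nm <- group_patients(rec, "type_combination", type_pair = c("nonsense", "missense"))
  expect_equal(sum(nm$in_group), 1)
  # order-insensitive pair
  expect_equal(
    group_patients(rec, "type_combination", type_pair = c("missense", "nonsense"))$in_group,
    nm$in_group
  )

  zy <- group_patients(rec, "zygosity")
  expect_equal(sum(zy$in_group), 3)

  all_hom <- rec[rec$zygosity == "homozygous", ]
  expect_equal(sum(!group_patients(all_hom, "zygosity")$in_group), 0)

  expect_error(group_patients(rec, "by_star_sign"), "Unknown scheme")
})

test_that("a cohort built to the published type-combination mix groups correctly", {
  n <- 293
  types <- c(rep("mm", 177), rep("nn", 43), rep("nm", 34), rep("ff", 29), rep("sf", 10))
  a1t <- c(mm = "missense", nn = "nonsense", nm = "nonsense", ff = "frameshift", sf = "splicing")
  a2t <- c(mm = "missense", nn = "nonsense", nm = "missense", ff = "frameshift", sf = "frameshift")
  rec <- validate_patient_table(tibble::tibble(
    id = sprintf("L%03d", 1:n), age_group = "infant_child",
    allele1_hgvs = sprintf("c.%dA>G", 1:n), allele1_type = unname(a1t[types]),
    allele2_hgvs = sprintf("c.%dC>T", 1:n), allele2_type = unname(a2t[types]),
    phenotypes = ""
  ))
  mm <- group_patients(rec, "type_combination", type_pair = c("missense", "missense"))
  expect_equal(sum(mm$in_group), 177)
  expect_equal(round(100 * mean(mm$in_group), 1), 60.4)
})

test_that("2x2 association: symmetry, infinite OR convention, and degenerate input", {
  sym <- test_association(matrix(c(1, 1, 1, 1), 2))
  expect_equal(sym$odds_ratio, 1)
  expect_equal(sym$p_value, 1)

  inf <- test_association(rbind(c(4, 0), c(6, 20)))
  expect_identical(inf$odds_ratio, Inf)

  zero <- test_association(rbind(c(0, 4), c(20, 6)))
  expect_identical(zero$odds_ratio, 0)

  expect_warning(und <- test_association(matrix(0, 2, 2)), "All-zero")
  expect_true(is.nan(und$odds_ratio))
  expect_equal(und$p_value, 1)
})

test_that("exact p and conditional-MLE OR match the brute-force oracles", {
  tab <- rbind(c(5, 5), c(2, 8))
  res <- test_association(tab)
  expect_equal(res$p_value, oracle_fisher_p(tab), tolerance = 1e-10)
  expect_equal(log(res$odds_ratio), log(oracle_or_cmle(tab)), tolerance = 5e-3)

  tabs <- withr::with_seed(31, replicate(40, matrix(sample(0:10, 4, replace = TRUE), 2), simplify = FALSE))
  for (tab in tabs) {
    impl <- pcdscreen:::fisher_stats_2x2(tab)
    orc_p <- oracle_fisher_p(tab)
    orc_or <- oracle_or_cmle(tab)
    if (is.nan(orc_or)) {
      expect_true(is.nan(impl$odds_ratio))
    } else if (!is.finite(orc_or) || orc_or == 0) {
      expect_identical(impl$odds_ratio, orc_or)
    } else {
      expect_equal(log(impl$odds_ratio), log(orc_or), tolerance = 5e-3)
    }
    expect_equal(impl$p_value, orc_p, tolerance = 1e-10)
  }
})

test_that("a single-test screen has q = p, and the screen ignores record order", {
  rec <- validate_patient_table(mini_patients())
  # restrict to a single homozygous site so the screen holds exactly one test
  single_site <- rec[rec$allele1_hgvs == "c.760C>T", ]
  one <- suppressMessages(run_association_screen(
    single_site,
    schemes = "variant_homozygous", phenotypes = "cardiomyopathy"
  ))
  expect_equal(nrow(one), 1)
  expect_equal(one$q_value, one$p_value)

  big <- random_patients(80, seed = 8, p_pheno_hom = 0.5, p_pheno_chet = 0.1)
  a <- suppressMessages(run_association_screen(validate_patient_table(big)))
  shuffled <- withr::with_seed(1, big[sample(nrow(big)), ])
  b <- suppressMessages(run_association_screen(validate_patient_table(shuffled)))
  expect_equal(
    a[order(a$group_label, a$phenotype), c("group_label", "phenotype", "p_value", "odds_ratio")],
    b[order(b$group_label, b$phenotype), c("group_label", "phenotype", "p_value", "odds_ratio")]
  )
})

test_that("null cohorts are essentially never flagged; real signal is", {
  # phenotypes independent of genotype: expected flagged fraction ~ 0 at q < 0.05
  flagged <- sapply(1:25, function(s) {
    rec <- validate_patient_table(
      random_patients(60, seed = 1000 + s, p_pheno_hom = 0.25, p_pheno_chet = 0.25)
    )
    res <- suppressMessages(run_association_screen(rec, schemes = "zygosity"))
    sum(res$q_value < 0.05)
  })
  expect_lt(mean(flagged > 0), 0.15)

  # homozygotes enriched for cardiomyopathy (0.6 vs 0.1) -> flagged with OR > 1
  rec <- validate_patient_table(
    random_patients(120, seed = 7, p_pheno_hom = 0.6, p_pheno_chet = 0.1)
  )
  res <- suppressMessages(run_association_screen(rec, schemes = "zygosity"))
  hit <- res[res$group_label == "homozygous" & res$phenotype == "cardiomyopathy", ]
  expect_lt(hit$q_value, 0.05)
  expect_gt(hit$odds_ratio, 1)
})

test_that("flag count is non-decreasing in the FDR threshold", {
  rec <- validate_patient_table(
    random_patients(100, seed = 21, p_pheno_hom = 0.55, p_pheno_chet = 0.15)
  )
  res <- suppressMessages(run_association_screen(rec))
  counts <- sapply(c(0.01, 0.05, 0.1, 0.2, 0.5), function(t) sum(res$q_value < t))
  expect_true(all(diff(counts) >= 0))
})

test_that("phenotype frequencies use exact arithmetic over the stratum denominator", {
  n <- 194
  rec <- validate_patient_table(tibble::tibble(
    id = sprintf("F%03d", 1:n), age_group = "infant_child",
    allele1_hgvs = "c.760C>T", allele1_type = "nonsense",
    allele2_hgvs = "c.1400C>G", allele2_type = "missense",
    phenotypes = c(
      rep("cardiomyopathy", 71), rep("hypoglycemia", 32), rep("hepatomegaly", 33),
      rep("", n - 71 - 32 - 33)
    )
  ))
  freq <- phenotype_frequencies(rec, age_group = "infant_child")
  expect_equal(freq$n[freq$phenotype == "cardiomyopathy"], 71L)
  # 71/194 = 36.6% at one decimal (exact arithmetic)
  expect_equal(freq$percent[freq$phenotype == "cardiomyopathy"], 36.6)
  expect_equal(freq$percent[freq$phenotype == "hypoglycemia"], 16.5)
  expect_equal(freq$percent[freq$phenotype == "hepatomegaly"], 17.0)
  expect_true(all(freq$denominator == 194))

  none <- phenotype_frequencies(rec, age_group = "infant_child", phenotypes = "cardiac_failure")
  expect_equal(none$n, 0L)

  expect_error(phenotype_frequencies(rec, age_group = "adult"), "No patient records")
})

test_that("treated-before-onset patients can be excluded from phenotype tests", {
  rec <- mini_patients()
  rec$treated_before_onset <- c(TRUE, FALSE, FALSE, FALSE, FALSE)
  rec <- validate_patient_table(rec)
  incl <- suppressMessages(run_association_screen(rec, schemes = "zygosity", phenotypes = "cardiomyopathy"))
  excl <- suppressMessages(run_association_screen(rec,
    schemes = "zygosity", phenotypes = "cardiomyopathy", exclude_treated = TRUE
  ))
  expect_equal(sum(incl$in_with + incl$out_with) / 2, 2)
  expect_equal(sum(excl$in_with + excl$out_with) / 2, 1)
})
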
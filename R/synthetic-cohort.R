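# Seeded synthetic neonatal cohorts with the statistical structure the
# screening analysis assumes: Hardy-Weinberg genotypes at configured allele
# frequencies, class-conditional lognormal C0, and maternal-transfer masking.

#' Build a simulation configuration
#'
#' Defaults emulate the CNGP study conditions: cohort size 17,864 with the
#' observed female fraction; the three printed hotspot allele frequencies
#' (c.1400C>G 1/239, c.51C>G 1/1,275, c.760C>T 1/1,322) with the remaining
#' frequency mass spread equally over the other seven panel sites so the
#' total carrier frequency is 1/66; class-conditional lognormal C0 with
#' medians at the published subgroup means (patients 5.27, low-C0 carriers
#' 6.47 umol/L; the negative-class median 25 umol/L is a free default chosen
#' well above the 10 umol/L cutoff) and scale 0.25 log-units; a
#' maternal-transfer masking rate of 2/17 (fraction of true patients whose
#' initial C0 is drawn from the negative distribution); 10/72 of carriers
#' drawn from the low-C0 carrier distribution; and second-tier drift toward
#' the printed follow-up means (patients 4.28, carriers 9.01 umol/L).
#'
#' @param n_newborns Cohort size.
#' @param female_fraction Probability a newborn is female.
#' @param variant_afs Named numeric vector of per-variant allele frequencies,
#'   all in (0, 0.05).
#' @param carrier_frequency Target total carrier frequency; used only to
#'   build the default `variant_afs` (total AF = carrier_frequency / 2).
#' @param c0_median Named list of class C0 medians (umol/L): `patient`,
#'   `carrier_low`, `negative`.
#' @param c0_sdlog Lognormal scale (log-units) shared by the classes.
#' @param maternal_mask_rate Fraction of true patients drawn with a
#'   negative-class initial C0.
#' @param carrier_low_fraction Fraction of carriers drawn from the low-C0
#'   carrier distribution (the rest look negative).
#' @param second_tier_median Named list of second-tier medians for `patient`
#'   and `carrier_low`; drift is applied multiplicatively.
#' @param masked_second_drop_rate Probability that a masked patient's
#'   second-tier C0 falls to the patient distribution (maternal carnitine
#'   waning); the rest stay normal.
#' @param treatment_median Named list of post-supplementation medians
#'   (`patient`, `carrier`), recorded for completeness.
#' @param cutoff C0 cutoff in umol/L.
#' @param panel_sites Panel variant names used to compute `panel_hits`.
#' @param seed Integer seed; all stage seeds derive from it.
#' @return A list of class `pcd_sim_config`.
#' @examples
#' cfg <- sim_config(n_newborns = 1000, seed = 7)
#' @export
sim_config <- function(n_newborns = 17864,
                       female_fraction = 7333 / 17864,
                       variant_afs = NULL,
                       carrier_frequency = 1 / 66,
                       c0_median = list(patient = 5.27, carrier_low = 6.47, negative = 25),
                       c0_sdlog = 0.25,
                       maternal_mask_rate = 2 / 17,
                       carrier_low_fraction = 10 / 72,
                       second_tier_median = list(patient = 4.28, carrier_low = 9.01),
                       masked_second_drop_rate = 0.5,
                       treatment_median = list(patient = 20.21, carrier = 18.61),
                       cutoff = 10,
                       panel_sites = cngp_panel_sites(),
                       seed = 1L) {
  check_number(n_newborns, "n_newborns", lower = 1)
  check_number(female_fraction, "female_fraction", lower = 0, upper = 1)
  check_number(maternal_mask_rate, "maternal_mask_rate", lower = 0, upper = 1 - 1e-12)
  check_number(carrier_low_fraction, "carrier_low_fraction", lower = 0, upper = 1)
  check_number(masked_second_drop_rate, "masked_second_drop_rate", lower = 0, upper = 1)
  check_number(c0_sdlog, "c0_sdlog", lower = 0)
  check_number(cutoff, "cutoff", lower = 1e-12)
  if (is.null(variant_afs)) {
    hot <- c("c.1400C>G" = 1 / 239, "c.51C>G" = 1 / 1275, "c.760C>T" = 1 / 1322)
    others <- setdiff(cngp_panel_sites(), names(hot))
    rest_mass <- carrier_frequency / 2 - sum(hot)
    if (rest_mass < 0) abort("`carrier_frequency` smaller than the hotspot AF mass.")
    variant_afs <- c(hot, setNames(rep(rest_mass / length(others), length(others)), others))
  }
  if (is.null(names(variant_afs)) || any(names(variant_afs) == "")) {
    abort("`variant_afs` must be a named vector.")
  }
  if (any(variant_afs <= 0 | variant_afs >= 0.05)) {
    abort("All allele frequencies must lie in (0, 0.05).")
  }
  medians <- unlist(c0_median)
  if (any(medians <= 0)) abort("C0 medians must be positive.")
  structure(list(
    n_newborns = as.integer(n_newborns),
    female_fraction = female_fraction,
    variant_afs = variant_afs,
    c0_median = c0_median,
    c0_sdlog = c0_sdlog,
    maternal_mask_rate = maternal_mask_rate,
    carrier_low_fraction = carrier_low_fraction,
    second_tier_median = second_tier_median,
    masked_second_drop_rate = masked_second_drop_rate,
    treatment_median = treatment_median,
    cutoff = cutoff,
    panel_sites = panel_sites,
    seed = as.integer(seed)
  ), class = "pcd_sim_config")
}

#' Simulate Hardy-Weinberg genotypes
#'
#' For each newborn and variant, two alleles are drawn independently
#' Bernoulli(AF) (independence across variants — random mating, no linkage),
#' so each variant's genotype counts follow Hardy-Weinberg proportions. The
#' true status is `patient` with two or more pathogenic alleles, `carrier`
#' with one, else `negative`. Fully determined by `config$seed`.
#'
#' @param config A `pcd_sim_config` (see [sim_config()]).
#' @return A tibble with `id`, `sex`, `n_alleles` (uncapped total),
#'   `total_plp_alleles` (capped at 2), `panel_hits`, `true_status`; the full
#'   per-variant allele-count matrix is in attribute `genotypes`.
#' @examples
#' g <- simulate_genotypes(sim_config(n_newborns = 500, seed = 3))
#' table(g$true_status)
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "pcd_sim_config"))
  afs <- config$variant_afs
  n <- config$n_newborns
  k <- length(afs)
  withr::with_seed(config$seed, {
    sex <- if_else(stats::runif(n) < config$female_fraction, "female", "male")
    geno <- matrix(
      rbinom(n * k, size = 2, prob = rep(afs, each = n)),
      nrow = n, ncol = k, dimnames = list(NULL, names(afs))
    )
  })
  total <- rowSums(geno)
  panel_cols <- intersect(colnames(geno), config$panel_sites)
  hits <- if (length(panel_cols)) rowSums(geno[, panel_cols, drop = FALSE]) else rep(0, n)
  out <- tibble(
    id = sprintf("N%06d", seq_len(n)),
    sex = sex,
    n_alleles = as.integer(total),
    total_plp_alleles = as.integer(pmin(2, total)),
    panel_hits = as.integer(pmin(pmin(2, hits), pmin(2, total))),
    true_status = dplyr::case_when(
      total >= 2 ~ "patient",
      total == 1 ~ "carrier",
      TRUE ~ "negative"
    )
  )
  attr(out, "genotypes") <- geno
  out
}

#' Simulate screening C0 values for a genotyped cohort
#'
#' Initial C0 is lognormal with a class-conditional median: patients draw
#' from the patient distribution except for a `maternal_mask_rate` fraction
#' that draws from the negative distribution (placental carnitine transfer
#' masking); a `carrier_low_fraction` of carriers draw from the low-C0
#' carrier distribution and the rest look negative. Second-tier C0 applies
#' the configured multiplicative drift (patients drop, low-C0 carriers rise
#' toward the published follow-up means); masked patients fall to the patient
#' second-tier distribution with probability `masked_second_drop_rate`.
#' Panel hits come from the genotype matrix and the configured panel.
#'
#' @param genotypes Output of [simulate_genotypes()].
#' @param config The same `pcd_sim_config`.
#' @return A newborn tibble ready for [classify_newborns()] /
#'   [screen_cohort()], with `c0_class` recording the generating component.
#' @export
simulate_c0 <- function(genotypes, config) {
  stopifnot(inherits(config, "pcd_sim_config"))
  n <- nrow(genotypes)
  med <- config$c0_median
  sdlog <- config$c0_sdlog
  withr::with_seed(config$seed + 1L, {
    u_mask <- stats::runif(n)
    u_low <- stats::runif(n)
    u_drop <- stats::runif(n)
    noise1 <- stats::rnorm(n, 0, sdlog)
    noise2 <- stats::rnorm(n, 0, sdlog / 2)
  })
  cls <- dplyr::case_when(
    genotypes$true_status == "patient" & u_mask < config$maternal_mask_rate ~ "masked_patient",
    genotypes$true_status == "patient" ~ "patient",
    genotypes$true_status == "carrier" & u_low < config$carrier_low_fraction ~ "carrier_low",
    TRUE ~ "negative"
  )
  base_median <- dplyr::case_when(
    cls == "patient" ~ med$patient,
    cls == "carrier_low" ~ med$carrier_low,
    TRUE ~ med$negative
  )
  c0_initial <- base_median * exp(noise1)
  drift <- dplyr::case_when(
    cls == "patient" ~ config$second_tier_median$patient / med$patient,
    cls == "carrier_low" ~ config$second_tier_median$carrier_low / med$carrier_low,
    cls == "masked_patient" & u_drop < config$masked_second_drop_rate ~
      config$second_tier_median$patient / med$negative,
    TRUE ~ 1
  )
  c0_second <- c0_initial * drift * exp(noise2)
  tibble(
    id = genotypes$id,
    sex = genotypes$sex,
    true_status = genotypes$true_status,
    c0_class = cls,
    c0_initial = c0_initial,
    c0_second = c0_second,
    panel_hits = genotypes$panel_hits,
    total_plp_alleles = genotypes$total_plp_alleles
  )
}

#' Simulate a complete newborn cohort
#'
#' [simulate_genotypes()] followed by [simulate_c0()] under one config.
#'
#' @inheritParams simulate_genotypes
#' @return A newborn tibble (see [simulate_c0()]); the genotype matrix is
#'   kept in attribute `genotypes`.
#' @examples
#' cohort <- simulate_cohort(sim_config(n_newborns = 1000, seed = 11))
#' @export
simulate_cohort <- function(config) {
  g <- simulate_genotypes(config)
  out <- simulate_c0(g, config)
  attr(out, "genotypes") <- attr(g, "genotypes")
  out
}

#' Validate prevalence recovery on synthetic cohorts
#'
#' For each replicate, simulates a genotyped cohort, excludes identified
#' patients (mirroring the study design), counts carriers by sex, and runs
#' the three prevalence estimators. Reports, per method, the mean estimated
#' rate, the bias against the true prevalence `(sum of AFs)^2`, the
#' Monte-Carlo standard error, and — for the Bayesian method — the empirical
#' coverage of its credible interval.
#'
#' @param config A `pcd_sim_config`; replicate r uses `config$seed + r`.
#' @param n_replicates Number of replicates.
#' @param ci_level Credible level for the Bayesian interval.
#' @return A tibble with one row per method plus attributes
#'   `true_rate` and `ci_coverage`.
#' @examples
#' \donttest{
#' end_to_end_recovery(sim_config(n_newborns = 20000, seed = 5), n_replicates = 20)
#' }
#' @export
end_to_end_recovery <- function(config, n_replicates = 100, ci_level = 0.95) {
  stopifnot(inherits(config, "pcd_sim_config"))
  check_number(n_replicates, "n_replicates", lower = 1)
  q_true <- sum(config$variant_afs)
  true_rate <- q_true^2
  res <- purrr::map(seq_len(n_replicates), function(r) {
    cfg <- config
    cfg$seed <- config$seed + r
    g <- simulate_genotypes(cfg)
    keep <- g$true_status != "patient"
    g <- g[keep, ]
    carriers_f <- sum(g$true_status == "carrier" & g$sex == "female")
    carriers_m <- sum(g$true_status == "carrier" & g$sex == "male")
    n_f <- sum(g$sex == "female")
    n_m <- sum(g$sex == "male")
    cohort <- cohort_counts(n_f + n_m, n_f, n_m, carriers_f, carriers_m)
    bay <- bayesian_prevalence(
      tibble(allele_count = carriers_f + carriers_m, allele_number = 2 * (n_f + n_m)),
      ci_level = ci_level
    )
    tibble(
      hw = hw_prevalence(cohort)$rate,
      permutation = permutation_prevalence(cohort)$rate,
      bayesian = bay$rate,
      covered = bay$ci_low_rate <= true_rate & true_rate <= bay$ci_high_rate
    )
  }) |> bind_rows()
  out <- tibble(
    method = c("hw", "permutation", "bayesian"),
    mean_rate = c(mean(res$hw), mean(res$permutation), mean(res$bayesian)),
    true_rate = true_rate,
    mc_se = c(sd(res$hw), sd(res$permutation), sd(res$bayesian)) / sqrt(n_replicates)
  ) |>
    mutate(bias = .data$mean_rate - .data$true_rate)
  attr(out, "true_rate") <- true_rate
  attr(out, "ci_coverage") <- mean(res$covered)
  out
}
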
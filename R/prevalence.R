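# Autosomal-recessive prevalence estimators from carrier counts and allele
# frequencies: Hardy-Weinberg, sex-stratified permutation-combination, and
# Beta-posterior Bayesian methods.

new_prevalence <- function(method, rate, ci_low = NA_real_, ci_high = NA_real_,
                           n = NA_real_, population = NA_character_) {
  out <- tibble(
    method = method,
    rate = rate,
    ratio_n = ratio_n(rate),
    ratio = ratio_string(rate),
    ci_low_rate = ci_low,
    ci_high_rate = ci_high,
    n = n,
    population = population
  )
  class(out) <- c("pcd_prevalence", class(out))
  out
}

#' Build a validated cohort-counts row
#'
#' A cohort is summarized by its size, sex strata, and the number of carriers
#' of at least one pathogenic allele in each stratum. Invariants:
#' `n_female + n_male == n_total` and carriers cannot exceed their stratum.
#'
#' @param n_total,n_female,n_male Cohort and stratum sizes.
#' @param carriers_female,carriers_male Carrier counts per stratum.
#' @return A one-row tibble.
#' @examples
#' cohort_counts(1000, 500, 500, 8, 7)
#' @export
cohort_counts <- function(n_total, n_female, n_male, carriers_female, carriers_male) {
  check_number(n_total, "n_total", lower = 0)
  check_number(n_female, "n_female", lower = 0)
  check_number(n_male, "n_male", lower = 0)
  if (n_female + n_male != n_total) {
    abort("`n_female` + `n_male` must equal `n_total`.")
  }
  check_number(carriers_female, "carriers_female", lower = 0, upper = n_female)
  check_number(carriers_male, "carriers_male", lower = 0, upper = n_male)
  tibble(
    n_total = n_total, n_female = n_female, n_male = n_male,
    carriers_female = carriers_female, carriers_male = carriers_male
  )
}

#' CNGP cohort carrier counts
#'
#' The published neonatal cohort summary: 17,864 neonates after excluding
#' identified/suspected patients (7,333 female / 10,531 male), with 125 female
#' and 144 male carriers of a P/LP allele. The source's running text and its
#' summary table disagree on which stratum is which sex; the table's
#' orientation is used here, and the permutation estimator is invariant to the
#' swap.
#'
#' @return A one-row cohort-counts tibble.
#' @examples
#' cngp_cohort()
#' @export
cngp_cohort <- function() {
  cohort_counts(
    n_total = 17864, n_female = 7333, n_male = 10531,
    carriers_female = 125, carriers_male = 144
  )
}

#' Read a cohort-counts TSV
#'
#' Expects columns `n_total`, `n_female`, `n_male`, `carriers_female`,
#' `carriers_male`.
#'
#' @param path Path to a TSV file.
#' @return A validated one-row cohort tibble.
#' @export
read_cohort_counts <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_double()), progress = FALSE)
  need <- c("n_total", "n_female", "n_male", "carriers_female", "carriers_male")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols)) {
    abort(paste0("Cohort file missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  cohort_counts(x$n_total[1], x$n_female[1], x$n_male[1], x$carriers_female[1], x$carriers_male[1])
}

#' Carrier frequency of a cohort
#'
#' Fraction of individuals carrying at least one pathogenic allele.
#'
#' @param cohort A cohort-counts tibble ([cohort_counts()]).
#' @return A one-row tibble with `rate` and its "1:N" rendering.
#' @examples
#' carrier_frequency(cngp_cohort()) # 1:66
#' @export
carrier_frequency <- function(cohort) {
  rate <- (cohort$carriers_female[1] + cohort$carriers_male[1]) / cohort$n_total[1]
  tibble(rate = rate, ratio_n = ratio_n(rate), ratio = ratio_string(rate))
}

#' Method 1: Hardy-Weinberg prevalence from carrier frequency
#'
#' Each carrier is counted as exactly one pathogenic allele (diagnosed or
#' suspected patients are excluded from the cohort beforehand), giving allele
#' frequency `q = carriers / (2 n)`; under Hardy-Weinberg equilibrium the
#' affected-birth rate is `q^2`.
#'
#' @param cohort A cohort-counts tibble.
#' @return A one-row `pcd_prevalence` tibble (`method = "hw"`).
#' @examples
#' hw_prevalence(cngp_cohort()) # 1:17641
#' @export
hw_prevalence <- function(cohort) {
  if (cohort$n_total[1] <= 0) abort("`n_total` must be positive.")
  carriers <- cohort$carriers_female[1] + cohort$carriers_male[1]
  q <- carriers / (2 * cohort$n_total[1])
  new_prevalence("hw", q^2, n = cohort$n_total[1])
}

#' Method 2: sex-stratified permutation-combination prevalence
#'
#' The probability that a random mating of a male carrier and a female carrier
#' produces an affected child: `(carriers_male / n_male) x
#' (carriers_female / n_female) x 1/4`. The estimate is invariant under
#' swapping the two sex strata wholesale, so an uncertain sex labelling does
#' not change it.
#'
#' @param cohort A cohort-counts tibble.
#' @return A one-row `pcd_prevalence` tibble (`method = "permutation"`).
#' @examples
#' permutation_prevalence(cngp_cohort()) # 1:17161
#' @export
permutation_prevalence <- function(cohort) {
  if (cohort$n_female[1] <= 0 || cohort$n_male[1] <= 0) {
    abort("Both sex strata must be non-empty.")
  }
  rate <- (cohort$carriers_male[1] / cohort$n_male[1]) *
    (cohort$carriers_female[1] / cohort$n_female[1]) / 4
  new_prevalence("permutation", rate, n = cohort$n_total[1])
}

#' Method 3: Bayesian prevalence from allele counts
#'
#' With a Beta(alpha, beta) prior on the pathogenic allele frequency `q` and
#' `AC` pathogenic alleles observed among `AN`, the posterior is
#' Beta(alpha + AC, beta + AN - AC). The point prevalence is the square of the
#' posterior mean of `q`, and the credible interval is obtained by squaring
#' the posterior quantiles of `q` (a monotone transform), either from the Beta
#' quantile function (default, deterministic) or from seeded Monte-Carlo
#' posterior draws.
#'
#' The default Jeffreys prior Beta(0.5, 0.5) reproduces the published point
#' estimate for the CNGP allele counts.
#'
#' @param counts A data frame with columns `allele_count` and `allele_number`
#'   (one row per population; optional `population` column is carried
#'   through).
#' @param prior_alpha,prior_beta Beta prior parameters (both > 0); default
#'   Jeffreys 0.5/0.5.
#' @param ci_level Credible level in (0, 1); default 0.95.
#' @param ci_method `"quantile"` (closed form, default) or `"montecarlo"`
#'   (empirical quantiles of squared posterior draws).
#' @param n_draws,seed Monte-Carlo settings, used only for
#'   `ci_method = "montecarlo"`.
#' @return A `pcd_prevalence` tibble, one row per input row
#'   (`method = "bayesian"`), with `ci_low_rate`/`ci_high_rate`.
#' @examples
#' bayesian_prevalence(data.frame(allele_count = 269, allele_number = 35728))
#' @export
bayesian_prevalence <- function(counts, prior_alpha = 0.5, prior_beta = 0.5,
                                ci_level = 0.95, ci_method = c("quantile", "montecarlo"),
                                n_draws = 1e5, seed = 1L) {
  ci_method <- match.arg(ci_method)
  check_number(prior_alpha, "prior_alpha", lower = .Machine$double.eps)
  check_number(prior_beta, "prior_beta", lower = .Machine$double.eps)
  check_number(ci_level, "ci_level", lower = 1e-9, upper = 1 - 1e-9)
  counts <- as_tibble(counts)
  if (!all(c("allele_count", "allele_number") %in% names(counts))) {
    abort("`counts` needs columns `allele_count` and `allele_number`.")
  }
  ac <- counts$allele_count
  an <- counts$allele_number
  if (any(an <= 0)) abort("`allele_number` must be positive.")
  if (any(ac < 0) || any(ac > an)) abort("`allele_count` must lie in [0, allele_number].")
  a <- prior_alpha + ac
  b <- prior_beta + an - ac
  post_mean <- a / (a + b)
  tail <- (1 - ci_level) / 2
  if (ci_method == "quantile") {
    lo <- qbeta(tail, a, b)^2
    hi <- qbeta(1 - tail, a, b)^2
  } else {
    qs <- withr::with_seed(seed, purrr::map(seq_along(a), function(i) {
      quantile(rbeta(n_draws, a[i], b[i])^2, c(tail, 1 - tail), names = FALSE)
    }))
    lo <- purrr::map_dbl(qs, 1)
    hi <- purrr::map_dbl(qs, 2)
  }
  new_prevalence(
    "bayesian", post_mean^2,
    ci_low = lo, ci_high = hi, n = an,
    population = if ("population" %in% names(counts)) counts$population else NA_character_
  )
}

#' Bayesian prevalence per population
#'
#' Applies [bayesian_prevalence()] to one allele-count row per population.
#' If the table carries per-variant rows (`variant` column), allele counts are
#' first aggregated within each population by summing `allele_count` over
#' variants (the shared `allele_number` of the population is used).
#'
#' @inheritParams bayesian_prevalence
#' @param counts A data frame with columns `population`, `allele_count`,
#'   `allele_number` (optionally `variant`).
#' @return A `pcd_prevalence` tibble keyed by `population`.
#' @export
multi_population_bayesian <- function(counts, prior_alpha = 0.5, prior_beta = 0.5,
                                      ci_level = 0.95, ...) {
  counts <- as_tibble(counts)
  if (!"population" %in% names(counts)) abort("`counts` needs a `population` column.")
  if ("variant" %in% names(counts)) {
    counts <- counts |>
      group_by(.data$population) |>
      summarise(
        allele_count = sum(.data$allele_count),
        allele_number = max(.data$allele_number),
        .groups = "drop"
      )
  }
  if (anyDuplicated(counts$population)) {
    abort("Duplicate population label in `counts`; aggregate per-variant rows first.")
  }
  bayesian_prevalence(counts,
    prior_alpha = prior_alpha, prior_beta = prior_beta,
    ci_level = ci_level, ...
  )
}

#' Average several prevalence estimates
#'
#' The combined estimate is the arithmetic mean of the input rates (the
#' convention used when reconciling the three estimation methods).
#'
#' @param estimates A `pcd_prevalence` tibble (one row per method).
#' @return A one-row `pcd_prevalence` tibble (`method = "average"`).
#' @export
average_prevalence <- function(estimates) {
  if (nrow(estimates) == 0) abort("Cannot average an empty set of estimates.")
  new_prevalence("average", mean(estimates$rate), n = max(estimates$n, na.rm = FALSE))
}

#' Estimate prevalence by all three methods plus their average
#'
#' Runs the Hardy-Weinberg (Method 1), permutation-combination (Method 2) and
#' Bayesian (Method 3) estimators on one cohort and appends their arithmetic
#' average. For Method 3 the cohort is converted to allele counts as
#' `AC = total carriers`, `AN = 2 n_total` (each carrier contributes exactly
#' one pathogenic allele).
#'
#' @param cohort A cohort-counts tibble.
#' @inheritParams bayesian_prevalence
#' @return A four-row `pcd_prevalence` tibble with attribute
#'   `carrier_frequency`.
#' @examples
#' estimate_prevalence(cngp_cohort())
#' @export
estimate_prevalence <- function(cohort, prior_alpha = 0.5, prior_beta = 0.5,
                                ci_level = 0.95, ...) {
  carriers <- cohort$carriers_female[1] + cohort$carriers_male[1]
  est <- bind_rows(
    hw_prevalence(cohort),
    permutation_prevalence(cohort),
    bayesian_prevalence(
      tibble(allele_count = carriers, allele_number = 2 * cohort$n_total[1]),
      prior_alpha = prior_alpha, prior_beta = prior_beta, ci_level = ci_level, ...
    )
  )
  out <- bind_rows(est, average_prevalence(est))
  attr(out, "carrier_frequency") <- carrier_frequency(cohort)
  if (!inherits(out, "pcd_prevalence")) class(out) <- c("pcd_prevalence", class(out))
  out
}

#' @exportS3Method generics::tidy
tidy.pcd_prevalence <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- setdiff(class(out), "pcd_prevalence")
  out
}

#' @exportS3Method generics::glance
glance.pcd_prevalence <- function(x, ...) {
  avg <- if ("average" %in% x$method) x[x$method == "average", ] else x
  cf <- attr(x, "carrier_frequency")
  tibble(
    n_methods = sum(x$method != "average"),
    rate = avg$rate[1],
    ratio = avg$ratio[1],
    carrier_frequency = if (!is.null(cf)) cf$ratio[1] else NA_character_
  )
}

#' @exportS3Method ggplot2::autoplot
autoplot.pcd_prevalence <- function(object, ...) {
  object <- as_tibble(object)
  object$label <- if_else(is.na(object$population) | object$population == "",
    object$method, paste0(object$population, " (", object$method, ")")
  )
  ggplot2::ggplot(object, ggplot2::aes(x = .data$label, y = .data$rate)) +
    ggplot2::geom_point(size = 2, colour = "firebrick") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$ci_low_rate, ymax = .data$ci_high_rate),
      width = 0.15, na.rm = TRUE
    ) +
    ggplot2::geom_text(ggplot2::aes(label = .data$ratio), vjust = -1, size = 3, na.rm = TRUE) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = NULL, y = "Affected births per birth (log scale)",
      title = "Estimated birth prevalence"
    ) +
    ggplot2::theme_minimal()
}
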
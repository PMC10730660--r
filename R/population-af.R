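# Cross-population allele-frequency comparison with FDR control.

# Fisher's exact test on a 2x2 table: two-sided p and the conditional
# maximum-likelihood odds ratio in one pass. Degenerate tables (a zero row or
# column margin) give p = 1 and an undefined OR.
fisher_stats_2x2 <- function(tab) {
  if (sum(tab) == 0 || any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    return(list(p_value = 1, odds_ratio = NaN))
  }
  ft <- fisher.test(tab)
  list(p_value = ft$p.value, odds_ratio = unname(ft$estimate))
}

# Two-sided test on a 2x2 allele table [[AC_a, AN_a-AC_a], [AC_b, AN_b-AC_b]].
# Chi-squared with continuity correction when every expected cell is >= 5,
# otherwise Fisher's exact test; degenerate tables give p = 1.
two_by_two_p <- function(tab) {
  if (sum(tab) == 0) {
    return(list(p_value = 1, test_used = "fisher"))
  }
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 5)) {
    list(p_value = fisher_stats_2x2(tab)$p_value, test_used = "fisher")
  } else {
    p <- suppressWarnings(chisq.test(tab, correct = TRUE)$p.value)
    list(p_value = p, test_used = "chi_squared")
  }
}

af_table <- function(ac_a, an_a, ac_b, an_b) {
  matrix(c(ac_a, an_a - ac_a, ac_b, an_b - ac_b), nrow = 2, byrow = TRUE)
}

#' Compare one variant's allele frequency between two populations
#'
#' Builds the 2x2 allele table (carrier vs non-carrier alleles in each
#' population) and tests frequency equality: chi-squared with continuity
#' correction when all expected cells are at least 5, Fisher's exact test
#' otherwise. The direction candidate records which population has the higher
#' sample frequency; it becomes a call only after FDR adjustment in
#' [screen_populations()].
#'
#' @param counts A data frame with columns `hgvs_c` (or `variant`),
#'   `population`, `allele_count`, `allele_number`.
#' @param variant HGVS c. name of the variant to compare.
#' @param pop_a,pop_b Population labels present in `counts`.
#' @return A one-row tibble with `af_a`, `af_b`, `p_value`, `test_used` and
#'   `direction_candidate`.
#' @export
compare_af <- function(counts, variant, pop_a, pop_b) {
  counts <- normalize_count_table(counts)
  a <- counts[counts$hgvs_c == variant & counts$population == pop_a, ]
  b <- counts[counts$hgvs_c == variant & counts$population == pop_b, ]
  if (nrow(a) != 1 || nrow(b) != 1) {
    abort(paste0("Variant ", variant, " needs exactly one row in each of ", pop_a, ", ", pop_b, "."))
  }
  if (a$allele_number <= 0 || b$allele_number <= 0) abort("`allele_number` must be positive.")
  res <- two_by_two_p(af_table(a$allele_count, a$allele_number, b$allele_count, b$allele_number))
  af_a <- a$allele_count / a$allele_number
  af_b <- b$allele_count / b$allele_number
  tibble(
    hgvs_c = variant, pop_a = pop_a, pop_b = pop_b,
    af_a = af_a, af_b = af_b,
    p_value = res$p_value, test_used = res$test_used,
    direction_candidate = dplyr::case_when(
      af_a > af_b ~ "higher_in_a",
      af_a < af_b ~ "lower_in_a",
      TRUE ~ "none"
    )
  )
}

normalize_count_table <- function(counts) {
  counts <- as_tibble(counts)
  if (!"hgvs_c" %in% names(counts) && "variant" %in% names(counts)) {
    counts <- rename(counts, hgvs_c = "variant")
  }
  need <- c("hgvs_c", "population", "allele_count", "allele_number")
  missing_cols <- setdiff(need, names(counts))
  if (length(missing_cols)) {
    abort(paste0("Count table missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  counts$hgvs_c <- normalize_hgvs(counts$hgvs_c)
  counts
}

#' Read an allele-count table from TSV
#'
#' Columns: `variant` (or `hgvs_c`), `population`, `allele_count`,
#' `allele_number`.
#'
#' @param path Path to a TSV file.
#' @return A tibble with normalized `hgvs_c` names.
#' @export
read_allele_counts <- function(path) {
  x <- readr::read_tsv(path,
    col_types = readr::cols(
      .default = readr::col_character(),
      allele_count = readr::col_double(),
      allele_number = readr::col_double()
    ), progress = FALSE
  )
  normalize_count_table(x)
}

#' Screen all variants for allele-frequency differences between populations
#'
#' For every variant with counts in both the target population and the
#' reference(s), tests allele-frequency equality ([compare_af()]) and adjusts
#' the p-values across the whole screen by Benjamini-Hochberg. A direction
#' (`higher_in_a` / `lower_in_a`, where "a" is the target) is called only
#' where `q_value < threshold`.
#'
#' @param counts Allele-count table (see [compare_af()]).
#' @param target Target population label (population "a").
#' @param refs Character vector of reference population labels; default all
#'   non-target populations.
#' @param threshold FDR threshold for direction calls (default 0.05).
#' @param pool_refs If `TRUE` (default) reference counts are pooled by summing
#'   AC and AN per variant; otherwise each reference is screened separately.
#' @return A tibble of comparison results sorted by `q_value`.
#' @export
screen_populations <- function(counts, target, refs = NULL, threshold = 0.05,
                               pool_refs = TRUE) {
  check_number(threshold, "threshold", lower = 0, upper = 1)
  counts <- normalize_count_table(counts)
  refs <- refs %||% setdiff(unique(counts$population), target)
  if (!target %in% counts$population) abort(paste0("Target population ", target, " not in counts."))
  ref_counts <- counts[counts$population %in% refs, ]
  if (pool_refs && length(refs) > 1) {
    ref_counts <- ref_counts |>
      group_by(.data$hgvs_c) |>
      summarise(
        allele_count = sum(.data$allele_count),
        allele_number = sum(.data$allele_number),
        .groups = "drop"
      ) |>
      mutate(population = paste(sort(refs), collapse = "+"))
  }
  tgt <- counts[counts$population == target, ]
  pairs <- dplyr::inner_join(tgt, ref_counts,
    by = "hgvs_c", suffix = c("_a", "_b"), relationship = "many-to-many"
  )
  skipped <- setdiff(unique(c(tgt$hgvs_c, ref_counts$hgvs_c)), pairs$hgvs_c)
  if (length(skipped)) {
    inform(paste0(
      "Skipping ", length(skipped),
      " variant(s) present in only one side: ",
      paste(head(skipped, 5), collapse = ", ")
    ))
  }
  if (nrow(pairs) == 0) abort("No variant has counts in both populations.")
  tests <- purrr::pmap(
    list(pairs$allele_count_a, pairs$allele_number_a, pairs$allele_count_b, pairs$allele_number_b),
    function(aca, ana, acb, anb) two_by_two_p(af_table(aca, ana, acb, anb))
  )
  out <- tibble(
    hgvs_c = pairs$hgvs_c,
    pop_a = target,
    pop_b = pairs$population_b,
    af_a = pairs$allele_count_a / pairs$allele_number_a,
    af_b = pairs$allele_count_b / pairs$allele_number_b,
    p_value = purrr::map_dbl(tests, "p_value"),
    test_used = purrr::map_chr(tests, "test_used")
  ) |>
    mutate(
      q_value = p.adjust(.data$p_value, method = "BH"),
      direction = dplyr::case_when(
        .data$q_value >= threshold ~ "none",
        .data$af_a > .data$af_b ~ "higher_in_a",
        .data$af_a < .data$af_b ~ "lower_in_a",
        TRUE ~ "none"
      )
    ) |>
    arrange(.data$q_value, .data$p_value, .data$hgvs_c)
  class(out) <- c("pcd_af_screen", class(out))
  out
}

#' @exportS3Method ggplot2::autoplot
autoplot.pcd_af_screen <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$af_b, y = .data$af_a, colour = .data$direction
  )) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_x_sqrt() +
    ggplot2::scale_y_sqrt() +
    ggplot2::scale_colour_manual(values = c(
      higher_in_a = "firebrick", lower_in_a = "dodgerblue3", none = "grey50"
    )) +
    ggplot2::labs(
      x = "Reference allele frequency", y = "Target allele frequency",
      title = "Per-variant allele-frequency comparison", colour = "Call"
    ) +
    ggplot2::theme_minimal()
}

#' Render an allele frequency as "1:N or F"
#'
#' The dual rendering used for variant frequencies: the nearest-integer
#' reciprocal and the frequency to two significant figures.
#'
#' @param af Allele frequency in (0, 1].
#' @return A string such as `"1:239 or 0.0042"`.
#' @examples
#' af_ratio_string(1 / 1965)
#' @export
af_ratio_string <- function(af) {
  check_number(af, "af", lower = 1e-300, upper = 1)
  f <- signif(af, 2)
  digits <- max(0L, 1L - as.integer(floor(log10(f))))
  paste0("1:", format(round_half_up(1 / af), scientific = FALSE, trim = TRUE),
    " or ", sprintf("%.*f", digits, f))
}
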
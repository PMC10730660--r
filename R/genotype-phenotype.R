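# Genotype-phenotype association screen: group biallelic patients by variant
# site, mutation-type combination, or zygosity and test phenotype
# over-representation with exact 2x2 tests under FDR control.

age_group_levels <- c("infant_child", "adult")
scheme_levels <- c("variant_homozygous", "type_combination", "zygosity")

#' Default phenotype vocabulary
#'
#' Common manifestations of carnitine-transport deficiency used by the
#' association screen when no explicit phenotype list is given. User-supplied
#' vocabularies simply replace it.
#'
#' @return Character vector of phenotype labels.
#' @export
default_phenotypes <- function() {
  c(
    "cardiomyopathy", "cardiac_failure", "hypoglycemia", "hyperammonemia",
    "hepatomegaly", "elevated_ALT", "fatigue", "asymptomatic",
    "growth_retardation", "metabolic_decompensation"
  )
}

parse_phenotypes <- function(x) {
  purrr::map(stringr::str_split(x %||% "", ";"), function(p) {
    p <- stringr::str_trim(p)
    p[p != ""]
  })
}

#' Validate a patient table
#'
#' Each patient carries exactly two pathogenic alleles (`allele1`, `allele2`);
#' zygosity is derived: homozygous iff the two HGVS names coincide. The
#' `phenotypes` column (semicolon-separated labels) is parsed into a list
#' column `phenotype_list`.
#'
#' @param records Data frame with columns `id`, `age_group`, `allele1_hgvs`,
#'   `allele1_type`, `allele2_hgvs`, `allele2_type`, `phenotypes`; optional
#'   logical `treated_before_onset`.
#' @return A validated tibble with derived `zygosity` and `phenotype_list`.
#' @export
validate_patient_table <- function(records) {
  records <- as_tibble(records)
  need <- c("id", "age_group", "allele1_hgvs", "allele1_type", "allele2_hgvs", "allele2_type", "phenotypes")
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols)) {
    abort(paste0("Patient table missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(records$id)) abort("Duplicate patient id.")
  if (!all(records$age_group %in% age_group_levels)) {
    abort("`age_group` must be 'infant_child' or 'adult'.")
  }
  bad_type <- !(records$allele1_type %in% mutation_type_levels) |
    !(records$allele2_type %in% mutation_type_levels)
  if (any(bad_type)) {
    abort(paste0("Unknown mutation type in row(s): ", paste(which(bad_type), collapse = ", ")))
  }
  records$allele1_hgvs <- normalize_hgvs(records$allele1_hgvs)
  records$allele2_hgvs <- normalize_hgvs(records$allele2_hgvs)
  records$zygosity <- if_else(records$allele1_hgvs == records$allele2_hgvs,
    "homozygous", "compound_het"
  )
  records$phenotype_list <- parse_phenotypes(records$phenotypes)
  if (!"treated_before_onset" %in% names(records)) {
    records$treated_before_onset <- FALSE
  }
  records
}

#' Read a patient table from TSV
#'
#' @param path TSV with columns `id`, `age_group`, `allele1_hgvs`,
#'   `allele1_type`, `allele2_hgvs`, `allele2_type`, `phenotypes`
#'   (semicolon-separated).
#' @return A validated patient tibble (see [validate_patient_table()]).
#' @export
read_patient_table <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()), progress = FALSE)
  if ("treated_before_onset" %in% names(x)) {
    x$treated_before_onset <- as.logical(x$treated_before_onset)
  }
  validate_patient_table(x)
}

#' Partition patients into an in-group and out-group
#'
#' Grouping schemes:
#' * `variant_homozygous`: in-group = patients homozygous for `site`; the
#'   out-group is everyone with a combination of other variant sites.
#' * `type_combination`: in-group = patients whose unordered pair of allele
#'   mutation types equals `type_pair`.
#' * `zygosity`: homozygous vs compound heterozygous.
#'
#' @param records A validated patient tibble.
#' @param scheme One of `"variant_homozygous"`, `"type_combination"`,
#'   `"zygosity"`.
#' @param site HGVS c. name (for `variant_homozygous`).
#' @param type_pair Character vector of length 2 (for `type_combination`),
#'   order-insensitive.
#' @return `records` with a logical `in_group` column.
#' @export
group_patients <- function(records, scheme, site = NULL, type_pair = NULL) {
  if (!scheme %in% scheme_levels) {
    abort(paste0("Unknown scheme '", scheme, "'; use one of: ", paste(scheme_levels, collapse = ", ")))
  }
  records <- as_tibble(records)
  records$in_group <- switch(scheme,
    variant_homozygous = {
      if (is.null(site)) abort("`site` is required for scheme 'variant_homozygous'.")
      site <- normalize_hgvs(site)
      records$zygosity == "homozygous" & records$allele1_hgvs == site
    },
    type_combination = {
      if (is.null(type_pair) || length(type_pair) != 2) {
        abort("`type_pair` (length 2) is required for scheme 'type_combination'.")
      }
      want <- paste(sort(type_pair), collapse = "+")
      have <- purrr::map2_chr(
        records$allele1_type, records$allele2_type,
        function(a, b) paste(sort(c(a, b)), collapse = "+")
      )
      have == want
    },
    zygosity = records$zygosity == "homozygous"
  )
  records
}

#' Test phenotype over-representation on one 2x2 table
#'
#' The table is `[[in&pheno, in&no], [out&pheno, out&no]]`. The p-value
#' follows the same rule as the allele-frequency screen (chi-squared with
#' continuity correction when all expected cells are at least 5, Fisher's
#' exact test otherwise). The odds ratio is always the conditional
#' maximum-likelihood estimate from the exact test, so a structural zero
#' yields exactly 0 or `Inf` — no continuity (Haldane) correction is applied.
#' An all-zero table returns `p = 1`, `OR = NaN` with a warning.
#'
#' @param tab A 2x2 matrix (or length-4 vector, column-major) of non-negative
#'   integers.
#' @return A one-row tibble with `odds_ratio`, `p_value`, `test_used`.
#' @examples
#' test_association(matrix(c(4, 6, 0, 20), nrow = 2)) # OR = Inf
#' @export
test_association <- function(tab) {
  tab <- matrix(as.numeric(tab), nrow = 2)
  if (any(tab < 0) || any(tab != round(tab))) abort("2x2 table must hold non-negative integers.")
  if (sum(tab) == 0) {
    warn("All-zero 2x2 table; association undefined.")
    return(tibble(odds_ratio = NaN, p_value = 1, test_used = "fisher"))
  }
  res <- two_by_two_p(tab)
  tibble(
    odds_ratio = fisher_stats_2x2(tab)$odds_ratio,
    p_value = res$p_value, test_used = res$test_used
  )
}

count_phenotype <- function(plist, phenotype) {
  purrr::map_lgl(plist, function(p) phenotype %in% p)
}

#' Run the full genotype-phenotype association screen
#'
#' One exact 2x2 test per (group, phenotype) pair: groups are every variant
#' site observed homozygous (`variant_homozygous`), every observed unordered
#' mutation-type pair (`type_combination`), and homozygous vs compound-het
#' (`zygosity`). p-values are Benjamini-Hochberg adjusted across the whole
#' screen; results are sorted by `q_value`. Odds ratios are conditional
#' maximum-likelihood estimates, so a structural zero prints as `Inf` or 0
#' exactly.
#'
#' @param records A validated patient tibble.
#' @param schemes Subset of the three schemes to run (default all).
#' @param phenotypes Phenotype vocabulary (default [default_phenotypes()]);
#'   phenotypes absent from every record are skipped with a message.
#' @param exclude_treated If `TRUE`, patients treated before symptom onset are
#'   dropped before testing (default `FALSE`, matching published
#'   denominators).
#' @return A tibble of class `pcd_assoc` with one row per test, columns
#'   `scheme`, `group_label`, `phenotype`, the four table cells,
#'   `odds_ratio`, `p_value`, `q_value`, `test_used`.
#' @export
run_association_screen <- function(records, schemes = scheme_levels,
                                   phenotypes = default_phenotypes(),
                                   exclude_treated = FALSE) {
  if (length(schemes) == 0 || !all(schemes %in% scheme_levels)) {
    abort(paste0("`schemes` must be drawn from: ", paste(scheme_levels, collapse = ", ")))
  }
  if (length(phenotypes) == 0) abort("Need at least one phenotype.")
  records <- as_tibble(records)
  if (exclude_treated) records <- records[!records$treated_before_onset, ]
  seen <- unique(unlist(records$phenotype_list))
  absent <- setdiff(phenotypes, seen)
  if (length(absent)) {
    inform(paste0("Skipping phenotype(s) absent from every record: ", paste(absent, collapse = ", ")))
    phenotypes <- intersect(phenotypes, seen)
  }
  if (length(phenotypes) == 0) abort("No listed phenotype occurs in the records.")

  groupings <- list()
  if ("variant_homozygous" %in% schemes) {
    hom_sites <- sort(unique(records$allele1_hgvs[records$zygosity == "homozygous"]))
    for (s in hom_sites) {
      groupings[[length(groupings) + 1]] <- list(
        scheme = "variant_homozygous", label = paste0("homozygous ", s),
        in_group = group_patients(records, "variant_homozygous", site = s)$in_group
      )
    }
  }
  if ("type_combination" %in% schemes) {
    pairs <- sort(unique(purrr::map2_chr(
      records$allele1_type, records$allele2_type,
      function(a, b) paste(sort(c(a, b)), collapse = "+")
    )))
    for (p in pairs) {
      tp <- stringr::str_split(p, "\\+")[[1]]
      groupings[[length(groupings) + 1]] <- list(
        scheme = "type_combination", label = p,
        in_group = group_patients(records, "type_combination", type_pair = tp)$in_group
      )
    }
  }
  if ("zygosity" %in% schemes) {
    ing <- group_patients(records, "zygosity")$in_group
    groupings[[length(groupings) + 1]] <- list(
      scheme = "zygosity", label = "homozygous", in_group = ing
    )
    groupings[[length(groupings) + 1]] <- list(
      scheme = "zygosity", label = "compound_het", in_group = !ing
    )
  }

  rows <- purrr::map(groupings, function(g) {
    purrr::map(phenotypes, function(ph) {
      has <- count_phenotype(records$phenotype_list, ph)
      tab <- matrix(c(
        sum(g$in_group & has), sum(g$in_group & !has),
        sum(!g$in_group & has), sum(!g$in_group & !has)
      ), nrow = 2, byrow = TRUE)
      res <- test_association(tab)
      tibble(
        scheme = g$scheme, group_label = g$label, phenotype = ph,
        in_with = tab[1, 1], in_without = tab[1, 2],
        out_with = tab[2, 1], out_without = tab[2, 2],
        odds_ratio = res$odds_ratio, p_value = res$p_value,
        test_used = res$test_used
      )
    }) |> bind_rows()
  }) |> bind_rows()

  rows <- rows |>
    mutate(q_value = p.adjust(.data$p_value, method = "BH")) |>
    arrange(.data$q_value, .data$p_value, .data$group_label, .data$phenotype) |>
    select(
      "scheme", "group_label", "phenotype", "in_with", "in_without",
      "out_with", "out_without", "odds_ratio", "p_value", "q_value", "test_used"
    )
  class(rows) <- c("pcd_assoc", class(rows))
  rows
}

#' @exportS3Method generics::tidy
tidy.pcd_assoc <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- setdiff(class(out), "pcd_assoc")
  out
}

#' @exportS3Method generics::glance
glance.pcd_assoc <- function(x, threshold = 0.05, ...) {
  tibble(
    n_tests = nrow(x),
    n_flagged = sum(x$q_value < threshold),
    min_q = min(x$q_value)
  )
}

#' @exportS3Method ggplot2::autoplot
autoplot.pcd_assoc <- function(object, threshold = 0.05, ...) {
  object <- as_tibble(object)
  object$log_or <- log2(pmax(pmin(object$odds_ratio, 64), 1 / 64))
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$log_or, y = -log10(.data$q_value),
    colour = .data$q_value < threshold
  )) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = -log10(threshold), linetype = 2, colour = "grey50") +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "firebrick", `FALSE` = "grey60"), guide = "none") +
    ggplot2::labs(
      x = "log2 odds ratio (clamped at ±6)", y = "-log10 q-value",
      title = "Genotype-phenotype association screen"
    ) +
    ggplot2::theme_minimal()
}

#' Phenotype frequencies within an age stratum
#'
#' Per-phenotype counts over the stratum denominator, with percentages to one
#' decimal (half-up). Exact arithmetic is reported; published tables
#' occasionally differ in the last decimal.
#'
#' @param records A validated patient tibble.
#' @param age_group `"infant_child"`, `"adult"`, or `NULL` for everyone.
#' @param phenotypes Vocabulary to tabulate (default [default_phenotypes()]).
#' @return A tibble with `phenotype`, `n`, `denominator`, `percent`.
#' @export
phenotype_frequencies <- function(records, age_group = NULL,
                                  phenotypes = default_phenotypes()) {
  records <- as_tibble(records)
  if (!is.null(age_group)) {
    if (!age_group %in% age_group_levels) abort("Unknown `age_group`.")
    records <- records[records$age_group == age_group, ]
  }
  if (nrow(records) == 0) abort("No patient records in the requested stratum.")
  denom <- nrow(records)
  tibble(
    phenotype = phenotypes,
    n = purrr::map_int(phenotypes, function(ph) sum(count_phenotype(records$phenotype_list, ph))),
    denominator = denom
  ) |>
    mutate(percent = round_half_up(100 * .data$n / denom, 1))
}
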
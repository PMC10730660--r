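# Curated pathogenic-variant catalog: loading, validation, spectrum summaries.

catalog_columns <- c(
  "hgvs_c", "hgvs_p", "location_kind", "exon_number",
  "domain", "mutation_type", "acmg_class"
)

location_levels <- c("exon", "intron")
domain_levels <- c("transmembrane", "non_transmembrane", "unassigned")
mutation_type_levels <- c(
  "missense", "frameshift", "nonsense", "splicing", "inframe_indel", "start_loss"
)
acmg_levels <- c("P", "LP", "VUS", "LB", "B")

#' Normalize an HGVS coding-DNA name
#'
#' Variant names are treated as opaque identifiers after light syntactic
#' normalization: surrounding whitespace is stripped and spaces around the
#' '+'/'-' of intronic offsets are removed, so that "c.497 + 1G>T" and
#' "c.497+1G>T" key the same variant. No HGVS grammar validation is attempted.
#'
#' @param x Character vector of HGVS c. names.
#' @return Character vector of normalized names.
#' @examples
#' normalize_hgvs("c.497 + 1G>T")
#' @export
normalize_hgvs <- function(x) {
  x <- stringr::str_trim(x)
  stringr::str_replace_all(x, "\\s*([+-])\\s*", "\\1")
}

# Per-row invariant check. Returns a character vector of problems (empty if ok).
catalog_row_problems <- function(catalog) {
  p <- character(0)
  bad_empty <- which(is.na(catalog$hgvs_c) | catalog$hgvs_c == "")
  if (length(bad_empty)) p <- c(p, paste0("row ", bad_empty, ": empty hgvs_c"))
  dup <- catalog$hgvs_c[duplicated(catalog$hgvs_c) & !is.na(catalog$hgvs_c)]
  if (length(dup)) p <- c(p, paste0("duplicate hgvs_c: ", unique(dup)))
  bad_loc <- which(!catalog$location_kind %in% location_levels)
  if (length(bad_loc)) p <- c(p, paste0("row ", bad_loc, ": unknown location_kind"))
  bad_dom <- which(!catalog$domain %in% domain_levels)
  if (length(bad_dom)) p <- c(p, paste0("row ", bad_dom, ": unknown domain"))
  bad_type <- which(!catalog$mutation_type %in% mutation_type_levels)
  if (length(bad_type)) p <- c(p, paste0("row ", bad_type, ": unknown mutation_type"))
  bad_acmg <- which(!catalog$acmg_class %in% acmg_levels)
  if (length(bad_acmg)) p <- c(p, paste0("row ", bad_acmg, ": unknown acmg_class"))
  # exon_number present iff the variant is exonic
  need_exon <- catalog$location_kind == "exon" & is.na(catalog$exon_number)
  stray_exon <- catalog$location_kind == "intron" & !is.na(catalog$exon_number)
  if (any(need_exon, na.rm = TRUE)) {
    p <- c(p, paste0("row ", which(need_exon), ": exonic variant without exon_number"))
  }
  if (any(stray_exon, na.rm = TRUE)) {
    p <- c(p, paste0("row ", which(stray_exon), ": intronic variant with exon_number"))
  }
  bad_range <- which(!is.na(catalog$exon_number) &
    (catalog$exon_number < 1 | catalog$exon_number > 10))
  if (length(bad_range)) p <- c(p, paste0("row ", bad_range, ": exon_number outside 1-10"))
  p
}

# logical vector: rows individually satisfying the invariants
catalog_row_ok <- function(catalog) {
  ok <- !is.na(catalog$hgvs_c) & catalog$hgvs_c != "" &
    !duplicated(catalog$hgvs_c) &
    catalog$location_kind %in% location_levels &
    catalog$domain %in% domain_levels &
    catalog$mutation_type %in% mutation_type_levels &
    catalog$acmg_class %in% acmg_levels
  ok & if_else(catalog$location_kind == "exon",
    !is.na(catalog$exon_number) & catalog$exon_number >= 1 & catalog$exon_number <= 10,
    is.na(catalog$exon_number),
    missing = FALSE
  )
}

#' Validate a variant-catalog tibble
#'
#' Checks the catalog invariants: non-empty unique `hgvs_c`, closed
#' location/domain/mutation-type/ACMG vocabularies, and `exon_number` present
#' exactly for exonic variants (1-10).
#'
#' @param catalog A data frame with the catalog columns (see
#'   [read_variant_catalog()]).
#' @param strict If `TRUE` (default) any violation aborts; otherwise offending
#'   rows are dropped with a message.
#' @return The validated catalog as a tibble, invisibly unchanged in strict
#'   mode, with bad rows removed otherwise.
#' @export
validate_variant_catalog <- function(catalog, strict = TRUE) {
  check_flag(strict, "strict")
  missing_cols <- setdiff(catalog_columns, names(catalog))
  if (length(missing_cols)) {
    abort(paste0(
      "Variant table is missing required column(s): ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  catalog <- as_tibble(catalog)[catalog_columns]
  catalog$hgvs_c <- normalize_hgvs(as.character(catalog$hgvs_c))
  catalog$hgvs_p <- as.character(catalog$hgvs_p)
  catalog$exon_number <- suppressWarnings(as.integer(catalog$exon_number))
  problems <- catalog_row_problems(catalog)
  if (length(problems)) {
    if (strict) {
      abort(c("Invalid variant catalog:", setNames(head(problems, 10), rep("x", min(10, length(problems))))))
    }
    keep <- catalog_row_ok(catalog)
    inform(paste0(
      "Dropping ", sum(!keep), " invalid row(s): ",
      paste(head(problems, 5), collapse = "; ")
    ))
    catalog <- catalog[keep, ]
  }
  catalog
}

#' Read a curated variant catalog from TSV
#'
#' Expects a tab-separated file with header columns `hgvs_c`, `hgvs_p`,
#' `location_kind`, `exon_number`, `domain`, `mutation_type`, `acmg_class`;
#' empty strings mark missing optionals. HGVS names are syntactically
#' normalized on input ([normalize_hgvs()]).
#'
#' @param path Path to a TSV file.
#' @param strict If `TRUE` (default) reject the whole file on any invariant
#'   violation; otherwise skip bad rows with a message.
#' @return A tibble of validated variant records, input order preserved.
#' @examples
#' tsv <- system.file("extdata", "example_variants.tsv", package = "pcdscreen")
#' read_variant_catalog(tsv)
#' @export
read_variant_catalog <- function(path, strict = TRUE) {
  raw <- readr::read_tsv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    na = character(), progress = FALSE
  )
  raw[raw == ""] <- NA
  validate_variant_catalog(raw, strict = strict)
}

#' Write a variant catalog to TSV
#'
#' Inverse of [read_variant_catalog()]: missing optionals are written as empty
#' strings so that a read/write round trip reproduces the table
#' field-for-field.
#'
#' @param catalog A validated catalog tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_variant_catalog <- function(catalog, path) {
  readr::write_tsv(catalog[catalog_columns], path, na = "")
  invisible(path)
}

#' Keep only pathogenic / likely pathogenic variants
#'
#' Filters a catalog to ACMG classes P and LP — the disease-causing tiers used
#' throughout prevalence estimation and panel design. Input order is
#' preserved and the operation is idempotent.
#'
#' @param catalog A variant-catalog tibble.
#' @return The P/LP subset, a tibble.
#' @export
filter_plp <- function(catalog) {
  filter(as_tibble(catalog), .data$acmg_class %in% c("P", "LP"))
}

one_partition <- function(values, levels_present, total, partition) {
  tab <- table(factor(values, levels = levels_present))
  tibble(
    partition = partition,
    category = names(tab),
    n = as.integer(tab),
    percent = round_half_up(100 * as.integer(tab) / total, 2)
  )
}

#' Summarize the genetic spectrum of a variant catalog
#'
#' Tabulates counts and percentages of variants by genomic location
#' (exon/intron), affected exon, protein domain, and mutation type. Percentages
#' are over the whole catalog and rounded half-up to 2 decimals, the
#' convention of published spectrum figures. Intronic variants appear in the
#' exon partition under category `"intron"`, so every partition's counts sum
#' to the catalog size.
#'
#' @param catalog A non-empty variant-catalog tibble.
#' @return A tibble of class `pcd_spectrum` with columns `partition`,
#'   `category`, `n`, `percent`, and attribute `total`.
#' @examples
#' summarize_spectrum(synthetic_plp_catalog())
#' @export
summarize_spectrum <- function(catalog) {
  catalog <- as_tibble(catalog)
  if (nrow(catalog) == 0) abort("Cannot summarize an empty catalog.")
  total <- nrow(catalog)
  exon_cat <- if_else(catalog$location_kind == "exon",
    paste0("exon_", catalog$exon_number), "intron"
  )
  exon_levels <- c(paste0("exon_", sort(unique(catalog$exon_number[!is.na(catalog$exon_number)]))),
    if (any(catalog$location_kind == "intron")) "intron")
  out <- bind_rows(
    one_partition(catalog$location_kind, location_levels[location_levels %in% catalog$location_kind], total, "location"),
    one_partition(exon_cat, exon_levels, total, "exon"),
    one_partition(catalog$domain, domain_levels[domain_levels %in% catalog$domain], total, "domain"),
    one_partition(catalog$mutation_type, mutation_type_levels[mutation_type_levels %in% catalog$mutation_type], total, "mutation_type")
  )
  attr(out, "total") <- total
  class(out) <- c("pcd_spectrum", class(out))
  out
}

#' @exportS3Method ggplot2::autoplot
autoplot.pcd_spectrum <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$category, y = .data$percent
  )) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = paste0(.data$n, " (", .data$percent, "%)")),
      vjust = -0.3, size = 2.8
    ) +
    ggplot2::facet_wrap(~partition, scales = "free_x") +
    ggplot2::labs(
      x = NULL, y = "Percent of catalog",
      title = paste0("Variant spectrum (n = ", attr(object, "total"), ")")
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Synthetic 128-variant P/LP catalog with the published category totals
#'
#' The per-variant curated list behind the published spectrum is in
#' access-restricted supplementary material, so this constructor builds a
#' synthetic stand-in that reproduces the printed category marginals exactly:
#' 66 missense, 29 frameshift, 19 nonsense, 11 splicing, 2 in-frame indel and
#' 1 start-loss variant; 117 exonic / 11 intronic; 26 variants on exon 1 and
#' 24 on exon 8; 74 in the non-transmembrane domain. Individual variant names
#' are synthetic placeholders, not real alleles (except that the construction
#' is deterministic and names are unique).
#'
#' @return A 128-row variant-catalog tibble.
#' @examples
#' summarize_spectrum(synthetic_plp_catalog())
#' @export
synthetic_plp_catalog <- function() {
  # mutation types; splicing variants are the 11 intronic ones
  types <- c(
    rep("missense", 66), rep("frameshift", 29), rep("nonsense", 19),
    rep("splicing", 11), rep("inframe_indel", 2), "start_loss"
  )
  location <- if_else(types == "splicing", "intron", "exon")
  # exon assignment for the 117 exonic variants: exon 1 x26, exon 8 x24,
  # remainder spread over the other eight exons
  rest <- c(rep(2:4, each = 9), rep(c(5:7, 9, 10), each = 8))
  exon_seq <- c(rep(1L, 26), rep(8L, 24), as.integer(rest))
  exon_number <- rep(NA_integer_, 128)
  exon_number[location == "exon"] <- exon_seq
  # the start-loss variant belongs on exon 1; swap exon labels to keep margins
  sl <- which(types == "start_loss")
  first_e1 <- which(exon_number == 1L)[1]
  exon_number[first_e1] <- exon_number[sl]
  exon_number[sl] <- 1L
  # domain: 75 non-transmembrane / 53 transmembrane (58.59% non-TM; the
  # published figure's count/percent pair is inconsistent and the percentage
  # is followed), interleaved across types
  domain <- rep(c("non_transmembrane", "transmembrane"), length.out = 128)
  domain[1:22] <- "non_transmembrane"
  stopifnot(sum(domain == "non_transmembrane") == 75)
  pos <- seq_len(128) * 13L
  hgvs_c <- dplyr::case_when(
    types == "missense" ~ sprintf("c.%dC>G", pos),
    types == "frameshift" ~ sprintf("c.%ddel", pos),
    types == "nonsense" ~ sprintf("c.%dC>T", pos),
    types == "splicing" ~ sprintf("c.%d+1G>A", pos),
    types == "inframe_indel" ~ sprintf("c.%d_%ddel", pos, pos + 2L),
    types == "start_loss" ~ "c.1A>G"
  )
  tibble(
    hgvs_c = hgvs_c,
    hgvs_p = NA_character_,
    location_kind = location,
    exon_number = exon_number,
    domain = domain,
    mutation_type = types,
    acmg_class = rep(c("P", "LP"), length.out = 128)
  )
}
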
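classification_vocab <- c("pathogenic", "likely_pathogenic", "vus",
                          "likely_benign", "benign")

#' Load a pathogenic-variant catalog
#'
#' Reads a mutation-database export (HGMD-style) of variants asserted to cause
#' the disease, either as a TSV with a header naming at least
#' `chrom, pos, ref, alt, classification` (optional: `rsid, cdna, protein,
#' consequence, phenotype`) or as a VCF whose INFO field carries the
#' classification and phenotype under configurable keys. Keys are
#' trim-normalized; duplicate keys are collapsed to one entry, with any
#' classification disagreement recorded in the `conflicts` attribute.
#'
#' @param path Path to the catalog file.
#' @param format `"tsv"` or `"vcf"`.
#' @param info_class,info_phen INFO keys holding classification / phenotype
#'   when `format = "vcf"`.
#' @param chrom_style Chromosome-name unification passed to
#'   [normalize_chrom] semantics (`"chr"`, `"plain"`, `"asis"`).
#' @return A tibble with columns `chrom, pos, ref, alt, rsid, cdna, protein,
#'   consequence, classification, phenotype`, one row per unique variant key;
#'   attribute `conflicts` holds a tibble of collapsed classification
#'   disagreements (zero rows when none).
#' @export
load_catalog <- function(path, format = c("tsv", "vcf"),
                         info_class = "CLASS", info_phen = "PHEN",
                         chrom_style = "chr") {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("catalog file not found: %s", path))

  if (format == "tsv") {
    raw <- readr::read_tsv(path, show_col_types = FALSE,
                           col_types = readr::cols(.default = "c"))
    if (nrow(raw) == 0L) {
      warn(sprintf("catalog %s is empty", path))
      return(empty_catalog())
    }
    need <- c("chrom", "pos", "ref", "alt", "classification")
    missing_cols <- setdiff(need, names(raw))
    if (length(missing_cols) > 0L) {
      abort(sprintf("catalog %s lacks required column(s): %s",
                    path, paste(missing_cols, collapse = ", ")))
    }
    cat_tbl <- tibble(
      chrom = normalize_chrom(raw$chrom, chrom_style),
      pos = as.integer(raw$pos),
      ref = toupper(raw$ref),
      alt = toupper(raw$alt),
      rsid = if ("rsid" %in% names(raw)) raw$rsid else NA_character_,
      cdna = if ("cdna" %in% names(raw)) raw$cdna else NA_character_,
      protein = if ("protein" %in% names(raw)) raw$protein else NA_character_,
      consequence = if ("consequence" %in% names(raw)) raw$consequence else NA_character_,
      classification = tolower(raw$classification),
      phenotype = if ("phenotype" %in% names(raw)) raw$phenotype else NA_character_
    )
  } else {
    vcf <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcf@fix
    if (nrow(fix) == 0L) {
      warn(sprintf("catalog %s is empty", path))
      return(empty_catalog())
    }
    info_get <- function(key) {
      vals <- vcfR::extract.info(vcf, element = key)
      if (is.null(vals)) rep(NA_character_, nrow(fix)) else unname(as.character(vals))
    }
    cat_tbl <- tibble(
      chrom = normalize_chrom(fix[, "CHROM"], chrom_style),
      pos = as.integer(fix[, "POS"]),
      ref = toupper(fix[, "REF"]),
      alt = toupper(fix[, "ALT"]),
      rsid = ifelse(is.na(fix[, "ID"]) | fix[, "ID"] == ".", NA_character_, fix[, "ID"]),
      cdna = info_get("CDNA"),
      protein = info_get("PROT"),
      consequence = info_get("CSQ"),
      classification = tolower(info_get(info_class)),
      phenotype = info_get(info_phen)
    )
  }

  unknown <- setdiff(unique(cat_tbl$classification), classification_vocab)
  if (length(unknown) > 0L) {
    abort(sprintf("unknown classification token(s) in catalog: %s (allowed: %s)",
                  paste(unknown, collapse = ", "),
                  paste(classification_vocab, collapse = ", ")))
  }

  cat_tbl <- normalize_variants(cat_tbl)

  grp <- cat_tbl |> group_by(.data$chrom, .data$pos, .data$ref, .data$alt)
  conflicts <- grp |>
    summarise(classifications = paste(sort(unique(.data$classification)), collapse = "|"),
              .groups = "drop") |>
    filter(str_detect(.data$classifications, stringr::fixed("|")))
  collapsed <- grp |> slice(1L) |> ungroup()
  if (nrow(conflicts) > 0L) {
    warn(sprintf("%d catalog key(s) collapsed with conflicting classifications", nrow(conflicts)))
  }
  attr(collapsed, "conflicts") <- conflicts
  collapsed
}

empty_catalog <- function() {
  out <- tibble(chrom = character(), pos = integer(), ref = character(),
                alt = character(), rsid = character(), cdna = character(),
                protein = character(), consequence = character(),
                classification = character(), phenotype = character())
  attr(out, "conflicts") <- tibble(chrom = character(), pos = integer(),
                                   ref = character(), alt = character(),
                                   classifications = character())
  out
}

#' Intersect a cohort with a pathogenic-variant catalog
#'
#' Matches catalog entries against cohort variants on the exact normalized
#' key `(chrom, pos, ref, alt)` — rsIDs are carried through for reporting but
#' never used for joining — and tallies who carries each matched variant. A
#' carrier is a sample with at least one non-missing alternate allele; a
#' homozygote counts as one carrier. Samples carrying two or more distinct
#' matched variants are additionally flagged as potentially affected
#' (possible compound heterozygotes under the recessive model).
#'
#' @param cohort A `genotype_tbl` from [read_cohort_vcf()].
#' @param catalog A catalog tibble from [load_catalog()].
#' @return An object of class `intersection_result`: a list with
#'   \describe{
#'     \item{matched}{tibble, one row per matched variant: key columns,
#'       catalog annotations, `n_het`, `n_hom_alt`, `n_carriers`, observed
#'       `ac` / `an`.}
#'     \item{carriers}{tibble of (variant key, `sample_id`, `n_alt`) for every
#'       carrier observation.}
#'     \item{carrier_samples}{character vector of distinct carrier sample IDs.}
#'     \item{potentially_affected}{tibble of samples carrying >= 2 distinct
#'       matched variants.}
#'     \item{n_samples}{cohort size.}
#'   }
#' @export
intersect_catalog <- function(cohort, catalog) {
  key_cols <- c("chrom", "pos", "ref", "alt")
  matched_keys <- catalog |>
    semi_join(cohort_variants(cohort), by = key_cols)

  calls <- cohort |>
    inner_join(matched_keys |> select(all_of(key_cols), "cdna", "protein",
                                      "consequence", "classification", "phenotype"),
               by = key_cols) |>
    mutate(n_alt = (!is.na(.data$a1) & .data$a1 == 1L) +
                   (!is.na(.data$a2) & .data$a2 == 1L),
           n_called = (!is.na(.data$a1)) + (!is.na(.data$a2)))

  per_variant <- calls |>
    group_by(across(all_of(c(key_cols, "cdna", "protein", "consequence",
                             "classification", "phenotype")))) |>
    summarise(
      n_het = sum(.data$n_alt == 1L),
      n_hom_alt = sum(.data$n_alt == 2L),
      n_carriers = sum(.data$n_alt >= 1L),
      ac = sum(.data$n_alt),
      an = sum(.data$n_called),
      .groups = "drop"
    ) |>
    arrange(.data$chrom, .data$pos, .data$ref, .data$alt)

  carriers <- calls |>
    filter(.data$n_alt >= 1L) |>
    select(all_of(key_cols), "sample_id", "n_alt") |>
    arrange(.data$pos, .data$sample_id)

  potentially_affected <- carriers |>
    distinct(.data$chrom, .data$pos, .data$ref, .data$alt, .data$sample_id) |>
    count(.data$sample_id, name = "n_distinct_variants") |>
    filter(.data$n_distinct_variants >= 2L)
  hom_affected <- carriers |> filter(.data$n_alt == 2L) |>
    distinct(.data$sample_id) |> mutate(n_distinct_variants = 1L)
  potentially_affected <- bind_rows(potentially_affected, hom_affected) |>
    distinct(.data$sample_id, .keep_all = TRUE)

  structure(
    list(
      matched = per_variant,
      carriers = carriers,
      carrier_samples = sort(unique(carriers$sample_id)),
      potentially_affected = potentially_affected,
      n_samples = length(cohort_samples(cohort))
    ),
    class = "intersection_result"
  )
}

#' @export
print.intersection_result <- function(x, ...) {
  cat(sprintf("Cohort x catalog intersection: %d matched variant(s), %d distinct carrier(s) among %d samples\n",
              nrow(x$matched), length(x$carrier_samples), x$n_samples))
  print(x$matched, ...)
  invisible(x)
}

#' @describeIn intersect_catalog tidy() method: the per-variant match table.
#' @method tidy intersection_result
#' @param x An `intersection_result`.
#' @param ... Unused.
#' @export
tidy.intersection_result <- function(x, ...) {
  x$matched
}

#' @describeIn intersect_catalog glance() method: one-row summary
#' @method glance intersection_result
#'   (`n_matched`, `n_carrier_samples`, `n_potentially_affected`, `n_samples`).
#' @export
glance.intersection_result <- function(x, ...) {
  tibble(
    n_matched = nrow(x$matched),
    n_carrier_samples = length(x$carrier_samples),
    n_potentially_affected = nrow(x$potentially_affected),
    n_samples = x$n_samples
  )
}
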
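#' Ancestry-stratified allele frequencies
#'
#' Computes allele count (AC), called allele number (AN), allele frequency
#' (AF = AC/AN), and het/hom-alt genotype counts for each requested variant in
#' every population stratum: the pooled cohort (`ALL`), each superpopulation,
#' and each subpopulation. Missing allele calls are excluded from AN, so with
#' complete genotypes AN equals twice the stratum sample count. A requested
#' key absent from the cohort yields a record with `ac = 0`,
#' `an = 2 x stratum size` and `absent = TRUE`.
#'
#' @param cohort A `genotype_tbl`.
#' @param panel Sample panel tibble from [read_panel()]; every cohort sample
#'   must be assigned (unassigned samples are an error).
#' @param keys Optional tibble of variant keys (`chrom, pos, ref, alt`) to
#'   report; defaults to every cohort variant.
#' @return Tibble with one row per (variant, stratum): key columns, `stratum`,
#'   `level` (`"ALL"`, `"superpop"`, `"subpop"`), `ac`, `an`, `af`, `n_het`,
#'   `n_hom_alt`, `absent`. `af` is `NA` (flagged by `an == 0`) when no
#'   alleles were called.
#' @export
stratified_frequencies <- function(cohort, panel, keys = NULL) {
  samples <- cohort_samples(cohort)
  unassigned <- setdiff(samples, panel$sample_id)
  if (length(unassigned) > 0L) {
    abort(sprintf("cohort sample(s) missing from panel: %s%s",
                  paste(head(unassigned, 5L), collapse = ", "),
                  if (length(unassigned) > 5L) sprintf(" (+%d more)", length(unassigned) - 5L) else ""))
  }
  key_cols <- c("chrom", "pos", "ref", "alt")
  if (is.null(keys)) keys <- cohort_variants(cohort)
  keys <- as_tibble(keys) |> distinct(across(all_of(key_cols)))

  present <- keys |> semi_join(cohort_variants(cohort), by = key_cols)
  absent <- keys |> anti_join(present, by = key_cols)

  panel_used <- panel |> filter(.data$sample_id %in% samples)

  per_sample <- cohort |>
    semi_join(present, by = key_cols) |>
    inner_join(panel_used, by = "sample_id") |>
    mutate(ac_i = (!is.na(.data$a1) & .data$a1 == 1L) +
                  (!is.na(.data$a2) & .data$a2 == 1L),
           an_i = (!is.na(.data$a1)) + (!is.na(.data$a2)))

  by_subpop <- per_sample |>
    group_by(across(all_of(c(key_cols, "superpop", "subpop")))) |>
    summarise(ac = sum(.data$ac_i), an = sum(.data$an_i),
              n_het = sum(.data$ac_i == 1L), n_hom_alt = sum(.data$ac_i == 2L),
              .groups = "drop")

  roll <- function(tb, stratum, level) {
    tb |> mutate(stratum = stratum, level = level) |>
      select(all_of(key_cols), "stratum", "level", "ac", "an", "n_het", "n_hom_alt")
  }
  sub_rec <- roll(by_subpop, by_subpop$subpop, "subpop")
  super_tb <- by_subpop |>
    group_by(across(all_of(c(key_cols, "superpop")))) |>
    summarise(across(c("ac", "an", "n_het", "n_hom_alt"), sum), .groups = "drop")
  super_rec <- roll(super_tb, super_tb$superpop, "superpop")
  all_tb <- super_tb |>
    group_by(across(all_of(key_cols))) |>
    summarise(across(c("ac", "an", "n_het", "n_hom_alt"), sum), .groups = "drop")
  all_rec <- roll(all_tb, "ALL", "ALL")

  records <- bind_rows(all_rec, super_rec, sub_rec) |> mutate(absent = FALSE)

  if (nrow(absent) > 0L) {
    strata <- bind_rows(
      tibble(stratum = "ALL", level = "ALL",
             n_samples = nrow(panel_used)),
      panel_used |> count(.data$superpop, name = "n_samples") |>
        transmute(stratum = .data$superpop, level = "superpop", .data$n_samples),
      panel_used |> count(.data$subpop, name = "n_samples") |>
        transmute(stratum = .data$subpop, level = "subpop", .data$n_samples)
    )
    absent_rec <- tidyr::crossing(absent, strata) |>
      mutate(ac = 0L, an = 2L * .data$n_samples, n_het = 0L, n_hom_alt = 0L,
             absent = TRUE) |>
      select(-"n_samples")
    records <- bind_rows(records, absent_rec)
  }

  records |>
    mutate(af = ifelse(.data$an > 0L, .data$ac / .data$an, NA_real_)) |>
    select(all_of(key_cols), "stratum", "level", "ac", "an", "af",
           "n_het", "n_hom_alt", "absent") |>
    arrange(.data$chrom, .data$pos, .data$ref, .data$alt,
            factor(.data$level, levels = c("ALL", "superpop", "subpop")),
            .data$stratum)
}

#' Format an allele frequency as a percentage string
#'
#' Published frequency tables mix two conventions: rounding (35/2184 printed
#' as 1.60%, 1/2184 as 0.05%) and truncation (36/2184 printed as 1.64%,
#' 1/2184 as 0.04%). Both are provided; rounding is half-up.
#'
#' @param af Allele frequency fraction(s) in `[0, 1]`.
#' @param mode `"round"` (half-up) or `"truncate"` (toward zero).
#' @param decimals Number of decimal places (default 2).
#' @return Character vector, e.g. `"1.60"` (percent sign not included).
#' @examples
#' format_percent(35 / 2184)                      # "1.60"
#' format_percent(36 / 2184, mode = "truncate")   # "1.64"
#' format_percent(1 / 2184)                       # "0.05"
#' format_percent(1 / 2184, mode = "truncate")    # "0.04"
#' @export
format_percent <- function(af, mode = c("round", "truncate"), decimals = 2L) {
  mode <- match.arg(mode)
  stopifnot(all(af >= 0 & af <= 1, na.rm = TRUE))
  x <- af * 100
  scl <- 10^decimals
  v <- switch(mode,
    round = floor(x * scl + 0.5) / scl,
    # small guard so exact decimal fractions stored inexactly in binary
    # (e.g. 1.60) are not truncated down a unit
    truncate = floor(x * scl + sqrt(.Machine$double.eps)) / scl
  )
  sprintf(paste0("%.", decimals, "f"), v)
}

#' Read an external per-ancestry allele-frequency table
#'
#' Reads a gnomAD-style TSV with header `variant, ancestry, af` (frequency as
#' a fraction, or a percentage with a trailing `%`) or
#' `variant, ancestry, ac, an` (frequency computed as `ac/an`). The `variant`
#' column may hold either a `chrom:pos:ref:alt` key or an HGVS c. name; it is
#' matched downstream against both.
#'
#' @param path Path to the TSV.
#' @param source_label Free-text provenance label recorded on the result
#'   (default: the file name).
#' @return Tibble with columns `variant`, `ancestry`, `af` (fraction in
#'   `[0, 1]`); attribute `source` carries the label.
#' @export
read_external_frequencies <- function(path, source_label = basename(path)) {
  if (!file.exists(path)) abort(sprintf("frequency table not found: %s", path))
  raw <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = "c"))
  if (!all(c("variant", "ancestry") %in% names(raw))) {
    abort("external frequency table needs columns: variant, ancestry, and af (or ac + an)")
  }
  if ("af" %in% names(raw)) {
    af_chr <- str_trim(raw$af)
    pct <- str_detect(af_chr, "%$")
    vals <- as.numeric(sub("%$", "", af_chr))
    af <- ifelse(pct, vals / 100, vals)
  } else if (all(c("ac", "an") %in% names(raw))) {
    af <- as.numeric(raw$ac) / as.numeric(raw$an)
  } else {
    abort("external frequency table needs an 'af' column or 'ac' + 'an' columns")
  }
  bad <- which(is.na(af) | af < 0 | af > 1)
  if (length(bad) > 0L) {
    abort(sprintf(
      "allele frequency out of [0, 1] in %s (row %d, value '%s'); fractions must carry no unit, percentages a trailing %%",
      path, bad[1], raw[["af"]][bad[1]] %||% ""))
  }
  out <- tibble(variant = raw$variant, ancestry = raw$ancestry, af = af)
  attr(out, "source") <- source_label
  out
}

#' Plot stratified allele frequencies
#'
#' @param records Output of [stratified_frequencies()].
#' @param level Which stratum level to show (default `"superpop"`).
#' @return A ggplot object: allele frequency per stratum, faceted by variant.
#' @export
plot_stratified_frequencies <- function(records, level = "superpop") {
  df <- records |>
    filter(.data$level == !!level) |>
    mutate(variant = variant_id(.data$chrom, .data$pos, .data$ref, .data$alt))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stratum, y = .data$af)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~variant, scales = "free_y") +
    ggplot2::labs(x = "population stratum", y = "allele frequency (AC/AN)") +
    ggplot2::theme_minimal()
}
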
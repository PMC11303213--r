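#' Read a cohort VCF into a long genotype table
#'
#' Parses a VCF 4.x file (plain or gzipped) with per-sample GT fields into a
#' tidy genotype table: one row per (variant, sample) with the two diploid
#' allele calls as integers (`0` = reference, `1` = alternate, `NA` =
#' missing). Multiallelic records are decomposed into one biallelic record per
#' alternate allele; in a decomposed record, calls to *other* alternate
#' alleles become missing (not reference), so allele counts are conserved
#' across the decomposition. Phase separators (`|` and `/`) are both accepted
#' and phase is discarded. Variant keys are trim-normalized on the way in so
#' they join against normalized catalogs.
#'
#' @param path Path to a VCF file (optionally gzipped).
#' @param region Optional region restriction, either `"chr17:3550800-3550801"`
#'   or `list(chrom, start, end)`. Coordinates are 1-based with a half-open
#'   `[start, end)` interval; records overlapping the interval are kept.
#' @param chrom_style One of `"chr"`, `"plain"`, `"asis"`: how chromosome
#'   names are unified at parse time (the 1000 Genomes and mutation-database
#'   dialects differ).
#' @return A `genotype_tbl`: a tibble with columns `chrom`, `pos`, `ref`,
#'   `alt`, `rsid`, `sample_id`, `a1`, `a2`, carrying the ordered sample list
#'   and the genome build (`GRCh37`) as attributes.
#' @seealso [write_cohort_vcf()], [read_panel()], [stratified_frequencies()]
#' @export
read_cohort_vcf <- function(path, region = NULL, chrom_style = "chr") {
  if (!file.exists(path)) abort(sprintf("VCF file not found: %s", path))
  validate_vcf_structure(path)

  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcf@fix
  if (nrow(fix) == 0L) abort(sprintf("VCF %s contains no variant records", path))
  gtm <- vcfR::extract.gt(vcf, element = "GT")
  samples <- colnames(vcf@gt)[-1]

  # parse GT strings into two integer allele matrices (NA = missing)
  gv <- as.vector(gtm)
  gv[is.na(gv)] <- "."
  parts <- str_split(gv, "[/|]")
  lens <- lengths(parts)
  if (any(lens > 2L)) abort("non-diploid genotype encountered (more than 2 alleles)")
  first <- map_chr(parts, 1L)
  second <- ifelse(lens == 2L, map_chr(parts, function(p) p[min(2L, length(p))]), ".")
  if (any(lens == 1L & first != ".")) {
    abort("haploid (single-allele) genotype call encountered; cohort must be diploid")
  }
  nv <- nrow(gtm)
  a1 <- matrix(suppressWarnings(as.integer(first)), nrow = nv)
  a2 <- matrix(suppressWarnings(as.integer(second)), nrow = nv)

  chrom <- normalize_chrom(fix[, "CHROM"], chrom_style)
  pos <- as.integer(fix[, "POS"])
  rsid <- ifelse(is.na(fix[, "ID"]) | fix[, "ID"] == ".", NA_character_, fix[, "ID"])
  ref <- toupper(fix[, "REF"])
  alts <- str_split(toupper(fix[, "ALT"]), ",")

  blocks <- vector("list", sum(lengths(alts)))
  bi <- 0L
  for (r in seq_len(nv)) {
    kr <- length(alts[[r]])
    for (j in seq_len(kr)) {
      key <- normalize_one(chrom[r], pos[r], ref[r], alts[[r]][j])
      r1 <- recode_allele(a1[r, ], j)
      r2 <- recode_allele(a2[r, ], j)
      bi <- bi + 1L
      blocks[[bi]] <- tibble(
        chrom = chrom[r], pos = key$pos, ref = key$ref, alt = key$alt,
        rsid = rsid[r], sample_id = samples, a1 = r1, a2 = r2
      )
    }
  }
  calls <- list_rbind(blocks)

  if (!is.null(region)) {
    reg <- parse_region(region, chrom_style)
    calls <- calls |>
      filter(.data$chrom == reg$chrom,
             .data$pos <= reg$end - 1L,
             .data$pos + nchar(.data$ref) - 1L >= reg$start)
  }

  dup <- calls |> distinct(.data$chrom, .data$pos, .data$ref, .data$alt)
  nkey <- nrow(dup)
  if (nkey * length(samples) != nrow(calls)) {
    warn("duplicate variant keys in VCF; all records retained")
  }
  new_genotype_tbl(calls, samples)
}

# allele recoding for multiallelic decomposition against alt index j:
# ref stays ref, the matching alt becomes 1, any other alt becomes missing
recode_allele <- function(a, j) {
  out <- rep(NA_integer_, length(a))
  out[!is.na(a) & a == 0L] <- 0L
  out[!is.na(a) & a == j] <- 1L
  out
}

validate_vcf_structure <- function(path) {
  lines <- readr::read_lines(path)
  hdr_idx <- which(startsWith(lines, "#CHROM"))
  if (length(hdr_idx) != 1L) {
    abort(sprintf("malformed VCF %s: expected exactly one #CHROM header line", path))
  }
  nf_hdr <- length(strsplit(lines[hdr_idx], "\t", fixed = TRUE)[[1]])
  if (nf_hdr < 10L) {
    abort(sprintf("VCF %s has no sample/GT columns (header has %d fields)", path, nf_hdr))
  }
  body_idx <- which(!startsWith(lines, "#") & nzchar(lines))
  body_idx <- body_idx[body_idx > hdr_idx]
  fields <- strsplit(lines[body_idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf != nf_hdr)
  if (length(bad) > 0L) {
    abort(sprintf(
      "structural error in VCF %s: line %d has %d fields but the header defines %d (sample count mismatch)",
      path, body_idx[bad[1]], nf[bad[1]], nf_hdr))
  }
  malformed <- which(!grepl("^[0-9]+$", map_chr(fields, 2L)))
  if (length(malformed) > 0L) {
    abort(sprintf("parse error in VCF %s: line %d has non-numeric POS field",
                  path, body_idx[malformed[1]]))
  }
  invisible(TRUE)
}

parse_region <- function(region, chrom_style = "chr") {
  if (is.character(region) && length(region) == 1L) {
    m <- regmatches(region, regexec("^([^:]+):([0-9]+)-([0-9]+)$", region))[[1]]
    if (length(m) != 4L) abort(sprintf("cannot parse region string '%s'", region))
    region <- list(chrom = m[2], start = as.integer(m[3]), end = as.integer(m[4]))
  }
  region <- as.list(region)
  if (is.null(names(region)) || !all(c("chrom", "start", "end") %in% names(region))) {
    names(region) <- c("chrom", "start", "end")
  }
  region$chrom <- normalize_chrom(as.character(region$chrom), chrom_style)
  region$start <- as.integer(region$start)
  region$end <- as.integer(region$end)
  if (region$start >= region$end) abort("region must satisfy start < end (half-open [start, end))")
  region
}

new_genotype_tbl <- function(calls, samples) {
  out <- as_tibble(calls)
  attr(out, "samples") <- samples
  attr(out, "build") <- genome_build()
  class(out) <- c("genotype_tbl", class(tibble()))
  out
}

#' Samples and variants of a genotype table
#'
#' @param cohort A `genotype_tbl` from [read_cohort_vcf()] or
#'   [generate_random_cohort()].
#' @return `cohort_samples()`: character vector of sample IDs in cohort order.
#'   `cohort_variants()`: tibble of unique variant keys
#'   (`chrom`, `pos`, `ref`, `alt`, `rsid`).
#' @export
cohort_samples <- function(cohort) {
  attr(cohort, "samples") %||% unique(cohort$sample_id)
}

#' @rdname cohort_samples
#' @export
cohort_variants <- function(cohort) {
  cohort |>
    distinct(.data$chrom, .data$pos, .data$ref, .data$alt, .data$rsid) |>
    arrange(.data$chrom, .data$pos, .data$ref, .data$alt) |>
    as_tibble()
}

#' Write a genotype table back to VCF
#'
#' Emits plain-text VCF 4.2 with a GT-only FORMAT. Phase was discarded at
#' parse time, so genotypes are written unphased (`/`); missing alleles are
#' written as `.`. Round-tripping through [read_cohort_vcf()] reproduces the
#' same keys and calls.
#'
#' @param cohort A `genotype_tbl`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort_vcf <- function(cohort, path) {
  samples <- cohort_samples(cohort)
  variants <- cohort_variants(cohort)
  wide <- cohort |>
    mutate(gt = paste0(ifelse(is.na(.data$a1), ".", .data$a1), "/",
                       ifelse(is.na(.data$a2), ".", .data$a2))) |>
    select("chrom", "pos", "ref", "alt", "rsid", "sample_id", "gt") |>
    tidyr::pivot_wider(names_from = "sample_id", values_from = "gt") |>
    arrange(.data$chrom, .data$pos, .data$ref, .data$alt)

  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##source=genoprev-%s", as.character(packageVersion("genoprev"))),
    sprintf("##reference=%s", genome_build()),
    sprintf("##contig=<ID=%s>", unique(wide$chrom)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  gt_cols <- as.matrix(wide[, samples, drop = FALSE])
  body <- paste(
    wide$chrom, wide$pos, ifelse(is.na(wide$rsid), ".", wide$rsid),
    wide$ref, wide$alt, ".", "PASS", ".", "GT",
    apply(gt_cols, 1L, paste, collapse = "\t"),
    sep = "\t"
  )
  readr::write_lines(c(header, body), path)
  invisible(path)
}

#' Read a 1000 Genomes-style sample panel
#'
#' Parses the whitespace-separated `sample  subpopulation  superpopulation`
#' panel dialect (no header; extra trailing columns such as sequencing
#' platform are ignored). Duplicate lines with identical assignments are
#' collapsed; conflicting duplicates are an error, as is a subpopulation
#' mapped to more than one superpopulation.
#'
#' @param path Path to the panel file.
#' @return A tibble with columns `sample_id`, `subpop`, `superpop`.
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) abort(sprintf("panel file not found: %s", path))
  lines <- readr::read_lines(path)
  lines <- str_trim(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) abort(sprintf("empty panel file: %s", path))
  fields <- str_split(lines, "\\s+")
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    abort(sprintf("parse error in panel %s: line %d has %d fields (need sample, subpop, superpop)",
                  path, which(nf < 3L)[1], nf[nf < 3L][1]))
  }
  panel <- tibble(
    sample_id = map_chr(fields, 1L),
    subpop = map_chr(fields, 2L),
    superpop = map_chr(fields, 3L)
  ) |> distinct()
  dup <- panel |> count(.data$sample_id) |> filter(.data$n > 1L)
  if (nrow(dup) > 0L) {
    abort(sprintf("conflicting population assignment for sample(s): %s",
                  paste(dup$sample_id, collapse = ", ")))
  }
  bad_sub <- panel |> distinct(.data$subpop, .data$superpop) |>
    count(.data$subpop) |> filter(.data$n > 1L)
  if (nrow(bad_sub) > 0L) {
    abort(sprintf("subpopulation(s) mapped to more than one superpopulation: %s",
                  paste(bad_sub$subpop, collapse = ", ")))
  }
  panel
}
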
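# Shared fixtures, generated once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

default_fixture <- function() {
  if (is.null(.fixture_cache$paths)) {
    .fixture_cache$paths <- generate_fixture(
      fixture_spec(seed = 1L),
      dir = file.path(tempdir(), "genoprev-default-fixture"))
  }
  .fixture_cache$paths
}

default_cohort <- function() {
  if (is.null(.fixture_cache$cohort)) {
    .fixture_cache$cohort <- read_cohort_vcf(default_fixture()$vcf)
  }
  .fixture_cache$cohort
}

default_panel <- function() {
  if (is.null(.fixture_cache$panel)) {
    .fixture_cache$panel <- read_panel(default_fixture()$panel)
  }
  .fixture_cache$panel
}

default_catalog <- function() {
  if (is.null(.fixture_cache$catalog)) {
    .fixture_cache$catalog <- load_catalog(default_fixture()$catalog)
  }
  .fixture_cache$catalog
}

default_intersection <- function() {
  if (is.null(.fixture_cache$ix)) {
    .fixture_cache$ix <- intersect_catalog(default_cohort(), default_catalog())
  }
  .fixture_cache$ix
}

default_matched_freqs <- function() {
  if (is.null(.fixture_cache$freqs)) {
    ix <- default_intersection()
    .fixture_cache$freqs <- stratified_frequencies(
      default_cohort(), default_panel(),
      keys = ix$matched[, c("chrom", "pos", "ref", "alt")])
  }
  .fixture_cache$freqs
}

# Write a minimal VCF from parallel vectors; gts is a matrix
# (variants x samples) of GT strings.
write_mini_vcf <- function(path, chrom, pos, id, ref, alt, gts,
                           samples = sprintf("S%d", seq_len(ncol(gts)))) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  body <- paste(chrom, pos, id, ref, alt, ".", "PASS", ".", "GT",
                apply(gts, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  path
}

# Brute-force per-stratum allele tallies by looping over every
# (variant, sample) pair — the oracle for stratified_frequencies().
brute_force_counts <- function(cohort, panel, stratum_samples) {
  variants <- cohort_variants(cohort)
  out <- list()
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    ac <- 0L; an <- 0L; n_het <- 0L; n_hom <- 0L
    for (s in stratum_samples) {
      row <- cohort[cohort$chrom == v$chrom & cohort$pos == v$pos &
                    cohort$ref == v$ref & cohort$alt == v$alt &
                    cohort$sample_id == s, ]
      alleles <- c(row$a1, row$a2)
      an <- an + sum(!is.na(alleles))
      n_alt <- sum(alleles == 1L, na.rm = TRUE)
      ac <- ac + n_alt
      if (n_alt == 1L) n_het <- n_het + 1L
      if (n_alt == 2L) n_hom <- n_hom + 1L
    }
    out[[i]] <- tibble::tibble(chrom = v$chrom, pos = v$pos, ref = v$ref,
                               alt = v$alt, ac = ac, an = an,
                               n_het = n_het, n_hom_alt = n_hom)
  }
  dplyr::bind_rows(out)
}
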
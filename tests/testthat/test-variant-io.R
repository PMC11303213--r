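test_that("a biallelic SNV record transcribes directly into calls", {
  path <- withr::local_tempfile(fileext = ".vcf")
  write_mini_vcf(path, "chr17", 3550800L, "rs1", "G", "A",
                 matrix(c("0|0", "0|1", "1|1"), nrow = 1))
  cohort <- read_cohort_vcf(path)
  expect_equal(nrow(cohort_variants(cohort)), 1L)
  expect_equal(cohort_samples(cohort), c("S1", "S2", "S3"))
  expect_equal(cohort$a1, c(0L, 0L, 1L))
  expect_equal(cohort$a2, c(0L, 1L, 1L))
})

test_that("phase separators are both accepted and phase is discarded", {
  p1 <- withr::local_tempfile(fileext = ".vcf")
  p2 <- withr::local_tempfile(fileext = ".vcf")
  write_mini_vcf(p1, "17", 100L, ".", "A", "C", matrix(c("0|1", "1|1"), nrow = 1))
  write_mini_vcf(p2, "17", 100L, ".", "A", "C", matrix(c("0/1", "1/1"), nrow = 1))
  c1 <- read_cohort_vcf(p1)
  c2 <- read_cohort_vcf(p2)
  expect_equal(c1$a1, c2$a1)
  expect_equal(c1$a2, c2$a2)
  expect_equal(c1$chrom, c("chr17", "chr17"))  # chr prefix unified
})

# hand-enumerated recodings of every ordered GT pair over {0, 1, 2, .}
# for a multiallelic record A>G,T split into A>G (alt 1) and A>T (alt 2):
# per decomposed record, ref stays 0, the matching alt becomes 1, the other
# alt and missing become NA
multiallelic_truth <- local({
  alleles <- c("0", "1", "2", ".")
  grid <- expand.grid(x = alleles, y = alleles, stringsAsFactors = FALSE)
  recode <- function(a, j) {
    if (a == ".") return(NA_integer_)
    if (a == "0") return(0L)
    if (a == j) return(1L)
    NA_integer_
  }
  tibble::tibble(
    gt = paste0(grid$x, "|", grid$y),
    alt1_a1 = vapply(grid$x, recode, integer(1), j = "1", USE.NAMES = FALSE),
    alt1_a2 = vapply(grid$y, recode, integer(1), j = "1", USE.NAMES = FALSE),
    alt2_a1 = vapply(grid$x, recode, integer(1), j = "2", USE.NAMES = FALSE),
    alt2_a2 = vapply(grid$y, recode, integer(1), j = "2", USE.NAMES = FALSE)
  )
})

test_that("multiallelic records decompose with other-alt calls recoded to missing", {
  path <- withr::local_tempfile(fileext = ".vcf")
  write_mini_vcf(path, "chr1", 500L, ".", "A", "G,T",
                 matrix(multiallelic_truth$gt, nrow = 1))
  cohort <- read_cohort_vcf(path)
  variants <- cohort_variants(cohort)
  expect_equal(nrow(variants), 2L)
  expect_setequal(variants$alt, c("G", "T"))

  for (alt in c("G", "T")) {
    got <- cohort[cohort$alt == alt, ]
    got <- got[match(sprintf("S%d", seq_len(nrow(multiallelic_truth))), got$sample_id), ]
    truth_a1 <- if (alt == "G") multiallelic_truth$alt1_a1 else multiallelic_truth$alt2_a1
    truth_a2 <- if (alt == "G") multiallelic_truth$alt1_a2 else multiallelic_truth$alt2_a2
    expect_equal(got$a1, truth_a1, info = alt)
    expect_equal(got$a2, truth_a2, info = alt)
  }

  # the specific case 1|2: A>G gets (1, NA), A>T gets (NA, 1)
  s <- multiallelic_truth$gt == "1|2"
  id <- sprintf("S%d", which(s))
  g_row <- cohort[cohort$alt == "G" & cohort$sample_id == id, ]
  t_row <- cohort[cohort$alt == "T" & cohort$sample_id == id, ]
  expect_equal(c(g_row$a1, g_row$a2), c(1L, NA_integer_))
  expect_equal(c(t_row$a1, t_row$a2), c(NA_integer_, 1L))
})

test_that("decomposition conserves each alternate allele's count", {
  set.seed(42)
  for (rep in 1:5) {
    gts <- matrix(paste0(sample(c("0", "1", "2", "."), 12, replace = TRUE), "|",
                         sample(c("0", "1", "2", "."), 12, replace = TRUE)),
                  nrow = 1)
    path <- withr::local_tempfile(fileext = ".vcf")
    write_mini_vcf(path, "chr1", 500L, ".", "A", "G,T", gts)
    cohort <- read_cohort_vcf(path)
    raw <- unlist(strsplit(gts, "[|]"))
    for (alt_code in c("1", "2")) {
      alt_base <- c("1" = "G", "2" = "T")[[alt_code]]
      want <- sum(raw == alt_code)
      got <- sum(cohort$a1[cohort$alt == alt_base] == 1L, na.rm = TRUE) +
             sum(cohort$a2[cohort$alt == alt_base] == 1L, na.rm = TRUE)
      expect_equal(got, want)
    }
  }
})

test_that("region restriction returns exactly the overlapping record", {
  cohort <- read_cohort_vcf(default_fixture()$vcf,
                            region = "chr17:3550800-3550801")
  variants <- cohort_variants(cohort)
  expect_equal(nrow(variants), 1L)
  expect_equal(variants$pos, 3550800L)
  expect_equal(variants$ref, "G")
  expect_equal(variants$alt, "A")
  # half-open and empty: a window beyond the gene region holds nothing
  empty <- read_cohort_vcf(default_fixture()$vcf,
                           region = "chr17:9000000-9000001")
  expect_equal(nrow(cohort_variants(empty)), 0L)
})

test_that("malformed and structurally inconsistent VCFs are rejected with line numbers", {
  path <- withr::local_tempfile(fileext = ".vcf")
  lines <- readLines(write_mini_vcf(tempfile(fileext = ".vcf"),
                                    "chr1", c(100L, 200L), ".", c("A", "C"),
                                    c("G", "T"),
                                    matrix(c("0|1", "0|0", "1|1", "0|1"), nrow = 2)))
  # drop one genotype column from the second record -> structural error
  bad <- lines
  bad[5] <- sub("\t[^\t]*$", "", bad[5])
  writeLines(bad, path)
  expect_error(read_cohort_vcf(path), "line 5.*sample count mismatch")

  # non-numeric POS -> parse error naming the line
  bad2 <- lines
  bad2[4] <- sub("^chr1\t100", "chr1\tXYZ", bad2[4])
  writeLines(bad2, path)
  expect_error(read_cohort_vcf(path), "parse error.*line 4")
})

test_that("genotype tables round-trip through VCF", {
  rc <- generate_random_cohort(n_samples = 12, n_variants = 8,
                               missing_rate = 0.1, seed = 7)
  path <- withr::local_tempfile(fileext = ".vcf")
  write_cohort_vcf(rc$cohort, path)
  back <- read_cohort_vcf(path, chrom_style = "asis")
  orig <- dplyr::arrange(tibble::as_tibble(rc$cohort),
                         chrom, pos, ref, alt, sample_id)
  got <- dplyr::arrange(tibble::as_tibble(back),
                        chrom, pos, ref, alt, sample_id)
  expect_equal(got$pos, orig$pos)
  expect_equal(got$ref, orig$ref)
  expect_equal(got$alt, orig$alt)
  expect_equal(got$a1, orig$a1)
  expect_equal(got$a2, orig$a2)
})

test_that("panel parsing handles the 1000 Genomes dialect and its edge cases", {
  panel <- default_panel()
  expect_equal(nrow(panel), 1092L)
  expect_equal(length(unique(panel$superpop)), 4L)
  expect_equal(length(unique(panel$subpop)), 14L)

  p <- withr::local_tempfile()
  writeLines("HG00096 GBR EUR", p)
  one <- read_panel(p)
  expect_equal(one$sample_id, "HG00096")
  expect_equal(one$superpop, "EUR")

  writeLines(c("HG00096 GBR EUR extra_platform_column"), p)
  expect_equal(read_panel(p)$subpop, "GBR")

  writeLines(c("HG00096 GBR"), p)
  expect_error(read_panel(p), "parse error.*2 fields")

  writeLines(c("HG00096 GBR EUR", "HG00096 GBR EUR"), p)
  expect_equal(nrow(read_panel(p)), 1L)  # identical duplicates collapse

  writeLines(c("HG00096 GBR EUR", "HG00096 YRI AFR"), p)
  expect_error(read_panel(p), "conflicting population")

  writeLines(character(), p)
  expect_error(read_panel(p), "empty panel")
})

test_that("SNVs and simple prefix-sharing variants normalize by trimming", {
  out <- normalize_variants(tibble::tibble(
    chrom = c("chr17", "chr17"), pos = c(3550800L, 100L),
    ref = c("G", "CT"), alt = c("A", "CA")))
  expect_equal(out$pos, c(3550800L, 101L))
  expect_equal(out$ref, c("G", "T"))
  expect_equal(out$alt, c("A", "A"))

  expect_error(normalize_variants(tibble::tibble(
    chrom = "chr1", pos = 5L, ref = "AC", alt = "AC")), "ref equals alt")
})

# Exhaustive-search oracle for left alignment on a toy reference: among all
# representations (p, ref', alt') that reproduce the same mutated sequence,
# the canonical one has minimal total allele length, breaking ties leftward.
normalize_oracle <- function(genome, pos, ref, alt) {
  apply_var <- function(p, r, a) {
    paste0(substr(genome, 1, p - 1), a,
           substr(genome, p + nchar(r), nchar(genome)))
  }
  target <- apply_var(pos, ref, alt)
  best <- NULL
  for (p in seq_len(nchar(genome))) {
    for (lr in 1:6) {
      if (p + lr - 1L > nchar(genome)) next
      r <- substr(genome, p, p + lr - 1L)
      la <- nchar(target) - (nchar(genome) - lr)
      if (la < 1L) next
      a <- substr(target, p, p + la - 1L)
      if (apply_var(p, r, a) != target || r == a) next
      cand <- list(p = p, r = r, a = a, len = lr + la)
      if (is.null(best) || cand$len < best$len ||
          (cand$len == best$len && cand$p < best$p)) best <- cand
    }
  }
  best
}

test_that("indel left-alignment agrees with an exhaustive shift-search oracle", {
  genome <- "TTCAAAGCTA"
  ctx <- function(chrom, pos) substr(genome, pos, pos)
  cases <- list(
    list(pos = 5L, ref = "AA", alt = "A"),    # deletion in an A-run
    list(pos = 4L, ref = "AAA", alt = "A"),   # longer deletion
    list(pos = 5L, ref = "A", alt = "AA"),    # insertion in the run
    list(pos = 3L, ref = "CAA", alt = "CA"),  # prefixed deletion
    list(pos = 7L, ref = "GC", alt = "GT")    # MNV-ish, prefix shared
  )
  for (cs in cases) {
    got <- normalize_variants(
      tibble::tibble(chrom = "toy", pos = cs$pos, ref = cs$ref, alt = cs$alt),
      reference_context = ctx)
    want <- normalize_oracle(genome, cs$pos, cs$ref, cs$alt)
    expect_equal(got$pos, want$p, info = paste(cs, collapse = "/"))
    expect_equal(got$ref, want$r, info = paste(cs, collapse = "/"))
    expect_equal(got$alt, want$a, info = paste(cs, collapse = "/"))
  }
})

test_that("normalization is idempotent on randomly generated variants", {
  genome <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE), collapse = "")
  ctx <- function(chrom, pos) substr(genome, pos, pos)
  set.seed(11)
  made <- 0L
  while (made < 25L) {
    p <- sample(5:50, 1)
    lr <- sample(1:4, 1)
    ref <- substr(genome, p, p + lr - 1L)
    alt <- paste(sample(c("A", "C", "G", "T"), sample(1:4, 1), replace = TRUE),
                 collapse = "")
    if (ref == alt) next
    once <- normalize_variants(
      tibble::tibble(chrom = "toy", pos = p, ref = ref, alt = alt),
      reference_context = ctx)
    twice <- normalize_variants(once, reference_context = ctx)
    expect_equal(twice, once)
    made <- made + 1L
  }
})
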
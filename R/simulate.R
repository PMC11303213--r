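# Run code under a seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      suppressWarnings(rm(".Random.seed", envir = globalenv()))
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# 1000 Genomes Phase 1 panel composition: 14 subpopulations in 4
# superpopulations, 1092 samples in total.
default_subpops <- function() {
  tribble(
    ~subpop, ~superpop, ~n,
    "ASW", "AFR", 61L,
    "LWK", "AFR", 97L,
    "YRI", "AFR", 88L,
    "CLM", "AMR", 60L,
    "MXL", "AMR", 66L,
    "PUR", "AMR", 55L,
    "CHB", "EAS", 97L,
    "CHS", "EAS", 100L,
    "JPT", "EAS", 89L,
    "CEU", "EUR", 85L,
    "FIN", "EUR", 93L,
    "GBR", "EUR", 89L,
    "IBS", "EUR", 14L,
    "TSI", "EUR", 98L
  )
}

default_overlaps <- function() {
  tribble(
    ~chrom, ~pos, ~ref, ~alt, ~rsid, ~cdna, ~protein, ~consequence, ~phenotype,
    ~n_het, ~n_hom, ~carrier_superpop, ~carrier_weight,
    "chr17", 3550800L, "G", "A", "rs35086888", "c.124G>A", "p.Val42Ile",
    "missense", "atypical cystinosis", 35L, 0L, "AFR", 0.9,
    "chr17", 3559792L, "T", "C", "rs113994206", "c.473T>C", "p.Leu158Pro",
    "missense", "infantile nephropathic cystinosis", 1L, 0L, NA_character_, NA_real_
  )
}

#' Specification for a synthetic study fixture
#'
#' Describes a synthetic cohort with the statistical structure of a
#' single-gene carrier study: a fixed number of diploid samples partitioned
#' into 1000 Genomes-style sub/superpopulations, a set of cohort variants in
#' the gene region, a catalog of reported pathogenic variants, and a small
#' designed overlap between the two. Defaults mirror the CTNS/cystinosis study
#' conditions: 1092 samples in 14 subpopulations (4 superpopulations), 444
#' unique cohort variants, a 75-entry catalog, and exactly 2 shared variants —
#' c.124G>A (chr17:3550800 G>A) in 35 heterozygotes placed preferentially
#' (weight 0.9) in African-ancestry samples, and c.473T>C (chr17:3559792 T>C)
#' in 1 heterozygote; all overlap carriers are distinct individuals.
#'
#' @param n_samples Cohort size.
#' @param subpops Tibble `subpop, superpop, n` (counts must sum to
#'   `n_samples`).
#' @param n_cohort_variants Unique variants in the cohort VCF.
#' @param n_catalog_variants Catalog entries (overlaps plus decoys absent from
#'   the cohort).
#' @param overlaps Tibble of designed cohort-catalog overlap variants with
#'   carrier counts and optional superpopulation placement weights.
#' @param region `list(chrom, start, end)` gene region (half-open,
#'   1-based; GRCh37 CTNS locus by default).
#' @param seed Integer seed; the generated files are byte-identical for
#'   identical spec + seed.
#' @return A list of class `fixture_spec`.
#' @export
fixture_spec <- function(n_samples = 1092L,
                         subpops = default_subpops(),
                         n_cohort_variants = 444L,
                         n_catalog_variants = 75L,
                         overlaps = default_overlaps(),
                         region = list(chrom = "chr17", start = 3539125L,
                                       end = 3565000L),
                         seed = 20240724L) {
  region <- parse_region(region)
  subpops <- as_tibble(subpops)
  overlaps <- as_tibble(overlaps)
  if (sum(subpops$n) != n_samples) {
    abort(sprintf("subpopulation counts sum to %d, not n_samples = %d",
                  sum(subpops$n), n_samples))
  }
  if (any(overlaps$n_het + overlaps$n_hom > n_samples)) {
    abort("infeasible spec: overlap carrier count exceeds cohort size")
  }
  if (sum(overlaps$n_het + overlaps$n_hom) > n_samples) {
    abort("infeasible spec: overlap variants need more distinct carriers than there are samples")
  }
  if (anyDuplicated(variant_id(overlaps$chrom, overlaps$pos, overlaps$ref, overlaps$alt))) {
    abort("overlap variant keys must be unique")
  }
  if (any(overlaps$pos < region$start | overlaps$pos >= region$end |
          overlaps$chrom != region$chrom)) {
    abort("overlap variants must lie inside the region")
  }
  if (n_cohort_variants < nrow(overlaps) || n_catalog_variants < nrow(overlaps)) {
    abort("cohort and catalog sizes must accommodate the overlap variants")
  }
  structure(list(
    n_samples = as.integer(n_samples), subpops = subpops,
    n_cohort_variants = as.integer(n_cohort_variants),
    n_catalog_variants = as.integer(n_catalog_variants),
    overlaps = overlaps, region = region, seed = as.integer(seed)
  ), class = "fixture_spec")
}

#' Generate a synthetic cohort fixture on disk
#'
#' Writes the four study inputs described by a [fixture_spec()]: a phased
#' cohort VCF, a panel file in the 1000 Genomes dialect, a pathogenic-variant
#' catalog TSV, and an external per-ancestry allele-frequency TSV carrying the
#' published gnomAD-style frequencies of the common overlap variant (AFR
#' 6.26%, NFE 0.006%, FIN 0%, EAS 0.002%). Background cohort variants are
#' SNVs at positions drawn uniformly from the region (excluding overlap
#' positions) and are absent from the catalog; catalog decoys are absent from
#' the cohort (one decoy shares a cohort position but differs in alternate
#' allele, to exercise exact-key matching). Output is deterministic given the
#' spec and seed.
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory (created if needed).
#' @return Named list of paths: `vcf`, `panel`, `catalog`, `external_freq`,
#'   plus the `spec`.
#' @export
generate_fixture <- function(spec = fixture_spec(), dir = tempfile("fixture")) {
  stopifnot(inherits(spec, "fixture_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    vcf = file.path(dir, "cohort.vcf"),
    panel = file.path(dir, "samples.panel"),
    catalog = file.path(dir, "catalog.tsv"),
    external_freq = file.path(dir, "external_freq.tsv"),
    spec = spec
  )

  with_seed(spec$seed, {
    samples <- sprintf("SIM%04d", seq_len(spec$n_samples))
    panel <- tibble(
      sample_id = samples,
      subpop = rep(spec$subpops$subpop, spec$subpops$n),
      superpop = rep(spec$subpops$superpop, spec$subpops$n)
    )

    # --- carrier placement for the designed overlap variants -------------
    taken <- character()
    overlap_carriers <- vector("list", nrow(spec$overlaps))
    for (i in seq_len(nrow(spec$overlaps))) {
      ov <- spec$overlaps[i, ]
      k <- ov$n_het + ov$n_hom
      avail <- setdiff(samples, taken)
      if (!is.na(ov$carrier_superpop)) {
        in_grp <- intersect(avail, panel$sample_id[panel$superpop == ov$carrier_superpop])
        out_grp <- setdiff(avail, in_grp)
        k_in <- min(round(ov$carrier_weight * k), length(in_grp))
        k_out <- k - k_in
        if (k_out > length(out_grp)) {
          abort(sprintf("infeasible spec: cannot place %d carriers for %s with weights",
                        k, variant_id(ov$chrom, ov$pos, ov$ref, ov$alt)))
        }
        ids <- c(sample(in_grp, k_in), sample(out_grp, k_out))
      } else {
        if (k > length(avail)) abort("infeasible spec: more carriers than remaining samples")
        ids <- sample(avail, k)
      }
      overlap_carriers[[i]] <- list(
        het = ids[seq_len(ov$n_het)],
        hom = if (ov$n_hom > 0L) ids[ov$n_het + seq_len(ov$n_hom)] else character()
      )
      taken <- c(taken, ids)
    }

    # --- background cohort variants and catalog decoy positions ----------
    n_back <- spec$n_cohort_variants - nrow(spec$overlaps)
    n_decoy <- spec$n_catalog_variants - nrow(spec$overlaps)
    pool <- setdiff(seq.int(spec$region$start, spec$region$end - 1L),
                    spec$overlaps$pos)
    if (length(pool) < n_back + n_decoy) {
      abort("region too small for the requested variant counts")
    }
    pos_draw <- sample(pool, n_back + n_decoy)
    back_pos <- sort(pos_draw[seq_len(n_back)])
    decoy_pos <- sort(pos_draw[n_back + seq_len(n_decoy)])

    bases <- c("A", "C", "G", "T")
    back_ref <- sample(bases, n_back, replace = TRUE)
    back_alt <- map_chr(back_ref, function(r) sample(setdiff(bases, r), 1L))
    # rare-ish background allele counts: every variant is observed >= once
    back_ncar <- 1L + rbinom(n_back, size = 20L, prob = 0.08)

    # --- cohort VCF -------------------------------------------------------
    variants <- bind_rows(
      spec$overlaps |> select("chrom", "pos", "ref", "alt", "rsid"),
      tibble(chrom = spec$region$chrom, pos = back_pos, ref = back_ref,
             alt = back_alt, rsid = NA_character_)
    ) |> arrange(.data$pos)

    is_overlap <- match(variant_id(variants$chrom, variants$pos, variants$ref, variants$alt),
                        variant_id(spec$overlaps$chrom, spec$overlaps$pos,
                                   spec$overlaps$ref, spec$overlaps$alt))
    back_idx <- cumsum(is.na(is_overlap))  # index into background vectors

    gt_lines <- character(nrow(variants))
    for (r in seq_len(nrow(variants))) {
      gt <- rep("0|0", spec$n_samples)
      if (!is.na(is_overlap[r])) {
        cars <- overlap_carriers[[is_overlap[r]]]
        het_sides <- sample(c("0|1", "1|0"), length(cars$het), replace = TRUE)
        gt[match(cars$het, samples)] <- het_sides
        gt[match(cars$hom, samples)] <- "1|1"
      } else {
        ids <- sample(samples, back_ncar[back_idx[r]])
        gt[match(ids, samples)] <- sample(c("0|1", "1|0"), length(ids), replace = TRUE)
      }
      gt_lines[r] <- paste(gt, collapse = "\t")
    }
    header <- c(
      "##fileformat=VCFv4.2",
      "##source=genoprev-synthetic-fixture",
      sprintf("##reference=%s", genome_build()),
      sprintf("##contig=<ID=%s>", spec$region$chrom),
      "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
      paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
              "FORMAT", samples), collapse = "\t")
    )
    body <- paste(variants$chrom, variants$pos,
                  ifelse(is.na(variants$rsid), ".", variants$rsid),
                  variants$ref, variants$alt, ".", "PASS", ".", "GT", gt_lines,
                  sep = "\t")
    readr::write_lines(c(header, body), paths$vcf)

    # --- panel ------------------------------------------------------------
    readr::write_lines(
      paste(panel$sample_id, panel$subpop, panel$superpop, "SYNTH", sep = "\t"),
      paths$panel)

    # --- catalog ----------------------------------------------------------
    decoy_ref <- sample(bases, n_decoy, replace = TRUE)
    decoy_alt <- map_chr(decoy_ref, function(r) sample(setdiff(bases, r), 1L))
    decoys <- tibble(
      chrom = spec$region$chrom, pos = decoy_pos, ref = decoy_ref,
      alt = decoy_alt, rsid = NA_character_,
      cdna = sprintf("c.%d%s>%s", seq_len(n_decoy) * 3L, decoy_ref, decoy_alt),
      protein = "p.?",
      consequence = sample(c("missense", "nonsense", "splice", "frameshift"),
                           n_decoy, replace = TRUE),
      classification = "pathogenic",
      phenotype = "cystinosis"
    )
    if (n_decoy > 0L && nrow(variants) > nrow(spec$overlaps)) {
      # one decoy re-uses a cohort position with a different alternate allele,
      # so exact (chrom, pos, ref, alt) matching is exercised
      bg <- variants |> filter(is.na(is_overlap)) |> slice(1L)
      other_alt <- setdiff(bases, c(bg$ref, bg$alt))[1]
      decoys[1, c("pos", "ref", "alt")] <- list(bg$pos, bg$ref, other_alt)
    }
    catalog <- bind_rows(
      spec$overlaps |>
        mutate(classification = "pathogenic") |>
        select("chrom", "pos", "ref", "alt", "rsid", "cdna", "protein",
               "consequence", "classification", "phenotype"),
      decoys
    ) |> arrange(.data$pos)
    readr::write_tsv(catalog, paths$catalog)

    # --- external per-ancestry frequencies -------------------------------
    common <- spec$overlaps[1, ]
    ext <- tibble(
      variant = common$cdna,
      ancestry = c("AFR", "NFE", "FIN", "EAS"),
      af = c("6.26%", "0.006%", "0%", "0.002%")
    )
    readr::write_tsv(ext, paths$external_freq)
  })

  paths
}

#' Generate a small random cohort for property testing
#'
#' Draws per-variant allele frequencies from a Beta distribution (or uses a
#' fixed frequency) and samples diploid genotypes binomially — no linkage,
#' relatedness, or sequencing error. Intended as an input source for
#' oracle-equivalence and aggregation-consistency checks.
#'
#' @param n_samples,n_variants Cohort dimensions (>= 1).
#' @param af Fixed allele frequency for every variant, or `NULL` (default) to
#'   draw per-variant frequencies from `Beta(af_shape1, af_shape2)`.
#' @param af_shape1,af_shape2 Beta parameters for the frequency distribution
#'   (defaults give mostly rare variants, mean 0.05).
#' @param missing_rate Probability that an allele call is missing.
#' @param seed Integer seed.
#' @param dir Optional directory: when given, the cohort VCF and panel are
#'   also written there.
#' @return List with `cohort` (a `genotype_tbl`), `panel` (tibble), `af`
#'   (the per-variant truth), and file `paths` when `dir` was given.
#' @export
generate_random_cohort <- function(n_samples, n_variants, af = NULL,
                                   af_shape1 = 1, af_shape2 = 19,
                                   missing_rate = 0, seed = 1L, dir = NULL) {
  stopifnot(n_samples >= 1L, n_variants >= 1L)
  with_seed(seed, {
    samples <- sprintf("S%03d", seq_len(n_samples))
    afs <- if (!is.null(af)) rep(af, n_variants) else rbeta(n_variants, af_shape1, af_shape2)
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, n_variants, replace = TRUE)
    alt <- map_chr(ref, function(r) sample(setdiff(bases, r), 1L))
    pos <- sort(sample.int(1e6L, n_variants))

    calls <- tidyr::crossing(
      tibble(chrom = "chr1", pos = pos, ref = ref, alt = alt,
             rsid = NA_character_, .af = afs),
      tibble(sample_id = samples)
    ) |>
      mutate(
        a1 = rbinom(n(), 1L, .data$.af),
        a2 = rbinom(n(), 1L, .data$.af)
      )
    if (missing_rate > 0) {
      calls <- calls |>
        mutate(a1 = ifelse(stats::runif(n()) < missing_rate, NA_integer_, .data$a1),
               a2 = ifelse(stats::runif(n()) < missing_rate, NA_integer_, .data$a2))
    }
    cohort <- new_genotype_tbl(calls |> select(-".af"), samples)

    supers <- c("POP1", "POP1", "POP2", "POP2")
    subs <- c("SUBA", "SUBB", "SUBC", "SUBD")
    idx <- ((seq_len(n_samples) - 1L) %% 4L) + 1L
    panel <- tibble(sample_id = samples, subpop = subs[idx], superpop = supers[idx])

    out <- list(cohort = cohort, panel = panel, af = afs)
    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      vcf_path <- file.path(dir, "random_cohort.vcf")
      panel_path <- file.path(dir, "random_cohort.panel")
      write_cohort_vcf(cohort, vcf_path)
      readr::write_lines(paste(panel$sample_id, panel$subpop, panel$superpop,
                               sep = "\t"), panel_path)
      out$paths <- list(vcf = vcf_path, panel = panel_path)
    }
    out
  })
}
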
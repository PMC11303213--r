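#' Pipeline run configuration
#'
#' Declarative configuration for [run_pipeline()]: input paths, gene region,
#' frequency-evidence thresholds, variant-inclusion policy, and output
#' directory. A config can also be loaded from a JSON file with
#' [read_run_config()]; command-line flags in the shipped CLI override config
#' keys one-to-one.
#'
#' @param vcf,panel,catalog Input paths (cohort VCF, sample panel, catalog).
#' @param external_freq Optional path to a per-ancestry frequency TSV.
#' @param region Optional region restriction (string or list; see
#'   [read_cohort_vcf()]).
#' @param thresholds An [evidence_thresholds()] object.
#' @param policy Inclusion policies to evaluate (subset of `all`,
#'   `acmg_filtered`, `leave_one_out`, `explicit`).
#' @param include Explicit inclusion keys (for `policy = "explicit"`).
#' @param out_dir Output directory for reports.
#' @param catalog_format `"tsv"` or `"vcf"`.
#' @param chrom_style Chromosome-name unification (`"chr"`, `"plain"`,
#'   `"asis"`).
#' @param seed Seed recorded in the run summary (used by the CLI `simulate`
#'   subcommand).
#' @return A list of class `run_config`.
#' @export
run_config <- function(vcf, panel, catalog, external_freq = NULL,
                       region = NULL, thresholds = evidence_thresholds(),
                       policy = c("all", "acmg_filtered"), include = NULL,
                       out_dir = tempfile("genoprev_run"),
                       catalog_format = "tsv", chrom_style = "chr",
                       seed = NULL) {
  for (p in c(vcf = vcf, panel = panel, catalog = catalog,
              external_freq = external_freq)) {
    if (!is.null(p) && !file.exists(p)) {
      abort(sprintf("configuration invalid: input path does not exist: %s", p))
    }
  }
  allowed <- c("all", "acmg_filtered", "leave_one_out", "explicit")
  bad <- setdiff(policy, allowed)
  if (length(bad) > 0L) {
    abort(sprintf("unknown policy: %s (allowed: %s)",
                  paste(bad, collapse = ", "), paste(allowed, collapse = ", ")))
  }
  stopifnot(inherits(thresholds, "evidence_thresholds"))
  structure(list(
    vcf = vcf, panel = panel, catalog = catalog,
    external_freq = external_freq, region = region,
    thresholds = thresholds, policy = policy, include = include,
    out_dir = out_dir, catalog_format = catalog_format,
    chrom_style = chrom_style, seed = seed
  ), class = "run_config")
}

#' @rdname run_config
#' @param path JSON config file; keys as in `run_config()` (the `thresholds`
#'   entry holds `ba1`/`bs1`/`pm2_max`).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  th <- cfg$thresholds %||% list()
  run_config(
    vcf = cfg$vcf, panel = cfg$panel, catalog = cfg$catalog,
    external_freq = cfg$external_freq,
    region = cfg$region,
    thresholds = evidence_thresholds(ba1 = th$ba1 %||% 0.05, bs1 = th$bs1,
                                     pm2_max = th$pm2_max),
    policy = cfg$policy %||% c("all", "acmg_filtered"),
    include = cfg$include,
    out_dir = cfg$out_dir %||% tempfile("genoprev_run"),
    catalog_format = cfg$catalog_format %||% "tsv",
    chrom_style = cfg$chrom_style %||% "chr",
    seed = cfg$seed
  )
}

#' Frequency-evidence classification for every matched variant
#'
#' For each variant in the intersection, assembles its per-ancestry
#' allele-frequency map — from the external table when the variant appears
#' there (matched on HGVS c. name or `chrom:pos:ref:alt` key), otherwise from
#' the cohort's superpopulation frequencies — assigns ACMG frequency evidence,
#' and reconciles it against the catalog's asserted classification.
#'
#' @param intersection An `intersection_result`.
#' @param records Output of [stratified_frequencies()].
#' @param external Optional [read_external_frequencies()] table.
#' @param thresholds An [evidence_thresholds()] object.
#' @return Reconciliation tibble (one row per matched variant) with a
#'   `freq_source` column (`"external"` or `"cohort"`); the underlying
#'   `evidence_assignment` objects are attached as the `assignments`
#'   attribute, named by `chrom:pos:ref:alt` key.
#' @export
classify_frequencies <- function(intersection, records, external = NULL,
                                 thresholds = evidence_thresholds()) {
  matched <- intersection$matched
  if (nrow(matched) == 0L) {
    out <- tibble(chrom = character(), pos = integer(), ref = character(),
                  alt = character(), cdna = character(), asserted = character(),
                  frequency_classification = character(), triggered = character(),
                  triggering_strata = character(), verdict = character(),
                  conflict = logical(), freq_source = character())
    attr(out, "assignments") <- list()
    return(out)
  }
  rows <- vector("list", nrow(matched))
  assignments <- list()
  for (i in seq_len(nrow(matched))) {
    v <- matched[i, ]
    key <- variant_id(v$chrom, v$pos, v$ref, v$alt)
    ext_rows <- if (!is.null(external)) {
      external |> filter(.data$variant %in% c(v$cdna, key))
    } else NULL
    if (!is.null(ext_rows) && nrow(ext_rows) > 0L) {
      freqs <- setNames(ext_rows$af, ext_rows$ancestry)
      src <- "external"
    } else {
      grp <- as_tibble(records) |>
        filter(.data$level == "superpop", .data$chrom == v$chrom,
               .data$pos == v$pos, .data$ref == v$ref, .data$alt == v$alt,
               .data$an > 0L)
      freqs <- setNames(grp$af, grp$stratum)
      src <- "cohort"
    }
    assignment <- assign_evidence(freqs, thresholds)
    assignments[[key]] <- assignment
    rows[[i]] <- reconcile(assignment, v) |> mutate(freq_source = src)
  }
  out <- list_rbind(rows)
  attr(out, "assignments") <- assignments
  out
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  })
}

#' Run the full prevalence pipeline
#'
#' Executes read -> intersect -> stratified frequencies -> frequency evidence
#' -> reconciliation -> inclusion scenarios, and writes the intersection,
#' frequency, reconciliation and prevalence reports (TSV; prevalence also as
#' JSON) plus a JSON run summary (tool version, genome build, input MD5
#' hashes, config, headline quantities) into `config$out_dir`.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the in-memory results: `cohort` (dimensions
#'   only), `intersection`, `frequencies`, `reconciliation`, `scenarios`, and
#'   `summary` (the content of `summary.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  cohort <- stage("read_cohort_vcf",
                  read_cohort_vcf(config$vcf, region = config$region,
                                  chrom_style = config$chrom_style))
  panel <- stage("read_panel", read_panel(config$panel))
  catalog <- stage("load_catalog",
                   load_catalog(config$catalog, format = config$catalog_format,
                                chrom_style = config$chrom_style))
  ix <- stage("intersect", intersect_catalog(cohort, catalog))
  freqs <- stage("stratified_frequencies",
                 stratified_frequencies(cohort, panel,
                                        keys = ix$matched |>
                                          select("chrom", "pos", "ref", "alt")))
  external <- if (!is.null(config$external_freq)) {
    stage("read_external_frequencies",
          read_external_frequencies(config$external_freq))
  } else NULL
  recon <- stage("classify",
                 classify_frequencies(ix, freqs, external = external,
                                      thresholds = config$thresholds))
  scenarios <- stage("prevalence",
                     sensitivity_scenarios(freqs, ix, reconciliations = recon,
                                           policy = config$policy,
                                           include = config$include))

  # ---- reports ----------------------------------------------------------
  intersection_report <- ix$matched |>
    mutate(genome_build = genome_build(),
           observed_af = ifelse(.data$an > 0, .data$ac / .data$an, NA_real_))
  readr::write_tsv(intersection_report,
                   file.path(config$out_dir, "intersection_report.tsv"))

  frequency_report <- freqs |>
    mutate(af_pct_rounded = ifelse(is.na(.data$af), NA_character_,
                                   format_percent(.data$af, "round")),
           af_pct_truncated = ifelse(is.na(.data$af), NA_character_,
                                     format_percent(.data$af, "truncate")),
           genome_build = genome_build())
  readr::write_tsv(frequency_report,
                   file.path(config$out_dir, "frequency_report.tsv"))

  readr::write_tsv(recon |> mutate(genome_build = genome_build()),
                   file.path(config$out_dir, "reconciliation_report.tsv"))

  prevalence_report <- tidy(scenarios) |>
    mutate(q_exact = sprintf("%d/%d", as.integer(.data$q_num), as.integer(.data$q_den)),
           q_pct_rounded = format_percent(.data$q, "round"),
           q_pct_truncated = format_percent(.data$q, "truncate"),
           carrier_convention_hwe = "2pq (Hardy-Weinberg)",
           carrier_convention_observed = "distinct carriers / cohort size",
           genome_build = genome_build())
  readr::write_tsv(prevalence_report,
                   file.path(config$out_dir, "prevalence_report.tsv"))
  jsonlite::write_json(prevalence_report,
                       file.path(config$out_dir, "prevalence_report.json"),
                       dataframe = "rows", digits = NA, pretty = TRUE)

  input_paths <- purrr::compact(list(vcf = config$vcf, panel = config$panel,
                                     catalog = config$catalog,
                                     external_freq = config$external_freq))
  summary <- list(
    tool = "genoprev",
    version = as.character(packageVersion("genoprev")),
    genome_build = genome_build(),
    inputs = map(input_paths, function(p) {
      list(path = p, md5 = unname(tools::md5sum(p)))
    }),
    config = list(
      region = if (is.null(config$region)) NULL else unlist(parse_region(config$region)),
      thresholds = list(ba1 = config$thresholds$ba1,
                        bs1 = config$thresholds$bs1,
                        pm2_max = config$thresholds$pm2_max),
      policy = config$policy, catalog_format = config$catalog_format,
      chrom_style = config$chrom_style, seed = config$seed
    ),
    cohort = list(n_samples = ix$n_samples,
                  n_variants = nrow(cohort_variants(cohort))),
    intersection = list(n_matched = nrow(ix$matched),
                        n_carrier_samples = length(ix$carrier_samples)),
    scenarios = map(seq_len(nrow(scenarios)), function(i) {
      s <- scenarios[i, ]
      list(scenario = s$scenario, n_variants = s$n_variants,
           q = sprintf("%d/%d", as.integer(s$q_num), as.integer(s$q_den)),
           q_decimal = s$q,
           carrier_rate_hwe = s$carrier_rate_hwe,
           carrier_rate_observed = s$carrier_rate_observed,
           affected_rate = s$affected_rate,
           one_in_carrier_hwe = s$one_in_carrier_hwe,
           one_in_carrier_observed = s$one_in_carrier_observed,
           one_in_affected = s$one_in_affected)
    })
  )
  summary <- summary[order(names(summary))]
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")

  invisible(list(
    cohort_dim = c(n_variants = nrow(cohort_variants(cohort)),
                   n_samples = length(cohort_samples(cohort))),
    intersection = ix,
    frequencies = freqs,
    reconciliation = recon,
    scenarios = scenarios,
    summary = summary,
    out_dir = config$out_dir
  ))
}
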
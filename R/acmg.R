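#' ACMG frequency-evidence thresholds
#'
#' Container for the frequency cutoffs of the ACMG/AMP classification
#' framework used here: BA1 (stand-alone benign; allele frequency strictly
#' above 5% in at least one continental ancestry group), optional BS1 (strong
#' benign), and optional PM2 (moderate pathogenic support when the allele is
#' absent or below a rarity ceiling in every group). BS1 and PM2 are disabled
#' unless explicitly configured.
#'
#' @param ba1 Stand-alone benign threshold, a fraction; triggered by
#'   `af > ba1` (strict). Default 0.05.
#' @param bs1 Optional strong benign threshold; must be `< ba1` when set.
#' @param pm2_max Optional rarity ceiling for pathogenic support; must be
#'   below `bs1` (when set) and `ba1`.
#' @return A list of class `evidence_thresholds`.
#' @export
evidence_thresholds <- function(ba1 = 0.05, bs1 = NULL, pm2_max = NULL) {
  stopifnot(is.numeric(ba1), length(ba1) == 1L, ba1 > 0, ba1 <= 1)
  if (!is.null(bs1)) stopifnot(is.numeric(bs1), bs1 > 0, bs1 < ba1)
  if (!is.null(pm2_max)) {
    stopifnot(is.numeric(pm2_max), pm2_max >= 0, pm2_max < ba1)
    if (!is.null(bs1)) stopifnot(pm2_max < bs1)
  }
  structure(list(ba1 = ba1, bs1 = bs1, pm2_max = pm2_max),
            class = "evidence_thresholds")
}

#' Assign ACMG frequency evidence from per-ancestry allele frequencies
#'
#' Evaluates the frequency-based evidence codes for one variant against a map
#' of per-ancestry-group allele frequencies. BA1 triggers when the frequency
#' exceeds the threshold (strictly) in *at least one* ancestry group — the
#' any-group-exceeds semantics under which a variant common in a single
#' continental population is stand-alone benign even though the pooled cohort
#' frequency stays low. PM2 (when configured) requires every group to be at or
#' below the rarity ceiling.
#'
#' @param freqs Named numeric vector (names = ancestry groups, values =
#'   allele-frequency fractions) or a data frame with columns
#'   `ancestry`/`group` and `af`.
#' @param thresholds An [evidence_thresholds()] object.
#' @return A list of class `evidence_assignment`:
#'   `triggered` (character subset of BA1/BS1/PM2), `triggering_strata`
#'   (tibble `code`, `ancestry`, `af`), `frequency_classification` (one of
#'   `benign`, `likely_benign`, `supports_pathogenic`, `no_frequency_call`),
#'   and `per_group_calls` (tibble `ancestry`, `af`, `call`: the
#'   classification that group's frequency alone would support).
#' @examples
#' assign_evidence(c(AFR = 0.0626, NFE = 0.00006, FIN = 0, EAS = 0.00002),
#'                 evidence_thresholds(ba1 = 0.05))
#' @export
assign_evidence <- function(freqs, thresholds = evidence_thresholds()) {
  stopifnot(inherits(thresholds, "evidence_thresholds"))
  if (is.data.frame(freqs)) {
    grp_col <- intersect(c("ancestry", "group", "stratum"), names(freqs))[1]
    if (is.na(grp_col) || !"af" %in% names(freqs)) {
      abort("freqs data frame needs an ancestry/group column and an af column")
    }
    freqs <- setNames(freqs$af, freqs[[grp_col]])
  }
  if (length(freqs) == 0L) {
    warn("empty frequency map: no frequency-based call possible")
    return(structure(list(
      triggered = character(),
      triggering_strata = tibble(code = character(), ancestry = character(), af = double()),
      frequency_classification = "no_frequency_call",
      per_group_calls = tibble(ancestry = character(), af = double(), call = character())
    ), class = "evidence_assignment"))
  }
  stopifnot(!is.null(names(freqs)), all(freqs >= 0 & freqs <= 1))
  freqs <- freqs[order(names(freqs))]  # independent of input iteration order

  group_call <- function(af) {
    if (af > thresholds$ba1) return("benign")
    if (!is.null(thresholds$bs1) && af > thresholds$bs1) return("likely_benign")
    if (!is.null(thresholds$pm2_max) && af <= thresholds$pm2_max) return("supports_pathogenic")
    "no_frequency_call"
  }
  per_group <- tibble(ancestry = names(freqs), af = unname(freqs)) |>
    mutate(call = map_chr(.data$af, group_call))

  triggered <- character()
  strata <- list()
  ba1_grp <- per_group |> filter(.data$af > thresholds$ba1)
  if (nrow(ba1_grp) > 0L) {
    triggered <- c(triggered, "BA1")
    strata$BA1 <- ba1_grp |> mutate(code = "BA1")
  }
  if (!is.null(thresholds$bs1)) {
    bs1_grp <- per_group |> filter(.data$af > thresholds$bs1)
    if (nrow(bs1_grp) > 0L) {
      triggered <- c(triggered, "BS1")
      strata$BS1 <- bs1_grp |> mutate(code = "BS1")
    }
  }
  if (!is.null(thresholds$pm2_max) && all(per_group$af <= thresholds$pm2_max)) {
    triggered <- c(triggered, "PM2")
    strata$PM2 <- per_group |> mutate(code = "PM2")
  }
  triggering_strata <- if (length(strata) > 0L) {
    list_rbind(unname(strata)) |> select("code", "ancestry", "af")
  } else {
    tibble(code = character(), ancestry = character(), af = double())
  }

  frequency_classification <-
    if ("BA1" %in% triggered) "benign"
    else if ("BS1" %in% triggered) "likely_benign"
    else if ("PM2" %in% triggered) "supports_pathogenic"
    else "no_frequency_call"

  structure(list(
    triggered = triggered,
    triggering_strata = triggering_strata,
    frequency_classification = frequency_classification,
    per_group_calls = per_group
  ), class = "evidence_assignment")
}

#' @export
print.evidence_assignment <- function(x, ...) {
  cat(sprintf("Frequency evidence: %s (codes: %s)\n",
              x$frequency_classification,
              if (length(x$triggered)) paste(x$triggered, collapse = ", ") else "none"))
  print(x$per_group_calls, ...)
  invisible(x)
}

#' @describeIn assign_evidence tidy() method: the per-group call table.
#' @method tidy evidence_assignment
#' @param x An `evidence_assignment`.
#' @param ... Unused.
#' @export
tidy.evidence_assignment <- function(x, ...) x$per_group_calls

#' Reconcile frequency evidence with an asserted classification
#'
#' Compares the frequency-based classification of a variant against the
#' classification asserted by the catalog and emits a verdict:
#' `conflict_benign_vs_pathogenic` when a benign-direction frequency call
#' meets a pathogenic/likely-pathogenic assertion (the situation in which the
#' ACMG frequency rule would exclude a variant the literature reports as
#' disease-causing), `frequency_silent` when the frequency data support no
#' call, and `concordant` otherwise. Reconciliation only flags; it never
#' removes a variant — inclusion decisions are made explicitly in
#' [sensitivity_scenarios()].
#'
#' @param assignment An `evidence_assignment` from [assign_evidence()].
#' @param catalog_entry One catalog row (tibble with the variant's key and
#'   `classification`); keys are checked when present on both sides.
#' @return One-row tibble: key columns (if available), `cdna`, `asserted`,
#'   `frequency_classification`, `triggered`, `triggering_strata` (compact
#'   string), `verdict`, `conflict` (logical).
#' @export
reconcile <- function(assignment, catalog_entry) {
  stopifnot(inherits(assignment, "evidence_assignment"))
  if (is.data.frame(catalog_entry)) {
    if (nrow(catalog_entry) != 1L) abort("catalog_entry must be a single catalog row")
    entry <- as.list(catalog_entry)
  } else {
    entry <- as.list(catalog_entry)
  }
  asserted <- entry$classification %||% abort("catalog_entry lacks a classification")
  if (!asserted %in% classification_vocab) {
    abort(sprintf("unknown asserted classification '%s'", asserted))
  }
  freq_class <- assignment$frequency_classification
  benign_dir <- freq_class %in% c("benign", "likely_benign")
  path_assert <- asserted %in% c("pathogenic", "likely_pathogenic")

  verdict <-
    if (freq_class == "no_frequency_call") "frequency_silent"
    else if (benign_dir && path_assert) "conflict_benign_vs_pathogenic"
    else "concordant"

  strata_str <- assignment$triggering_strata |>
    mutate(s = sprintf("%s:%s=%.4g", .data$code, .data$ancestry, .data$af)) |>
    pull("s") |> paste(collapse = ";")

  tibble(
    chrom = entry$chrom %||% NA_character_,
    pos = entry$pos %||% NA_integer_,
    ref = entry$ref %||% NA_character_,
    alt = entry$alt %||% NA_character_,
    cdna = entry$cdna %||% NA_character_,
    asserted = asserted,
    frequency_classification = freq_class,
    triggered = paste(assignment$triggered, collapse = ","),
    triggering_strata = strata_str,
    verdict = verdict,
    conflict = verdict == "conflict_benign_vs_pathogenic"
  )
}
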
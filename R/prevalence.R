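#' Exact fractions for allele-frequency arithmetic
#'
#' Allele frequencies here are ratios of small integer counts, and the
#' headline quantities (2pq, q^2 and their reciprocals) are exact rationals —
#' e.g. an affected rate of 1/2184^2 is exactly 1 in 4,769,856. `frac()`
#' keeps numerator and denominator as integers so these identities hold
#' bit-for-bit; conversion to double happens only at formatting time.
#'
#' @param num,den Non-negative numerator and positive denominator (integers).
#' @return An object of class `frac`.
#' @export
frac <- function(num, den) {
  num <- as.numeric(num); den <- as.numeric(den)
  stopifnot(length(num) == 1L, length(den) == 1L, den > 0, num >= 0,
            num == trunc(num), den == trunc(den))
  structure(list(num = num, den = den), class = "frac")
}

#' @export
as.double.frac <- function(x, ...) x$num / x$den

#' @export
print.frac <- function(x, ...) {
  cat(sprintf("%s/%s (= %.10g)\n",
              format(x$num, big.mark = ","), format(x$den, big.mark = ","),
              x$num / x$den))
  invisible(x)
}

#' Combined pathogenic allele frequency for an inclusion set
#'
#' Sums the allele counts of the included pathogenic variants over one shared
#' allele-number denominator: `q = sum(AC) / AN`. This treats all included
#' pathogenic alleles as interchangeable alleles of a single locus (full
#' allelic heterogeneity), which is what makes `q^2` the affected rate
#' downstream. All records must belong to the same population stratum.
#'
#' @param records Allele-frequency records (rows of
#'   [stratified_frequencies()] output) for the included variants.
#' @param stratum Population stratum to use (default `"ALL"`); the records are
#'   filtered to it and must all carry it.
#' @param an_policy When records disagree on AN (differential missingness):
#'   `"strict"` errors (default), `"max"` uses the largest AN.
#' @return A `frac`: q as an exact rational (0/AN-sized denominator when the
#'   inclusion set is empty).
#' @export
combined_q <- function(records, stratum = "ALL", an_policy = c("strict", "max")) {
  an_policy <- match.arg(an_policy)
  rec <- as_tibble(records) |> filter(.data$stratum == !!stratum)
  if (nrow(rec) == 0L) {
    if (nrow(records) > 0L) {
      abort(sprintf("no records for stratum '%s' (mixed or wrong strata?)", stratum))
    }
    return(frac(0, 1))
  }
  ans <- unique(rec$an)
  if (any(ans == 0L)) abort("undefined frequency: allele number is 0 in this stratum")
  if (length(ans) > 1L) {
    if (an_policy == "strict") {
      abort(sprintf(
        "records disagree on AN within stratum '%s' (%s); q = sum(AC)/AN needs one denominator (an_policy = \"max\" to override)",
        stratum, paste(ans, collapse = ", ")))
    }
    warn("records disagree on AN; using the largest")
  }
  frac(sum(rec$ac), max(ans))
}

#' Hardy-Weinberg carrier and affected rates
#'
#' Under Hardy-Weinberg equilibrium with pathogenic allele frequency `q` and
#' `p = 1 - q`, the expected carrier rate is `2pq` and the expected affected
#' rate is `q^2`. Given a `frac`, both are returned as exact rationals.
#'
#' @param q Pathogenic allele frequency: a number in `[0, 1]` or a [frac()].
#' @return List with `carrier_rate_hwe` and `affected_rate`, of the same type
#'   as the input.
#' @examples
#' hwe_rates(frac(36, 2184))
#' @export
hwe_rates <- function(q) {
  if (inherits(q, "frac")) {
    n <- q$num; d <- q$den
    stopifnot(n <= d)
    return(list(
      carrier_rate_hwe = frac(2 * n * (d - n), d * d),
      affected_rate = frac(n * n, d * d)
    ))
  }
  stopifnot(is.numeric(q), all(q >= 0 & q <= 1))
  list(carrier_rate_hwe = 2 * q * (1 - q), affected_rate = q^2)
}

#' Observed carrier rate
#'
#' The directly observed analogue of 2pq: the number of distinct individuals
#' carrying at least one matched pathogenic allele, divided by the cohort
#' size. Reported alongside the Hardy-Weinberg expectation because the two
#' conventions differ slightly (e.g. 36 heterozygous carriers among 1092
#' samples give 1 in 30 observed but 1 in 31 is *not* the HWE value — HWE on
#' the corresponding q gives its own reciprocal).
#'
#' @param result An `intersection_result` from [intersect_catalog()], or a
#'   count of distinct carriers.
#' @param cohort_size Number of individuals in the cohort (positive).
#' @return A `frac`: carriers / cohort size.
#' @export
observed_carrier_rate <- function(result, cohort_size = NULL) {
  if (inherits(result, "intersection_result")) {
    n_carriers <- length(result$carrier_samples)
    cohort_size <- cohort_size %||% result$n_samples
  } else {
    n_carriers <- as.numeric(result)
  }
  if (is.null(cohort_size) || cohort_size <= 0) {
    abort("cohort_size must be a positive integer")
  }
  if (n_carriers > cohort_size) abort("more carriers than samples")
  frac(n_carriers, cohort_size)
}

#' "1 in X" rendering of a rate
#'
#' Reciprocal of a rate, rounded half-up to the nearest integer; exact when
#' the input is a [frac()] (integer arithmetic, no floating error — so
#' 4366/4769856 gives 1093 from a reciprocal of 1092.5002, and 1/4769856
#' gives exactly 4769856). A zero rate returns `Inf` (the "never" sentinel).
#'
#' @param rate A rate in `(0, 1]`, numeric or `frac`.
#' @return The integer X of "1 in X" (as a double, since X can exceed
#'   `.Machine$integer.max`-scale values); `Inf` for a zero rate.
#' @examples
#' one_in(frac(1296, 4769856))  # 3680
#' one_in(frac(4366, 4769856))  # 1093
#' @export
one_in <- function(rate) {
  if (inherits(rate, "frac")) {
    if (rate$num == 0) return(Inf)
    # floor(den/num + 1/2) without leaving integer arithmetic
    return((2 * rate$den + rate$num) %/% (2 * rate$num))
  }
  stopifnot(is.numeric(rate), length(rate) == 1L, rate >= 0, rate <= 1)
  if (rate == 0) return(Inf)
  floor(1 / rate + 0.5)
}

#' Prevalence estimates across variant inclusion scenarios
#'
#' Builds one Hardy-Weinberg prevalence estimate per inclusion scenario of
#' the matched pathogenic variants. Policies:
#' \describe{
#'   \item{`all`}{every matched variant included;}
#'   \item{`acmg_filtered`}{variants whose reconciliation verdict is
#'     `conflict_benign_vs_pathogenic` (asserted pathogenic but stand-alone
#'     benign by frequency) are dropped;}
#'   \item{`leave_one_out`}{one scenario per matched variant, dropping it;}
#'   \item{`explicit`}{exactly the keys passed via `include` (possibly none).}
#' }
#' Each scenario reports the combined pathogenic allele frequency
#' `q = sum(AC)/AN` (exact rational and decimal), `p = 1 - q`, the HWE carrier
#' rate `2pq`, the observed carrier rate (distinct carriers of included
#' variants / cohort size), the affected rate `q^2`, and half-up "1 in X"
#' renderings of all three.
#'
#' @param records Output of [stratified_frequencies()] covering (at least) the
#'   matched variants.
#' @param intersection An `intersection_result` from [intersect_catalog()].
#' @param reconciliations Tibble of [reconcile()] rows (needed for
#'   `acmg_filtered`).
#' @param policy One or more of `"all"`, `"acmg_filtered"`, `"leave_one_out"`,
#'   `"explicit"`.
#' @param include For `policy = "explicit"`: tibble of keys
#'   (`chrom, pos, ref, alt`) to include; unknown keys are an error.
#' @param stratum Population stratum (default `"ALL"`).
#' @return A tibble of class `prevalence_scenarios`, one row per scenario:
#'   `scenario`, `included` (list-column of key tibbles), `n_variants`,
#'   `q_num`, `q_den`, `q`, `p`, `carrier_rate_hwe`, `carrier_rate_observed`,
#'   `affected_rate`, `one_in_carrier_hwe`, `one_in_carrier_observed`,
#'   `one_in_affected`.
#' @export
sensitivity_scenarios <- function(records, intersection, reconciliations = NULL,
                                  policy = "all", include = NULL,
                                  stratum = "ALL") {
  stopifnot(inherits(intersection, "intersection_result"))
  key_cols <- c("chrom", "pos", "ref", "alt")
  matched <- intersection$matched |> select(all_of(key_cols))
  missing_rec <- matched |>
    anti_join(as_tibble(records) |> filter(.data$stratum == !!stratum), by = key_cols)
  if (nrow(missing_rec) > 0L) {
    abort(sprintf("no '%s' frequency record for matched variant(s): %s",
                  stratum,
                  paste(variant_id(missing_rec$chrom, missing_rec$pos,
                                   missing_rec$ref, missing_rec$alt), collapse = ", ")))
  }

  scenario_sets <- list()
  for (pol in policy) {
    if (pol == "all") {
      scenario_sets[["all"]] <- matched
    } else if (pol == "acmg_filtered") {
      if (is.null(reconciliations)) {
        abort("policy 'acmg_filtered' needs reconciliation records")
      }
      drop <- reconciliations |>
        filter(.data$verdict == "conflict_benign_vs_pathogenic") |>
        select(all_of(key_cols))
      scenario_sets[["acmg_filtered"]] <- matched |> anti_join(drop, by = key_cols)
    } else if (pol == "leave_one_out") {
      for (i in seq_len(nrow(matched))) {
        left_out <- matched[i, ]
        lbl <- sprintf("drop_%s", variant_id(left_out$chrom, left_out$pos,
                                             left_out$ref, left_out$alt))
        scenario_sets[[lbl]] <- matched[-i, ]
      }
    } else if (pol == "explicit") {
      include <- as_tibble(include %||% matched[0, ])
      unknown <- include |> anti_join(matched, by = key_cols)
      if (nrow(unknown) > 0L) {
        abort(sprintf("explicit inclusion list references unmatched key(s): %s",
                      paste(variant_id(unknown$chrom, unknown$pos,
                                       unknown$ref, unknown$alt), collapse = ", ")))
      }
      scenario_sets[["explicit"]] <- include |> select(all_of(key_cols))
    } else {
      abort(sprintf("unknown policy '%s' (use all, acmg_filtered, leave_one_out, explicit)", pol))
    }
  }

  rec_stratum <- as_tibble(records) |> filter(.data$stratum == !!stratum)
  an_pool <- if (nrow(rec_stratum) > 0L) max(rec_stratum$an) else 1L

  rows <- map2(names(scenario_sets), scenario_sets, function(lbl, keys) {
    rec <- rec_stratum |> semi_join(keys, by = key_cols)
    q <- if (nrow(keys) == 0L) frac(0, an_pool) else combined_q(rec, stratum = stratum)
    rates <- hwe_rates(q)
    carriers <- intersection$carriers |>
      semi_join(keys, by = key_cols) |>
      distinct(.data$sample_id)
    obs <- frac(nrow(carriers), intersection$n_samples)
    tibble(
      scenario = lbl,
      included = list(keys),
      n_variants = nrow(keys),
      q_num = q$num, q_den = q$den,
      q = as.numeric(q),
      p = 1 - as.numeric(q),
      carrier_rate_hwe = as.numeric(rates$carrier_rate_hwe),
      carrier_rate_observed = as.numeric(obs),
      affected_rate = as.numeric(rates$affected_rate),
      one_in_carrier_hwe = one_in(rates$carrier_rate_hwe),
      one_in_carrier_observed = one_in(obs),
      one_in_affected = one_in(rates$affected_rate)
    )
  })
  out <- list_rbind(rows)
  class(out) <- c("prevalence_scenarios", class(out))
  out
}

#' @method tidy prevalence_scenarios
#' @describeIn sensitivity_scenarios tidy() method (the table itself, without
#'   the list-column).
#' @param x A `prevalence_scenarios` tibble.
#' @param ... Unused.
#' @export
tidy.prevalence_scenarios <- function(x, ...) {
  as_tibble(x) |> select(-"included")
}

#' @method glance prevalence_scenarios
#' @describeIn sensitivity_scenarios glance() method: scenario count and the
#'   range of q across scenarios.
#' @export
glance.prevalence_scenarios <- function(x, ...) {
  tibble(n_scenarios = nrow(x), q_min = min(x$q), q_max = max(x$q))
}

#' @method autoplot prevalence_scenarios
#' @describeIn sensitivity_scenarios autoplot() method: carrier and affected
#'   rates per scenario on a log scale.
#' @param object A `prevalence_scenarios` tibble.
#' @export
autoplot.prevalence_scenarios <- function(object, ...) {
  df <- as_tibble(object) |>
    select("scenario", "carrier_rate_hwe", "carrier_rate_observed",
           "affected_rate") |>
    tidyr::pivot_longer(-"scenario", names_to = "quantity", values_to = "rate") |>
    filter(.data$rate > 0)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$scenario, y = .data$rate,
                                   fill = .data$quantity)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "inclusion scenario", y = "rate (log scale)",
                  fill = NULL) +
    ggplot2::theme_minimal()
}
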
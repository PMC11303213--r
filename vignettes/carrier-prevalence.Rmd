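---
title: "Methods: recessive carrier and prevalence estimation from cohort allele frequencies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: recessive carrier and prevalence estimation from cohort allele frequencies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genoprev)
```

## The estimation problem

For a rare autosomal recessive disease, affected individuals are too few for
direct prevalence surveys, but carriers are not. If a healthy reference cohort
of `N` diploid genomes is available together with a catalog of alleles
reported to cause the disease, the expected disease prevalence can be derived
from carrier frequencies. `genoprev` implements this chain for a single gene:

1. subset the cohort VCF to the gene region and normalize variant keys;
2. intersect the cohort's variants with the pathogenic catalog on the exact
   `(chrom, pos, ref, alt)` key;
3. compute allele counts and frequencies per subpopulation, superpopulation,
   and pooled;
4. screen each matched variant's per-ancestry frequencies against ACMG
   frequency-evidence thresholds and reconcile with the asserted
   classification;
5. convert the combined pathogenic allele frequency into Hardy-Weinberg
   carrier and affected rates, under explicit inclusion/exclusion scenarios.

## Model and assumptions

Let the inclusion set of pathogenic variants have allele counts `AC_i` over a
shared called-allele number `AN` in the chosen stratum. The combined
pathogenic allele frequency is `q = (Σ AC_i)/AN` and `p = 1 − q`. Under
Hardy-Weinberg equilibrium the carrier rate is `2pq` and the affected rate
`q²`.

The `q²` form embeds **full allelic heterogeneity at a single locus**: any two
pathogenic alleles in trans are assumed to cause disease, so pathogenic
alleles are interchangeable and their frequencies add. This is the standard
assumption for genes where compound heterozygotes are affected; it
overestimates prevalence if some allele pairs are non-penetrant, and the
reports state the assumption explicitly.

Further assumptions inherited from Hardy-Weinberg: random mating, no
consanguinity adjustment (no inbreeding coefficient), no selection at the
locus, and a cohort that is a fair sample of the target population. Genotype
phase is parsed and discarded — no step here uses it — and all counting is
unphased. Missing allele calls are excluded from `AN` rather than imputed,
the standard AC/AN semantics; with complete genotypes `AN = 2N`.

Two carrier-rate conventions are always reported side by side:

* **HWE carrier rate** `2pq`, with `q` from summed allele counts;
* **observed carrier rate**: distinct individuals carrying at least one
  matched pathogenic allele, divided by `N`. A homozygote is one carrier, and
  an individual carrying two different matched variants counts once.

With 36 heterozygous carriers among 1092 samples these give reciprocals
1092.5 (rendered 1 in 1,093) and 30.33 (rendered 1 in 30) respectively. The
published style of reporting mixes the two conventions, so neither alone can
reproduce all literature values; every report cell is therefore labelled with
its convention rather than picking one.

## Exact arithmetic and rounding

`q`, `2pq` and `q²` are ratios of small integers, and some of their
reciprocals are exact (an affected rate of `(1/2184)² = 1/4,769,856`
exactly). The package keeps numerator and denominator as integers in a tiny
`frac` class and converts to doubles only at formatting time, so these
identities hold bit for bit and `1 in X` values are computed as
`floor((2·den + num) / (2·num))` — a half-up reciprocal rounding done entirely
in integer arithmetic. Half-up is the convention that maps a reciprocal of
1092.5002 to 1093 and 3680.44 to 3680.

Percentage formatting supports two conventions because published tables mix
them: `round` (half-up; 35/2184 → "1.60", 1/2184 → "0.05") and `truncate`
(toward zero; 36/2184 → "1.64", 1/2184 → "0.04"). Truncation applies a guard
of `sqrt(.Machine$double.eps)` before flooring so that decimal fractions
stored inexactly in binary (0.016 × 100 = 1.5999…) are not truncated a unit
low; the guard is ~1.5e-8 on the percent scale, far below any reportable
frequency resolution. Exact fractions are printed alongside any formatted
percentage in the reports, and are the source of truth.

## Variant identity

Joins between the cohort and the catalog use the normalized
`(chrom, pos, ref, alt)` key only. rsIDs are carried for reporting but never
used for matching, since they drift across dbSNP builds. Normalization trims
the shared allele suffix, then the shared prefix (keeping at least one base
of each allele, adjusting `pos`), and — when a reference-context function is
supplied — left-aligns indels by the usual truncate-then-extend procedure.
SNVs pass through unchanged, and normalization is idempotent. Chromosome
dialects (`17` vs `chr17`) are unified at parse time (configurable, default
`chr`-prefixed). Coordinates are 1-based GRCh37 throughout; region arguments
are half-open `[start, end)` so adjacent windows tile without overlap. The
genome build is stamped into every report; no liftover is attempted.

Multiallelic records are decomposed into one biallelic record per alternate
allele. In a decomposed record, calls to *other* alternate alleles are
recoded to missing, not to reference — recoding them to reference would
inflate `AN` with alleles that are known not to be reference. Decomposition
therefore conserves each alternate allele's count exactly.

## ACMG frequency evidence

The frequency screen implements the frequency-based evidence codes only, not
the full ACMG/AMP combining rules:

| code | meaning | default | trigger |
|------|---------|---------|---------|
| BA1 | stand-alone benign | 0.05 | `af > ba1` in **at least one** ancestry group (strict) |
| BS1 | strong benign | disabled | `af > bs1` in at least one group |
| PM2 | supports pathogenic | disabled | `af ≤ pm2_max` in **every** group |

BA1 is evaluated per ancestry group, not on the pooled frequency. This is the
substantive choice: a variant at 6.26% in African-ancestry samples but ~0
elsewhere pools to 1.60% in a mixed cohort and would never trigger a pooled
threshold, yet the per-group rule classifies it stand-alone benign. The
strictness of the inequality matters at the boundary: a frequency of exactly
5% does not trigger ("more than 5%" semantics), and the tests pin this with
an ulp-scale increment. BS1 and PM2 ship disabled because sensible defaults
are disease-specific (they depend on penetrance and prevalence priors); they
activate only when configured, with validity checks `pm2_max < bs1 < ba1`.

Filtering-allele-frequency refinements (popmax confidence bounds) are out of
scope; raw frequencies are compared to thresholds.

Reconciliation against the catalog's asserted classification emits one of
three verdicts: `concordant`, `conflict_benign_vs_pathogenic` (benign-direction
frequency call against a pathogenic assertion), or `frequency_silent` (no
frequency call possible). The vocabulary is deliberately closed and the
conflict direction deliberately asymmetric: the decision the pipeline needs
downstream is "would the frequency rule exclude this reportedly pathogenic
variant?". A PM2-style frequency call against a benign assertion is reported
as `concordant` with its triggered codes visible, since it removes nothing
from any scenario. Crucially, reconciliation never deletes a variant:
exclusion happens only in the scenario engine, under a named policy, so the
sensitivity of the final estimate to a contested allele stays visible.

Per-ancestry frequencies come from an external table (gnomAD-style) when the
variant appears there, else from the cohort's own superpopulation
frequencies; the report records which source was used per variant. External
ancestry labels are carried verbatim.

## Inclusion scenarios

`sensitivity_scenarios()` evaluates prevalence under: `all` (every matched
variant), `acmg_filtered` (drop variants with verdict
`conflict_benign_vs_pathogenic`), `leave_one_out` (one scenario per dropped
variant), and `explicit` (a caller-supplied list, possibly empty). `q` is
monotone under exclusion by construction. When records within a stratum
disagree on `AN` (differential missingness), `q = ΣAC/AN` is not
well-defined; the default errors, and an explicit `an_policy = "max"` uses
the largest `AN` (the most conservative denominator, biasing `q` downward by
at most the missingness fraction). An `AN` of zero in the requested stratum
is an error, not a zero.

## What the synthetic generator emulates — and what it does not

`fixture_spec()`/`generate_fixture()` produce a cohort VCF, a panel file in
the 1000 Genomes dialect, a catalog TSV and an external frequency table whose
*marginal structure* matches the study conditions of the CTNS/cystinosis
analysis the package was built around:

* 1092 samples in the 14 subpopulations / 4 superpopulations of the 1000
  Genomes Phase 1 panel, at the real panel's subpopulation sizes;
* 444 unique cohort variants in the GRCh37 CTNS region
  (chr17:3,539,125–3,565,000), 75 catalog entries, and exactly two designed
  overlaps: chr17:3550800 G>A (c.124G>A, 35 heterozygous carriers, placed in
  African-ancestry samples with weight 0.9, applied as a deterministic split:
  32 of the 35 carriers are African-ancestry) and chr17:3559792 T>C
  (c.473T>C, 1 heterozygote);
* carriers of distinct overlap variants are distinct individuals, so 35 + 1
  variant observations are 36 carriers;
* the external table carries the published per-ancestry frequencies of the
  common variant: AFR 6.26%, NFE 0.006%, FIN 0%, EAS 0.002%.

The subpopulation-level placement of the 35 carriers is not published
anywhere; any placement consistent with the pooled counts and the
African-ancestry concentration is acceptable, and the 0.9 weight is recorded
in the spec object. Background variants get 1 + Binomial(20, 0.08) carriers
each — every cohort variant is observed at least once, as in a variant list
derived from called genotypes — at positions drawn uniformly from the region.
One catalog decoy reuses a cohort position with a different alternate allele
so exact-key matching is exercised; all other decoys sit at positions absent
from the cohort.

Not emulated: linkage disequilibrium, phasing structure, relatedness,
sequencing error, and subpopulation-specific background frequency spectra.
Passing tests therefore demonstrate the counting, classification and
arithmetic machinery on data with realistic marginal counts — they say
nothing about robustness to cryptic relatedness or call-quality artifacts in
real cohorts, which must be handled upstream.

Fixture generation is deterministic given spec + seed (byte-identical files);
the package default seed is 20240724. The designed counts (2 matched
variants, 36 carriers, 444/75 totals) are invariant to the seed, which only
moves sample placement and background/decoy positions.

## Problem sizes and runtime

The test suite runs the full fixture (1092 × 444) once and caches it;
property-style checks (brute-force tally equivalence, aggregation
conservation, intersection oracle, normalization idempotence) use generated
cohorts of 8–40 samples × 2–10 variants, where exhaustive double loops are
trivially checkable by eye, plus one 2000-sample binomial-calibration check.
The whole suite completes in well under a minute on one core.

## Known limitations

* No confidence intervals on `q` or the derived rates (binomial or bootstrap
  CIs are a natural extension; with AC = 1 the uncertainty spans orders of
  magnitude).
* No inbreeding/consanguinity adjustment; founder-effect populations violate
  the random-mating assumption in the direction of more affected individuals.
* Diploid autosomal model only; no structural variants, symbolic alleles, or
  sex chromosomes.
* The per-group BA1 screen uses point frequency estimates; a variant at 5.1%
  on a small denominator triggers the same way as one at 5.1% on a huge one.
* Per-stratum prevalence scenarios are supported, but interpreting a
  stratified `q²` as a subpopulation prevalence assumes within-stratum random
  mating.
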
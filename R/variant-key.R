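#' Normalize variant representations
#'
#' Reduces each (chrom, pos, ref, alt) record to its canonical minimal
#' representation so that records from different sources (cohort VCFs,
#' mutation-database exports) join on identical keys. The shared suffix is
#' trimmed first, then the shared prefix (always keeping at least one base of
#' each allele), adjusting `pos` as bases are removed from the front. When a
#' `reference_context` is supplied, indels are additionally left-aligned by the
#' standard truncate-then-extend procedure, so a deletion inside a repeat run
#' is anchored at the leftmost equivalent position. SNVs pass through
#' unchanged.
#'
#' @param variants Data frame with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt` (uppercase ACGT strings).
#' @param reference_context Optional function `(chrom, pos) -> single base`,
#'   giving the reference base at a position; required only to left-align
#'   indels. `NULL` (default) performs trimming only.
#' @return The input tibble with `pos`, `ref`, `alt` normalized; all other
#'   columns carried through unchanged.
#' @examples
#' normalize_variants(tibble::tibble(
#'   chrom = "chr17", pos = 100L, ref = "CT", alt = "CA"
#' ))
#' @export
normalize_variants <- function(variants, reference_context = NULL) {
  stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(variants)))
  if (nrow(variants) == 0L) return(as_tibble(variants))
  norm <- pmap(
    list(variants$chrom, variants$pos, variants$ref, variants$alt),
    function(chrom, pos, ref, alt) {
      normalize_one(chrom, pos, ref, alt, reference_context)
    }
  )
  out <- as_tibble(variants)
  out$pos <- map_int(norm, "pos")
  out$ref <- map_chr(norm, "ref")
  out$alt <- map_chr(norm, "alt")
  out
}

normalize_one <- function(chrom, pos, ref, alt, reference_context = NULL) {
  ref <- toupper(ref); alt <- toupper(alt)
  if (!grepl("^[ACGT]+$", ref) || !grepl("^[ACGT]+$", alt)) {
    abort(sprintf("alleles must be non-empty ACGT strings, got %s>%s at %s:%s",
                  ref, alt, chrom, pos))
  }
  if (identical(ref, alt)) {
    abort(sprintf("invalid variant at %s:%s: ref equals alt (%s)", chrom, pos, ref))
  }
  pos <- as.integer(pos)

  last1 <- function(x) substr(x, nchar(x), nchar(x))
  chop_last <- function(x) substr(x, 1L, nchar(x) - 1L)

  if (is.null(reference_context)) {
    # suffix trim, keeping >= 1 base of each allele
    while (nchar(ref) > 1L && nchar(alt) > 1L && last1(ref) == last1(alt)) {
      ref <- chop_last(ref); alt <- chop_last(alt)
    }
  } else {
    # truncate-then-extend: allows alleles to empty, refilling from the
    # reference to the left, which left-aligns indels through repeat runs
    repeat {
      if (nchar(ref) > 0L && nchar(alt) > 0L &&
          last1(ref) == last1(alt) &&
          !(nchar(ref) == 1L && nchar(alt) == 1L)) {
        ref <- chop_last(ref); alt <- chop_last(alt)
      } else if (nchar(ref) == 0L || nchar(alt) == 0L) {
        if (pos <= 1L) abort(sprintf(
          "cannot left-extend variant at %s:%s beyond position 1", chrom, pos))
        pos <- pos - 1L
        b <- toupper(reference_context(chrom, pos))
        ref <- paste0(b, ref); alt <- paste0(b, alt)
      } else {
        break
      }
    }
  }

  # prefix trim, keeping >= 1 base of each allele
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    ref <- substr(ref, 2L, nchar(ref)); alt <- substr(alt, 2L, nchar(alt))
    pos <- pos + 1L
  }

  if (identical(ref, alt)) {
    abort(sprintf("invalid variant at %s:%s: ref equals alt after trimming", chrom, pos))
  }
  list(pos = pos, ref = ref, alt = alt)
}
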
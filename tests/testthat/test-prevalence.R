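test_that("combined q pools allele counts over one shared denominator", {
  rec <- tibble::tibble(
    chrom = "chr17", pos = c(3550800L, 3559792L), ref = c("G", "T"),
    alt = c("A", "C"), stratum = "ALL", level = "ALL",
    ac = c(35L, 1L), an = 2184L, af = c(35, 1) / 2184,
    n_het = c(35L, 1L), n_hom_alt = 0L, absent = FALSE)

  q_both <- combined_q(rec)
  expect_equal(q_both$num, 36)
  expect_equal(q_both$den, 2184)
  expect_equal(as.numeric(q_both), 36 / 2184, tolerance = 1e-15)

  q_one <- combined_q(rec[2, ])
  expect_equal(q_one$num, 1)
  expect_equal(as.numeric(q_one), 1 / 2184, tolerance = 1e-15)

  expect_equal(as.numeric(combined_q(rec[0, ])), 0)

  expect_error(combined_q(rec, stratum = "AFR"), "no records for stratum")
  rec_bad <- rec; rec_bad$an <- c(2184L, 2000L)
  expect_error(combined_q(rec_bad), "disagree on AN")
  rec_zero <- rec; rec_zero$an <- 0L
  expect_error(combined_q(rec_zero), "allele number is 0")
})

test_that("Hardy-Weinberg rates are exact rationals with the published values", {
  r1 <- hwe_rates(frac(1, 2184))
  expect_equal(r1$carrier_rate_hwe$num, 4366)
  expect_equal(r1$carrier_rate_hwe$den, 4769856)
  expect_equal(r1$affected_rate$num, 1)
  expect_equal(r1$affected_rate$den, 4769856)  # exactly 2184^2

  r36 <- hwe_rates(frac(36, 2184))
  expect_equal(r36$affected_rate$num, 1296)
  expect_equal(one_in(r36$affected_rate), 3680)  # reciprocal 3680.44 -> 3680

  # boundary identities
  expect_equal(as.numeric(hwe_rates(0)$carrier_rate_hwe), 0)
  expect_equal(as.numeric(hwe_rates(0)$affected_rate), 0)
  expect_equal(hwe_rates(1)$carrier_rate_hwe, 0)
  expect_equal(hwe_rates(1)$affected_rate, 1)
})

test_that("one-in renderings round half-up and handle the zero sentinel", {
  expect_equal(one_in(frac(1296, 4769856)), 3680)
  expect_equal(one_in(frac(1, 4769856)), 4769856)
  expect_equal(one_in(frac(4366, 4769856)), 1093)  # 1092.5002... rounds up
  expect_equal(one_in(frac(36, 1092)), 30)         # 30.33
  expect_equal(one_in(frac(1, 1092)), 1092)
  expect_equal(one_in(frac(2, 3)), 2)              # 1.5 rounds half-up
  expect_equal(one_in(frac(0, 10)), Inf)
  expect_equal(one_in(0), Inf)
  expect_equal(one_in(0.25), 4)
})

test_that("observed carrier rate divides distinct carriers by cohort size", {
  ix <- default_intersection()
  obs <- observed_carrier_rate(ix)
  expect_equal(obs$num, 36)
  expect_equal(obs$den, 1092)
  expect_equal(one_in(obs), 30)

  expect_equal(one_in(observed_carrier_rate(1, 1092)), 1092)
  expect_equal(as.numeric(observed_carrier_rate(0, 50)), 0)
  expect_error(observed_carrier_rate(3, 0), "positive")
  expect_error(observed_carrier_rate(10, 5), "more carriers than samples")
})

test_that("rates converge to their leading terms as q tends to zero", {
  for (q in 10^(-3:-8)) {
    r <- hwe_rates(q)
    expect_equal(r$affected_rate / q^2, 1, tolerance = 1e-12)
    expect_equal(r$carrier_rate_hwe / (2 * q), 1, tolerance = 1e-2)
  }
})

test_that("inclusion scenarios reproduce both published calculations", {
  freqs <- default_matched_freqs()
  ix <- default_intersection()
  ext <- read_external_frequencies(default_fixture()$external_freq)
  recon <- classify_frequencies(ix, freqs, external = ext)

  sc <- sensitivity_scenarios(freqs, ix, reconciliations = recon,
                              policy = c("all", "acmg_filtered",
                                         "leave_one_out"))
  all_row <- sc[sc$scenario == "all", ]
  expect_equal(c(all_row$q_num, all_row$q_den), c(36, 2184))
  expect_equal(all_row$one_in_carrier_observed, 30)
  expect_equal(all_row$one_in_affected, 3680)

  excl <- sc[sc$scenario == "acmg_filtered", ]
  expect_equal(c(excl$q_num, excl$q_den), c(1, 2184))
  expect_equal(excl$one_in_carrier_hwe, 1093)
  expect_equal(excl$one_in_affected, 4769856)

  expect_equal(sum(startsWith(sc$scenario, "drop_")), 2L)

  empty <- sensitivity_scenarios(freqs, ix, policy = "explicit", include = NULL)
  expect_equal(empty$q, 0)
  expect_equal(empty$one_in_affected, Inf)

  expect_error(
    sensitivity_scenarios(freqs, ix, policy = "explicit",
                          include = tibble::tibble(chrom = "chr1", pos = 1L,
                                                   ref = "A", alt = "T")),
    "unmatched key")
  expect_error(sensitivity_scenarios(freqs, ix, policy = "bogus"), "unknown policy")
})

test_that("q is monotone under variant exclusion", {
  freqs <- default_matched_freqs()
  ix <- default_intersection()
  sc <- sensitivity_scenarios(freqs, ix, policy = c("all", "leave_one_out",
                                                    "explicit"))
  q_all <- sc$q[sc$scenario == "all"]
  q_loo <- sc$q[startsWith(sc$scenario, "drop_")]
  q_none <- sc$q[sc$scenario == "explicit"]
  expect_true(all(q_all >= q_loo))
  expect_true(all(q_loo >= q_none))
  expect_equal(q_none, 0)
})

test_that("combined q equals a brute-force allele tally on random cohorts", {
  for (seed in c(13, 14)) {
    rc <- generate_random_cohort(n_samples = 12, n_variants = 5,
                                 af_shape1 = 2, af_shape2 = 4,
                                 missing_rate = 0.1, seed = seed)
    rec <- stratified_frequencies(rc$cohort, rc$panel)
    # brute force over genotypes, pooled stratum
    total_alt <- 0L
    keys <- cohort_variants(rc$cohort)
    for (i in seq_len(nrow(keys))) {
      rows <- rc$cohort[rc$cohort$pos == keys$pos[i] &
                        rc$cohort$alt == keys$alt[i] &
                        rc$cohort$ref == keys$ref[i], ]
      total_alt <- total_alt + sum(c(rows$a1, rows$a2) == 1L, na.rm = TRUE)
    }
    all_rec <- rec[rec$stratum == "ALL", ]
    ans <- unique(all_rec$an)
    if (length(ans) == 1L) {
      q <- combined_q(all_rec)
      expect_equal(q$num, total_alt)
    } else {
      expect_error(combined_q(all_rec), "disagree on AN")
    }
  }
})

test_that("scenario tables expose tidy, glance and autoplot methods", {
  freqs <- default_matched_freqs()
  ix <- default_intersection()
  sc <- sensitivity_scenarios(freqs, ix, policy = "all")
  td <- tidy(sc)
  expect_false("included" %in% names(td))
  gl <- glance(sc)
  expect_equal(gl$n_scenarios, 1L)
  p <- autoplot(sc)
  expect_s3_class(p, "ggplot")
})
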
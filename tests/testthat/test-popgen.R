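four_panel <- tibble::tibble(
  sample_id = c("S1", "S2", "S3", "S4"),
  population = c("YRI", "YRI", "CEU", "CEU"),
  super_population = c("AFR", "AFR", "EUR", "EUR"),
  sex = "female")

test_that("allele counts, numbers and frequencies are stratified correctly", {
  call <- make_call(gt = c(S1 = 1L, S2 = 0L, S3 = 0L, S4 = 0L))
  s <- allele_summary(call)
  expect_equal(s$ac, 1L)
  expect_equal(s$an, 8L)
  expect_equal(s$af, 0.125)

  miss <- make_call(gt = c(S1 = 1L, S2 = NA, S3 = 0L, S4 = 0L))
  expect_equal(allele_summary(miss)$an, 6L)  # missing excluded from AN

  by_sp <- allele_summary(call, four_panel, "super_population")
  expect_equal(by_sp$ac[by_sp$group == "AFR"], 1L)
  expect_equal(by_sp$ac[by_sp$group == "EUR"], 0L)
  expect_equal(sum(by_sp$ac), allele_summary(call)$ac)  # partition sums

  expect_equal(allele_summary(call, four_panel, "YRI")$an, 4L)
  expect_error(allele_summary(call, four_panel, "XXX"), "unknown group")
  # a printed AC over a 3202-sample diploid panel
  expect_equal(round(269 / 6404, 4), 0.042)
})

test_that("singleton means one alternate allele cohort-wide", {
  expect_true(is_singleton(make_call(gt = c(S1 = 1L, S2 = 0L))))
  expect_false(is_singleton(make_call(gt = c(S1 = 2L, S2 = 0L))))
  expect_false(is_singleton(make_call(gt = c(S1 = 0L, S2 = 0L))))
})

test_that("super-population presence and specificity", {
  afr_only <- make_call(gt = c(S1 = 1L, S2 = 2L, S3 = 0L, S4 = 0L))
  expect_equal(superpop_presence(afr_only, four_panel)[[1]], "AFR")
  everywhere <- make_call(gt = c(S1 = 1L, S2 = 0L, S3 = 1L, S4 = 0L))
  expect_equal(superpop_presence(everywhere, four_panel)[[1]],
               c("AFR", "EUR"))
  absent <- make_call(gt = c(S1 = 0L, S2 = 0L, S3 = 0L, S4 = 0L))
  expect_length(superpop_presence(absent, four_panel)[[1]], 0L)

  calls <- dplyr::bind_rows(
    dplyr::mutate(afr_only, variant_id = "a"),
    dplyr::mutate(everywhere, variant_id = "b"))
  spec <- specificity_summary(calls, four_panel)
  expect_equal(spec$n_present, 2L)
  expect_equal(spec$pct_specific, 50)
})

test_that("het/hom ratio uses totals across sites and flags zero denominators", {
  calls <- dplyr::bind_rows(
    make_call(variant_id = "a", gt = c(S1 = 1L, S2 = 1L, S3 = 1L, S4 = 2L)),
    make_call(variant_id = "b", gt = c(S1 = 1L, S2 = 1L, S3 = 1L, S4 = 1L)),
    make_call(variant_id = "c", gt = c(S1 = 1L, S2 = 1L, S3 = 1L, S4 = 1L)),
    make_call(variant_id = "d", gt = c(S1 = 2L, S2 = 0L, S3 = 0L, S4 = 0L)))
  r <- het_hom_ratio(calls)
  expect_equal(r$ratio, 11 / 2)
  no_hom <- het_hom_ratio(make_call(gt = c(S1 = 1L, S2 = 0L)))
  expect_equal(no_hom$ratio, Inf)
})

test_that("under HWE the het/hom ratio approaches 2(1-p)/p", {
  set.seed(77)
  n_loci <- 200; n_samples <- 500; p <- 0.1
  calls <- dplyr::bind_rows(lapply(seq_len(n_loci), function(i) {
    make_call(variant_id = paste0("v", i),
              gt = setNames(simulate_genotypes(p, n_samples),
                            paste0("S", seq_len(n_samples))))
  }))
  r <- het_hom_ratio(calls)$ratio
  expect_gt(r, 18 * 0.85)
  expect_lt(r, 18 * 1.15)
})

test_that("exact HWE matches the log-factorial oracle and degenerate cases", {
  expect_equal(hwe_exact(25, 0, 0)$p_two_sided, 1)   # monomorphic
  expect_equal(hwe_exact(99, 1, 0)$p_two_sided, 1)   # ac=1 forces one config
  res <- hwe_exact(57, 33, 10)
  orc <- oracle_hwe(57, 33, 10)
  expect_equal(res$p_two_sided, orc$p_two_sided, tolerance = 1e-10)
  expect_equal(res$p_excess_het, orc$p_excess_het, tolerance = 1e-10)
  expect_error(hwe_exact(0, 0, 0), "at least one genotype")
  expect_error(hwe_exact(-1, 2, 0), "non-negative")

  # every configuration with up to 12 genotypes, against the oracle
  for (n in 1:12) {
    for (a in 0:n) for (b in 0:(n - a)) {
      cc <- n - a - b
      got <- hwe_exact(a, b, cc)
      want <- oracle_hwe(a, b, cc)
      expect_equal(got$p_two_sided, want$p_two_sided, tolerance = 1e-9,
                   info = paste(a, b, cc))
      expect_equal(got$p_excess_het, want$p_excess_het, tolerance = 1e-9,
                   info = paste(a, b, cc))
      expect_equal(want$total, 1, tolerance = 1e-12)  # enumeration sums to 1
    }
  }
})

test_that("hwe_screen runs per locus and keeps large counts stable", {
  sim <- small_sim(seed = 55)
  h <- hwe_screen(sim$calls)
  expect_equal(nrow(h), nrow(sim$calls))
  expect_true(all(h$p_two_sided > 0 & h$p_two_sided <= 1))
  big <- hwe_exact(2500, 600, 102)  # cohort-scale counts stay finite
  expect_true(is.finite(big$p_two_sided) && big$p_two_sided > 0)
})

test_that("insertional density divides by megabases", {
  cs <- tibble::tibble(chrom = c("chrY", "chr1"),
                       length = c(57227415, 1e6))
  calls <- dplyr::bind_rows(
    make_call(variant_id = "a", chrom = "chrY", pos = 1e6),
    make_call(variant_id = "b", chrom = "chrY", pos = 2e6),
    make_call(variant_id = "c", chrom = "chrY", pos = 3e6),
    make_call(variant_id = "d", chrom = "chr1", pos = 5e5))
  d <- density_per_mbp(calls, cs)
  expect_equal(round(d$density_per_mbp[d$chrom == "chrY"], 3), 0.052)
  expect_equal(d$density_per_mbp[d$chrom == "chr1"], 1.0)
  empty <- density_per_mbp(calls[0, ], cs)
  expect_equal(empty$density_per_mbp, c(0, 0))
  expect_error(density_per_mbp(make_call(chrom = "chrM"), cs), "chrM")
})

test_that("per-element transduction rate is a simple percent", {
  expect_equal(round(per_element_rate(268, 9847), 2), 2.72)
  expect_equal(round(per_element_rate(162, 4066), 2), 3.98)
  expect_equal(per_element_rate(0, 100), 0)
  expect_error(per_element_rate(1, 0), "positive")
})

test_that("the AF spectrum partitions polymorphic sites", {
  s <- tibble::tibble(variant_id = letters[1:4], me_type = "L1",
                      group = "ALL", n_hom_ref = 0L, n_het = 0L,
                      n_hom_alt = 0L, n_missing = 0L,
                      ac = c(1L, 0L, 50L, 0L), an = c(200L, 200L, 100L, 0L),
                      af = c(0.005, 0, 0.5, 0))
  sp <- af_spectrum(s)
  expect_equal(sum(sp$n), 3L)  # an = 0 excluded
  expect_equal(sp$n[sp$bin == "[0,0.01)"], 1L)       # rare variant
  expect_equal(sp$n[sp$bin == "monomorphic"], 1L)    # ac = 0, an > 0
  expect_equal(sp$n[sp$bin == "[0.5,1]"], 1L)
  expect_error(af_spectrum(s, breaks = c(0, 0.5, 0.4, 1)), "breaks")
  expect_s3_class(plot_af_spectrum(sp), "ggplot")
})

test_that("allele frequencies are recovered within binomial error", {
  set.seed(99)
  n_samples <- 500
  afs <- rep(c(0.05, 0.1, 0.2, 0.5), each = 50)
  calls <- dplyr::bind_rows(lapply(seq_along(afs), function(i) {
    make_call(variant_id = paste0("v", i),
              gt = setNames(simulate_genotypes(afs[i], n_samples),
                            paste0("S", seq_len(n_samples))))
  }))
  s <- allele_summary(calls)
  se <- sqrt(afs * (1 - afs) / s$an)
  frac_in <- mean(abs(s$af - afs) <= 3 * se)
  expect_gte(frac_in, 0.99)
})
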
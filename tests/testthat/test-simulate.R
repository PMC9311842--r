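test_that("genotype simulation hits planted frequencies and HWE structure", {
  set.seed(1)
  expect_equal(simulate_genotypes(0, 50), rep(0L, 50))
  expect_equal(simulate_genotypes(1, 50), rep(2L, 50))
  g <- simulate_genotypes(0.2, 10000)
  af_hat <- mean(g) / 2
  se <- sqrt(0.2 * 0.8 / (2 * 10000))
  expect_lt(abs(af_hat - 0.2), 3 * se)
  # excess-het mode inflates heterozygosity
  ge <- simulate_genotypes(0.3, 20000, list(kind = "excess_het", eps = 0.5))
  expect_gt(mean(ge == 1), 2 * 0.3 * 0.7 * 1.2)
  expect_error(simulate_genotypes(0.5, 10, list(kind = "nope")), "hwe_mode")
})

test_that("the default panel mirrors a 26-population 5-super-population cohort", {
  pops <- default_populations()
  expect_equal(nrow(pops), 26L)
  expect_equal(sum(pops$n), 320L)
  expect_setequal(unique(pops$super_population),
                  c("AFR", "AMR", "EUR", "SAS", "EAS"))
  sim <- small_sim(seed = 2)
  expect_equal(nrow(sim$panel), 320L)
  expect_equal(dplyr::n_distinct(sim$panel$population), 26L)
})

test_that("identical seeds give byte-identical bundles, distinct seeds differ", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  d3 <- withr::local_tempdir()
  cfg <- function(s) sim_config(n_loci = c(L1 = 60L, SVA = 30L), seed = s)
  simulate_cohort(cfg(7), dir = d1)
  simulate_cohort(cfg(7), dir = d2)
  simulate_cohort(cfg(8), dir = d3)
  files <- list.files(d1)
  md5 <- function(d) unname(tools::md5sum(file.path(d, files)))
  expect_identical(md5(d1), md5(d2))
  expect_false(all(md5(d1) == md5(d3)))
})

test_that("transduction_fraction = 0 yields no candidates", {
  sim <- simulate_cohort(
    sim_config(n_loci = c(L1 = 40L, SVA = 20L),
               transduction_fraction = c(L1 = 0, SVA = 0), seed = 3),
    write = FALSE)
  expect_false(any(sim$calls$is_transduction))
  expect_true(all(sim$calls$metrans == "null"))
})

test_that("planted truth is internally consistent with the emitted records", {
  sim <- small_sim(seed = 13)
  tr <- sim$truth[match(sim$calls$variant_id, sim$truth$variant_id), ]
  # candidates are exactly the non-null METRANS records, and QC-pass only
  expect_identical(sim$calls$is_transduction, tr$is_transduction)
  expect_true(all(tr$planted_qc_pass[tr$is_transduction]))
  # HIGH plants always keep the strict length inequality
  high <- tr$planted_label %in% "HIGH"
  expect_true(all(sim$calls$src_td_len[high] < sim$calls$svlen[high]))
  # REMOVED plants really sit inside an emitted segdup
  rem <- tr$planted_label %in% "REMOVED_SEGDUP"
  expect_true(all(overlaps_segdup(sim$calls[rem, ], sim$segdups, "point")))
  # transduced lengths stay inside the configured bounds
  expect_true(all(tr$planted_td_len[tr$is_transduction] >= 7 &
                    tr$planted_td_len[tr$is_transduction] <= 997))
})

test_that("inconsistent configuration is rejected", {
  expect_error(sim_config(), "seed")
  expect_error(
    sim_config(label_proportions = list(L1 = c(HIGH = 0.9, LOW = 0.9,
                                               REMOVED = 0.1),
                                        SVA = c(HIGH = 1, LOW = 0,
                                                REMOVED = 0)),
               seed = 1))
  bad_pops <- dplyr::bind_rows(default_populations(),
                               tibble::tibble(population = "YRI",
                                              super_population = "EUR",
                                              n = 5L))
  expect_error(sim_config(populations = bad_pops, seed = 1),
               "super-population")
})
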
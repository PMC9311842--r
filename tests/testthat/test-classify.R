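test_that("segdup overlap honours the BED half-open convention", {
  sd <- segdup_track(start = 50L, end = 150L)
  at <- function(pos) overlaps_segdup(make_candidate(pos = pos), sd, "point")
  expect_true(at(100L))
  expect_true(at(51L))    # first covered base
  expect_true(at(150L))   # last covered base (0-based 149)
  expect_false(at(50L))
  expect_false(at(151L))
  expect_false(overlaps_segdup(make_candidate(chrom = "chr9", pos = 100L),
                               sd, "point"))
  # span mode: insertion upstream of the segdup but spanning into it
  expect_true(overlaps_segdup(make_candidate(pos = 40L, svlen = 20L),
                              sd, "span"))
  expect_false(overlaps_segdup(make_candidate(pos = 40L, svlen = 5L),
                               sd, "span"))
})

test_that("segdup overlap agrees with an O(n*m) brute force", {
  set.seed(402)
  n <- 300; m <- 300
  calls <- dplyr::bind_rows(lapply(seq_len(n), function(i) {
    make_candidate(chrom = sample(c("chr1", "chr2"), 1),
                   pos = sample.int(1e5, 1), variant_id = paste0("v", i),
                   svlen = sample.int(5000, 1))
  }))
  starts <- sample.int(1e5, m)
  sd <- tibble::tibble(chrom = sample(c("chr1", "chr2"), m, replace = TRUE),
                       start = starts, end = starts + sample.int(2000, m),
                       name = "", strand = ".", me_type = "",
                       subfamily = "", width = 0L)
  for (mode in c("point", "span")) {
    expect_identical(overlaps_segdup(calls, sd, mode),
                     oracle_overlap(calls, sd, mode), info = mode)
  }
})

test_that("length consistency is strict and errors without SVLEN", {
  expect_true(length_consistent(make_candidate(src_td_len = 100L,
                                               svlen = 6100L)))
  expect_false(length_consistent(make_candidate(src_td_len = 997L,
                                                svlen = 900L)))
  expect_false(length_consistent(make_candidate(src_td_len = 900L,
                                                svlen = 900L)))  # tie is LOW
  expect_true(length_consistent(make_candidate(src_td_len = 0L, svlen = 1L)))
  expect_error(length_consistent(make_candidate(svlen = NA_integer_)),
               "SVLEN")
})

test_that("family activity is case-insensitive and honours UNDETERMINED", {
  expect_true(family_active(make_candidate(src_subfamily = "L1HS")))
  expect_true(family_active(make_candidate(src_subfamily = "l1hs")))
  expect_false(family_active(make_candidate(src_subfamily = "L1PA4")))
  expect_true(family_active(make_candidate(src_subfamily = "UNDETERMINED")))
  cfg <- classifier_config(undetermined_is_active = FALSE)
  expect_false(family_active(make_candidate(src_subfamily = "UNDETERMINED"),
                             cfg))
})

test_that("classification composes the three checks with segdup precedence", {
  sd <- segdup_track(start = 50L, end = 150L)
  high <- classify_transductions(make_candidate(sr = 5L), sd)
  expect_equal(high$label, "HIGH")
  expect_length(high$reasons[[1]], 0L)

  low_sr <- classify_transductions(make_candidate(sr = 4L), sd)
  expect_equal(low_sr$label, "LOW")
  expect_equal(low_sr$reasons[[1]], "LOW_SUPPORT")

  low_len <- classify_transductions(
    make_candidate(sr = 7L, src_td_len = 7000L, svlen = 6100L,
                   src_subfamily = "SVA_E"), sd)
  expect_equal(low_len$reasons[[1]], "LENGTH_INCONSISTENT")

  # all reasons accumulate
  low_all <- classify_transductions(
    make_candidate(sr = 2L, src_td_len = 7000L, svlen = 6100L,
                   src_subfamily = "L1PA4"), sd)
  expect_equal(low_all$reasons[[1]],
               c("LOW_SUPPORT", "LENGTH_INCONSISTENT", "INACTIVE_FAMILY"))

  # a segdup hit removes the record regardless of everything else
  rem <- classify_transductions(make_candidate(pos = 100L, sr = 50L), sd)
  expect_equal(rem$label, "REMOVED_SEGDUP")
  expect_equal(rem$reasons[[1]], "SEGDUP_OVERLAP")

  expect_error(classify_transductions(make_call(), sd), "candidates")
})

test_that("funnel counts partition the cohort per element type", {
  sim <- small_sim(seed = 31)
  cand <- dplyr::filter(sim$calls, is_transduction)
  cls <- classify_transductions(cand, sim$segdups)
  f <- td_funnel(cls)
  expect_equal(f$n_total, f$n_removed_segdup + f$n_after_segdup)
  expect_equal(f$n_after_segdup, f$n_high + f$n_low)
  expect_equal(sum(f$n_total), nrow(cand))
  # subfamily sums reproduce the high-confidence totals
  fam <- source_family_table(cls)
  fam_sum <- dplyr::count(fam, me_type, wt = n, name = "n")
  expect_equal(fam_sum$n, f$n_high[match(fam_sum$me_type, f$me_type)])
  expect_equal(nrow(td_funnel(cls[0, ])), 0L)
})

test_that("classification is order-invariant and recovers planted labels", {
  sim <- small_sim(seed = 33)
  cand <- dplyr::filter(sim$calls, is_transduction)
  cls <- classify_transductions(cand, sim$segdups)
  truth <- sim$truth[match(cls$variant_id, sim$truth$variant_id), ]
  expect_identical(cls$label, truth$planted_label)
  low <- cls$label == "LOW"
  expect_identical(vapply(cls$reasons[low], paste, "", collapse = ";"),
                   truth$planted_reason[low])

  perm <- sample(nrow(cand))
  cls2 <- classify_transductions(cand[perm, ], sim$segdups)
  expect_identical(cls2$label[order(cls2$variant_id)],
                   cls$label[order(cls$variant_id)])
})

test_that("tidy and glance summarise a classification", {
  sim <- small_sim(seed = 34)
  cls <- classify_transductions(dplyr::filter(sim$calls, is_transduction),
                                sim$segdups)
  td <- tidy(cls)
  expect_true(all(c("variant_id", "label", "reasons") %in% names(td)))
  expect_type(td$reasons, "character")
  g <- glance(cls)
  expect_equal(g$n_total, nrow(cls))
  expect_equal(g$n_high + g$n_low + g$n_removed_segdup, g$n_total)
  expect_s3_class(autoplot(cls), "ggplot")
})
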
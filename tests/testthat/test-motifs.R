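# planted sequences on an all-C backbone: C occurs in no motif, so every
# detected motif is a planted one
backbone <- function(n = 400L) strrep("C", n)

plant_at <- function(s, at, motif) {
  substr(s, at, at + nchar(motif) - 1L) <- motif
  s
}

test_that("PAS scanning honours the 10-40 nt window and RNA rendering", {
  cleav <- 250L
  s <- plant_at(backbone(), 225L, "AATAAA")  # offset 25
  hit <- find_pas(s, cleav)
  expect_equal(hit$rna, "AAUAAA")
  expect_equal(hit$offset, 25L)

  s2 <- plant_at(backbone(), 225L, "ATTAAA")
  expect_equal(find_pas(s2, cleav)$rna, "AUUAAA")

  expect_null(find_pas(plant_at(backbone(), 245L, "AATAAA"), cleav))  # 5 nt
  expect_null(find_pas(plant_at(backbone(), 190L, "AATAAA"), cleav))  # 60 nt
  # inclusive boundaries
  expect_equal(find_pas(plant_at(backbone(), cleav - 10L, "AATAAA"),
                        cleav)$offset, 10L)
  expect_equal(find_pas(plant_at(backbone(), cleav - 40L, "AATAAA"),
                        cleav)$offset, 40L)
  # the smallest offset wins over a more upstream hit
  s3 <- plant_at(plant_at(backbone(), 212L, "AATAAA"), 230L, "ATTAAA")
  hit3 <- find_pas(s3, cleav)
  expect_equal(hit3$rna, "AUUAAA")
  expect_equal(hit3$offset, 20L)
})

test_that("USE scanning anchors to the PAS start and rejects genomic N", {
  pas_start <- 225L
  s <- plant_at(backbone(), pas_start - 60L, "TGTAC")
  hit <- find_use(s, pas_start)
  expect_equal(hit$motif, "UGUAN")
  expect_equal(hit$offset, 60L)
  expect_null(find_use(plant_at(backbone(), pas_start - 20L, "TGTAC"),
                       pas_start))  # outside 40-100
  expect_null(find_use(plant_at(backbone(), pas_start - 60L, "TGTAN"),
                       pas_start))  # genomic N at the wildcard position
})

test_that("DSE flag is a sliding G+T fraction over the 40-100 nt region", {
  pas_start <- 100L
  pas_end <- pas_start + 5L
  run <- paste0(strrep("GT", 7L), strrep("A", 6L))  # 14/20 G+T = 0.7
  s <- plant_at(backbone(300L), pas_end + 50L, run)
  expect_true(find_dse(s, pas_start)$gu_rich)
  weak <- paste0(strrep("GT", 5L), strrep("A", 10L))  # 10/20 = 0.5
  expect_false(find_dse(plant_at(backbone(300L), pas_end + 50L, weak),
                        pas_start)$gu_rich)
  expect_false(find_dse(backbone(300L), pas_start)$gu_rich)  # no G/T at all
  short <- find_dse(backbone(150L), pas_start)
  expect_true(short$truncated)
})

test_that("3' context extraction orients and truncates correctly", {
  set.seed(5)
  chr <- paste(sample(c("A", "C", "G", "T"), 1000, replace = TRUE),
               collapse = "")
  genome <- Biostrings::DNAStringSet(c(c1 = chr))
  ctx <- extract_3prime_context(genome, "c1", 100L, 600L, "+", flank = 50L)
  expect_equal(nchar(ctx$seq), 100L)
  expect_equal(ctx$cleavage_idx, 50L)
  expect_equal(ctx$seq, substr(chr, 551L, 650L))
  expect_false(ctx$truncated)

  # minus strand: cleavage base is 1-based 101; element side is [101, 150]
  mins <- extract_3prime_context(genome, "c1", 100L, 600L, "-", flank = 50L)
  expect_equal(mins$seq, as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(chr, 51L, 150L)))))
  expect_equal(mins$cleavage_idx, 50L)

  edge <- extract_3prime_context(genome, "c1", 100L, 980L, "+", flank = 50L)
  expect_true(edge$truncated)
  expect_error(extract_3prime_context(genome, "nope", 1L, 10L), "absent")
})

test_that("minus-strand annotation equals plus-strand on the reverse complement", {
  set.seed(31)
  for (rep in 1:5) {
    chr <- paste(sample(c("A", "C", "G", "T"), 1200, replace = TRUE),
                 collapse = "")
    genome <- Biostrings::DNAStringSet(c(c1 = chr))
    rc <- Biostrings::reverseComplement(genome[[1]])
    genome_rc <- Biostrings::DNAStringSet(c(c1 = as.character(rc)))
    len <- 1200L
    start0 <- 300L; end0 <- 800L  # BED interval on the minus strand
    src_minus <- tibble::tibble(chrom = "c1", start = start0, end = end0,
                                strand = "-", subfamily = "L1HS")
    # cleavage base (1-based start0+1) maps to len - start0 in the revcomp
    src_plus <- tibble::tibble(chrom = "c1", start = len - end0,
                               end = len - start0, strand = "+",
                               subfamily = "L1HS")
    a <- annotate_sources(genome, src_minus)
    b <- annotate_sources(genome_rc, src_plus)
    expect_equal(a[, c("pas", "pas_offset", "use", "dse")],
                 b[, c("pas", "pas_offset", "use", "dse")])
  }
})

test_that("PAS/USE scans agree with a naive windowed substring oracle", {
  set.seed(88)
  cfg <- motif_config()
  for (i in 1:100) {
    s <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE,
                      prob = c(0.4, 0.2, 0.2, 0.2)), collapse = "")
    cleav <- 200L
    got <- find_pas(s, cleav, cfg)
    want <- oracle_pas(s, cleav)
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_equal(got$hexamer, want$hexamer)
      expect_equal(got$offset, want$offset)
      # window containment invariant
      expect_gte(got$offset, cfg$pas_window[1])
      expect_lte(got$offset, cfg$pas_window[2])
      u_got <- find_use(s, cleav - got$offset, cfg)
      u_want <- oracle_use(s, cleav - want$offset)
      expect_equal(is.null(u_got), is.null(u_want))
      if (!is.null(u_got)) expect_equal(u_got$offset, u_want$offset)
    }
  }
})

test_that("annotation reproduces every planted PAS/USE/DSE combination", {
  fl <- simulate_flanks(seed = 404)
  ann <- annotate_sources(fl$flanks, fl$sources)
  expect_equal(ann$pas, fl$truth$exp_pas)
  expect_equal(ann$use, fl$truth$exp_use)
  expect_equal(ann$dse, fl$truth$exp_dse)
  expect_equal(ann$pas_offset[!is.na(ann$pas_offset)],
               fl$truth$exp_pas_offset[fl$truth$pas])
  expect_equal(sum(ann$pas != "-"), sum(fl$truth$pas))
  expect_equal(nrow(annotate_sources(fl$flanks, fl$sources[0, ])), 0L)
})
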
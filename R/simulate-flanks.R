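# Planted donor-flank sequences for motif-scan validation.
#
# One contig per presence/absence combination of {PAS, USE, DSE}, each with
# a synthetic element ending (cleavage site) at position 250 of a 460-nt
# contig.  Planted motifs sit at fixed in-window offsets (PAS start 25 nt
# upstream of cleavage, USE 60 nt upstream of the PAS, GU run 50 nt
# downstream of the PAS end); decoy motifs are planted just outside their
# windows.  Background sequence is scrubbed so that no unplanted motif can
# be detected: scrubbing replaces one base of an unwanted occurrence with a
# letter absent from every motif (C for PAS/USE) or dilutes G/T content
# below the DSE threshold.

FLANK_LEN <- 460L
FLANK_CLEAVAGE <- 250L
FLANK_PAS_START <- 225L   # offset 25 upstream of cleavage
FLANK_USE_START <- 165L   # offset 60 upstream of the PAS start
FLANK_DSE_START <- 280L   # 50 nt downstream of the PAS end (230)

find_occurrences <- function(s, pattern, lo, hi) {
  len <- nchar(pattern)
  starts <- seq.int(max(1L, lo), min(hi, nchar(s) - len + 1L))
  if (length(starts) == 0) return(integer(0))
  starts[substring(s, starts, starts + len - 1L) == pattern]
}

# kill every occurrence of `patterns` starting inside [lo, hi], except one
# starting exactly at keep_start; the replacement base is written outside
# the kept motif's span so a planted motif is never corrupted
scrub_patterns <- function(s, patterns, lo, hi, keep_start = NULL,
                           keep_len = 0L) {
  keep_span <- if (is.null(keep_start)) integer(0)
               else seq.int(keep_start, keep_start + keep_len - 1L)
  for (iter in 1:100) {
    done <- TRUE
    for (p in patterns) {
      occ <- find_occurrences(s, p, lo, hi)
      if (!is.null(keep_start)) occ <- occ[occ != keep_start]
      if (length(occ) == 0) next
      done <- FALSE
      span <- seq.int(occ[1], occ[1] + nchar(p) - 1L)
      target <- setdiff(span, keep_span)[1]
      substr(s, target, target) <- "C"
    }
    if (done) return(s)
  }
  abort("scrubbing did not converge")
}

# dilute G/T content so no sliding subwindow in [lo, hi] reaches the
# threshold fraction
scrub_gt_rich <- function(s, lo, hi, width, fraction) {
  for (iter in 1:500) {
    chars <- strsplit(substr(s, lo, hi), "")[[1]]
    is_gt <- chars %in% c("G", "T")
    counts <- vapply(seq_len(length(chars) - width + 1L), function(i) {
      sum(is_gt[i:(i + width - 1L)])
    }, integer(1))
    bad <- which(counts >= ceiling(width * fraction))
    if (length(bad) == 0) return(s)
    w <- bad[1]
    gt_pos <- which(is_gt[w:(w + width - 1L)])[1] + w - 1L
    substr(s, lo + gt_pos - 1L, lo + gt_pos - 1L) <- "A"
  }
  abort("GT dilution did not converge")
}

plant <- function(s, at, motif) {
  substr(s, at, at + nchar(motif) - 1L) <- motif
  s
}

build_flank <- function(pas, use, dse, hexamer, config) {
  cleav <- FLANK_CLEAVAGE
  pas_lo <- cleav - config$pas_window[2]
  pas_hi <- cleav - config$pas_window[1]
  use_lo <- FLANK_PAS_START - config$use_window[2]
  use_hi <- FLANK_PAS_START - config$use_window[1]
  dse_lo <- FLANK_PAS_START + 5L + config$dse_window[1]
  dse_hi <- FLANK_PAS_START + 5L + config$dse_window[2]

  s <- paste(sample(c("A", "C", "G", "T"), FLANK_LEN, replace = TRUE,
                    prob = c(0.3, 0.3, 0.2, 0.2)), collapse = "")
  s <- scrub_patterns(s, config$pas_hexamers, pas_lo, pas_hi)
  s <- scrub_patterns(s, "TGTA", use_lo, use_hi)
  s <- scrub_gt_rich(s, dse_lo, dse_hi, config$dse_subwindow,
                     config$dse_gt_fraction)

  if (pas) s <- plant(s, FLANK_PAS_START, hexamer)
  if (use) s <- plant(s, FLANK_USE_START, "TGTAC")
  if (dse) {
    run <- paste(sample(c("G", "T"), config$dse_subwindow, replace = TRUE),
                 collapse = "")
    s <- plant(s, FLANK_DSE_START, run)
  }
  # out-of-window decoys: a hexamer 5 nt (too close) and 60 nt (too far)
  # upstream of the cleavage site, and a TGTA 20 nt upstream of the PAS
  s <- plant(s, cleav - 5L, config$pas_hexamers[1])
  s <- plant(s, cleav - 60L, config$pas_hexamers[1])
  s <- plant(s, FLANK_PAS_START - 20L, "TGTAC")

  # planting may have created stray in-window occurrences; final scrub
  s <- scrub_patterns(s, config$pas_hexamers, pas_lo, pas_hi,
                      keep_start = if (pas) FLANK_PAS_START, keep_len = 6L)
  s <- scrub_patterns(s, "TGTA", use_lo, use_hi,
                      keep_start = if (use) FLANK_USE_START, keep_len = 4L)
  if (!dse) {
    s <- scrub_gt_rich(s, dse_lo, dse_hi, config$dse_subwindow,
                       config$dse_gt_fraction)
  }
  s
}

#' Simulate donor flank sequences with planted 3'-end motifs
#'
#' Emits one contig per presence/absence combination of {PAS, USE, DSE}
#' (plus one extra contig carrying the secondary `ATTAAA` hexamer), each
#' with its planted motifs at fixed in-window offsets and decoy motifs just
#' outside the scan windows, together with a matching source table and the
#' expected annotation.
#'
#' @param seed Integer seed.
#' @param config A [motif_config()].
#' @return A list: `flanks` (`DNAStringSet`), `sources` (tibble usable by
#'   [annotate_sources()]) and `truth` (per contig, the planted booleans
#'   and the expected `pas` / `pas_offset` / `use` / `dse` annotation
#'   values).
#' @export
simulate_flanks <- function(seed, config = motif_config()) {
  set.seed(seed)
  combos <- tidyr::expand_grid(pas = c(TRUE, FALSE), use = c(TRUE, FALSE),
                               dse = c(TRUE, FALSE))
  combos$hexamer <- config$pas_hexamers[1]
  extra <- tibble(pas = TRUE, use = FALSE, dse = TRUE,
                  hexamer = config$pas_hexamers[2])
  combos <- bind_rows(combos, extra)
  combos$contig <- sprintf("donor%02d_PAS%d_USE%d_DSE%d",
                           seq_len(nrow(combos)), combos$pas, combos$use,
                           combos$dse)
  seqs <- purrr::pmap_chr(combos[, c("pas", "use", "dse", "hexamer")],
                          function(pas, use, dse, hexamer) {
                            build_flank(pas, use, dse, hexamer, config)
                          })
  flanks <- Biostrings::DNAStringSet(setNames(seqs, combos$contig))
  subfam <- rep(c("L1HS", "SVA_E", "SVA_F"), length.out = nrow(combos))
  sources <- tibble(chrom = combos$contig, start = 0L,
                    end = FLANK_CLEAVAGE, name = subfam, strand = "+",
                    me_type = ifelse(subfam == "L1HS", "L1", "SVA"),
                    subfamily = subfam, source_type = "reference")
  truth <- combos %>%
    mutate(exp_pas = ifelse(.data$pas, dna_to_rna(.data$hexamer), "-"),
           exp_pas_offset = ifelse(.data$pas,
                                   FLANK_CLEAVAGE - FLANK_PAS_START,
                                   NA_integer_),
           exp_use = ifelse(.data$pas & .data$use, "UGUAN",
                            ifelse(.data$pas, "-", "-")),
           exp_dse = ifelse(!.data$pas, "-",
                            ifelse(.data$dse, "GU-rich", "No")))
  list(flanks = flanks, sources = sources, truth = truth)
}
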
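# Seeded synthetic cohort generator.
#
# Emits every input the pipeline consumes -- MELT-dialect VCF, element and
# segdup BED tracks, sample panel, chrom.sizes, donor flank FASTA -- with a
# planted truth table, so that QC, classification, population statistics and
# motif scanning can all be validated end to end without external data.
# All randomness flows from the mandatory seed; the same seed reproduces
# every file byte for byte.

default_populations <- function() {
  tibble(
    population = c("ASW", "YRI", "LWK", "GWD", "MSL", "ESN", "ACB",
                   "MXL", "PUR", "CLM", "PEL",
                   "CEU", "TSI", "FIN", "GBR", "IBS",
                   "GIH", "PJL", "BEB", "STU", "ITU",
                   "CHB", "JPT", "CHS", "CDX", "KHV"),
    super_population = c(rep("AFR", 7), rep("AMR", 4), rep("EUR", 5),
                         rep("SAS", 5), rep("EAS", 5)),
    n = c(7L, 18L, 10L, 18L, 10L, 15L, 12L,
          10L, 14L, 13L, 12L,
          18L, 11L, 10L, 9L, 16L,
          10L, 15L, 13L, 11L, 11L,
          10L, 10L, 16L, 9L, 12L)
  )
}

default_chrom_sizes <- function() {
  tibble(chrom = c("chr1", "chr2", "chr3", "chrX", "chrY"),
         length = c(60e6, 50e6, 45e6, 30e6, 12e6))
}

INACTIVE_SUBFAMILIES <- c(L1 = "L1PA4", L1 = "L1PA7", L1 = "L1PA2",
                          SVA = "SVA_A", SVA = "SVA_B")

#' Synthetic cohort configuration
#'
#' Defaults mirror the structure of a 26-population, 5-super-population
#' high-coverage cohort at one tenth of its sample size, with the observed
#' per-type candidate fractions and HIGH/LOW/REMOVED outcome proportions of
#' a genome-wide L1/SVA transduction screen, transduced-segment lengths in
#' the observed 7-997 bp range, and consensus element lengths of 6019 bp
#' (L1) and 1316 bp (SVA).
#'
#' @param populations Tibble with `population`, `super_population`, `n`
#'   (per-population sample counts).
#' @param n_loci Named integer vector of polymorphic loci per element type.
#' @param n_elements Named count of reference elements emitted to the
#'   element track per type.
#' @param fulllength_fraction Fraction of emitted elements that are
#'   full length (the rest are 5'-truncated decoys).
#' @param chrom_sizes Synthetic chromosome table (`chrom`, `length`).
#' @param af_distribution `list(kind = "beta", shape1, shape2)` or
#'   `list(kind = "point", af)` for planted allele frequencies.
#' @param hwe_mode `list(kind = "exact_hwe")` or
#'   `list(kind = "excess_het", eps)` (het probability inflated by `eps`
#'   and renormalized).
#' @param qc_fail_fraction Fraction of loci planted to fail QC, one clause
#'   each.
#' @param rsd_fraction Among QC-passing loci, fraction tagged `rSD` rather
#'   than `PASS`.
#' @param transduction_fraction Named per-type probability that a
#'   QC-passing locus is a transduction candidate.
#' @param label_proportions Named list per type of planted
#'   HIGH/LOW/REMOVED proportions.
#' @param nonref_source_fraction Named per-type probability that a
#'   candidate's source is itself a non-reference insertion.
#' @param transduced_length_range Bounds (bp) of the log-uniform
#'   transduced-segment length.
#' @param te_consensus Named consensus element lengths (bp) added to the
#'   transduced length to form SVLEN.
#' @param svlen_jitter Half-width (bp) of the uniform jitter on SVLEN.
#' @param n_segdups,segdup_width_range Segdup track geometry.
#' @param seed Mandatory integer seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(populations = default_populations(),
                       n_loci = c(L1 = 400L, SVA = 170L),
                       n_elements = c(L1 = 300L, SVA = 150L),
                       fulllength_fraction = 0.6,
                       chrom_sizes = default_chrom_sizes(),
                       af_distribution = list(kind = "beta", shape1 = 0.3,
                                              shape2 = 3),
                       hwe_mode = list(kind = "exact_hwe"),
                       qc_fail_fraction = 0.1,
                       rsd_fraction = 0.04,
                       transduction_fraction = c(L1 = 0.071, SVA = 0.119),
                       label_proportions = list(
                         L1 = c(HIGH = 268, LOW = 198, REMOVED = 39) / 505,
                         SVA = c(HIGH = 162, LOW = 180, REMOVED = 19) / 361),
                       nonref_source_fraction = c(L1 = 0.19, SVA = 0.05),
                       transduced_length_range = c(7L, 997L),
                       te_consensus = c(L1 = 6019L, SVA = 1316L),
                       svlen_jitter = 10L,
                       n_segdups = 40L,
                       segdup_width_range = c(5e3, 5e4),
                       seed = NULL) {
  if (is.null(seed)) abort("sim_config() requires an explicit seed")
  stopifnot(all(populations$n > 0),
            qc_fail_fraction >= 0, qc_fail_fraction <= 1,
            all(transduction_fraction >= 0), all(transduction_fraction <= 1),
            transduced_length_range[1] >= 1,
            transduced_length_range[1] < transduced_length_range[2])
  for (p in label_proportions) {
    stopifnot(abs(sum(p) - 1) < 1e-8, all(p >= 0))
  }
  map <- distinct(populations, .data$population, .data$super_population)
  if (anyDuplicated(map$population)) {
    abort("a population maps to more than one super-population")
  }
  structure(list(populations = populations,
                 n_samples = sum(populations$n),
                 n_loci = n_loci, n_elements = n_elements,
                 fulllength_fraction = fulllength_fraction,
                 chrom_sizes = chrom_sizes,
                 af_distribution = af_distribution, hwe_mode = hwe_mode,
                 qc_fail_fraction = qc_fail_fraction,
                 rsd_fraction = rsd_fraction,
                 transduction_fraction = transduction_fraction,
                 label_proportions = label_proportions,
                 nonref_source_fraction = nonref_source_fraction,
                 transduced_length_range = transduced_length_range,
                 te_consensus = te_consensus,
                 svlen_jitter = as.integer(svlen_jitter),
                 n_segdups = as.integer(n_segdups),
                 segdup_width_range = segdup_width_range,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate diploid genotypes at a planted allele frequency
#'
#' Draws alternate-allele dosages i.i.d. per sample.  Under `exact_hwe`
#' the genotype probabilities are `(1-p)^2`, `2p(1-p)`, `p^2`; under
#' `excess_het(eps)` the heterozygote probability is inflated by `eps` and
#' the vector renormalized.
#'
#' @param af Planted alternate allele frequency in `[0, 1]`.
#' @param n_samples Number of diploid samples.
#' @param hwe_mode `list(kind = "exact_hwe")` or
#'   `list(kind = "excess_het", eps = ...)`.
#' @return Integer dosage vector of length `n_samples`.
#' @export
simulate_genotypes <- function(af, n_samples,
                               hwe_mode = list(kind = "exact_hwe")) {
  stopifnot(af >= 0, af <= 1)
  probs <- c((1 - af)^2, 2 * af * (1 - af), af^2)
  if (hwe_mode$kind == "excess_het") {
    probs[2] <- probs[2] * (1 + hwe_mode$eps)
    probs <- probs / sum(probs)
  } else if (hwe_mode$kind != "exact_hwe") {
    abort(sprintf("unknown hwe_mode '%s'", hwe_mode$kind))
  }
  sample(0:2, n_samples, replace = TRUE, prob = probs)
}

draw_af <- function(n, dist) {
  switch(dist$kind,
         beta = stats::rbeta(n, dist$shape1, dist$shape2),
         point = rep(dist$af, n),
         abort(sprintf("unknown af_distribution '%s'", dist$kind)))
}

random_positions <- function(n, chrom_sizes, margin = 1e5) {
  chrom <- sample(chrom_sizes$chrom, n, replace = TRUE,
                  prob = chrom_sizes$length)
  len <- chrom_sizes$length[match(chrom, chrom_sizes$chrom)]
  pos <- floor(runif(n, margin, len - margin))
  tibble(chrom = chrom, pos = as.integer(pos))
}

in_segdup_point <- function(chrom, pos, segdups) {
  if (nrow(segdups) == 0) return(rep(FALSE, length(chrom)))
  hit <- rep(FALSE, length(chrom))
  for (i in seq_len(nrow(segdups))) {
    hit <- hit | (chrom == segdups$chrom[i] & pos > segdups$start[i] &
                    pos <= segdups$end[i])
  }
  hit
}

simulate_elements <- function(cfg) {
  rows <- purrr::imap(as.list(cfg$n_elements), function(n, type) {
    full <- runif(n) < cfg$fulllength_fraction
    minlen <- if (type == "L1") 5900L else 1000L
    maxlen <- cfg$te_consensus[[type]]
    len <- integer(n)
    len[full] <- as.integer(floor(runif(sum(full), minlen, maxlen + 1)))
    len[!full] <- as.integer(floor(runif(sum(!full), minlen / 10, minlen)))
    active <- ACTIVE_BY_TYPE[[type]]
    inactive <- unname(INACTIVE_SUBFAMILIES[names(INACTIVE_SUBFAMILIES) == type])
    subfam <- ifelse(runif(n) < 0.8,
                     sample(active, n, replace = TRUE),
                     sample(inactive, n, replace = TRUE))
    loc <- random_positions(n, cfg$chrom_sizes)
    tibble(chrom = loc$chrom, start = loc$pos,
           end = loc$pos + len, name = subfam,
           strand = sample(c("+", "-"), n, replace = TRUE),
           me_type = type, subfamily = subfam, width = len,
           fulllength = full)
  })
  bind_rows(rows)
}

ACTIVE_BY_TYPE <- list(L1 = c("L1HS", "L1Ta", "L1ta1d", "L1T1d"),
                       SVA = c("SVA_D", "SVA_E", "SVA_F"))

simulate_segdups <- function(cfg) {
  loc <- random_positions(cfg$n_segdups, cfg$chrom_sizes, margin = 2e5)
  w <- as.integer(floor(runif(cfg$n_segdups, cfg$segdup_width_range[1],
                              cfg$segdup_width_range[2])))
  tibble(chrom = loc$chrom, start = loc$pos, end = loc$pos + w,
         name = sprintf("SD%03d", seq_len(cfg$n_segdups)),
         strand = ".", me_type = "", subfamily = "", width = w)
}

rlunif_int <- function(n, lo, hi) {
  as.integer(floor(exp(runif(n, log(lo), log(hi + 1)))))
}

metrans_string <- function(src_chrom, src_start, src_end, strand, td_len) {
  ifelse(strand == "-",
         paste(src_chrom, src_start - td_len, src_start - 1L, strand,
               sep = "|"),
         paste(src_chrom, src_end + 1L, src_end + td_len, strand, sep = "|"))
}

plant_candidate_fields <- function(df, cfg, elements, segdups) {
  type <- df$me_type[1]
  n <- nrow(df)
  full <- elements[elements$me_type == type & elements$fulllength, ]
  full_active <- full[toupper(full$subfamily) %in%
                        toupper(ACTIVE_BY_TYPE[[type]]), ]
  full_inactive <- full[!toupper(full$subfamily) %in%
                          toupper(ACTIVE_BY_TYPE[[type]]), ]
  if (nrow(full_active) == 0 || nrow(full_inactive) == 0) {
    abort("element track lacks active or inactive full-length sources")
  }
  td_len <- rlunif_int(n, cfg$transduced_length_range[1],
                       cfg$transduced_length_range[2])
  svlen <- cfg$te_consensus[[type]] + td_len +
    sample(seq(-cfg$svlen_jitter, cfg$svlen_jitter), n, replace = TRUE)
  nonref <- runif(n) < cfg$nonref_source_fraction[[type]]
  low_reason <- rep(NA_character_, n)
  low_reason[df$planted_label == "LOW"] <-
    sample(c("LOW_SUPPORT", "LENGTH_INCONSISTENT", "INACTIVE_FAMILY"),
           sum(df$planted_label == "LOW"), replace = TRUE)
  # INACTIVE_FAMILY plants need a reference source carrying the subfamily
  nonref[!is.na(low_reason) & low_reason == "INACTIVE_FAMILY"] <- FALSE

  src_chrom <- character(n); src_start <- integer(n); src_end <- integer(n)
  src_strand <- character(n); src_subfam <- character(n)
  pick <- function(pool) pool[sample(nrow(pool), 1L), ]
  for (i in seq_len(n)) {
    inactive_wanted <- !is.na(low_reason[i]) &&
      low_reason[i] == "INACTIVE_FAMILY"
    if (nonref[i]) {
      loc <- random_positions(1L, cfg$chrom_sizes)
      src_chrom[i] <- loc$chrom; src_start[i] <- loc$pos
      src_end[i] <- loc$pos
      src_strand[i] <- sample(c("+", "-"), 1L)
      src_subfam[i] <- if (type == "L1") {
        sample(c(SUBFAM_UNDETERMINED, "L1Ta", "L1T1d"), 1L,
               prob = c(32, 3, 16))
      } else SUBFAM_UNDETERMINED
    } else {
      el <- if (inactive_wanted) pick(full_inactive) else pick(full_active)
      src_chrom[i] <- el$chrom
      src_start[i] <- el$start + 1L  # BED -> 1-based
      src_end[i] <- el$end
      src_strand[i] <- el$strand
      src_subfam[i] <- el$subfamily
    }
  }
  src_td_len <- td_len
  li <- !is.na(low_reason) & low_reason == "LENGTH_INCONSISTENT"
  src_td_len[li] <- svlen[li] + sample(0:50, sum(li), replace = TRUE)

  sr <- df$sr
  sr[df$planted_label %in% c("HIGH", "REMOVED_SEGDUP")] <-
    sample(5:60, sum(df$planted_label %in% c("HIGH", "REMOVED_SEGDUP")),
           replace = TRUE)
  low <- df$planted_label == "LOW"
  sr[low] <- sample(5:60, sum(low), replace = TRUE)
  ls <- !is.na(low_reason) & low_reason == "LOW_SUPPORT"
  sr[ls] <- sample(3:4, sum(ls), replace = TRUE)

  # REMOVED plants sit at a segdup midpoint
  rem <- df$planted_label == "REMOVED_SEGDUP"
  if (any(rem)) {
    sd_idx <- sample(nrow(segdups), sum(rem), replace = TRUE)
    df$chrom[rem] <- segdups$chrom[sd_idx]
    df$pos[rem] <- as.integer(floor((segdups$start[sd_idx] + 1 +
                                       segdups$end[sd_idx]) / 2))
  }

  df$sr <- sr
  df$svlen <- as.integer(svlen)
  df$src_chrom <- src_chrom
  df$src_start <- src_start
  df$src_end <- src_end
  df$src_strand <- src_strand
  df$src_subfamily <- src_subfam
  df$src_type <- ifelse(nonref, "nonreference", "reference")
  df$src_td_len <- as.integer(src_td_len)
  df$metrans <- metrans_string(src_chrom, src_start, src_end, src_strand,
                               td_len)
  df$planted_reason <- low_reason
  df$planted_td_len <- td_len
  df
}

simulate_loci <- function(cfg, type, elements, segdups) {
  n <- cfg$n_loci[[type]]
  af <- draw_af(n, cfg$af_distribution)
  loc <- random_positions(n, cfg$chrom_sizes)
  # keep non-removed loci clear of segdups (rejection resampling)
  for (it in 1:20) {
    bad <- in_segdup_point(loc$chrom, loc$pos, segdups)
    if (!any(bad)) break
    loc[bad, ] <- random_positions(sum(bad), cfg$chrom_sizes)
  }
  qc_fail <- runif(n) < cfg$qc_fail_fraction
  qc_reason <- rep(NA_character_, n)
  qc_reason[qc_fail] <- sample(c("SR_BELOW_MIN", "ASSESS_BELOW_MIN",
                                 "NO_KEEP_FILTER", "REJECT_FILTER"),
                               sum(qc_fail), replace = TRUE)
  sr <- 3L + stats::rpois(n, 8)
  assess <- 3L + stats::rpois(n, 4)
  sr[qc_fail & qc_reason == "SR_BELOW_MIN"] <-
    sample(0:2, sum(qc_fail & qc_reason == "SR_BELOW_MIN"), replace = TRUE)
  assess[qc_fail & qc_reason == "ASSESS_BELOW_MIN"] <-
    sample(0:2, sum(qc_fail & qc_reason == "ASSESS_BELOW_MIN"),
           replace = TRUE)
  flags <- ifelse(runif(n) < cfg$rsd_fraction, "rSD", "PASS")
  flags[qc_fail & qc_reason == "NO_KEEP_FILTER"] <- "lc"
  flags[qc_fail & qc_reason == "REJECT_FILTER"] <-
    sample(c("PASS;lc", "PASS;hDP", "rSD;lc"),
           sum(qc_fail & qc_reason == "REJECT_FILTER"), replace = TRUE)

  cand <- !qc_fail & runif(n) < cfg$transduction_fraction[[type]]
  label <- rep(NA_character_, n)
  props <- cfg$label_proportions[[type]]
  label[cand] <- sample(names(props), sum(cand), replace = TRUE,
                        prob = props)
  label[label == "REMOVED"] <- "REMOVED_SEGDUP"

  lenr <- if (type == "L1") c(33L, 6019L) else c(31L, 1316L)
  df <- tibble(
    chrom = loc$chrom, pos = loc$pos,
    variant_id = sprintf("%s_%04d", type, seq_len(n)),
    ref = sample(c("A", "C", "G", "T"), n, replace = TRUE),
    alt = sprintf("<INS:ME:%s>", type),
    me_type = type,
    subfamily = sample(ACTIVE_BY_TYPE[[type]], n, replace = TRUE),
    svlen = as.integer(floor(runif(n, lenr[1], lenr[2] + 1))),
    assess = as.integer(assess), sr = as.integer(sr),
    filter_flags = stringr::str_split(flags, stringr::fixed(";")),
    metrans = METRANS_NULL,
    is_transduction = cand,
    info_other = rep(list(character(0) %>% setNames(character(0))), n),
    src_chrom = NA_character_, src_start = NA_integer_,
    src_end = NA_integer_, src_strand = NA_character_,
    src_subfamily = NA_character_, src_type = NA_character_,
    src_td_len = NA_integer_,
    planted_af = af, planted_qc_pass = !qc_fail, planted_qc_reason = qc_reason,
    planted_label = label, planted_reason = NA_character_,
    planted_td_len = NA_integer_
  )
  if (any(cand)) {
    df[cand, ] <- plant_candidate_fields(df[cand, ], cfg, elements, segdups)
  }
  df
}

#' Simulate a complete synthetic cohort with planted ground truth
#'
#' Generates the sample panel, chromosome table, element and segdup tracks,
#' per-locus genotypes, QC outcomes and transduction plants described by a
#' [sim_config()], optionally writing the full file bundle (VCF, BEDs,
#' panel TSV, chrom.sizes, donor-flank FASTA, truth TSV) to `dir`.
#' Each planted QC failure violates exactly one QC clause; each planted
#' LOW transduction violates exactly one classification clause; REMOVED
#' plants sit inside an emitted segdup interval.  Identical seeds yield
#' byte-identical bundles.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if needed); `NULL` with
#'   `write = FALSE` keeps everything in memory.
#' @param write Whether to write the file bundle.
#' @return A list: `calls` (calls tibble including genotypes), `truth`
#'   (per-locus planted values), `panel`, `elements`, `segdups`,
#'   `chrom_sizes`, `flanks` (`DNAStringSet`), `flank_sources`,
#'   `flank_truth`, and -- when written -- `paths`.
#' @export
simulate_cohort <- function(config = NULL, dir = NULL,
                            write = !is.null(dir)) {
  if (is.null(config)) abort("simulate_cohort() requires a sim_config()")
  cfg <- config
  set.seed(cfg$seed)
  pops <- cfg$populations
  panel <- tibble(
    sample_id = sprintf("S%04d", seq_len(cfg$n_samples)),
    population = rep(pops$population, pops$n),
    super_population = rep(pops$super_population, pops$n),
    sex = sample(c("male", "female"), cfg$n_samples, replace = TRUE)
  )
  elements <- simulate_elements(cfg)
  segdups <- simulate_segdups(cfg)
  loci <- bind_rows(purrr::map(names(cfg$n_loci), function(type) {
    simulate_loci(cfg, type, elements, segdups)
  }))
  loci$gt <- lapply(loci$planted_af, function(p) {
    setNames(simulate_genotypes(p, cfg$n_samples, cfg$hwe_mode),
             panel$sample_id)
  })
  loci <- arrange(loci, .data$chrom, .data$pos)

  truth_cols <- c("variant_id", "chrom", "pos", "me_type", "planted_af",
                  "planted_qc_pass", "planted_qc_reason", "is_transduction",
                  "planted_label", "planted_reason", "planted_td_len",
                  "src_chrom", "src_start", "src_end", "src_type",
                  "src_subfamily")
  truth <- loci[, truth_cols]
  calls <- loci[, names(empty_calls())]

  fl <- simulate_flanks(seed = cfg$seed + 1L)

  out <- list(calls = calls, truth = truth, panel = panel,
              elements = elements[, c("chrom", "start", "end", "name",
                                      "strand", "me_type", "subfamily",
                                      "width")],
              segdups = segdups[, c("chrom", "start", "end", "name",
                                    "strand", "me_type", "subfamily",
                                    "width")],
              chrom_sizes = cfg$chrom_sizes,
              flanks = fl$flanks, flank_sources = fl$sources,
              flank_truth = fl$truth)
  if (write) {
    if (is.null(dir)) abort("dir is required when write = TRUE")
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      vcf = file.path(dir, "cohort.vcf"),
      elements = file.path(dir, "elements.bed"),
      segdups = file.path(dir, "segdups.bed"),
      panel = file.path(dir, "panel.tsv"),
      chrom_sizes = file.path(dir, "chrom.sizes"),
      flanks = file.path(dir, "flanks.fa"),
      flank_sources = file.path(dir, "flank_sources.bed"),
      truth = file.path(dir, "truth.tsv")
    )
    write_mei_vcf(calls, paths$vcf)
    write_bed <- function(x, path) {
      readr::write_tsv(x[, c("chrom", "start", "end", "name", "strand",
                             "me_type")], path, col_names = FALSE,
                       progress = FALSE)
    }
    write_bed(out$elements, paths$elements)
    write_bed(out$segdups, paths$segdups)
    readr::write_tsv(panel, paths$panel, progress = FALSE)
    readr::write_tsv(cfg$chrom_sizes, paths$chrom_sizes, col_names = FALSE,
                     progress = FALSE)
    Biostrings::writeXStringSet(fl$flanks, paths$flanks)
    readr::write_tsv(fl$sources[, c("chrom", "start", "end", "name",
                                    "strand", "me_type")],
                     paths$flank_sources, col_names = FALSE,
                     progress = FALSE)
    readr::write_tsv(truth, paths$truth, na = ".", progress = FALSE)
    out$paths <- paths
  }
  out
}
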
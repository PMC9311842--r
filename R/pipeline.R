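# End-to-end orchestration: QC -> transduction classification -> population
# statistics -> progenitor mapping -> motif annotation, with TSV reports.
# All analysis stages are deterministic; randomness lives only in the
# synthetic-cohort generator.

#' Pipeline run configuration
#'
#' @param vcf Path to the MEI VCF.
#' @param panel Path to the sample panel TSV.
#' @param chrom_sizes Path to the chrom.sizes file.
#' @param elements Path to the element BED track (optional; enables
#'   full-length source counting and per-element rates).
#' @param segdups Path to the segdup BED track (optional; without it no
#'   `REMOVED_SEGDUP` tier exists and a warning is emitted).
#' @param fasta Path to a genome / donor-flank FASTA (optional; enables
#'   motif annotation of progenitor loci).
#' @param out_dir Directory for the TSV reports.
#' @param qc A [qc_thresholds()].
#' @param classifier A [classifier_config()].
#' @param motif A [motif_config()].
#' @param top_sources Number of ranked progenitors annotated for motifs
#'   (default 7).
#' @return A list of class `run_config`.
#' @export
run_config <- function(vcf, panel, chrom_sizes, elements = NULL,
                       segdups = NULL, fasta = NULL, out_dir = NULL,
                       qc = qc_thresholds(),
                       classifier = classifier_config(),
                       motif = motif_config(), top_sources = 7L) {
  for (p in c(vcf, panel, chrom_sizes, elements, segdups, fasta)) {
    if (!is.null(p) && !file.exists(p)) abort(sprintf("no such file: %s", p))
  }
  structure(list(vcf = vcf, panel = panel, chrom_sizes = chrom_sizes,
                 elements = elements, segdups = segdups, fasta = fasta,
                 out_dir = out_dir, qc = qc, classifier = classifier,
                 motif = motif, top_sources = as.integer(top_sources)),
            class = "run_config")
}

stage_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, sprintf(...)))
}

#' Run the full post-processing pipeline
#'
#' Reads all inputs, applies QC, classifies transduction candidates,
#' computes population statistics, maps progenitors and (when a FASTA is
#' supplied) annotates the most prolific donor loci with 3'-end motifs.
#' When `config$out_dir` is set, writes `funnel.tsv`,
#' `source_families.tsv`, `popstats.tsv`, `progenitors.tsv`, `motifs.tsv`,
#' `qc_drops.tsv` and `density.tsv`; reruns on identical inputs reproduce
#' the reports byte for byte.
#'
#' @param config A [run_config()].
#' @return A list with `calls`, `qc` (kept/dropped), `classified`,
#'   `funnel`, `source_families`, `popstats`, `hwe`, `density`,
#'   `progenitors`, `ranked`, `motifs` (or `NULL`), `per_element_rates`
#'   (or `NULL`), and `reports` (paths, when written).
#' @export
run_pipeline <- function(config) {
  panel <- read_sample_panel(config$panel)
  calls <- read_mei_vcf(config$vcf, panel)
  chrom_sizes <- read_chrom_sizes(config$chrom_sizes)
  stage_log("read", "%d calls, %d samples", nrow(calls), nrow(panel))

  qcres <- qc_filter(calls, config$qc)
  stage_log("qc", "%d kept, %d dropped", nrow(qcres$kept),
            nrow(qcres$dropped))

  segdups <- NULL
  if (!is.null(config$segdups)) {
    segdups <- read_bed(config$segdups)
  } else {
    warn("no segdup track supplied; classification has no REMOVED_SEGDUP tier")
  }
  candidates <- filter(qcres$kept, .data$is_transduction)
  classified <- classify_transductions(candidates, segdups,
                                       config$classifier)
  funnel <- td_funnel(classified)
  families <- source_family_table(classified)
  stage_log("classify", "%d candidates -> %d high, %d low, %d removed",
            nrow(classified), sum(classified$label == "HIGH"),
            sum(classified$label == "LOW"),
            sum(classified$label == "REMOVED_SEGDUP"))

  popstats <- allele_summary(qcres$kept, panel,
                             c("ALL", "super_population"))
  hwe <- hwe_screen(qcres$kept)
  dens <- density_per_mbp(qcres$kept, chrom_sizes)
  stage_log("popstats", "%d summaries, %d HWE tests", nrow(popstats),
            nrow(hwe))

  progenitors <- build_progenitor_map(classified)
  ranked <- rank_sources(progenitors)
  stage_log("progenitors", "%d distinct sources for %d offspring",
            nrow(progenitors), sum(progenitors$n_offspring))

  rates <- NULL
  if (!is.null(config$elements)) {
    elements <- read_bed(config$elements)
    full <- select_fulllength_sources(elements, config$qc)
    n_full <- count(full, .data$me_type, name = "n_elements")
    rates <- funnel %>%
      left_join(n_full, by = "me_type") %>%
      filter(!is.na(.data$n_elements)) %>%
      mutate(rate_pct = per_element_rate(.data$n_high, .data$n_elements)) %>%
      select("me_type", "n_high", "n_elements", "rate_pct")
  }

  motifs <- NULL
  if (!is.null(config$fasta)) {
    genome <- read_genome_fasta(config$fasta)
    top <- head(ranked, config$top_sources)
    top_src <- tibble(chrom = top$src_chrom,
                      start = ifelse(top$src_type == "nonreference",
                                     top$src_start - 1L, top$src_start - 1L),
                      end = top$src_end, strand = "+",
                      subfamily = top$src_subfamily,
                      source_type = top$src_type)
    top_src <- top_src[top_src$chrom %in% names(genome), ]
    motifs <- annotate_sources(genome, top_src, config$motif)
    stage_log("motifs", "%d donor loci annotated", nrow(motifs))
  }

  reports <- NULL
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    out <- function(f) file.path(config$out_dir, f)
    reports <- list(funnel = out("funnel.tsv"),
                    source_families = out("source_families.tsv"),
                    popstats = out("popstats.tsv"),
                    progenitors = out("progenitors.tsv"),
                    qc_drops = out("qc_drops.tsv"),
                    density = out("density.tsv"))
    write_report(funnel, reports$funnel, "funnel")
    readr::write_tsv(families, reports$source_families, progress = FALSE)
    write_report(popstats, reports$popstats, "popstats")
    prog_rows <- ranked %>%
      mutate(source_locus = .data$source_locus,
             subfamily = .data$src_subfamily, source_type = .data$src_type)
    write_report(prog_rows, reports$progenitors, "progenitors")
    readr::write_tsv(qcres$dropped %>%
                       select("variant_id", "chrom", "pos", "me_type",
                              "qc_reason"),
                     reports$qc_drops, progress = FALSE)
    readr::write_tsv(dens, reports$density, progress = FALSE)
    if (!is.null(motifs)) {
      reports$motifs <- out("motifs.tsv")
      write_report(motifs, reports$motifs, "motifs")
    }
  }

  list(calls = calls, qc = qcres, classified = classified, funnel = funnel,
       source_families = families, popstats = popstats, hwe = hwe,
       density = dens, progenitors = progenitors, ranked = ranked,
       motifs = motifs, per_element_rates = rates, reports = reports)
}
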
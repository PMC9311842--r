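# 3'-end processing motifs at donor loci: polyadenylation signal hexamer
# (PAS, AAUAAA/AUUAAA on the transcript), upstream sequence element (USE,
# UGUAN) and downstream GU-rich element (DSE).
#
# All scanning happens in transcript orientation: minus-strand sources are
# reverse-complemented so that "upstream" always means toward the element
# body.  The cleavage site is approximated by the annotated 3' terminus of
# the source element.  Offsets are measured from the motif start; windows
# are inclusive at both ends.  An ambiguity base (N) in the genome never
# matches a motif position.

#' Motif-scan configuration
#'
#' @param pas_hexamers PAS hexamers in priority order, DNA alphabet
#'   (default `AATAAA`, `ATTAAA`).
#' @param pas_window Inclusive (min, max) distance in nt of the hexamer
#'   start upstream of the cleavage site (default 10-40).
#' @param use_window Inclusive (min, max) distance of the USE (`TGTAN`,
#'   N = any base) start upstream of the PAS start (default 40-100).
#' @param dse_window Inclusive (min, max) distance downstream of the PAS
#'   end scanned for the GU-rich element (default 40-100).
#' @param dse_gt_fraction Minimum G+T fraction for a window to count as
#'   GU-rich (default 0.6).
#' @param dse_subwindow Sliding-window width in nt for the DSE test
#'   (default 20).
#' @return A list of class `motif_config`.
#' @export
motif_config <- function(pas_hexamers = c("AATAAA", "ATTAAA"),
                         pas_window = c(10L, 40L),
                         use_window = c(40L, 100L),
                         dse_window = c(40L, 100L),
                         dse_gt_fraction = 0.6,
                         dse_subwindow = 20L) {
  stopifnot(pas_window[1] < pas_window[2], use_window[1] < use_window[2],
            dse_window[1] < dse_window[2],
            dse_gt_fraction > 0, dse_gt_fraction <= 1,
            dse_subwindow >= 1,
            dse_subwindow <= dse_window[2] - dse_window[1] + 1)
  structure(list(pas_hexamers = toupper(pas_hexamers),
                 pas_window = as.integer(pas_window),
                 use_window = as.integer(use_window),
                 dse_window = as.integer(dse_window),
                 dse_gt_fraction = dse_gt_fraction,
                 dse_subwindow = as.integer(dse_subwindow)),
            class = "motif_config")
}

dna_to_rna <- function(x) chartr("T", "U", x)

#' Read a genome or flank FASTA
#'
#' @param path Path to a (possibly gzipped) FASTA file.
#' @return A named `Biostrings::DNAStringSet`; names are truncated at the
#'   first whitespace.
#' @export
read_genome_fasta <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- stringr::str_split_i(names(g), "\\s+", 1)
  g
}

#' Extract the oriented 3' context of a source element
#'
#' Returns genomic sequence around the element's 3' terminus in transcript
#' orientation: for a plus-strand source the window ends `flank` nt past
#' the annotated end; a minus-strand source is reverse-complemented so the
#' cleavage site still reads left-to-right.  Windows are truncated (and
#' flagged) at contig edges.
#'
#' @param genome A `DNAStringSet` (see [read_genome_fasta()]).
#' @param chrom,start,end Source interval, BED coordinates (0-based
#'   half-open).
#' @param strand `"+"`, `"-"` or `"."` (treated as `"+"`).
#' @param flank Number of nt kept on each side of the cleavage site
#'   (default 200).
#' @return A list with `seq` (character), `cleavage_idx` (the sequence is
#'   element-side up to and including this index, downstream after it) and
#'   `truncated`.
#' @export
extract_3prime_context <- function(genome, chrom, start, end, strand = "+",
                                   flank = 200L) {
  if (!chrom %in% names(genome)) {
    abort(sprintf("chromosome '%s' absent from FASTA", chrom))
  }
  chrom_seq <- genome[[chrom]]
  len <- length(chrom_seq)
  minus <- identical(strand, "-")
  cleavage <- if (minus) start + 1L else end  # 1-based terminal base
  if (cleavage < 1L || cleavage > len) {
    abort("source interval lies outside the chromosome")
  }
  if (minus) {
    lo <- max(1L, cleavage - flank)
    hi <- min(len, cleavage + flank - 1L)
    s <- as.character(Biostrings::reverseComplement(
      Biostrings::subseq(chrom_seq, lo, hi)))
    cleavage_idx <- hi - cleavage + 1L
    truncated <- (hi - cleavage + 1L) < flank || (cleavage - lo) < flank
  } else {
    lo <- max(1L, cleavage - flank + 1L)
    hi <- min(len, cleavage + flank)
    s <- as.character(Biostrings::subseq(chrom_seq, lo, hi))
    cleavage_idx <- cleavage - lo + 1L
    truncated <- (cleavage - lo + 1L) < flank || (hi - cleavage) < flank
  }
  list(seq = s, cleavage_idx = cleavage_idx, truncated = truncated)
}

match_starts <- function(pattern, seq) {
  as.integer(Biostrings::start(Biostrings::matchPattern(
    pattern, Biostrings::DNAString(seq), fixed = TRUE)))
}

#' Find the polyadenylation signal upstream of the cleavage site
#'
#' Scans hexamer start positions between `pas_window[1]` and
#' `pas_window[2]` nt upstream of the cleavage site (inclusive).  Among all
#' hits the smallest offset wins; ties at the same offset are broken by
#' hexamer priority order.
#'
#' @param seq Character sequence in transcript orientation.
#' @param cleavage_idx 1-based index of the cleavage-site base in `seq`.
#' @param config A [motif_config()].
#' @return `NULL` if no hit, else a list with `hexamer` (DNA), `rna`
#'   (RNA-alphabet rendering, e.g. `AAUAAA`) and `offset` (nt upstream of
#'   the cleavage site).
#' @export
find_pas <- function(seq, cleavage_idx, config = motif_config()) {
  p_min <- cleavage_idx - config$pas_window[2]
  p_max <- cleavage_idx - config$pas_window[1]
  if (p_max < 1L) return(NULL)
  hits <- purrr::imap(config$pas_hexamers, function(hex, rank) {
    starts <- match_starts(hex, seq)
    starts <- starts[starts >= max(1L, p_min) & starts <= p_max]
    if (length(starts) == 0) return(NULL)
    tibble(hexamer = hex, rank = rank,
           offset = cleavage_idx - max(starts))
  })
  hits <- bind_rows(hits)
  if (nrow(hits) == 0) return(NULL)
  best <- hits[order(hits$offset, hits$rank), ][1, ]
  list(hexamer = best$hexamer, rna = dna_to_rna(best$hexamer),
       offset = best$offset)
}

#' Find the upstream sequence element (UGUAN)
#'
#' Searches for `TGTA` followed by any unambiguous base, starting
#' `use_window[1]`-`use_window[2]` nt upstream of the PAS start
#' (inclusive).
#'
#' @param seq Character sequence in transcript orientation.
#' @param pas_start 1-based start index of the PAS hexamer in `seq`.
#' @param config A [motif_config()].
#' @return `NULL` if absent, else a list with `motif` (`"UGUAN"`) and
#'   `offset` (nt upstream of the PAS start).
#' @export
find_use <- function(seq, pas_start, config = motif_config()) {
  p_min <- pas_start - config$use_window[2]
  p_max <- pas_start - config$use_window[1]
  if (p_max < 1L) return(NULL)
  starts <- match_starts("TGTA", seq)
  starts <- starts[starts >= max(1L, p_min) & starts <= p_max &
                     starts + 4L <= nchar(seq)]
  if (length(starts) == 0) return(NULL)
  # fifth position is N-of-the-motif: any real base, never a genomic N
  starts <- starts[substring(seq, starts + 4L, starts + 4L) %in%
                     c("A", "C", "G", "T")]
  if (length(starts) == 0) return(NULL)
  list(motif = "UGUAN", offset = pas_start - max(starts))
}

#' Test for a GU-rich downstream sequence element
#'
#' Slides a `dse_subwindow`-nt window across the region
#' `dse_window[1]`-`dse_window[2]` nt downstream of the PAS end; the DSE
#' flag is set iff any fully contained window reaches a G+T fraction of
#' `dse_gt_fraction`.  Ambiguity bases count as non-G/T.
#'
#' @param seq Character sequence in transcript orientation.
#' @param pas_start 1-based start index of the PAS hexamer in `seq`.
#' @param config A [motif_config()].
#' @return A list with `gu_rich` (logical) and `truncated` (`TRUE` when
#'   the downstream region was clipped by the end of `seq`).
#' @export
find_dse <- function(seq, pas_start, config = motif_config()) {
  pas_end <- pas_start + 5L
  lo <- pas_end + config$dse_window[1]
  hi <- min(nchar(seq), pas_end + config$dse_window[2])
  truncated <- hi < pas_end + config$dse_window[2]
  w <- config$dse_subwindow
  if (hi - lo + 1L < w) {
    return(list(gu_rich = FALSE, truncated = TRUE))
  }
  region <- Biostrings::DNAString(substr(seq, lo, hi))
  gt <- Biostrings::letterFrequencyInSlidingView(region, w, "GT")
  list(gu_rich = any(gt / w >= config$dse_gt_fraction),
       truncated = truncated)
}

#' Annotate source loci with 3'-end processing motifs
#'
#' Produces one annotation row per source, in the shape of a donor-locus
#' motif table: PAS hexamer (RNA alphabet) with its offset upstream of the
#' cleavage site, USE presence, and the GU-rich DSE flag.  USE and DSE are
#' anchored to the PAS and reported as `"-"` when no PAS is found.
#'
#' @param genome A `DNAStringSet`, or a FASTA path.
#' @param sources A tibble of source loci with `chrom`, `start`, `end`
#'   (BED coordinates), `strand`, `subfamily`; an optional `source_type`
#'   column (`reference` / `nonreference`) defaults to `reference`.
#' @param config A [motif_config()].
#' @param flank Context length per side of the cleavage site (default
#'   200 nt).
#' @return A tibble with `locus` (1-based interval for reference sources,
#'   point for non-reference), `element`, `source_type`, `pas`,
#'   `pas_offset`, `use`, `dse` (`"GU-rich"`, `"No"`, or `"-"` when not
#'   scanned), `strand`, `truncated`.
#' @export
annotate_sources <- function(genome, sources, config = motif_config(),
                             flank = 200L) {
  if (is.character(genome)) genome <- read_genome_fasta(genome)
  if (flank < config$pas_window[2] + config$use_window[2] + 6L) {
    abort("flank too short for the configured scan windows")
  }
  out <- tibble(locus = character(), element = character(),
                source_type = character(), pas = character(),
                pas_offset = integer(), use = character(), dse = character(),
                strand = character(), truncated = logical())
  if (nrow(sources) == 0) return(out)
  src_type <- if ("source_type" %in% names(sources)) sources$source_type
              else rep("reference", nrow(sources))
  rows <- purrr::map(seq_len(nrow(sources)), function(i) {
    ctx <- extract_3prime_context(genome, sources$chrom[i], sources$start[i],
                                  sources$end[i], sources$strand[i], flank)
    pas <- find_pas(ctx$seq, ctx$cleavage_idx, config)
    if (is.null(pas)) {
      use_lab <- "-"; dse_lab <- "-"; pas_lab <- "-"; off <- NA_integer_
      trunc <- ctx$truncated
    } else {
      pas_lab <- pas$rna
      off <- pas$offset
      pas_start <- ctx$cleavage_idx - pas$offset
      use <- find_use(ctx$seq, pas_start, config)
      use_lab <- if (is.null(use)) "-" else use$motif
      dse <- find_dse(ctx$seq, pas_start, config)
      dse_lab <- if (dse$gu_rich) "GU-rich" else "No"
      trunc <- ctx$truncated || dse$truncated
    }
    locus <- if (src_type[i] == "nonreference") {
      paste0(sources$chrom[i], ":", sources$start[i] + 1L)
    } else {
      paste0(sources$chrom[i], ":", sources$start[i] + 1L, "-",
             sources$end[i])
    }
    tibble(locus = locus, element = sources$subfamily[i],
           source_type = src_type[i], pas = pas_lab, pas_offset = off,
           use = use_lab, dse = dse_lab, strand = sources$strand[i],
           truncated = trunc)
  })
  bind_rows(rows)
}
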
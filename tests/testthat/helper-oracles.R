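# Independent brute-force oracles and small fixture builders.  Oracles are
# deliberately written by a different route than the package code they
# check (direct log-factorial formula vs recurrence, plain loops vs
# interval trees / Biostrings).

# direct log-factorial enumeration of the exact HWE null
oracle_hwe <- function(n_hom_ref, n_het, n_hom_alt) {
  n <- n_hom_ref + n_het + n_hom_alt
  n_alt <- 2 * n_hom_alt + n_het
  minor <- min(n_alt, 2 * n - n_alt)
  if (minor == 0) return(list(p_two_sided = 1, p_excess_het = 1, total = 1))
  h <- seq(minor %% 2, minor, by = 2)
  hom_min <- (minor - h) / 2
  hom_maj <- n - h - hom_min
  logp <- h * log(2) + lgamma(n + 1) - lgamma(h + 1) - lgamma(hom_min + 1) -
    lgamma(hom_maj + 1) + lgamma(minor + 1) + lgamma(2 * n - minor + 1) -
    lgamma(2 * n + 1)
  p <- exp(logp)
  total <- sum(p)
  p <- p / total
  p_obs <- p[match(n_het, h)]
  list(p_two_sided = sum(p[p <= p_obs * (1 + 1e-10)]),
       p_excess_het = sum(p[h >= n_het]),
       total = total)
}

# O(n * m) loop over every call x segdup pair
oracle_overlap <- function(calls, segdups, mode = "point") {
  vapply(seq_len(nrow(calls)), function(i) {
    if (mode == "point") {
      lo <- calls$pos[i]; hi <- calls$pos[i]
    } else {
      lo <- calls$pos[i]; hi <- calls$pos[i] + max(calls$svlen[i], 1) - 1
    }
    any(segdups$chrom == calls$chrom[i] &
          segdups$start + 1 <= hi & segdups$end >= lo)
  }, logical(1))
}

# naive windowed substring search for the PAS scan
oracle_pas <- function(seq, cleavage_idx, hexamers = c("AATAAA", "ATTAAA"),
                       window = c(10, 40)) {
  best <- NULL
  for (off in window[1]:window[2]) {
    p <- cleavage_idx - off
    if (p < 1) next
    for (hx in hexamers) {
      if (substr(seq, p, p + 5) == hx) {
        if (is.null(best) || off < best$offset) {
          best <- list(hexamer = hx, offset = off)
        } else if (off == best$offset &&
                   match(hx, hexamers) < match(best$hexamer, hexamers)) {
          best <- list(hexamer = hx, offset = off)
        }
      }
    }
  }
  best
}

oracle_use <- function(seq, pas_start, window = c(40, 100)) {
  for (off in window[1]:window[2]) {
    p <- pas_start - off
    if (p < 1 || p + 4 > nchar(seq)) next
    if (substr(seq, p, p + 3) == "TGTA" &&
        substr(seq, p + 4, p + 4) %in% c("A", "C", "G", "T")) {
      # smallest offset wins: keep scanning downward is not needed because
      # we scan offsets in increasing order
      return(list(motif = "UGUAN", offset = off))
    }
  }
  NULL
}

# one-row calls-tibble builder with sensible defaults
make_call <- function(chrom = "chr1", pos = 1000L, variant_id = "v1",
                      me_type = "L1", subfamily = "L1HS", svlen = 6000L,
                      assess = 5L, sr = 6L, filter_flags = "PASS",
                      metrans = transdux:::METRANS_NULL,
                      src_chrom = NA_character_, src_start = NA_integer_,
                      src_end = NA_integer_, src_strand = NA_character_,
                      src_subfamily = NA_character_,
                      src_type = NA_character_, src_td_len = NA_integer_,
                      gt = c(S1 = 1L, S2 = 0L, S3 = 0L, S4 = 0L)) {
  tibble::tibble(
    chrom = chrom, pos = as.integer(pos), variant_id = variant_id,
    ref = "A", alt = sprintf("<INS:ME:%s>", me_type), me_type = me_type,
    subfamily = subfamily, svlen = as.integer(svlen),
    assess = as.integer(assess), sr = as.integer(sr),
    filter_flags = list(filter_flags), metrans = metrans,
    is_transduction = !is.na(metrans) & metrans != "null",
    info_other = list(setNames(character(0), character(0))),
    src_chrom = src_chrom, src_start = as.integer(src_start),
    src_end = as.integer(src_end), src_strand = src_strand,
    src_subfamily = src_subfamily, src_type = src_type,
    src_td_len = as.integer(src_td_len), gt = list(gt)
  )
}

# transduction-candidate row builder
make_candidate <- function(..., src_chrom = "chr2", src_start = 5000L,
                           src_end = 11019L, src_strand = "+",
                           src_subfamily = "L1HS", src_type = "reference",
                           src_td_len = 150L, svlen = 6169L,
                           metrans = "chr2|11020|11169|+") {
  make_call(..., src_chrom = src_chrom, src_start = src_start,
            src_end = src_end, src_strand = src_strand,
            src_subfamily = src_subfamily, src_type = src_type,
            src_td_len = src_td_len, svlen = svlen, metrans = metrans)
}

segdup_track <- function(chrom = "chr1", start = 50L, end = 150L) {
  tibble::tibble(chrom = chrom, start = as.integer(start),
                 end = as.integer(end), name = "SD", strand = ".",
                 me_type = "", subfamily = "", width = end - start)
}

small_sim <- function(seed = 11, ...) {
  simulate_cohort(sim_config(n_loci = c(L1 = 120L, SVA = 60L), seed = seed,
                             ...),
                  write = FALSE)
}
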
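# Progenitor-offspring mapping: group classified transduction offspring by
# their source locus, label links inter/intrachromosomal, and rank prolific
# ("master") source elements.
#
# Source identity is the exact coordinate key: chrom:start-end for
# reference sources, chrom:pos for non-reference insertions.  Chromosome
# names are compared verbatim -- alternate-haplotype contigs such as
# chr6_GL000253v2_alt are distinct chromosomes.

source_locus_key <- function(calls) {
  ifelse(calls$src_type == "nonreference",
         paste0(calls$src_chrom, ":", calls$src_start),
         paste0(calls$src_chrom, ":", calls$src_start, "-", calls$src_end))
}

#' Is each progenitor-offspring link inter- or intrachromosomal?
#'
#' @param source_chrom Chromosome of the source locus.
#' @param offspring_chrom Chromosome of the offspring insertion.
#' @return `"intra"` where the names are identical, `"inter"` otherwise.
#' @export
link_type <- function(source_chrom, offspring_chrom) {
  ifelse(source_chrom == offspring_chrom, "intra", "inter")
}

#' Build the progenitor-offspring map
#'
#' Groups transduction offspring by their source locus and summarises each
#' progenitor's productivity.
#'
#' @param classified A `td_classification` tibble (see
#'   [classify_transductions()]).
#' @param include `"HIGH"` (default) to map high-confidence offspring only,
#'   or `"HIGH+LOW"` to include low-confidence ones; `REMOVED_SEGDUP`
#'   records are never mapped.
#' @param merge_radius Merge reference source keys whose starts lie within
#'   this many bp on the same chromosome (default 0: exact-coordinate
#'   identity, no fuzzy merging).
#' @return A tibble with one row per distinct source locus:
#'   `source_locus`, `src_chrom`, `src_start`, `src_end`, `src_type`,
#'   `src_subfamily`, `me_type`, `n_offspring`, `n_inter`, `n_intra`, and
#'   an `offspring` list-column of per-offspring tibbles (`chrom`, `pos`,
#'   `link`) sorted by (chrom, pos).
#' @export
build_progenitor_map <- function(classified, include = c("HIGH", "HIGH+LOW"),
                                 merge_radius = 0L) {
  include <- match.arg(include)
  keep_labels <- if (include == "HIGH") "HIGH" else c("HIGH", "LOW")
  x <- as_tibble(classified) %>% filter(.data$label %in% keep_labels)
  if (nrow(x) == 0) {
    return(tibble(source_locus = character(), src_chrom = character(),
                  src_start = integer(), src_end = integer(),
                  src_type = character(), src_subfamily = character(),
                  me_type = character(), n_offspring = integer(),
                  n_inter = integer(), n_intra = integer(),
                  offspring = list()))
  }
  if (anyNA(x$src_chrom)) abort("a classified record lacks MESOURCE")
  if (merge_radius > 0) {
    x <- x %>%
      group_by(.data$src_chrom, .data$src_type) %>%
      arrange(.data$src_start, .by_group = TRUE) %>%
      mutate(.grp = cumsum(c(TRUE, diff(.data$src_start) > merge_radius))) %>%
      group_by(.data$src_chrom, .data$src_type, .data$.grp) %>%
      mutate(src_start = min(.data$src_start),
             src_end = max(.data$src_end)) %>%
      ungroup() %>%
      select(-".grp")
  }
  x$source_locus <- source_locus_key(x)
  x$link <- link_type(x$src_chrom, x$chrom)
  x %>%
    arrange(.data$chrom, .data$pos) %>%
    group_by(.data$source_locus, .data$src_chrom, .data$src_start,
             .data$src_end, .data$src_type, .data$src_subfamily,
             .data$me_type) %>%
    summarise(n_offspring = dplyr::n(),
              n_inter = sum(.data$link == "inter"),
              n_intra = sum(.data$link == "intra"),
              offspring = list(as_tibble(dplyr::pick("chrom", "pos",
                                                     "link"))),
              .groups = "drop") %>%
    arrange(.data$src_chrom, .data$src_start)
}

#' Rank progenitors by productivity
#'
#' @param summaries A progenitor map from [build_progenitor_map()].
#' @param top_k Optionally truncate to the `top_k` most prolific sources
#'   (after computing shares over all of them).
#' @return `summaries` sorted by descending `n_offspring` (ties by
#'   `src_chrom`, `src_start`) with `share` and `cum_share` columns: each
#'   source's fraction, and running fraction, of all mapped offspring.
#' @export
rank_sources <- function(summaries, top_k = NULL) {
  total <- sum(summaries$n_offspring)
  out <- summaries %>%
    arrange(desc(.data$n_offspring), .data$src_chrom, .data$src_start) %>%
    mutate(share = .data$n_offspring / total,
           cum_share = cumsum(.data$n_offspring) / total)
  if (!is.null(top_k)) out <- head(out, top_k)
  out
}
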
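# Two-tier validation of 3' transduction candidates.
#
# Candidates overlapping segmental duplications are removed outright (read
# mapping in these regions confounds the transduction signature).  The
# remainder are HIGH confidence iff all three checks hold, otherwise LOW
# with every failing check recorded:
#   * read support:      SR >= min_support_reads (default 5)
#   * length consistency: transduced length at the source is strictly
#     shorter than the offspring SVLEN (SVLEN = TE length + transduced
#     segment, so it must exceed the bare segment length)
#   * active family:     the source subfamily is a currently active human
#     L1/SVA subfamily (or undetermined, which the caller could not resolve
#     for non-reference sources)

#' Transduction classifier configuration
#'
#' @param min_support_reads Minimum split-read support for a HIGH call
#'   (default 5).
#' @param active_subfamilies Subfamilies considered retrotranspositionally
#'   active in the recent human genome; matched case-insensitively.
#' @param undetermined_is_active Treat `UNDETERMINED` source subfamilies as
#'   active (default `TRUE`; non-reference sources often lack a subfamily
#'   annotation).
#' @param segdup_mode `"point"` tests the insertion point against the
#'   segdup track; `"span"` tests the interval `[pos, pos + svlen)`.
#' @return A list of class `classifier_config`.
#' @export
classifier_config <- function(min_support_reads = 5L,
                              active_subfamilies = c("L1HS", "L1Ta", "L1ta1d",
                                                     "L1T1d", "SVA_D", "SVA_E",
                                                     "SVA_F"),
                              undetermined_is_active = TRUE,
                              segdup_mode = c("point", "span")) {
  stopifnot(min_support_reads >= 1, length(active_subfamilies) > 0)
  structure(list(min_support_reads = as.integer(min_support_reads),
                 active_subfamilies = active_subfamilies,
                 undetermined_is_active = isTRUE(undetermined_is_active),
                 segdup_mode = match.arg(segdup_mode)),
            class = "classifier_config")
}

#' Does each candidate overlap the segmental-duplication track?
#'
#' In `"point"` mode the 1-based insertion point must lie inside a segdup
#' interval (0-based half-open BED, so point `pos` hits `[start, end)` iff
#' `start < pos <= end`); in `"span"` mode the interval
#' `[pos, pos + svlen)` (1-based) must intersect one.
#'
#' @param calls A calls tibble.
#' @param segdups A segdup track tibble from [read_bed()]; may have zero
#'   rows.
#' @param mode `"point"` or `"span"`.
#' @return A logical vector along `calls`.
#' @export
overlaps_segdup <- function(calls, segdups, mode = c("point", "span")) {
  mode <- match.arg(mode)
  if (nrow(calls) == 0) return(logical(0))
  if (is.null(segdups) || nrow(segdups) == 0) return(rep(FALSE, nrow(calls)))
  if (mode == "point") {
    q_start <- calls$pos
    q_end <- calls$pos
  } else {
    q_start <- calls$pos
    q_end <- calls$pos + pmax(calls$svlen, 1L) - 1L
  }
  lv <- union(unique(calls$chrom), unique(segdups$chrom))
  query <- GenomicRanges::GRanges(factor(calls$chrom, lv),
                                  IRanges::IRanges(q_start, q_end))
  # BED 0-based half-open -> 1-based closed
  subj <- GenomicRanges::GRanges(factor(segdups$chrom, lv),
                                 IRanges::IRanges(segdups$start + 1L,
                                                  segdups$end))
  GenomicRanges::countOverlaps(query, subj) > 0
}

#' Is the source/offspring length relationship consistent?
#'
#' The offspring SVLEN reports the whole structural variant (TE plus
#' transduced segment) while the source records only the transduced segment,
#' so a genuine transduction must satisfy
#' `src_td_len < svlen` (strictly).
#'
#' @param calls A calls tibble of transduction candidates.
#' @return Logical vector; errors if `svlen` is missing.
#' @export
length_consistent <- function(calls) {
  if (anyNA(calls$svlen)) abort("SVLEN missing on a transduction candidate")
  if (anyNA(calls$src_td_len)) {
    abort("MESOURCE transduced length missing on a transduction candidate")
  }
  calls$src_td_len < calls$svlen
}

#' Does each candidate's source belong to an active subfamily?
#'
#' @param calls A calls tibble of transduction candidates (uses
#'   `src_subfamily`).
#' @param config A [classifier_config()].
#' @return Logical vector: `TRUE` iff the source subfamily is in the active
#'   set (case-insensitive) or is `UNDETERMINED` and
#'   `undetermined_is_active` is set.
#' @export
family_active <- function(calls, config = classifier_config()) {
  fam <- toupper(calls$src_subfamily)
  active <- fam %in% toupper(config$active_subfamilies)
  undet <- fam == SUBFAM_UNDETERMINED
  active | (undet & config$undetermined_is_active)
}

#' Classify transduction candidates into HIGH / LOW / REMOVED_SEGDUP
#'
#' Applies the two-tier validation to every transduction candidate
#' (`is_transduction` rows) of a calls tibble.  Candidates overlapping the
#' segmental-duplication track are labelled `REMOVED_SEGDUP`; the rest are
#' `HIGH` iff read support, length consistency and family activity all
#' hold, else `LOW` with every failing reason listed (in the order
#' `LOW_SUPPORT`, `LENGTH_INCONSISTENT`, `INACTIVE_FAMILY`).
#'
#' @param calls A calls tibble; non-candidate rows are rejected.
#' @param segdups Segdup track tibble (or `NULL` for no removal tier).
#' @param config A [classifier_config()].
#' @return The candidate rows with added `label` and `reasons`
#'   (list-column) columns, of class `td_classification`.  The per-type
#'   funnel is available via [td_funnel()] / [glance()].
#' @examples
#' sim <- simulate_cohort(sim_config(seed = 7), write = FALSE)
#' cls <- classify_transductions(dplyr::filter(sim$calls, is_transduction),
#'                               sim$segdups)
#' glance(cls)
#' @export
classify_transductions <- function(calls, segdups = NULL,
                                   config = classifier_config()) {
  if (!all(calls$is_transduction)) {
    abort("classify_transductions() expects transduction candidates only; subset on is_transduction first")
  }
  if (nrow(calls) == 0) {
    out <- mutate(calls, label = character(0), reasons = list())
    class(out) <- c("td_classification", class(out))
    return(out)
  }
  in_segdup <- overlaps_segdup(calls, segdups, config$segdup_mode)
  support_ok <- calls$sr >= config$min_support_reads
  length_ok <- length_consistent(calls)
  family_ok <- family_active(calls, config)

  reasons <- purrr::pmap(
    list(in_segdup, support_ok, length_ok, family_ok),
    function(sd, su, le, fa) {
      if (sd) return("SEGDUP_OVERLAP")
      c(if (!su) "LOW_SUPPORT", if (!le) "LENGTH_INCONSISTENT",
        if (!fa) "INACTIVE_FAMILY")
    })
  label <- ifelse(in_segdup, "REMOVED_SEGDUP",
                  ifelse(lengths(reasons) == 0, "HIGH", "LOW"))
  out <- mutate(calls, label = label, reasons = reasons)
  class(out) <- c("td_classification", class(out))
  out
}

#' Classification funnel counts per element type
#'
#' @param classified A `td_classification` tibble.
#' @return A tibble with one row per `me_type`: `n_total`,
#'   `n_removed_segdup`, `n_after_segdup`, `n_low`, `n_high`.  The counts
#'   always satisfy `n_total = n_removed_segdup + n_after_segdup` and
#'   `n_after_segdup = n_high + n_low`.
#' @export
td_funnel <- function(classified) {
  if (nrow(classified) == 0) {
    return(tibble(me_type = character(), n_total = integer(),
                  n_removed_segdup = integer(), n_after_segdup = integer(),
                  n_low = integer(), n_high = integer()))
  }
  classified %>%
    as_tibble() %>%
    group_by(.data$me_type) %>%
    summarise(n_total = dplyr::n(),
              n_removed_segdup = sum(.data$label == "REMOVED_SEGDUP"),
              n_low = sum(.data$label == "LOW"),
              n_high = sum(.data$label == "HIGH"),
              .groups = "drop") %>%
    mutate(n_after_segdup = .data$n_total - .data$n_removed_segdup) %>%
    select("me_type", "n_total", "n_removed_segdup", "n_after_segdup",
           "n_low", "n_high") %>%
    arrange(.data$me_type)
}

#' Source-subfamily breakdown of high-confidence transductions
#'
#' Groups HIGH-labelled candidates by source type and subfamily; the counts
#' sum to the funnel's high-confidence totals by construction.
#'
#' @param classified A `td_classification` tibble.
#' @return A tibble with `me_type`, `src_type`, `src_subfamily`, `n`.
#' @export
source_family_table <- function(classified) {
  classified %>%
    as_tibble() %>%
    filter(.data$label == "HIGH") %>%
    count(.data$me_type, .data$src_type, .data$src_subfamily, name = "n") %>%
    arrange(.data$me_type, .data$src_type, desc(.data$n))
}

#' @export
tidy.td_classification <- function(x, ...) {
  x %>%
    as_tibble() %>%
    select("variant_id", "chrom", "pos", "me_type", "sr", "svlen",
           "src_subfamily", "src_type", "src_td_len", "label", "reasons") %>%
    mutate(reasons = purrr::map_chr(.data$reasons, paste, collapse = ";"))
}

#' @export
glance.td_classification <- function(x, ...) {
  f <- td_funnel(x)
  tibble(n_total = sum(f$n_total),
         n_removed_segdup = sum(f$n_removed_segdup),
         n_after_segdup = sum(f$n_after_segdup),
         n_low = sum(f$n_low),
         n_high = sum(f$n_high),
         n_types = nrow(f))
}
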
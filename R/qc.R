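# Cohort-level QC of polymorphic MEI calls and full-length selection of
# candidate source elements.
#
# The QC rule is the net effect of three chained bcftools views collapsed
# into one conjunction: SR >= 3 AND ASSESS >= 3 AND (FILTER has PASS or rSD)
# AND (FILTER has none of ac0/hDP/lc).

#' QC thresholds for polymorphic MEI calls
#'
#' @param min_sr Minimum split-read count (default 3).
#' @param min_assess Minimum breakpoint-evidence score (default 3).
#' @param keep_filters FILTER flags at least one of which must be present
#'   (default `PASS`, `rSD`).
#' @param reject_filters FILTER flags none of which may be present
#'   (default `ac0`, `hDP`, `lc`).
#' @param min_source_length Named bp minima per element type used by
#'   [select_fulllength_sources()] (default `L1` 5900, `SVA` 1000).
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_sr = 3L, min_assess = 3L,
                          keep_filters = c("PASS", "rSD"),
                          reject_filters = c("ac0", "hDP", "lc"),
                          min_source_length = c(L1 = 5900L, SVA = 1000L)) {
  stopifnot(min_sr >= 0, min_assess >= 0)
  if (length(intersect(keep_filters, reject_filters)) > 0) {
    abort("keep_filters and reject_filters must be disjoint")
  }
  structure(list(min_sr = as.integer(min_sr),
                 min_assess = as.integer(min_assess),
                 keep_filters = keep_filters,
                 reject_filters = reject_filters,
                 min_source_length = min_source_length),
            class = "qc_thresholds")
}

qc_reason_vec <- function(calls, thresholds) {
  if (anyNA(calls$sr) || anyNA(calls$assess)) {
    abort("SR and ASSESS are required by the dialect and must not be missing")
  }
  has_keep <- purrr::map_lgl(calls$filter_flags,
                             ~ any(.x %in% thresholds$keep_filters))
  has_reject <- purrr::map_lgl(calls$filter_flags,
                               ~ any(.x %in% thresholds$reject_filters))
  # first failing clause, in the order the chained filter applies them
  reason <- ifelse(calls$sr < thresholds$min_sr, "SR_BELOW_MIN",
            ifelse(calls$assess < thresholds$min_assess, "ASSESS_BELOW_MIN",
            ifelse(!has_keep, "NO_KEEP_FILTER",
            ifelse(has_reject, "REJECT_FILTER", NA_character_))))
  reason
}

#' Does each call pass the MEI QC filter?
#'
#' @param calls A calls tibble (see [read_mei_vcf()]).
#' @param thresholds A [qc_thresholds()] object.
#' @return A logical vector, one element per call: `TRUE` iff
#'   `sr >= min_sr`, `assess >= min_assess`, at least one keep flag is
#'   present and no reject flag is present.
#' @export
passes_qc <- function(calls, thresholds = qc_thresholds()) {
  is.na(qc_reason_vec(calls, thresholds))
}

#' Partition a cohort into QC-kept and QC-dropped calls
#'
#' @inheritParams passes_qc
#' @return A list with `kept` (calls passing QC) and `dropped` (failing
#'   calls with a `qc_reason` column naming the first failing clause:
#'   `SR_BELOW_MIN`, `ASSESS_BELOW_MIN`, `NO_KEEP_FILTER`,
#'   `REJECT_FILTER`).
#' @export
qc_filter <- function(calls, thresholds = qc_thresholds()) {
  if (nrow(calls) == 0) {
    return(list(kept = calls, dropped = mutate(calls, qc_reason = character(0))))
  }
  reason <- qc_reason_vec(calls, thresholds)
  keep <- is.na(reason)
  list(kept = calls[keep, ],
       dropped = mutate(calls[!keep, ], qc_reason = reason[!keep]))
}

#' Keep only full-length candidate source elements
#'
#' 5'-truncated L1s and SVAs cannot drive transduction; the source track is
#' restricted to elements whose annotated span meets an absolute per-type
#' minimum (defaults 5900 bp for L1, 1000 bp for SVA).
#'
#' @param intervals An element track tibble from [read_bed()]; `me_type`
#'   must be populated.
#' @param thresholds A [qc_thresholds()] object supplying
#'   `min_source_length`.
#' @return The subset of `intervals` with `end - start >=
#'   min_source_length[me_type]`, input order preserved.
#' @export
select_fulllength_sources <- function(intervals, thresholds = qc_thresholds()) {
  if (nrow(intervals) == 0) return(intervals)
  unknown <- setdiff(unique(intervals$me_type),
                     names(thresholds$min_source_length))
  if (length(unknown) > 0) {
    abort(sprintf("no minimum source length configured for me_type '%s'",
                  unknown[1]))
  }
  minlen <- thresholds$min_source_length[intervals$me_type]
  intervals[(intervals$end - intervals$start) >= minlen, ]
}
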
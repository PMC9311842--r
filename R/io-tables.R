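# Plain-text track and table formats: BED element/segdup tracks, the sample
# panel, chrom.sizes, and the pipeline's TSV reports.  BED intervals are
# 0-based half-open; VCF positions elsewhere in the package are 1-based.

#' Read a BED element or segmental-duplication track
#'
#' Reads whitespace-delimited BED with at least three columns.  The optional
#' columns of the element-track dialect are `name` (the RepeatMasker repeat
#' name, also used as the subfamily), `strand`, and `me_type` (`L1`, `SVA`,
#' ...).  Missing optionals default to `"."` strand and empty
#' name/subfamily/me_type.
#'
#' @param path Path to the BED file.
#' @return A tibble with `chrom`, `start` (0-based inclusive), `end`
#'   (exclusive), `name`, `strand`, `me_type`, `subfamily` (= `name`) and
#'   `width` columns, one row per interval.
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines("chrX\t11707247\t11713279\tL1HS\t+\tL1", bed)
#' read_bed(bed)$width  # 6032
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  empty <- tibble(chrom = character(), start = integer(), end = integer(),
                  name = character(), strand = character(),
                  me_type = character(), subfamily = character(),
                  width = integer())
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(empty)
  parts <- stringr::str_split(trimws(lines), "\\s+")
  nf <- lengths(parts)
  if (any(nf < 3L)) {
    abort(sprintf("line %d: BED requires at least 3 columns", which(nf < 3L)[1]))
  }
  col <- function(k, default) {
    purrr::map_chr(parts, function(p) if (length(p) >= k) p[[k]] else default)
  }
  out <- tibble(
    chrom = col(1L, NA_character_),
    start = as.integer(col(2L, NA_character_)),
    end = as.integer(col(3L, NA_character_)),
    name = col(4L, ""),
    strand = col(5L, "."),
    me_type = col(6L, "")
  )
  bad <- is.na(out$start) | is.na(out$end) | out$start < 0L | out$start >= out$end
  if (any(bad)) {
    abort(sprintf("line %d: invalid BED interval (need 0 <= start < end)",
                  which(bad)[1]))
  }
  out$subfamily <- out$name
  out$width <- out$end - out$start
  out
}

#' Read the sample panel
#'
#' A four-column TSV with header `sample_id`, `population`,
#' `super_population`, `sex` mapping each sample to one of the 26 cohort
#' populations and its continental super-population (AFR, AMR, EUR, SAS,
#' EAS).
#'
#' @param path Path to the panel TSV.
#' @return A tibble with those four character columns.
#' @export
read_sample_panel <- function(path) {
  panel <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                           progress = FALSE)
  need <- c("sample_id", "population", "super_population", "sex")
  if (!all(need %in% names(panel))) {
    abort(sprintf("panel must have columns %s", paste(need, collapse = ", ")))
  }
  panel <- panel[, need]
  if (anyDuplicated(panel$sample_id)) {
    abort("duplicate sample_id in panel")
  }
  map <- distinct(panel, .data$population, .data$super_population)
  if (anyDuplicated(map$population)) {
    abort("a population maps to more than one super-population")
  }
  panel
}

#' Read a chrom.sizes table
#'
#' Two whitespace-separated columns, chromosome name and length in bp, no
#' header (the UCSC `chrom.sizes` convention).
#'
#' @param path Path to the file.
#' @return A tibble with `chrom` and `length` columns.
#' @export
read_chrom_sizes <- function(path) {
  cs <- utils::read.table(path, header = FALSE,
                          col.names = c("chrom", "length"),
                          colClasses = c("character", "numeric"))
  cs <- as_tibble(cs)
  if (any(cs$length <= 0)) abort("chromosome lengths must be positive")
  cs
}

REPORT_SCHEMAS <- list(
  funnel = c("me_type", "n_total", "n_removed_segdup", "n_after_segdup",
             "n_low", "n_high"),
  popstats = c("variant_id", "me_type", "group", "n_hom_ref", "n_het",
               "n_hom_alt", "n_missing", "ac", "an", "af"),
  progenitors = c("source_locus", "source_type", "subfamily", "me_type",
                  "n_offspring", "n_inter", "n_intra", "share", "cum_share"),
  motifs = c("locus", "element", "source_type", "pas", "pas_offset", "use",
             "dse")
)

#' Write a pipeline report TSV
#'
#' Writes `rows` as a tab-separated file with a deterministic column order
#' given by the named schema, a header line, and `.` for missing values.
#'
#' @param rows A tibble containing at least the schema's columns.
#' @param path Output path.
#' @param schema One of `"funnel"`, `"popstats"`, `"progenitors"`,
#'   `"motifs"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(rows, path, schema) {
  if (!schema %in% names(REPORT_SCHEMAS)) {
    abort(sprintf("unknown report schema '%s'", schema))
  }
  cols <- REPORT_SCHEMAS[[schema]]
  missing <- setdiff(cols, names(rows))
  if (length(missing) > 0) {
    abort(sprintf("rows lack schema column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  readr::write_tsv(rows[, cols, drop = FALSE], path, na = ".",
                   progress = FALSE)
  invisible(path)
}
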
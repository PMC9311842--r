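# MELT-like MEI VCF dialect.
#
# The dialect is a strict subset of VCF 4.2: biallelic symbolic insertion
# records (<INS:ME:L1>, <INS:ME:SVA>, <INS:ME:ALU>), unphased diploid GT as
# the only FORMAT field, and the INFO keys ASSESS, SR, SVLEN, SUBFAM and --
# for transduction candidates -- MESOURCE and METRANS.  The exact on-disk
# serialization MELT uses for MESOURCE/METRANS is not publicly documented;
# the pipe-delimited encoding below is this package's own stand-in dialect:
#
#   MESOURCE = chrom|start|end|strand|subfamily|source_type|transduced_length
#   METRANS  = chrom|start|end|strand   or the literal "null"
#
# start/end are 1-based inclusive; a non-reference source is encoded with
# start == end == insertion point.  A record is a transduction candidate iff
# METRANS is present and not "null".

MESOURCE_FIELDS <- c("src_chrom", "src_start", "src_end", "src_strand",
                     "src_subfamily", "src_type", "src_td_len")

KNOWN_INFO_KEYS <- c("ASSESS", "SR", "SVLEN", "SUBFAM", "MESOURCE", "METRANS")

VALID_GT <- c("0/0", "0/1", "1/0", "1/1")

parse_mesource <- function(x) {
  out <- tibble(src_chrom = NA_character_, src_start = NA_integer_,
                src_end = NA_integer_, src_strand = NA_character_,
                src_subfamily = NA_character_, src_type = NA_character_,
                src_td_len = NA_integer_)
  out <- out[rep(1L, length(x)), ]
  has <- !is.na(x)
  if (any(has)) {
    parts <- stringr::str_split(x[has], stringr::fixed("|"))
    bad <- lengths(parts) != 7L
    if (any(bad)) {
      abort(sprintf("malformed MESOURCE value '%s' (expected 7 '|'-fields)",
                    x[has][bad][1]))
    }
    m <- do.call(rbind, parts)
    out$src_chrom[has] <- m[, 1]
    out$src_start[has] <- as.integer(m[, 2])
    out$src_end[has] <- as.integer(m[, 3])
    out$src_strand[has] <- m[, 4]
    out$src_subfamily[has] <- m[, 5]
    out$src_type[has] <- m[, 6]
    out$src_td_len[has] <- as.integer(m[, 7])
  }
  out
}

encode_mesource <- function(calls) {
  ifelse(is.na(calls$src_chrom), NA_character_,
         paste(calls$src_chrom, calls$src_start, calls$src_end,
               calls$src_strand, calls$src_subfamily, calls$src_type,
               calls$src_td_len, sep = "|"))
}

gt_to_dosage <- function(gt_strings, samples, line_no) {
  miss <- is.na(gt_strings)
  bad <- !miss & !(gt_strings %in% VALID_GT)
  if (any(bad)) {
    abort(sprintf(
      "line %d: malformed or non-diploid genotype '%s' for sample '%s'",
      line_no, gt_strings[bad][1], samples[bad][1]))
  }
  out <- rep(NA_integer_, length(gt_strings))
  out[!miss] <- stringr::str_count(gt_strings[!miss], "1")
  names(out) <- samples
  out
}

#' Read a MELT-dialect MEI VCF into a calls tibble
#'
#' Parses a plain-text (optionally gzipped) VCF in the package's documented
#' MELT-like dialect into one row per insertion call.  Multi-valued FILTER
#' entries are split on `;` into the `filter_flags` list-column; per-sample
#' genotypes become named integer alternate-allele dosages (0, 1, 2, `NA`
#' for `./.`) in the `gt` list-column.  Records whose `METRANS` INFO field is
#' present and not the literal `"null"` are transduction candidates
#' (`is_transduction = TRUE`) and carry parsed source-locus columns
#' (`src_chrom`, `src_start`, `src_end`, `src_strand`, `src_subfamily`,
#' `src_type`, `src_td_len`).  INFO keys outside the dialect are preserved
#' verbatim in the `info_other` list-column.
#'
#' @param path Path to the VCF file.
#' @param panel Optional sample panel tibble (see [read_sample_panel()]);
#'   when supplied, the VCF sample set must match the panel exactly.
#' @return A tibble with one row per call: `chrom`, `pos` (1-based), `ref`,
#'   `alt`, `variant_id`, `me_type`, `subfamily`, `svlen`, `assess`, `sr`,
#'   `filter_flags`, `is_transduction`, the `src_*` columns, `metrans`,
#'   `info_other` and `gt`.
#' @examples
#' sim <- simulate_cohort(sim_config(n_loci = c(L1 = 20, SVA = 10), seed = 1),
#'                        dir = tempfile())
#' calls <- read_mei_vcf(sim$paths$vcf)
#' dplyr::count(calls, me_type, is_transduction)
#' @export
read_mei_vcf <- function(path, panel = NULL) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  n_rec <- nrow(fix)
  # data line i sits after the meta lines and the #CHROM header line
  line_of <- function(i) length(v@meta) + 1L + i

  if (n_rec == 0L) {
    return(empty_calls())
  }

  alt <- fix[, "ALT"]
  multi <- grepl(",", alt, fixed = TRUE)
  if (any(multi)) {
    abort(sprintf("line %d: multi-allelic ALT '%s' (dialect is biallelic)",
                  line_of(which(multi)[1]), alt[which(multi)[1]]))
  }
  me_type <- stringr::str_match(alt, "^<INS:ME:([A-Za-z0-9_]+)>$")[, 2]
  if (anyNA(me_type)) {
    i <- which(is.na(me_type))[1]
    abort(sprintf("line %d: ALT '%s' is not a symbolic MEI allele",
                  line_of(i), alt[i]))
  }

  filter_flags <- stringr::str_split(
    ifelse(is.na(fix[, "FILTER"]), ".", fix[, "FILTER"]), stringr::fixed(";"))

  info <- stringr::str_split(fix[, "INFO"], stringr::fixed(";"))
  info_kv <- purrr::map(info, function(fields) {
    eq <- stringr::str_locate(fields, stringr::fixed("="))[, 1]
    keys <- ifelse(is.na(eq), fields, substr(fields, 1L, eq - 1L))
    vals <- ifelse(is.na(eq), "", substr(fields, eq + 1L, nchar(fields)))
    setNames(vals, keys)
  })
  get_info <- function(key) {
    purrr::map_chr(info_kv, function(kv) {
      if (key %in% names(kv)) kv[[key]] else NA_character_
    })
  }
  info_other <- purrr::map(info_kv, function(kv) {
    kv[setdiff(names(kv), KNOWN_INFO_KEYS)]
  })

  assess <- suppressWarnings(as.integer(get_info("ASSESS")))
  sr <- suppressWarnings(as.integer(get_info("SR")))
  svlen <- suppressWarnings(as.integer(get_info("SVLEN")))
  subfam <- get_info("SUBFAM")
  metrans <- get_info("METRANS")
  src <- parse_mesource(get_info("MESOURCE"))

  # genotypes; vcfR renders "./." (and ".") as NA
  gt_mat <- v@gt
  samples <- colnames(gt_mat)[-1L]
  if (!is.null(panel)) {
    if (!setequal(samples, panel$sample_id)) {
      abort("VCF sample set does not match the supplied panel")
    }
  }
  gt <- lapply(seq_len(n_rec), function(i) {
    gt_to_dosage(unname(gt_mat[i, -1L]), samples, line_of(i))
  })

  calls <- tibble(
    chrom = fix[, "CHROM"],
    pos = as.integer(fix[, "POS"]),
    variant_id = fix[, "ID"],
    ref = fix[, "REF"],
    alt = alt,
    me_type = me_type,
    subfamily = ifelse(is.na(subfam), SUBFAM_UNDETERMINED, subfam),
    svlen = svlen,
    assess = assess,
    sr = sr,
    filter_flags = filter_flags,
    metrans = metrans,
    is_transduction = !is.na(metrans) & metrans != METRANS_NULL,
    info_other = info_other,
    gt = gt
  )
  dplyr::bind_cols(calls, src)[, names(empty_calls())]
}

empty_calls <- function() {
  tibble(
    chrom = character(), pos = integer(), variant_id = character(),
    ref = character(), alt = character(), me_type = character(),
    subfamily = character(), svlen = integer(), assess = integer(),
    sr = integer(), filter_flags = list(), metrans = character(),
    is_transduction = logical(), info_other = list(),
    src_chrom = character(), src_start = integer(), src_end = integer(),
    src_strand = character(), src_subfamily = character(),
    src_type = character(), src_td_len = integer(), gt = list()
  )
}

vcf_header_lines <- function(samples) {
  c("##fileformat=VCFv4.2",
    "##source=transdux",
    '##INFO=<ID=ASSESS,Number=1,Type=Integer,Description="Breakpoint evidence score">',
    '##INFO=<ID=SR,Number=1,Type=Integer,Description="Split reads at the insertion site">',
    '##INFO=<ID=SVLEN,Number=1,Type=Integer,Description="Structural variant length (TE plus transduced segment)">',
    '##INFO=<ID=SUBFAM,Number=1,Type=String,Description="Element subfamily or UNDETERMINED">',
    '##INFO=<ID=MESOURCE,Number=1,Type=String,Description="Source locus: chrom|start|end|strand|subfamily|source_type|transduced_length">',
    '##INFO=<ID=METRANS,Number=1,Type=String,Description="Transduced segment: chrom|start|end|strand, or null">',
    '##FILTER=<ID=rSD,Description="Breakpoint support imbalance beyond 2 SD">',
    '##FILTER=<ID=ac0,Description="Zero allele count">',
    '##FILTER=<ID=hDP,Description="Excessive depth">',
    '##FILTER=<ID=lc,Description="Low complexity region">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
}

dosage_to_gt <- function(d) {
  out <- c("0/0", "0/1", "1/1")[d + 1L]
  out[is.na(d)] <- "./."
  out
}

#' Write a calls tibble back to the MELT-dialect VCF
#'
#' Serializes a calls tibble (the shape produced by [read_mei_vcf()]) with a
#' canonical INFO key order (`ASSESS`, `SR`, `SVLEN`, `SUBFAM`, `MESOURCE`,
#' `METRANS`, then pass-through keys in stored order), so that
#' write / read / write round-trips are byte-identical.
#'
#' @param calls A calls tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mei_vcf <- function(calls, path) {
  samples <- if (nrow(calls) > 0) names(calls$gt[[1]]) else character()
  info <- character(nrow(calls))
  mesource <- encode_mesource(calls)
  for (i in seq_len(nrow(calls))) {
    fields <- c(
      paste0("ASSESS=", calls$assess[i]),
      paste0("SR=", calls$sr[i]),
      paste0("SVLEN=", calls$svlen[i]),
      paste0("SUBFAM=", calls$subfamily[i])
    )
    if (!is.na(mesource[i])) fields <- c(fields, paste0("MESOURCE=", mesource[i]))
    if (!is.na(calls$metrans[i])) fields <- c(fields, paste0("METRANS=", calls$metrans[i]))
    other <- calls$info_other[[i]]
    if (length(other) > 0) {
      fields <- c(fields, ifelse(other == "", names(other),
                                 paste0(names(other), "=", other)))
    }
    info[i] <- paste(fields, collapse = ";")
  }
  body <- paste(
    calls$chrom, calls$pos, calls$variant_id, calls$ref, calls$alt, ".",
    purrr::map_chr(calls$filter_flags, paste, collapse = ";"), info, "GT",
    sep = "\t")
  if (length(samples) > 0) {
    gts <- vapply(calls$gt, function(d) paste(dosage_to_gt(unname(d)),
                                              collapse = "\t"), character(1))
    body <- paste(body, gts, sep = "\t")
  }
  writeLines(c(vcf_header_lines(samples), body), path)
  invisible(path)
}
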
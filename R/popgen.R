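# Population-genetic summaries of a QC-passed MEI cohort: stratified allele
# counts and frequencies, singletons, super-population specificity,
# heterozygosity ratio, an exact Hardy-Weinberg test, genomic insertion
# density, and per-element transduction rates.
#
# Genotypes are alternate-allele dosages (0/1/2, NA = missing).  A missing
# genotype contributes 0 to both AC and AN, matching bcftools fill-tags.

dosage_matrix <- function(calls) {
  if (nrow(calls) == 0) return(matrix(integer(), nrow = 0, ncol = 0))
  m <- do.call(rbind, calls$gt)
  rownames(m) <- calls$variant_id
  m
}

group_sample_sets <- function(panel, groups) {
  sets <- list()
  for (g in groups) {
    if (g == "ALL") {
      sets[["ALL"]] <- panel$sample_id
    } else if (g == "super_population") {
      for (sp in sort(unique(panel$super_population))) {
        sets[[sp]] <- panel$sample_id[panel$super_population == sp]
      }
    } else if (g == "population") {
      for (p in sort(unique(panel$population))) {
        sets[[p]] <- panel$sample_id[panel$population == p]
      }
    } else if (g %in% panel$super_population) {
      sets[[g]] <- panel$sample_id[panel$super_population == g]
    } else if (g %in% panel$population) {
      sets[[g]] <- panel$sample_id[panel$population == g]
    } else {
      abort(sprintf("unknown group '%s'", g))
    }
  }
  sets
}

#' Stratified allele counts and frequencies
#'
#' Computes, per variant and per requested group of samples, the genotype
#' counts, alternate allele count `ac = 2 * n_hom_alt + n_het`, called
#' allele number `an = 2 * (non-missing genotypes)`, and `af = ac / an`
#' (0 when `an = 0`).
#'
#' @param calls A calls tibble.
#' @param panel A sample panel tibble; required unless `groups = "ALL"`, in
#'   which case all VCF samples are used.
#' @param groups Character vector; each entry is `"ALL"`, the keyword
#'   `"super_population"` or `"population"` (expanded to every code in the
#'   panel), or an individual population / super-population code.
#' @return A tibble with `variant_id`, `me_type`, `group`, `n_hom_ref`,
#'   `n_het`, `n_hom_alt`, `n_missing`, `ac`, `an`, `af`.
#' @export
allele_summary <- function(calls, panel = NULL, groups = "ALL") {
  empty <- tibble(variant_id = character(), me_type = character(),
                  group = character(), n_hom_ref = integer(),
                  n_het = integer(), n_hom_alt = integer(),
                  n_missing = integer(), ac = integer(), an = integer(),
                  af = double())
  if (nrow(calls) == 0) return(empty)
  m <- dosage_matrix(calls)
  if (is.null(panel)) {
    if (!identical(groups, "ALL")) {
      abort("a panel is required for groups other than ALL")
    }
    sets <- list(ALL = colnames(m))
  } else {
    sets <- group_sample_sets(panel, groups)
  }
  out <- purrr::imap(sets, function(samples, gname) {
    missing <- setdiff(samples, colnames(m))
    if (length(missing) > 0) {
      abort(sprintf("sample '%s' absent from the VCF", missing[1]))
    }
    sub <- m[, samples, drop = FALSE]
    n_het <- as.integer(rowSums(sub == 1L, na.rm = TRUE))
    n_hom_alt <- as.integer(rowSums(sub == 2L, na.rm = TRUE))
    n_hom_ref <- as.integer(rowSums(sub == 0L, na.rm = TRUE))
    n_missing <- as.integer(rowSums(is.na(sub)))
    ac <- 2L * n_hom_alt + n_het
    an <- 2L * (length(samples) - n_missing)
    tibble(variant_id = calls$variant_id, me_type = calls$me_type,
           group = gname, n_hom_ref = n_hom_ref, n_het = n_het,
           n_hom_alt = n_hom_alt, n_missing = n_missing, ac = ac, an = an,
           af = ifelse(an == 0L, 0, ac / an))
  })
  bind_rows(out)
}

#' Singleton status of each call
#'
#' A singleton carries exactly one alternate allele across the whole cohort
#' (one heterozygous carrier); a single homozygous carrier has `ac = 2` and
#' is not a singleton.
#'
#' @param calls A calls tibble.
#' @return Logical vector: global `ac == 1`.
#' @export
is_singleton <- function(calls) {
  allele_summary(calls)$ac == 1L
}

#' Super-populations in which each call is present
#'
#' @param calls A calls tibble.
#' @param panel A sample panel tibble.
#' @return A list-column-style list, one character vector of
#'   super-population codes with `ac > 0` per call (empty when the call is
#'   absent everywhere).  A call is super-population *specific* when the
#'   set has exactly one element.
#' @export
superpop_presence <- function(calls, panel) {
  s <- allele_summary(calls, panel, "super_population")
  s <- s[s$ac > 0L, ]
  present <- split(s$group, factor(s$variant_id, levels = calls$variant_id))
  lapply(present, sort)
}

#' Population-specificity summary
#'
#' Among calls present anywhere (`ac > 0`), the fraction confined to a
#' single group at the requested stratification level.
#'
#' @param calls A calls tibble.
#' @param panel A sample panel tibble.
#' @param level `"super_population"` or `"population"`.
#' @return A tibble per `me_type`: `n_present`, `n_specific`,
#'   `pct_specific` (percent).
#' @export
specificity_summary <- function(calls, panel,
                                level = c("super_population", "population")) {
  level <- match.arg(level)
  s <- allele_summary(calls, panel, level)
  s %>%
    group_by(.data$variant_id, .data$me_type) %>%
    summarise(n_groups = sum(.data$ac > 0L), .groups = "drop") %>%
    filter(.data$n_groups > 0L) %>%
    group_by(.data$me_type) %>%
    summarise(n_present = dplyr::n(),
              n_specific = sum(.data$n_groups == 1L),
              pct_specific = 100 * .data$n_specific / .data$n_present,
              .groups = "drop")
}

#' Heterozygous-to-homozygous ratio per element type
#'
#' The cohort-wide proportion of heterozygous genotype calls to alternate
#' homozygous calls, computed as a ratio of totals over all sites (a mean
#' of per-site ratios is undefined at sites with no homozygotes).  `Inf`
#' marks a zero denominator.
#'
#' @param calls A calls tibble (typically QC-passed).
#' @param mode `"totals"` (default) or `"mean_site"` (mean of per-site
#'   ratios over sites with at least one alternate homozygote).
#' @return A tibble per `me_type`: `n_het`, `n_hom_alt`, `ratio`.
#' @export
het_hom_ratio <- function(calls, mode = c("totals", "mean_site")) {
  mode <- match.arg(mode)
  s <- allele_summary(calls)
  if (mode == "totals") {
    s %>%
      group_by(me_type = .data$me_type) %>%
      summarise(n_het = sum(.data$n_het), n_hom_alt = sum(.data$n_hom_alt),
                .groups = "drop") %>%
      mutate(ratio = ifelse(.data$n_hom_alt == 0L, Inf,
                            .data$n_het / .data$n_hom_alt))
  } else {
    s %>%
      filter(.data$n_hom_alt > 0L) %>%
      group_by(me_type = .data$me_type) %>%
      summarise(n_het = sum(.data$n_het), n_hom_alt = sum(.data$n_hom_alt),
                ratio = mean(.data$n_het / .data$n_hom_alt),
                .groups = "drop")
  }
}

# Exact HWE: conditional distribution of the het count given the allele
# counts.  Admissible het counts share the parity of the minor allele
# count; probabilities are built from the ratio recurrence
#   P(h+2) / P(h) = 4 * hom_minor(h) * hom_major(h) / ((h+1) * (h+2))
# accumulated in log space and normalized by log-sum-exp, which is stable
# for cohort-scale genotype counts.
hwe_exact_one <- function(n_hom_ref, n_het, n_hom_alt) {
  n <- n_hom_ref + n_het + n_hom_alt
  if (n == 0L) abort("hwe_exact() requires at least one genotype")
  n_alt <- 2L * n_hom_alt + n_het
  minor <- min(n_alt, 2L * n - n_alt)
  if (minor == 0L) return(c(p_two_sided = 1, p_excess_het = 1))
  h_min <- minor %% 2L
  h <- seq.int(h_min, minor, by = 2L)
  hom_minor <- (minor - h) / 2
  hom_major <- n - h - hom_minor
  logp <- numeric(length(h))
  if (length(h) > 1L) {
    k <- h[-length(h)]
    ratio <- log(4) + log(hom_minor[-length(h)]) + log(hom_major[-length(h)]) -
      log(k + 1) - log(k + 2)
    logp <- c(0, cumsum(ratio))
  }
  logp <- logp - max(logp)
  probs <- exp(logp) / sum(exp(logp))
  obs <- match(n_het, h)
  if (is.na(obs)) {
    abort("observed het count is inconsistent with the allele counts")
  }
  p_obs <- probs[obs]
  c(p_two_sided = min(1, sum(probs[probs <= p_obs * (1 + 1e-10)])),
    p_excess_het = min(1, sum(probs[h >= n_het])))
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Exact conditional test of HWE genotype proportions given the observed
#' allele counts: the null distribution of the heterozygote count is
#' enumerated over every admissible value (same parity as the minor allele
#' count).  `p_two_sided` sums the probabilities of all configurations no
#' more probable than the observed one; `p_excess_het` is the one-sided
#' tail of configurations with at least as many heterozygotes (small values
#' flag excess heterozygosity, the typical genotyping-artifact signature).
#' Monomorphic sites return 1 for both.
#'
#' @param n_hom_ref,n_het,n_hom_alt Genotype counts (vectorized).
#' @return A tibble with the three counts and `p_two_sided`,
#'   `p_excess_het`.
#' @examples
#' hwe_exact(57, 33, 10)
#' @export
hwe_exact <- function(n_hom_ref, n_het, n_hom_alt) {
  stopifnot(length(n_het) == length(n_hom_ref),
            length(n_hom_alt) == length(n_hom_ref))
  if (any(n_hom_ref < 0 | n_het < 0 | n_hom_alt < 0)) {
    abort("genotype counts must be non-negative")
  }
  p <- purrr::pmap(list(n_hom_ref, n_het, n_hom_alt),
                   function(a, b, c) hwe_exact_one(a, b, c))
  tibble(n_hom_ref = as.integer(n_hom_ref), n_het = as.integer(n_het),
         n_hom_alt = as.integer(n_hom_alt),
         p_two_sided = purrr::map_dbl(p, 1),
         p_excess_het = purrr::map_dbl(p, 2))
}

#' Exact HWE screen of a cohort
#'
#' Runs [hwe_exact()] on every call's cohort-wide genotype counts.
#'
#' @param calls A calls tibble.
#' @return A tibble with `variant_id`, `me_type`, the genotype counts and
#'   both p-values.
#' @export
hwe_screen <- function(calls) {
  s <- allele_summary(calls)
  res <- hwe_exact(s$n_hom_ref, s$n_het, s$n_hom_alt)
  dplyr::bind_cols(s[, c("variant_id", "me_type")],
                   res[, c("n_hom_ref", "n_het", "n_hom_alt",
                           "p_two_sided", "p_excess_het")])
}

#' Insertions per megabase of chromosome
#'
#' @param calls A calls tibble.
#' @param chrom_sizes A chrom.sizes tibble (see [read_chrom_sizes()]);
#'   every call chromosome must be listed.  Chromosomes with no calls get
#'   density 0.
#' @return A tibble per chromosome: `n`, `length`, `density_per_mbp`.
#' @export
density_per_mbp <- function(calls, chrom_sizes) {
  missing <- setdiff(unique(calls$chrom), chrom_sizes$chrom)
  if (length(missing) > 0) {
    abort(sprintf("no chromosome length for '%s'", missing[1]))
  }
  counts <- count(as_tibble(calls), chrom = .data$chrom, name = "n")
  chrom_sizes %>%
    left_join(counts, by = "chrom") %>%
    mutate(n = ifelse(is.na(.data$n), 0L, .data$n),
           density_per_mbp = .data$n / (.data$length / 1e6))
}

#' Transductions produced per full-length element, as a percent
#'
#' @param n_high_conf Number of high-confidence transductions of a type.
#' @param n_fulllength_elements Number of full-length elements of that type
#'   screened as potential sources; must be positive.
#' @return `100 * n_high_conf / n_fulllength_elements`.
#' @examples
#' per_element_rate(268, 9847)  # ~2.72 for L1
#' per_element_rate(162, 4066)  # ~3.98 for SVA
#' @export
per_element_rate <- function(n_high_conf, n_fulllength_elements) {
  if (any(n_fulllength_elements <= 0)) {
    abort("n_fulllength_elements must be positive")
  }
  100 * n_high_conf / n_fulllength_elements
}

#' Allele-frequency spectrum
#'
#' Bins allele frequencies per group.  Sites with `an > 0` but `ac = 0`
#' fall in a dedicated `monomorphic` bin; polymorphic sites are binned
#' left-closed / right-open (the last bin is closed at 1).  Sites with
#' `an = 0` are excluded.
#'
#' @param summaries An [allele_summary()] tibble.
#' @param breaks Strictly increasing numeric vector from 0 to 1 defining a
#'   partition of (0, 1]; the default's first bin is the sub-1-percent
#'   rare-variant class.
#' @return A tibble with `group`, `bin`, `n`; per group, the `n` sum over
#'   bins equals the number of sites with `an > 0`.
#' @export
af_spectrum <- function(summaries,
                        breaks = c(0, 0.01, 0.05, 0.1, 0.25, 0.5, 1)) {
  if (is.unsorted(breaks, strictly = TRUE) || breaks[1] != 0 ||
      breaks[length(breaks)] != 1) {
    abort("breaks must increase strictly from 0 to 1")
  }
  labels <- paste0("[", utils::head(breaks, -1), ",", breaks[-1],
                   c(rep(")", length(breaks) - 2), "]"))
  s <- summaries[summaries$an > 0L, ]
  bin <- ifelse(s$ac == 0L, "monomorphic",
                as.character(cut(s$af, breaks, labels = labels,
                                 right = FALSE, include.lowest = FALSE)))
  bin[s$af == 1] <- labels[length(labels)]
  lv <- c("monomorphic", labels)
  tibble(group = s$group, bin = factor(bin, levels = lv)) %>%
    count(.data$group, .data$bin, .drop = FALSE, name = "n")
}
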
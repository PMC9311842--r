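---
title: "Classifying and characterising L1/SVA 3' DNA transductions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying and characterising L1/SVA 3' DNA transductions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(transdux)
library(dplyr)
```

## The problem

LINE-1 (L1) and SVA retroelements are the human-active non-LTR
retrotransposons. Because their 3' polyadenylation signal is weak, RNA
polymerase II sometimes reads through it and terminates at a downstream
signal instead; the retrotransposition machinery then copies the element
*plus* its 3' flanking sequence to a new locus. This is 3' DNA
transduction: the new insertion ("offspring") carries a unique tag of
genomic sequence that identifies its donor element ("progenitor").

Split-read MEI callers emit transduction candidates embedded in a VCF
dialect: each insertion call carries breakpoint evidence (`ASSESS`),
split-read support (`SR`), the structural-variant length (`SVLEN` = element
plus transduced segment), and — for candidates — a source-locus descriptor
(`MESOURCE`, whose length field records only the transduced segment) and a
transduced-segment descriptor (`METRANS`, the literal `null` for ordinary
insertions). `transdux` takes over *after* calling: cohort QC,
candidate validation, population genetics, progenitor mapping and donor
3'-end motif annotation.

## The procedure and its assumptions

### Cohort QC

A call is kept iff

* `SR >= 3` and `ASSESS >= 3`,
* its FILTER field contains `PASS` or `rSD` (the latter marks breakpoint
  support imbalanced beyond two standard deviations; keeping it raises
  transduction discovery sensitivity), and
* contains none of `ac0`, `hDP`, `lc`.

This is a single conjunction equivalent to three chained `bcftools view`
calls; a record carrying both `PASS` and a reject flag is dropped. Dropped
records are labelled with the *first* failing clause in that order, which
makes QC audits deterministic. Candidate *source* elements are restricted
to full-length copies — at least 5900 bp for L1 and 1000 bp for SVA —
because 5'-truncated elements cannot retrotranspose; the test uses the
annotated span, not a fraction of the consensus, since the thresholds are
absolute.

### Two-tier candidate validation

Candidates whose insertion point falls in a segmental duplication are
removed outright (`REMOVED_SEGDUP`): homology in these regions confounds
read mapping and progenitor inference. The default geometry tests the
1-based insertion point against the 0-based half-open BED track (point
`p` hits `[start, end)` iff `start < p <= end`); a `span` mode testing
`[pos, pos + svlen)` is available since the overlap geometry is a modelling
choice. Remaining candidates are `HIGH` confidence iff

1. `SR >= 5` supporting reads (`min_support_reads`; the read-support field
   of the dialect is `SR`),
2. the source's transduced length is *strictly* shorter than the offspring
   `SVLEN` ("shorter than" is strict, so equal lengths are `LOW`) — a real
   transduction's `SVLEN` exceeds the bare segment length by roughly one
   element length, and
3. the source subfamily is retrotranspositionally active
   (`L1HS`, `L1Ta`, `L1ta1d`, `L1T1d`, `SVA_D`, `SVA_E`, `SVA_F` by
   default, case-insensitive, fully configurable) or `UNDETERMINED`
   (callers often cannot resolve the subfamily of a non-reference source;
   treating it as inactive would discard every such donor).

`LOW` records list *every* failing clause, so a funnel audit can see why
each candidate fell. For any input the funnel satisfies
`n_total = n_removed_segdup + n_high + n_low` per element type, and
grouping `HIGH` records by source subfamily reproduces the
high-confidence totals.

### Population statistics

Allele summaries follow `bcftools fill-tags` semantics: a missing genotype
contributes 0 to both AC and AN; `af = ac/an` with 0 at `an = 0`.
Summaries stratify by population, super-population, or the whole cohort.
A singleton is `ac == 1` cohort-wide (a single homozygote, `ac = 2`, is
not). The heterozygous/homozygous ratio is a ratio of *totals* across
sites — a mean of per-site ratios is undefined wherever a site has no
alternate homozygote — with a `mean_site` variant for comparison and an
`Inf` marker at zero denominators.

The Hardy–Weinberg test is the exact conditional test: given the allele
counts, the heterozygote count ranges over values sharing the parity of
the minor-allele count, with probabilities computed by the ratio
recurrence accumulated in log space and normalised by log-sum-exp (stable
at cohort-scale counts). The two-sided p sums all configurations no more
probable than the observed one (standard exact-test convention; no mid-p
correction by default), and the excess-heterozygosity tail flags the
genotyping-artifact signature. Insertional density divides raw counts by
chromosome length in Mbp, including assembly N runs in the denominator —
published per-Mbp rates for chrY are quoted against the full assembly
length. Report percentages round half-even to two decimals.

### Progenitor mapping and motif annotation

Source identity is the exact coordinate key — `chrom:start-end` for
reference donors, `chrom:pos` for non-reference ones — with no fuzzy
merging by default (a configurable merge radius exists, default 0, since
no merge window is part of the method). Chromosome names are compared
verbatim: an alternate-haplotype contig is its own chromosome, so a link
from `chr6_GL000253v2_alt` to `chr6` is interchromosomal. Ranking sorts
by offspring count with positional tie-breaks and reports cumulative
shares of all mapped offspring.

Motif annotation approximates the polyadenylation cleavage site by the
annotated 3' terminus of the donor (for minus-strand donors the context is
reverse-complemented so "upstream" always points into the element). The
PAS hexamer (`AAUAAA`, then `AUUAAA`) is sought 10–40 nt upstream of the
cleavage site; the hit closest to the cleavage site wins, with hexamer
priority breaking exact ties. The USE (`UGUAN`) is sought 40–100 nt
upstream of the PAS start and the GU-rich DSE 40–100 nt downstream of the
PAS end — the windows anchor to the PAS start/end respectively, one of the
two readings of "upstream/downstream of the signal", chosen and stated
here once. "GU-rich" is not quantified in the motif literature we follow,
so it is operationalised as any 20-nt sliding window reaching 60% G+T,
both parameters exposed. All windows are inclusive; offsets are measured
from motif starts; a genomic `N` never matches any motif position and
counts as non-G/T. Without a PAS there is no anchor, so USE and DSE are
reported `-`.

## The synthetic cohort generator

`simulate_cohort()` emits every input the pipeline consumes, with planted
truth. Its defaults are the study conditions of a 26-population /
5-super-population, high-coverage human cohort, scaled to desk size:

* the panel reproduces the published per-population sample sizes at one
  tenth (320 samples);
* 400 L1 and 170 SVA polymorphic loci (roughly a twentieth of the
  published 7103/3040) on five synthetic chromosomes;
* planted allele frequencies follow Beta(0.3, 3) — a rare-skewed spectrum
  matching the observation that most polymorphic MEI loci are below 1%
  frequency — and genotypes are drawn i.i.d. per sample under exact HWE
  (the cohort is unrelated individuals), with an optional excess-het mode
  for calibration studies;
* QC-passing loci become transduction candidates with the published
  per-type fractions (505/7103 ≈ 0.071 for L1, 361/3040 ≈ 0.119 for SVA),
  and candidate outcomes use the published funnel proportions
  (HIGH/LOW/REMOVED = 268/198/39 of 505 for L1, 162/180/19 of 361 for
  SVA);
* transduced-segment lengths are log-uniform on 7–997 bp (the observed
  range; only min/median/max are published, so the distributional form is
  a choice — log-uniform reproduces the strong small-length skew);
* `SVLEN` is consensus length (6019 L1 / 1316 SVA) plus segment length
  with ±10 bp jitter, never large enough to flip the strict
  length-consistency inequality of a HIGH plant;
* every planted QC failure violates exactly one QC clause and every
  planted LOW exactly one classification clause, so recovered reasons are
  comparable string-for-string; REMOVED plants keep otherwise-HIGH fields
  and sit at segdup midpoints, so only the removal tier can explain their
  label.

The flank generator plants each of the eight PAS/USE/DSE presence
combinations (plus an `AUUAAA` carrier) at fixed in-window offsets on an
actively scrubbed background — unwanted in-window motifs are destroyed by
substituting a base absent from every motif, and the DSE region is diluted
below the G+T threshold — with decoy motifs planted just outside each
window.

What the generator does *not* model: read-level signal (SR/ASSESS are
drawn, not derived from alignments), linkage and relatedness, reference
biases, sequence evolution of element bodies, or segdup-mediated
mis-mapping. Passing closed-loop tests therefore demonstrates that the
*post-calling* logic is faithful to its stated rules, not that the
upstream caller's errors are survivable.

## Numerical choices and degenerate inputs

* Coordinates: VCF 1-based, BED 0-based half-open, converted in one
  place (the IO layer); the segdup point test is the standard conversion
  `start < pos <= end`.
* Monomorphic sites: HWE p-values are exactly 1; `af_spectrum()` puts
  `ac = 0, an > 0` sites in a dedicated `monomorphic` bin and excludes
  `an = 0` sites.
* Exact-test comparisons use a `1 + 1e-10` relative guard when summing
  configurations "no more probable than observed", avoiding
  floating-point ties.
* Empty inputs (empty VCF body, empty BED, zero candidates) return empty
  tibbles with stable schemas rather than errors; a missing segdup track
  degrades to a warning and removes the `REMOVED_SEGDUP` tier.
* All analysis stages are deterministic; randomness is confined to the
  generator and flows from one mandatory seed, so identical seeds give
  byte-identical bundles and reports.

## Problem sizes used in the test-suite

The shipped tests run the generator at 60–600 loci for unit checks, a
10,000-candidate cohort for the funnel-partition and label-recovery
property, 10,000 HWE-planted loci (500 samples, allele frequency 0.2) for
type-I calibration of the exact test, 400 loci at frequencies 0.05–0.5
for allele-frequency recovery, an exhaustive oracle sweep of every HWE
configuration with up to 50 genotypes, 1,000 random 1-kb sequences for
the motif-scan oracle, and 1,000 × 1,000 random call/segdup instances for
the overlap oracle. These sizes are the package's chosen balance between
statistical resolution and a test suite that runs in minutes.

## Worked example

```{r example}
sim <- simulate_cohort(sim_config(seed = 42), write = FALSE)
kept <- qc_filter(sim$calls)$kept
cls <- classify_transductions(filter(kept, is_transduction), sim$segdups)
td_funnel(cls)
rank_sources(build_progenitor_map(cls)) %>%
  select(source_locus, me_type, n_offspring, share) %>%
  head(3)
annotate_sources(sim$flanks, sim$flank_sources)[1:4, c("locus", "pas", "use", "dse")]
```

## Known limitations

* The on-disk `MESOURCE`/`METRANS` serialization of real callers is not
  publicly documented; the pipe-delimited dialect here is a stand-in and
  files from other tools need a one-line conversion.
* Only the offspring locus is screened against segmental duplications;
  whether donor loci should also be screened is left to the user (the
  track and the overlap primitive are exposed).
* Read-support for classification is taken from `SR` alone; callers that
  count discordant pairs separately will need the threshold adjusted.
* The cleavage site is approximated by the annotated element end;
  true cleavage heterogeneity (±10–30 nt) is not modelled, which is why
  the PAS window is generous.
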
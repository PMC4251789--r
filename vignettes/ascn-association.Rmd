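---
title: "Allele-specific copy-number association scanning: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Allele-specific copy-number association scanning: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ascnscan)
```

## The problem

Somatic copy-number alterations (CNAs) are candidate prognostic markers in
colon cancer: tumours that go on to disseminate (metastasis at diagnosis, or
distant recurrence within five years of surgery) may carry recurrent
deletions or amplifications that tumours with uneventful follow-up lack.
Testing this requires comparing alteration *frequencies* between a
disseminated and a non-disseminated group, segment by segment, across the
genome — and doing so on *absolute allele-specific* copy numbers, i.e. the
integer pair (total copies, minor-allele copies) per cancer cell, as
produced by purity/ploidy-resolving callers from SNP-array or sequencing
data. Working on absolute allele-specific states rather than log-ratios is
what makes it possible to distinguish an *absolute* loss (fewer than 2
copies) from a loss *relative* to a hyperploid genome's own average — a
distinction that matters because roughly 40% of chromosomally unstable
colon cancers have undergone whole-genome duplication (WGD), in which a
deletion leaves 2 of 4 copies and is invisible to absolute thresholds.

`ascnscan` implements this analysis end to end: parsing caller output,
building a cohort-wide segment grid, classifying alteration types, scoring
WGD, scanning for group-differential alterations, and the clinical
contingency tests — plus a seeded synthetic-cohort generator so that every
stage is testable without array data.

## Input contract

The input is the *output layer* of an allele-specific caller (e.g. a
TAPS/ASCAT-style segment table): per sample, ordered non-overlapping
autosomal segments with integer `total_cn` and `minor_cn`. File coordinates
are 1-based inclusive (SEG convention); arm definitions are 0-based
half-open BED; internally everything is 0-based half-open. The minor allele
is canonicalised to the lesser homolog, so `minor_cn <= total_cn -
minor_cn` always holds and states like "1m1" are corrected to "1m0" at
parse time. Sex chromosomes are rejected: ploidy, arm medians and burden
are defined over autosomes only. Gaps between segments are legitimate
(uncallable regions) and are treated as missing data, not as normal
diploid.

Purity, probe noise and segmentation error are *upstream* of this contract:
they are the caller's problem, and the package deliberately does not model
them.

## The breakpoint-union grid

All per-segment statistics are computed on intervals that contain no
breakpoint of any sample, obtained as the disjoint partition of the cohort's
covered territory at the union of all samples' segment boundaries
(`union_breakpoints()`, built on `GenomicRanges::disjoin`). Each sample then
has exactly one state — or a gap — on every interval, and the per-interval
2x2 tables are well defined. Two design points:

* Adjacent union intervals with identical state vectors are *not* re-merged.
  The grid is a pure function of the breakpoints, and every per-interval
  statistic is constant under such merging anyway.
* Missing states are excluded per interval from that interval's table, so
  the frequency denominator varies along the genome. This keeps frequencies
  unbiased under partial coverage, at the cost of slightly varying power
  from interval to interval.

The grid imposes no minimum interval size; the input segmentation's
resolution is inherited as-is.

## Alteration types

Nine flags are evaluated per (interval, sample), against the sample's own
length-weighted average ploidy $\bar{c}$:

| flag | rule |
|---|---|
| GAIN | total $> 2$ |
| LOSS | total $< 2$ |
| REL_GAIN | total $> 1.25\,\bar{c}$ |
| REL_LOSS | total $< 0.67\,\bar{c}$ |
| HOMDEL | total $= 0$ |
| HIGH_GAIN | total $> \bar{c} + 3$ |
| FOCAL_GAIN / FOCAL_LOSS | gain/loss and source segment $< 1$ Mb |
| LOH | minor $= 0$ |

All inequalities are strict, exactly as the thresholds are conventionally
printed; the relative and high-gain rules use the real-valued ploidy with
no rounding. LOH includes homozygous deletions (a region lost to 0 copies
has necessarily lost heterozygosity), so HOMDEL implies both LOSS and LOH.
Focality refers to the *sample's own* containing segment, not the (shorter)
union interval it is evaluated on. All thresholds live in one
`cna_thresholds()` object and can be changed coherently.

## Ploidy, arm states, and the WGD score

Average ploidy is the base-pair-length-weighted mean total copy number over
the covered autosomes; hyperploidy is an average above 2.5 copies.
Length-weighting (rather than per-segment averaging) makes the value
invariant under re-segmentation, which a property test enforces.

For each of the 44 autosome arms, the arm state is the pair of
length-weighted medians of total and minor copies over the arm's covered
bases, computed independently and taking the *lower* median on even-weight
ties (so an arm split exactly 50/50 between 4m2 and 2m1 is called 2m1 —
the conservative, non-duplicated reading). Medians are reported as achieved
integers since the inputs are integer states.

The WGD score counts arms whose median state is more parsimonious under a
genome doubling than under successive single events:

$$\mathrm{score} = \#\{\text{arms at } 2m0 \text{ or } 4m2\}
                 - \#\{\text{arms at } 2m1 \text{ or } 4m1\}$$

4m2 arises naturally from doubling both homologs; 2m0 from doubling after
(or before) loss of one homolog; while 2m1 is the undisturbed diploid state
and 4m1 is the signature of successive gains of one homolog. Arms in any
other state contribute 0 — only these four states carry unambiguous
evidence either way. The score ranges over ±(number of scored arms), and a
genome is called WGD when the score is positive: the score is a signed
evidence balance and 0 is its natural separatrix; no cut-off is estimated
from data, and the threshold is exposed for sensitivity analysis. Arms with
no coverage are skipped; a profile with no covered arm is an error.

## CIN and burden

A genome is classified as chromosomally unstable (CIN) when at least 5
distinct chromosomes carry an altered run of at least 10 Mb, where
"altered" means any state other than 2m1 and contiguous equal-state
segments are merged before the length test (so the call does not depend on
segmentation granularity). The same "altered = not 2m1" reading defines the
burden summaries (chromosomes affected, Mb altered). This is the broadest
defensible definition — it counts copy-neutral LOH as altered — and an
argument (`loh_as_altered = FALSE`) exposes the narrower total-copy-only
reading, since published burden figures rarely state which convention they
used.

## The association scan

For one alteration type, each union interval yields a 2x2 table: altered
vs unaltered against disseminated vs non-disseminated, among samples with a
call there. The p-value is the two-sided Fisher exact probability under the
point-probability convention (the sum of all tables at fixed margins whose
probability does not exceed the observed one — the convention of
`stats::fisher.test`, stated here because two-sided exact conventions
differ). P-values are reported unadjusted, matching the discovery-style use
with external validation; a Benjamini-Hochberg column is available as
plumbing (`adjust_p = TRUE`). Intervals where one outcome group has no
informative sample are flagged degenerate with p = 1 and an undefined odds
ratio.

Two odds-ratio estimators are provided:

* `cmle` (default): the conditional maximum-likelihood estimate under the
  noncentral hypergeometric model with the exact 95% interval, consistent
  with the Fisher framework and tolerant of zero cells (bounds may be 0 or
  infinite — intervals like "4.4 (0.3–262)" are expected at small counts).
* `sample`: the cross-product ratio ad/bc with the Haldane–Anscombe +0.5
  correction when any cell is zero and the Woolf logit interval, kept for
  transparency and for comparison with log-ratio-era literature.

Candidate regions are maximal runs of scan-adjacent intervals on one
chromosome that individually pass both the significance cut-off (p < 0.05)
and the effect-size cut-off (odds ratio >= 4); a region reports its peak
odds ratio, minimum p and segment count. Stratified analyses (stage subsets,
MSS only, chemotherapy-naive) are plain metadata filters applied before the
scan — no stratified test statistic is computed, mirroring how such
subset odds ratios are usually reported.

For the clinical cross-table, `contingency_test()` exposes Pearson's χ²
with and without the Yates continuity correction and Fisher's exact test,
two-sided or one-sided. The one-sided variant returns the smaller of the
two hypergeometric tail probabilities. Published cross-tables rarely state
which χ² variant or sidedness produced each printed p-value, so none of
these is hard-wired as "the" method; in the bundled validation the
uncorrected χ² reproduces six of the printed values, the Yates-corrected χ²
the MSI row, and the one-sided Fisher the sparse perineural row.

## The synthetic-cohort generator

`simulate_cohort()` emulates the statistical structure the analysis
assumes, not raw data. Two genome classes:

* **Quiet (MSI-like)**: near-diploid, Poisson(3) background events.
* **CNA-rich (MSS/CIN-like)**: Poisson(20) background events, and with
  probability 0.4 a whole-genome duplication applied as the first event
  (configurably after a number of pre-WGD events).

Background events are single-copy gains, single-copy losses, and
copy-neutral LOH — the minimal grammar that generates all the arm states
the WGD score reads — at whole-arm scale with probability 0.5, otherwise
at exponentially distributed sub-arm lengths (mean 30 Mb). One homolog is
chosen per event so the event is allele-consistent along its span. Default
group sizes (63 disseminated / 53 control, ~20% quiet) mirror a stage
II–IV case-control cohort; clinical covariates (stage, MSI status,
recurrence, follow-up, chemotherapy) are drawn consistently with the group
label. The calibration targets for the event rates are the published burden
medians of the two phenotypes (about 3 chromosomes / 87 Mb altered for MSI
tumours vs 17 chromosomes / 940 Mb for MSS) — the CNA-rich rate of 20 was
chosen so that the pooled CNA-rich class, *including* its WGD fraction
(whose genomes are altered throughout under the "not 2m1" definition),
lands near the printed medians. The acceptance script recomputes the
simulated medians so the achieved calibration is always visible.

A group-differential lesion can be planted on a configurable interval
(default: a 15-Mb distal-1p region, 13–28 Mb, the 1p36.11–21-like target)
with per-group Bernoulli frequencies (default 0.5 disseminated / 0.15
control, a sample odds ratio of 5.67). Two semantic choices matter:

* **The lesion is the loss of one *pre-duplication* copy.** In a genome
  that duplicated, the lesion removes both copies of one homolog
  (4m2 → 2m0): a relative loss and LOH but *not* an absolute loss. In a
  diploid genome it is 2m1 → 1m0: absolute and relative loss at once. This
  reproduces the dissociation that motivates scanning relative alterations:
  the same biological event is visible to a relative-loss scan in all
  genomes but to an absolute-loss scan only in near-diploid ones.
* **Configured frequencies are realised exactly.** Background events are
  masked (reset to the ploidy baseline) inside the planted interval before
  planting, so the observed alteration frequency at the interval *is* the
  configured group frequency. Published region frequencies are observed
  totals; without masking, background alterations stack on the planted ones
  and the realised odds ratio drifts below the configured regime.

Reproducibility: a cohort is a pure function of its configuration; each
sample's genome is drawn under a seed derived deterministically from the
cohort seed and the sample index.

What the generator does *not* emulate — and what passing tests therefore do
not show about real data: tumour purity and its estimation error, probe
noise and segmentation error, subclonal (non-integer) states, germline
CNVs/polymorphic deletions, interdependence of events (chromothripsis,
arm-level co-occurrence patterns), and any spatial non-uniformity of
breakpoints. Results on simulated cohorts validate the *pipeline's
statistics*, not the biology of any particular locus.

## Numerical and edge-case choices

* Lower weighted median on even-weight ties (deterministic, conservative
  toward the diploid state); a brute-force expanded-vector median is the
  test oracle.
* Fisher p-values are compared with a direct hypergeometric enumeration via
  `choose()` arithmetic in the tests, exhaustively for all tables with
  n ≤ 30.
* Degenerate scan tables (an empty outcome group) give p = 1 and flagged,
  undefined odds ratios rather than errors, so genome-wide scans never
  abort on a sparse interval.
* Zero-margin tables are undefined for the odds ratio (NA) and an error for
  χ².
* Overlapping segments within a sample are an error, never silently merged;
  an interval straddling a profile breakpoint during projection is an
  internal-consistency error (impossible when the grid was built from the
  same cohort).
* Empty profiles error on ploidy; profiles with no covered arm error on the
  WGD score.

## Validation problem sizes

The bundled validation studies (tests and `scripts/acceptance.R`) use:
exhaustive Fisher-oracle checks for all 2x2 tables with n ≤ 30; 200
randomised toy cohorts (≤ 10 kb genomes) against a per-base-pair grid
oracle; 20 null cohorts of 64 samples (~1,000 union segments each) for the
scan's type-I error; a 250-sample mixed-WGD cohort for duplication
recovery and score bimodality; 100 seeded replicates at the study-like
57/35 group sizes for planted-lesion recovery, odds-ratio regime and CI
coverage; and 10 replicates of 200-sample all-WGD cohorts for the
relative-vs-absolute dissociation. With Bernoulli planting at 0.5/0.15 and
n = 57/35, the probability that the planted interval's table passes both
candidate cut-offs (p < 0.05 and OR ≥ 4) is 0.75 by exact binomial
enumeration — sampling noise at these group sizes, not pipeline error, is
the ceiling on top-region recovery, which is why the recovery rate is
reported alongside the CI coverage rather than expected to approach 1.

## Known limitations

* The WGD score reads only four arm states; genomes with pervasive
  non-canonical states (e.g. triploid-range) score near 0 and the call is
  weakly informed.
* Fisher's exact test is conservative at small counts; the scan's realised
  type-I error is well below nominal, which costs power at segment level.
* Candidate-region merging is scan-adjacency-based; regions separated by a
  single noisy interval are reported as two.
* No multiple-testing control is applied by default (by design, matching
  discovery-plus-external-validation practice); the BH column is available.
* The pipeline analyses autosomes only.
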
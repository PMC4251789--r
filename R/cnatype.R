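# Per-sample genome summaries and per-segment alteration classification.

#' Alteration-type flags
#'
#' The nine segment-level alteration types: absolute gain (>2 copies per
#' cell) and loss (<2), gain and loss relative to the sample's own average
#' ploidy (>1.25x / <0.67x), homozygous deletion, high gain (more than 3
#' copies above the sample average), focal gain/loss (<1 Mb), and loss of
#' heterozygosity (no minor-allele copy with at least one copy retained).
#'
#' @export
ALTERATION_TYPES <- c("GAIN", "LOSS", "REL_GAIN", "REL_LOSS", "HOMDEL",
                      "HIGH_GAIN", "FOCAL_GAIN", "FOCAL_LOSS", "LOH")

#' Classification thresholds
#'
#' All copy-number classification cut-offs in one place. Defaults follow the
#' standard definitions for absolute allele-specific copy numbers: absolute
#' gain/loss against the normal two-copy state, relative gain/loss at 1.25x
#' and 0.67x the sample's average ploidy (strict inequalities), high gain at
#' more than 3 copies above the (real-valued) average ploidy, focal events
#' under 1 Mb, hyperploidy above an average copy number of 2.5, and
#' chromosomal instability as large alterations (>= 10 Mb) on at least 5
#' chromosomes.
#'
#' @param gain_above Copies; absolute gain is `total > gain_above`.
#' @param loss_below Copies; absolute loss is `total < loss_below`.
#' @param rel_gain_factor Relative gain is `total > rel_gain_factor * ploidy`.
#' @param rel_loss_factor Relative loss is `total < rel_loss_factor * ploidy`.
#' @param high_gain_above_ploidy High gain is
#'   `total > ploidy + high_gain_above_ploidy`.
#' @param focal_max_len Base pairs; focal events are strictly shorter.
#' @param hyperploid_above Average copies; hyperploid is
#'   `avg_ploidy > hyperploid_above`.
#' @param cin_min_cna_len Base pairs; minimum altered-run length counting
#'   towards chromosomal instability.
#' @param cin_min_chroms Minimum chromosomes carrying such a run.
#' @return A list of class `cna_thresholds`.
#' @export
cna_thresholds <- function(gain_above = 2, loss_below = 2,
                           rel_gain_factor = 1.25, rel_loss_factor = 0.67,
                           high_gain_above_ploidy = 3, focal_max_len = 1e6,
                           hyperploid_above = 2.5, cin_min_cna_len = 1e7,
                           cin_min_chroms = 5) {
  th <- list(gain_above = gain_above, loss_below = loss_below,
             rel_gain_factor = rel_gain_factor,
             rel_loss_factor = rel_loss_factor,
             high_gain_above_ploidy = high_gain_above_ploidy,
             focal_max_len = focal_max_len,
             hyperploid_above = hyperploid_above,
             cin_min_cna_len = cin_min_cna_len,
             cin_min_chroms = cin_min_chroms)
  if (any(unlist(th) <= 0)) stop("all thresholds must be positive")
  if (!(th$rel_loss_factor < 1 && 1 < th$rel_gain_factor))
    stop("rel_loss_factor < 1 < rel_gain_factor is required")
  structure(th, class = "cna_thresholds")
}

#' Average ploidy of a profile
#'
#' The base-pair-length-weighted mean total copy number over all covered
#' autosomal bases — the sample's "average copy number".
#'
#' @param profile A [sample_profile] with at least one segment.
#' @return Mean copies per cell (numeric scalar).
#' @export
average_ploidy <- function(profile) {
  seg <- profile$segments
  if (nrow(seg) == 0L) stop("cannot compute ploidy of an empty profile")
  len <- seg$end - seg$start
  sum(len * seg$total_cn) / sum(len)
}

#' Classify segments into alteration types
#'
#' Vectorised classification of allele-specific states against a sample's
#' average ploidy. A segment may carry several flags at once: a single-copy
#' deletion in a diploid genome is simultaneously an absolute loss, a
#' relative loss and LOH, whereas 3 copies in a near-tetraploid genome is an
#' absolute gain but no relative change — the distinction that motivates
#' scanning relative alterations separately in hyperploid genomes.
#'
#' @param total,minor Integer vectors of total and minor copy numbers.
#' @param len Segment lengths in base pairs (for the focal flags).
#' @param ploidy The sample's [average_ploidy()].
#' @param thresholds A [cna_thresholds()] object.
#' @return Logical matrix, one row per segment, columns [ALTERATION_TYPES].
#' @export
classify_calls <- function(total, minor, len, ploidy,
                           thresholds = cna_thresholds()) {
  th <- thresholds
  gain <- total > th$gain_above
  loss <- total < th$loss_below
  cbind(GAIN = gain,
        LOSS = loss,
        REL_GAIN = total > th$rel_gain_factor * ploidy,
        REL_LOSS = total < th$rel_loss_factor * ploidy,
        HOMDEL = total == 0L,
        HIGH_GAIN = total > ploidy + th$high_gain_above_ploidy,
        FOCAL_GAIN = gain & len < th$focal_max_len,
        FOCAL_LOSS = loss & len < th$focal_max_len,
        LOH = minor == 0L)
}

#' Classify one segment
#'
#' Convenience wrapper around [classify_calls()] for a single segment.
#'
#' @param seg One-row `data.frame` with `start`, `end`, `total_cn`,
#'   `minor_cn`.
#' @param ploidy The sample's average ploidy.
#' @param thresholds A [cna_thresholds()] object.
#' @return Character vector of flags carried by the segment.
#' @export
classify_segment <- function(seg, ploidy, thresholds = cna_thresholds()) {
  m <- classify_calls(seg$total_cn, seg$minor_cn, seg$end - seg$start,
                      ploidy, thresholds)
  colnames(m)[m[1L, ]]
}

#' Arm-median allele-specific states
#'
#' For each autosome arm, the base-pair-length-weighted median of total and
#' of minor copy number over the covered bases of the arm, each computed
#' independently and taking the lower median on even-weight ties. Arms with
#' no coverage get a missing state. These integer arm states
#' (diploid-heterozygous 2m1, copy-neutral LOH 2m0, balanced tetraploid 4m2,
#' unbalanced 4m1, ...) are the inputs of the duplication score.
#'
#' @param profile A [sample_profile].
#' @param arms Arm definitions, e.g. [hg19_arms()].
#' @return `data.frame` with one row per arm: `chrom`, `arm`, `median_total`,
#'   `median_minor` (`NA` where the arm is uncovered).
#' @export
arm_median_states <- function(profile, arms = hg19_arms()) {
  seg <- profile$segments
  res <- arms[c("chrom", "arm")]
  res$median_total <- NA_real_
  res$median_minor <- NA_real_
  for (i in seq_len(nrow(arms))) {
    s <- seg[seg$chrom == arms$chrom[i] & seg$end > arms$start[i] &
               seg$start < arms$end[i], , drop = FALSE]
    if (nrow(s) == 0L) next
    w <- pmin(s$end, arms$end[i]) - pmax(s$start, arms$start[i])
    res$median_total[i] <- weighted_median_low(s$total_cn, w)
    res$median_minor[i] <- weighted_median_low(s$minor_cn, w)
  }
  res
}

#' Whole-genome-duplication score
#'
#' Counts arm-median states that are more parsimoniously explained by a
#' genome doubling than by successive single events: an arm at 4m2 (two
#' copies of each homolog) or 2m0 (copy-neutral LOH) scores +1, an arm at
#' 2m1 (normal heterozygous diploid) or 4m1 scores -1, and any other state
#' scores 0. The score is the sum over scored autosome arms; its range is
#' plus/minus the number of arms. A positive score calls a duplication
#' event.
#'
#' @param arm_states Output of [arm_median_states()].
#' @return Integer score.
#' @export
wgd_score <- function(arm_states) {
  t <- arm_states$median_total
  m <- arm_states$median_minor
  ok <- !is.na(t) & !is.na(m)
  if (!any(ok)) stop("no arm has a non-missing median state")
  pos <- (t == 2 & m == 0) | (t == 4 & m == 2)
  neg <- (t == 2 & m == 1) | (t == 4 & m == 1)
  sum(pos[ok]) - sum(neg[ok])
}

# contiguous runs of equal-state segments merged per chromosome; returns
# merged segments (used by the CIN length rule)
merge_equal_adjacent <- function(seg) {
  if (nrow(seg) <= 1L) return(seg)
  new_run <- c(TRUE, !(seg$chrom[-1L] == seg$chrom[-nrow(seg)] &
                         seg$start[-1L] == seg$end[-nrow(seg)] &
                         seg$total_cn[-1L] == seg$total_cn[-nrow(seg)] &
                         seg$minor_cn[-1L] == seg$minor_cn[-nrow(seg)]))
  firsts <- which(new_run)
  lasts <- c(firsts[-1L] - 1L, nrow(seg))
  out <- seg[firsts, , drop = FALSE]
  out$end <- seg$end[lasts]
  rownames(out) <- NULL
  out
}

#' Chromosomal-instability classification
#'
#' A genome is called CIN when at least `cin_min_chroms` distinct
#' chromosomes carry an altered run (state different from the normal 2m1) of
#' at least `cin_min_cna_len` base pairs. Contiguous equal-state altered
#' segments are merged before the length test, so segmentation granularity
#' does not affect the call.
#'
#' @param profile A [sample_profile].
#' @param thresholds A [cna_thresholds()] object.
#' @return Logical flag.
#' @export
classify_cin <- function(profile, thresholds = cna_thresholds()) {
  seg <- merge_equal_adjacent(profile$segments)
  altered <- !(seg$total_cn == 2L & seg$minor_cn == 1L)
  large <- altered & (seg$end - seg$start) >= thresholds$cin_min_cna_len
  length(unique(seg$chrom[large])) >= thresholds$cin_min_chroms
}

#' Copy-number-alteration burden
#'
#' Counts a base as altered when its state differs from the normal
#' diploid-heterozygous 2m1 (so copy-neutral LOH counts; set
#' `loh_as_altered = FALSE` to count only total-copy deviations).
#'
#' @param profile A [sample_profile].
#' @param loh_as_altered Count 2m0-style copy-neutral LOH as altered
#'   (default `TRUE`).
#' @return List with `chromosomes_affected` (count of chromosomes carrying
#'   at least one altered base) and `mb_altered` (total altered length in
#'   Mb).
#' @export
cna_burden <- function(profile, loh_as_altered = TRUE) {
  seg <- profile$segments
  altered <- if (loh_as_altered)
    !(seg$total_cn == 2L & seg$minor_cn == 1L)
  else seg$total_cn != 2L
  list(chromosomes_affected = length(unique(seg$chrom[altered])),
       mb_altered = sum((seg$end - seg$start)[altered]) / 1e6)
}

#' Per-sample genome summary table
#'
#' Computes, for every profile in a cohort, the average ploidy and
#' hyperploidy flag, the whole-genome-duplication score and call, the
#' chromosomal-instability flag, and the alteration burden.
#'
#' @param profiles Named list of [sample_profile] objects.
#' @param arms Arm definitions, e.g. [hg19_arms()].
#' @param thresholds A [cna_thresholds()] object.
#' @return `data.frame` with one row per sample: `sample`, `avg_ploidy`,
#'   `hyperploid`, `wgd_score`, `wgd_call`, `cin`, `chromosomes_affected`,
#'   `mb_altered`.
#' @export
sample_summary <- function(profiles, arms = hg19_arms(),
                           thresholds = cna_thresholds()) {
  rows <- lapply(profiles, function(p) {
    pl <- average_ploidy(p)
    ws <- wgd_score(arm_median_states(p, arms))
    b <- cna_burden(p)
    data.frame(sample = p$sample_id, avg_ploidy = pl,
               hyperploid = pl > thresholds$hyperploid_above,
               wgd_score = ws, wgd_call = ws > 0,
               cin = classify_cin(p, thresholds),
               chromosomes_affected = b$chromosomes_affected,
               mb_altered = b$mb_altered)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
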
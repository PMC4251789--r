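# Cohort-wide breakpoint-union segment grid. All association statistics are
# computed on intervals that contain no breakpoint of any sample, so that
# every sample has a single well-defined allele-specific state (or a gap) on
# each interval.

profile_granges <- function(profile) {
  seg <- profile$segments
  GenomicRanges::GRanges(
    seqnames = as.character(seg$chrom),
    ranges = IRanges::IRanges(start = seg$start + 1, end = seg$end))
}

#' Breakpoint union of a cohort of profiles
#'
#' Partitions the base-pair union of all samples' covered territory into the
#' finest intervals whose boundaries are the union of every sample's segment
#' boundaries, so that no interval straddles a breakpoint of any sample.
#' Uncovered territory (covered by no sample) is absent from the result.
#'
#' @param profiles List of [sample_profile] objects (at least one).
#' @return `data.frame` with columns `chrom`, `start`, `end` (0-based
#'   half-open), sorted by genome position, pairwise disjoint.
#' @export
union_breakpoints <- function(profiles) {
  if (length(profiles) == 0L) stop("at least one profile is required")
  gr <- do.call(c, unname(lapply(profiles, profile_granges)))
  dj <- GenomicRanges::disjoin(gr)
  dj <- GenomicRanges::sort(dj)
  out <- data.frame(
    chrom = as.integer(as.character(GenomicRanges::seqnames(dj))),
    start = GenomicRanges::start(dj) - 1,
    end = as.numeric(GenomicRanges::end(dj)))
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Project one profile onto union intervals
#'
#' Looks up, for each union interval, the allele-specific state of the unique
#' profile segment containing it, or missing (`NA`) where the profile has a
#' gap. An interval that straddles a profile breakpoint indicates the
#' intervals were not built from a cohort containing this profile and is an
#' internal-consistency error.
#'
#' @param profile A [sample_profile].
#' @param intervals Intervals from [union_breakpoints()].
#' @return `data.frame` with columns `total_cn`, `minor_cn` and `seg_len`
#'   (the length of the containing source segment, used for focal-event
#'   classification), `NA` for gaps; one row per interval.
#' @export
project_profile <- function(profile, intervals) {
  # segments and intervals are sorted; encode (chrom, pos) on a single
  # axis and locate the containing segment with a binary search
  seg <- profile$segments
  n <- nrow(intervals)
  seg_s <- seg$chrom * 1e10 + seg$start
  seg_e <- seg$chrom * 1e10 + seg$end
  u_s <- intervals$chrom * 1e10 + intervals$start
  u_e <- intervals$chrom * 1e10 + intervals$end
  idx <- findInterval(u_s, seg_s)
  inside <- idx > 0L & u_e <= seg_e[pmax(idx, 1L)]
  straddle <- idx > 0L & !inside & u_s < seg_e[pmax(idx, 1L)]
  if (any(straddle))
    stop("interval straddles a breakpoint of sample ", profile$sample_id,
         "; intervals were not built from a cohort containing this profile")
  total <- rep(NA_integer_, n)
  minor <- rep(NA_integer_, n)
  seg_len <- rep(NA_real_, n)
  hit <- which(inside)
  sh <- idx[hit]
  total[hit] <- seg$total_cn[sh]
  minor[hit] <- seg$minor_cn[sh]
  seg_len[hit] <- seg$end[sh] - seg$start[sh]
  data.frame(total_cn = total, minor_cn = minor, seg_len = seg_len)
}

#' Build the cohort union grid
#'
#' Combines [union_breakpoints()] and [project_profile()] into a
#' `union_grid`: the union intervals plus two interval-by-sample integer
#' matrices of total and minor copy numbers (`NA` marking gaps).
#'
#' @param profiles Named list of [sample_profile] objects.
#' @return An object of class `union_grid` with elements `intervals`
#'   (`data.frame`), `samples` (character), and intervals-by-samples
#'   matrices `total`, `minor` and `seglen` (source-segment length).
#' @export
build_union_grid <- function(profiles) {
  intervals <- union_breakpoints(profiles)
  samples <- vapply(profiles, function(p) p$sample_id, character(1L))
  if (anyDuplicated(samples)) stop("duplicated sample ids in cohort")
  states <- lapply(profiles, project_profile, intervals = intervals)
  total <- do.call(cbind, lapply(states, `[[`, "total_cn"))
  minor <- do.call(cbind, lapply(states, `[[`, "minor_cn"))
  seglen <- do.call(cbind, lapply(states, `[[`, "seg_len"))
  colnames(total) <- colnames(minor) <- colnames(seglen) <- samples
  structure(list(intervals = intervals, samples = unname(samples),
                 total = total, minor = minor, seglen = seglen),
            class = "union_grid")
}

#' @export
print.union_grid <- function(x, ...) {
  cat(sprintf("<union_grid> %d intervals x %d samples (%.1f Mb covered)\n",
              nrow(x$intervals), length(x$samples),
              sum(x$intervals$end - x$intervals$start) / 1e6))
  invisible(x)
}

#' Export a union grid as a segments-by-samples text matrix
#'
#' Cells are `"total/minor"`, `"."` for missing; first three columns give the
#' interval coordinates (0-based half-open).
#'
#' @param grid A `union_grid`.
#' @param path Output path.
#' @export
write_grid <- function(grid, path) {
  cells <- matrix(sprintf("%d/%d", grid$total, grid$minor),
                  nrow = nrow(grid$total))
  cells[is.na(grid$total)] <- "."
  colnames(cells) <- grid$samples
  out <- cbind(format(grid$intervals, scientific = FALSE, trim = TRUE), cells)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
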
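# Seeded synthetic tumour-cohort generator. Emulates the output layer of
# absolute allele-specific copy-number callers: integer (total, minor)
# segment profiles for two genome classes — quiet near-diploid genomes (the
# MSI phenotype: few, mostly small alterations) and CNA-rich genomes (the
# MSS/CIN phenotype: many arm-scale events, a substantial fraction
# hyperploid through whole-genome duplication) — with an optional planted
# group-differential lesion for power and recovery studies. Purity, probe
# noise and segmentation error are deliberately absent: they are resolved
# upstream by the caller whose output this emulates.

#' Simulation configuration
#'
#' Defaults emulate the structure of a stage II-IV colon-cancer case-control
#' cohort: 63 disseminated vs 53 non-disseminated samples, roughly 20%
#' quiet near-diploid (MSI-like) genomes, whole-genome duplication in 40% of
#' the CNA-rich class, about 20 background events per CNA-rich genome and 3
#' per quiet genome, events at whole-arm scale half of the time and
#' exponentially distributed sub-arm lengths (mean 30 Mb) otherwise, and a
#' planted relative-loss lesion on a 15-Mb distal 1p region at frequency
#' 0.5 in disseminated vs 0.15 in control samples.
#'
#' @param genome Arm definitions ([hg19_arms()] or any toy arm set).
#' @param n_disseminated,n_control Group sizes.
#' @param quiet_fraction Proportion of quiet (MSI-like) samples per group.
#' @param wgd_prob Probability that a CNA-rich genome carries a
#'   whole-genome duplication.
#' @param background_event_rate Expected background events per CNA-rich
#'   genome (Poisson).
#' @param quiet_event_rate Expected background events per quiet genome.
#' @param whole_arm_prob Probability that an event spans a whole arm.
#' @param sub_arm_scale Mean sub-arm event length, base pairs.
#' @param event_type_probs Probabilities of the three background event
#'   types: single-copy gain, single-copy loss, copy-neutral LOH.
#' @param pre_wgd_events Number of background events applied before the
#'   doubling (default 0: the duplication is the first event).
#' @param lesion_chrom,lesion_start,lesion_end Planted-lesion interval
#'   (0-based half-open); `NULL` chrom disables the lesion.
#' @param lesion_freq_disseminated,lesion_freq_control Planting
#'   probabilities per group.
#' @param seed Integer seed; a fixed seed makes the cohort bit-identical.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(genome = hg19_arms(),
                              n_disseminated = 63, n_control = 53,
                              quiet_fraction = 0.2, wgd_prob = 0.4,
                              background_event_rate = 20,
                              quiet_event_rate = 3,
                              whole_arm_prob = 0.5, sub_arm_scale = 3e7,
                              event_type_probs = c(gain = 0.4, loss = 0.4,
                                                   cnloh = 0.2),
                              pre_wgd_events = 0,
                              lesion_chrom = 1, lesion_start = 13e6,
                              lesion_end = 28e6,
                              lesion_freq_disseminated = 0.5,
                              lesion_freq_control = 0.15,
                              seed = 1L) {
  cfg <- list(genome = validate_arms(genome),
              n_disseminated = n_disseminated, n_control = n_control,
              quiet_fraction = quiet_fraction, wgd_prob = wgd_prob,
              background_event_rate = background_event_rate,
              quiet_event_rate = quiet_event_rate,
              whole_arm_prob = whole_arm_prob, sub_arm_scale = sub_arm_scale,
              event_type_probs = event_type_probs,
              pre_wgd_events = pre_wgd_events,
              lesion_chrom = lesion_chrom, lesion_start = lesion_start,
              lesion_end = lesion_end,
              lesion_freq_disseminated = lesion_freq_disseminated,
              lesion_freq_control = lesion_freq_control,
              seed = as.integer(seed))
  probs <- c(cfg$quiet_fraction, cfg$wgd_prob, cfg$whole_arm_prob,
             cfg$lesion_freq_disseminated, cfg$lesion_freq_control)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (abs(sum(cfg$event_type_probs) - 1) > 1e-8)
    stop("event_type_probs must sum to 1")
  if (!is.null(cfg$lesion_chrom)) {
    g <- cfg$genome
    inside <- any(g$chrom == cfg$lesion_chrom &
                    g$start <= cfg$lesion_start & cfg$lesion_end <= g$end)
    if (!inside)
      stop("planted-lesion interval must lie within one arm of the genome")
  }
  structure(cfg, class = "simulation_config")
}

#' Read a simulation configuration from YAML
#'
#' Scalar fields override the [simulation_config()] defaults; `genome` may
#' be a path to an arm BED file.
#'
#' @param path Path to a YAML file.
#' @return A `simulation_config`.
#' @export
simulation_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$genome)) y$genome <- parse_arm_bed(y$genome)
  if (!is.null(y$event_type_probs)) y$event_type_probs <-
      unlist(y$event_type_probs)
  do.call(simulation_config, y)
}

# Segments are held as a numeric matrix (chrom, start, end, total, minor)
# during simulation; events split rows at their boundaries and transform the
# allele state inside [start, end) on chrom with a vectorised
# fn(total, minor) -> list(total, minor).
apply_event <- function(m, chrom, start, end, fn) {
  hit <- m[, 1L] == chrom & m[, 3L] > start & m[, 2L] < end
  if (!any(hit)) return(m)
  h <- m[hit, , drop = FALSE]
  left <- h[h[, 2L] < start, , drop = FALSE]
  if (nrow(left) > 0L) left[, 3L] <- pmin(left[, 3L], start)
  right <- h[h[, 3L] > end, , drop = FALSE]
  if (nrow(right) > 0L) right[, 2L] <- pmax(right[, 2L], end)
  mid <- h
  mid[, 2L] <- pmax(mid[, 2L], start)
  mid[, 3L] <- pmin(mid[, 3L], end)
  st <- fn(mid[, 4L], mid[, 5L])
  mid[, 4L] <- st$total
  mid[, 5L] <- st$minor
  out <- rbind(m[!hit, , drop = FALSE], left, mid, right)
  out[order(out[, 1L], out[, 2L]), , drop = FALSE]
}

# background event transforms on allele pairs (total, minor); one homolog
# is picked per event (hit_minor) so the whole event interval is consistent
ev_gain <- function(hit_minor) {
  function(total, minor) {
    t2 <- total + 1
    list(total = t2,
         minor = ifelse(hit_minor & total > 0,
                        canonical_minor(t2, minor + 1), minor))
  }
}

ev_loss <- function(hit_minor) {
  function(total, minor) {
    t2 <- pmax(0, total - 1)
    m2 <- ifelse(hit_minor & minor > 0, minor - 1, minor)
    list(total = t2, minor = canonical_minor(t2, pmin(m2, t2)))
  }
}

ev_cnloh <- function(total, minor) {
  # minor allele replaced by copies of the major: total preserved, minor 0
  list(total = total, minor = 0)
}

# lesion: loss of one pre-duplication copy, i.e. one homolog equivalent --
# post-WGD genomes lose 2 copies (4m2 -> 2m0, relative loss without
# absolute loss), non-WGD genomes lose 1 (2m1 -> 1m0, both)
ev_lesion <- function(wgd) {
  delta <- if (wgd) 2 else 1
  function(total, minor) {
    t2 <- pmax(0, total - delta)
    list(total = t2, minor = canonical_minor(t2, pmin(minor, t2)))
  }
}

draw_event_interval <- function(config) {
  g <- config$genome
  arm <- g[sample.int(nrow(g), 1L), ]
  if (stats::runif(1) < config$whole_arm_prob)
    return(list(chrom = arm$chrom, start = arm$start, end = arm$end))
  len <- min(round(max(1e5, stats::rexp(1, 1 / config$sub_arm_scale))),
             arm$end - arm$start)
  start <- arm$start + floor(stats::runif(1) * (arm$end - arm$start - len + 1))
  list(chrom = arm$chrom, start = start, end = start + len)
}

#' Simulate one tumour genome
#'
#' Starts from a fully diploid-heterozygous (2m1) genome covering the arm
#' set (the centromere gap is uncovered, as in real calls), optionally
#' applies a whole-genome duplication, overlays Poisson-count background
#' events (single-copy gain, single-copy loss, copy-neutral LOH) at
#' whole-arm or sub-arm scale, and optionally plants the configured lesion
#' (loss of one pre-duplication copy over the lesion interval).
#'
#' @param config A [simulation_config()].
#' @param sample_id Sample identifier.
#' @param quiet Simulate a quiet near-diploid genome (no duplication, low
#'   event rate)?
#' @param wgd Apply a whole-genome duplication?
#' @param lesion Plant the configured lesion?
#' @return A [sample_profile].
#' @export
simulate_profile <- function(config, sample_id, quiet = FALSE, wgd = FALSE,
                             lesion = FALSE) {
  g <- config$genome
  seg <- cbind(g$chrom, g$start, g$end, 2, 1)
  rate <- if (quiet) config$quiet_event_rate else config$background_event_rate
  n_events <- stats::rpois(1L, rate)
  n_pre <- if (wgd) min(config$pre_wgd_events, n_events) else 0L
  do_events <- function(seg, k) {
    for (i in seq_len(k)) {
      iv <- draw_event_interval(config)
      hit_minor <- stats::runif(1) < 0.5
      fn <- switch(sample(names(config$event_type_probs), 1L,
                          prob = config$event_type_probs),
                   gain = ev_gain(hit_minor), loss = ev_loss(hit_minor),
                   cnloh = ev_cnloh)
      seg <- apply_event(seg, iv$chrom, iv$start, iv$end, fn)
    }
    seg
  }
  seg <- do_events(seg, n_pre)
  if (wgd) seg <- wgd_all(seg)
  seg <- do_events(seg, n_events - n_pre)
  if (!is.null(config$lesion_chrom)) {
    # the planted interval realises the configured group frequency exactly:
    # background events are masked there (reset to the ploidy baseline), so
    # the observed alteration frequency at the interval is the planted one
    baseline <- function(total, minor)
      list(total = if (wgd) 4 else 2, minor = if (wgd) 2 else 1)
    seg <- apply_event(seg, config$lesion_chrom, config$lesion_start,
                       config$lesion_end, baseline)
    if (lesion)
      seg <- apply_event(seg, config$lesion_chrom, config$lesion_start,
                         config$lesion_end, ev_lesion(wgd))
  }
  df <- data.frame(chrom = seg[, 1L], start = seg[, 2L], end = seg[, 3L],
                   total_cn = seg[, 4L], minor_cn = seg[, 5L])
  sample_profile(sample_id, merge_equal_adjacent(df))
}

wgd_all <- function(seg) {
  seg[, 4L] <- 2 * seg[, 4L]
  seg[, 5L] <- 2 * seg[, 5L]
  seg
}

#' Simulate a two-group cohort
#'
#' Draws `n_disseminated + n_control` genomes with per-group class
#' assignment (quiet vs CNA-rich), duplication status and lesion planting,
#' plus matching clinical metadata (stage, MSI status, recurrence and
#' follow-up consistent with the group label, adjuvant chemotherapy) and a
#' truth table recording what was planted. Reproducible: the cohort is a
#' pure function of the configuration, with per-sample substream seeds
#' derived from the cohort seed and the sample index.
#'
#' @param config A [simulation_config()].
#' @return List with `profiles` (named list of [sample_profile]), `metadata`
#'   (as from [read_metadata()]), `truth` (`data.frame`: `sample`, `group`,
#'   `quiet`, `wgd`, `lesion`).
#' @export
simulate_cohort <- function(config) {
  n <- config$n_disseminated + config$n_control
  group <- rep(c("disseminated", "control"),
               c(config$n_disseminated, config$n_control))
  ids <- sprintf("S%03d", seq_len(n))
  set.seed(config$seed)
  quiet <- stats::runif(n) < config$quiet_fraction
  wgd <- !quiet & stats::runif(n) < config$wgd_prob
  lesion_freq <- ifelse(group == "disseminated",
                        config$lesion_freq_disseminated,
                        config$lesion_freq_control)
  lesion <- stats::runif(n) < lesion_freq
  meta <- simulate_metadata(ids, group, quiet, config$seed)
  profiles <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed((config$seed * 1009L + i * 7L) %% .Machine$integer.max)
    profiles[[i]] <- simulate_profile(config, ids[i], quiet = quiet[i],
                                      wgd = wgd[i], lesion = lesion[i])
  }
  names(profiles) <- ids
  list(profiles = profiles, metadata = meta,
       truth = data.frame(sample = ids, group = group, quiet = quiet,
                          wgd = wgd, lesion = lesion))
}

# clinical covariates consistent with the group label: disseminated samples
# are stage IV at diagnosis or stage II-III with distant recurrence within
# 5 years; controls are stage II-III with > 5 years of uneventful follow-up
simulate_metadata <- function(ids, group, quiet, seed) {
  set.seed(seed + 104729L)
  n <- length(ids)
  diss <- group == "disseminated"
  stage <- character(n)
  stage[diss] <- sample(c("IV", "II", "III"), sum(diss), replace = TRUE,
                        prob = c(0.37, 0.24, 0.39))
  stage[!diss] <- sample(c("II", "III"), sum(!diss), replace = TRUE,
                         prob = c(0.47, 0.53))
  recur <- diss & stage != "IV"
  followup <- ifelse(recur, stats::runif(n, 0.5, 5), stats::runif(n, 6, 12))
  followup[diss & stage == "IV"] <- stats::runif(sum(diss & stage == "IV"),
                                                 0.2, 5)
  chemo <- stats::runif(n) < ifelse(diss, 0.7, 0.4)
  data.frame(sample = ids, stage = stage,
             msi = ifelse(quiet, "MSI-H", "MSS"),
             distant_recurrence = recur, followup_years = round(followup, 2),
             adjuvant_chemo = chemo)
}

#' Write a simulated cohort to disk
#'
#' Writes the SEG-dialect segment table, the metadata table and the truth
#' table into a directory.
#'
#' @param sim Output of [simulate_cohort()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the three file paths.
#' @export
write_simulated_cohort <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(segments = file.path(dir, "segments.seg"),
             metadata = file.path(dir, "metadata.tsv"),
             truth = file.path(dir, "truth.tsv"))
  write_segment_file(sim$profiles, paths[["segments"]])
  utils::write.table(sim$metadata, paths[["metadata"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth, paths[["truth"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}
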
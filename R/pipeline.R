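# End-to-end driver: parse -> label -> stratify -> grid -> summaries ->
# scans -> tracks -> candidate regions, with a run log for reproducibility.

#' Pipeline run configuration
#'
#' @param segments Path to the SEG-like segment table.
#' @param metadata Path to the clinical metadata table.
#' @param arms Path to an arm BED file, or `NULL` for the bundled hg19 arms.
#' @param out_dir Output directory.
#' @param alterations Alteration types to scan (subset of
#'   [ALTERATION_TYPES]).
#' @param stages Stage stratum to keep (subset of II/III/IV).
#' @param msi MSI stratum to keep (subset of `"MSI-H"`, `"MSS"`).
#' @param chemo_naive_only Keep only samples without adjuvant chemotherapy.
#' @param thresholds A [cna_thresholds()] object.
#' @param p_max,or_min Candidate-region cut-offs.
#' @param or_method Odds-ratio method, see [odds_ratio_ci()].
#' @param seed Integer seed recorded in the run log (the analysis itself is
#'   deterministic).
#' @return A list of class `run_config`.
#' @export
run_config <- function(segments, metadata, arms = NULL, out_dir,
                       alterations = c("LOSS", "REL_LOSS", "GAIN",
                                       "REL_GAIN", "LOH"),
                       stages = c("II", "III", "IV"),
                       msi = c("MSI-H", "MSS"), chemo_naive_only = FALSE,
                       thresholds = cna_thresholds(), p_max = 0.05,
                       or_min = 4, or_method = "cmle", seed = 1L) {
  for (f in c(segments, metadata, arms))
    if (!file.exists(f)) stop("input file does not exist: ", f)
  alterations <- match.arg(alterations, ALTERATION_TYPES, several.ok = TRUE)
  structure(list(segments = segments, metadata = metadata, arms = arms,
                 out_dir = out_dir, alterations = alterations,
                 stages = stages, msi = msi,
                 chemo_naive_only = chemo_naive_only,
                 thresholds = thresholds, p_max = p_max, or_min = or_min,
                 or_method = or_method, seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full association pipeline
#'
#' Parses segments and metadata, applies the configured strata filters,
#' labels dissemination, builds the breakpoint-union grid, and writes to the
#' output directory: the per-sample summary table
#' (`sample_summary.tsv`), one association table and one
#' frequency-difference bedGraph per alteration type
#' (`assoc_<TYPE>.tsv`, `freqdiff_<TYPE>.bedgraph`), candidate regions
#' (`candidate_regions.bed`), and a run log (`run_log.txt`) with package
#' version, configuration hash and seed. Identical configuration and inputs
#' produce byte-identical outputs.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the in-memory results (`summary`, `scans`,
#'   `regions`, `labels`, `grid`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  arms <- if (is.null(config$arms)) hg19_arms() else
    parse_arm_bed(config$arms)
  profiles <- parse_segment_file(config$segments)
  meta <- read_metadata(config$metadata)
  orphans <- c(setdiff(names(profiles), meta$sample),
               setdiff(meta$sample, names(profiles)))
  if (length(orphans) > 0L)
    stop("sample ids present in only one of segments/metadata: ",
         paste(sort(unique(orphans)), collapse = ", "))
  keep <- meta$stage %in% config$stages & meta$msi %in% config$msi
  if (config$chemo_naive_only) keep <- keep & !meta$adjuvant_chemo
  if (!any(keep))
    stop("no samples left after strata filter (stages ",
         paste(config$stages, collapse = "/"), ", msi ",
         paste(config$msi, collapse = "/"),
         if (config$chemo_naive_only) ", chemotherapy-naive" else "", ")")
  meta <- meta[keep, , drop = FALSE]
  profiles <- profiles[meta$sample]
  labels <- stats::setNames(label_dissemination(meta), meta$sample)

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  summ <- sample_summary(profiles, arms, config$thresholds)
  utils::write.table(summ, file.path(config$out_dir, "sample_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  grid <- build_union_grid(profiles)
  ploidies <- stats::setNames(vapply(profiles, average_ploidy, numeric(1L)),
                              names(profiles))
  scans <- list()
  regions <- list()
  for (type in config$alterations) {
    rec <- fisher_scan(grid, labels, type, thresholds = config$thresholds,
                       ploidies = ploidies, or_method = config$or_method)
    scans[[type]] <- rec
    write_association_table(
      rec, file.path(config$out_dir, paste0("assoc_", type, ".tsv")))
    write_tracks(rec, file.path(config$out_dir,
                                paste0("freqdiff_", type, ".bedgraph")))
    regions[[type]] <- candidate_regions(rec, config$p_max, config$or_min)
  }
  all_regions <- do.call(rbind, regions)
  rownames(all_regions) <- NULL
  write_regions_bed(all_regions,
                    file.path(config$out_dir, "candidate_regions.bed"))
  write_run_log(config, file.path(config$out_dir, "run_log.txt"),
                n_samples = nrow(meta), n_intervals = nrow(grid$intervals))
  invisible(list(summary = summ, scans = scans, regions = all_regions,
                 labels = labels, grid = grid))
}

write_run_log <- function(config, path, n_samples, n_intervals) {
  # paths are machine-specific; the input md5 identifies the data instead
  skip <- c("thresholds", "segments", "metadata", "arms", "out_dir")
  cfg_txt <- yaml::as.yaml(c(
    lapply(config[setdiff(names(config), skip)],
           function(x) if (is.character(x) || is.numeric(x) ||
                           is.logical(x)) x else NULL),
    list(thresholds = unclass(config$thresholds))))
  hash <- substr(tools::md5sum(config$segments)[[1L]], 1L, 12L)
  lines <- c(
    paste0("ascnscan ", as.character(utils::packageVersion("ascnscan"))),
    paste0("seed: ", config$seed),
    paste0("input_md5: ", hash),
    paste0("n_samples: ", n_samples),
    paste0("n_union_intervals: ", n_intervals),
    "config:", cfg_txt)
  writeLines(lines, path)
  invisible(path)
}
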
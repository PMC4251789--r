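#' @importFrom stats setNames
NULL

#' Construct a per-sample allele-specific copy-number profile
#'
#' A `sample_profile` holds one tumour genome as ordered, non-overlapping
#' allele-specific integer copy-number segments on the autosomes, the usual
#' output layer of absolute allele-specific copy-number callers. Coordinates
#' are 0-based half-open. The minor allele is canonicalised to the lesser
#' homolog (`minor_cn <= total_cn - minor_cn`); a total of 0 forces a minor
#' of 0. Gaps between segments are permitted and treated as missing data.
#'
#' @param sample_id Sample identifier.
#' @param segments `data.frame` with columns `chrom` (autosome 1-22), `start`,
#'   `end` (0-based half-open), `total_cn`, `minor_cn` (non-negative
#'   integers).
#' @return An object of class `sample_profile`.
#' @export
sample_profile <- function(sample_id, segments) {
  stopifnot(is.character(sample_id), length(sample_id) == 1L)
  req <- c("chrom", "start", "end", "total_cn", "minor_cn")
  if (!all(req %in% names(segments)))
    stop("segments must have columns ", paste(req, collapse = ", "))
  seg <- segments[req]
  seg$chrom <- parse_chrom(seg$chrom, context = paste0("sample ", sample_id))
  for (col in c("total_cn", "minor_cn")) {
    v <- seg[[col]]
    if (any(is.na(v)) || any(v != round(v)) || any(v < 0))
      stop("non-integer or negative ", col, " in sample ", sample_id)
    seg[[col]] <- as.integer(round(v))
  }
  if (any(seg$start >= seg$end))
    stop("segment with start >= end in sample ", sample_id)
  if (any(seg$total_cn == 0L & seg$minor_cn > 0L))
    stop("total_cn 0 with minor_cn > 0 in sample ", sample_id)
  seg$minor_cn <- as.integer(canonical_minor(seg$total_cn, seg$minor_cn))
  seg <- seg[order(seg$chrom, seg$start), , drop = FALSE]
  overlaps <- seg$chrom[-1L] == seg$chrom[-nrow(seg)] &
    seg$start[-1L] < seg$end[-nrow(seg)]
  if (nrow(seg) > 1L && any(overlaps)) {
    i <- which(overlaps)[1L]
    stop(sprintf(
      "overlapping segments in sample %s on chromosome %d: [%.0f,%.0f) and [%.0f,%.0f)",
      sample_id, seg$chrom[i], seg$start[i], seg$end[i],
      seg$start[i + 1L], seg$end[i + 1L]))
  }
  rownames(seg) <- NULL
  structure(list(sample_id = sample_id, segments = seg),
            class = "sample_profile")
}

#' @export
print.sample_profile <- function(x, ...) {
  cat(sprintf("<sample_profile> %s: %d segments on %d chromosome(s), %.1f Mb\n",
              x$sample_id, nrow(x$segments),
              length(unique(x$segments$chrom)),
              sum(x$segments$end - x$segments$start) / 1e6))
  invisible(x)
}

#' Parse a SEG-like allele-specific segment table into sample profiles
#'
#' Reads a tab-separated file with header columns `sample`, `chrom`, `start`,
#' `end`, `total_cn`, `minor_cn`. File coordinates are 1-based inclusive (the
#' SEG convention) unless `dialect = "bed"`, in which case they are taken as
#' 0-based half-open. Internally all coordinates are 0-based half-open.
#' Minor/total copies are swapped into canonical order where needed (the
#' minor allele is always the lesser homolog). Overlapping segments within a
#' sample, sex chromosomes, and non-integer copy numbers are errors.
#'
#' @param path Path to the segment table.
#' @param dialect `"seg"` (1-based inclusive, default) or `"bed"`
#'   (0-based half-open).
#' @return Named list of [sample_profile] objects, ordered by sample id.
#' @export
parse_segment_file <- function(path, dialect = c("seg", "bed")) {
  dialect <- match.arg(dialect)
  raw <- utils::read.table(path, sep = "\t", header = TRUE,
                           colClasses = "character")
  req <- c("sample", "chrom", "start", "end", "total_cn", "minor_cn")
  if (!all(req %in% names(raw)))
    stop("segment file must have header columns ", paste(req, collapse = ", "))
  for (col in c("start", "end", "total_cn", "minor_cn")) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- is.na(v) | v != round(v)
    if (any(bad))
      stop(sprintf("non-integer %s at line %d of %s", col,
                   which(bad)[1L] + 1L, path))
    raw[[col]] <- round(v)
  }
  if (dialect == "seg") raw$start <- raw$start - 1
  profiles <- lapply(split(raw, raw$sample), function(d)
    sample_profile(d$sample[1L], d[c("chrom", "start", "end",
                                     "total_cn", "minor_cn")]))
  profiles[order(names(profiles))]
}

#' Write sample profiles as a SEG-like segment table
#'
#' Inverse of [parse_segment_file()]: writes 1-based inclusive coordinates
#' when `dialect = "seg"`. Parsing the written file reproduces the profiles.
#'
#' @param profiles Named list of [sample_profile] objects.
#' @param path Output path.
#' @param dialect Coordinate convention, as in [parse_segment_file()].
#' @export
write_segment_file <- function(profiles, path, dialect = c("seg", "bed")) {
  dialect <- match.arg(dialect)
  tab <- do.call(rbind, lapply(profiles, function(p)
    cbind(sample = p$sample_id, p$segments)))
  if (dialect == "seg") tab$start <- tab$start + 1
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a clinical metadata table
#'
#' Tab-separated with header columns `sample`, `stage` (II/III/IV), `msi`
#' (MSI-H[igh], MSI-L[ow] or MSS; MSI-Low is merged into MSS, following the
#' evidence that low-level instability behaves like stability),
#' `distant_recurrence` (TRUE/FALSE or 1/0), `followup_years`,
#' `adjuvant_chemo`. Stage II-III samples without recurrence whose follow-up
#' is 5 years or shorter cannot contribute to dissemination labelling (a late
#' recurrence could still occur) and are dropped with a warning unless
#' `drop_short_followup = FALSE`.
#'
#' @param path Path to the metadata table.
#' @param drop_short_followup Drop non-recurrent stage II-III samples with
#'   follow-up of 5 years or less (default `TRUE`).
#' @return `data.frame` with columns `sample`, `stage`, `msi`
#'   (`"MSI-H"`/`"MSS"`), `distant_recurrence`, `followup_years`,
#'   `adjuvant_chemo`.
#' @export
read_metadata <- function(path, drop_short_followup = TRUE) {
  raw <- utils::read.table(path, sep = "\t", header = TRUE,
                           colClasses = "character")
  req <- c("sample", "stage", "msi", "distant_recurrence", "followup_years",
           "adjuvant_chemo")
  if (!all(req %in% names(raw)))
    stop("metadata must have header columns ", paste(req, collapse = ", "))
  meta <- data.frame(
    sample = raw$sample,
    stage = raw$stage,
    msi = normalise_msi(raw$msi),
    distant_recurrence = parse_flag(raw$distant_recurrence),
    followup_years = as.numeric(raw$followup_years),
    adjuvant_chemo = parse_flag(raw$adjuvant_chemo)
  )
  if (!all(meta$stage %in% c("II", "III", "IV")))
    stop("stage must be one of II, III, IV")
  validate_metadata(meta, drop_short_followup = drop_short_followup)
}

normalise_msi <- function(x) {
  x <- toupper(as.character(x))
  out <- ifelse(x %in% c("MSI-H", "MSI-HIGH"), "MSI-H",
                ifelse(x %in% c("MSS", "MSI-L", "MSI-LOW"), "MSS", NA))
  if (any(is.na(out)))
    stop("unrecognised MSI status: ", paste(unique(x[is.na(out)]),
                                            collapse = ", "))
  out
}

parse_flag <- function(x) {
  out <- as.logical(x)
  num <- suppressWarnings(as.numeric(x))
  out[is.na(out) & !is.na(num)] <- num[is.na(out) & !is.na(num)] != 0
  if (any(is.na(out))) stop("unparseable logical flag: ",
                            paste(unique(x[is.na(out)]), collapse = ", "))
  out
}

validate_metadata <- function(meta, drop_short_followup = TRUE) {
  short <- meta$stage %in% c("II", "III") & !meta$distant_recurrence &
    meta$followup_years <= 5
  if (any(short) && drop_short_followup) {
    warning("excluding ", sum(short), " stage II-III sample(s) without ",
            "recurrence and follow-up <= 5 years: ",
            paste(meta$sample[short], collapse = ", "))
    meta <- meta[!short, , drop = FALSE]
    rownames(meta) <- NULL
  }
  meta
}

#' Label tumour dissemination
#'
#' Dissemination is distant metastasis at diagnosis (stage IV) or, for stage
#' II-III disease, distant recurrence within 5 years of diagnosis. Stage IV
#' dominates: the recurrence flag is ignored for stage IV samples.
#'
#' @param meta Metadata `data.frame` from [read_metadata()].
#' @return Logical vector, one flag per row of `meta`.
#' @export
label_dissemination <- function(meta) {
  stopifnot(all(c("stage", "distant_recurrence", "followup_years")
                %in% names(meta)))
  meta$stage == "IV" |
    (meta$stage %in% c("II", "III") & meta$distant_recurrence &
       meta$followup_years <= 5)
}

#' Write frequency/difference tracks as bedGraph
#'
#' Serialises one numeric column of a position-sorted record table as a
#' 4-column bedGraph (chrom, 0-based start, end, value), the format used for
#' the genome-wide alteration-frequency tracks.
#'
#' @param records `data.frame` with columns `chrom`, `start`, `end` plus the
#'   value column, sorted by genome position.
#' @param path Output path.
#' @param value Name of the value column (default `"freq_diff"`).
#' @export
write_tracks <- function(records, path, value = "freq_diff") {
  stopifnot(all(c("chrom", "start", "end", value) %in% names(records)))
  if (nrow(records) > 1L) {
    o <- order(records$chrom, records$start)
    if (!identical(o, seq_len(nrow(records))))
      stop("records must be sorted by genome position")
  }
  bed <- records[c("chrom", "start", "end", value)]
  utils::write.table(format(bed, scientific = FALSE, trim = TRUE), path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Write and read full association-record tables
#'
#' Tab-separated with header; `read_association_table()` round-trips the
#' output of [fisher_scan()].
#'
#' @param records Association records (`data.frame`).
#' @param path File path.
#' @export
write_association_table <- function(records, path) {
  if (nrow(records) > 1L) {
    o <- order(records$chrom, records$start)
    if (!identical(o, seq_len(nrow(records))))
      stop("records must be sorted by genome position")
  }
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_association_table
#' @export
read_association_table <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}
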
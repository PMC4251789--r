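# shared internal helpers

# Parse chromosome labels to autosome integers 1..22. Accepts "chr" prefixes.
# Sex chromosomes and anything unrecognised are an error: every downstream
# statistic (ploidy, arm medians, burden) is defined over autosomes only.
parse_chrom <- function(x, context = "input") {
  x <- sub("^chr", "", as.character(x))
  if (any(toupper(x) %in% c("X", "Y", "23", "24", "M", "MT")))
    stop("sex/mitochondrial chromosome in ", context,
         "; only autosomes 1-22 are supported")
  n <- suppressWarnings(as.integer(x))
  bad <- is.na(n) | n < 1L | n > 22L
  if (any(bad))
    stop("unrecognised chromosome label(s) in ", context, ": ",
         paste(unique(x[bad]), collapse = ", "))
  n
}

# Lower weighted median: smallest value whose cumulative weight reaches half
# the total. On an exact 50/50 tie between two values this returns the lower
# one, which is the tie rule used for arm-median copy-number states.
weighted_median_low <- function(values, weights) {
  stopifnot(length(values) == length(weights), all(weights >= 0))
  keep <- weights > 0
  values <- values[keep]
  weights <- weights[keep]
  if (length(values) == 0L) return(NA_real_)
  o <- order(values)
  values <- values[o]
  weights <- weights[o]
  cw <- cumsum(weights)
  half <- sum(weights) / 2
  values[which(cw >= half - 1e-9)[1L]]
}

# enforce minor <= total - minor (minor allele is the lesser homolog)
canonical_minor <- function(total, minor) {
  pmin(minor, total - minor)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
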
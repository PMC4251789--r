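#' Autosome arm definitions (hg19)
#'
#' Returns the 44 autosome arm intervals of the hg19 reference: for each of
#' chromosomes 1-22, the p arm runs from the telomere to the centromere start
#' and the q arm from the centromere end to the chromosome end (UCSC gap-table
#' centromere coordinates). Coordinates are 0-based half-open, the convention
#' used throughout the package. Sex chromosomes are excluded because all
#' downstream summaries (ploidy, duplication scoring) are defined over
#' autosomes only.
#'
#' @return A `data.frame` with columns `chrom` (integer 1-22), `arm`
#'   (`"p"`/`"q"`), `start`, `end` (0-based half-open base pairs).
#' @seealso [parse_arm_bed()] to substitute any other genome build.
#' @export
hg19_arms <- function() {
  len <- c(249250621, 243199373, 198022430, 191154276, 180915260, 171115067,
           159138663, 146364022, 141213431, 135534747, 135006516, 133851895,
           115169878, 107349540, 102531392, 90354753, 81195210, 78077248,
           59128983, 63025520, 48129895, 51304566)
  cen_start <- c(121535434, 92326171, 90504854, 49660117, 46405641, 58830166,
                 58054331, 43838887, 47367679, 39254935, 51644205, 34856694,
                 16000000, 16000000, 17000000, 35335801, 22263006, 15460898,
                 24681782, 26369569, 11288129, 13000000)
  cen_end <- c(124535434, 95326171, 93504854, 52660117, 49405641, 61830166,
               61054331, 46838887, 50367679, 42254935, 54644205, 37856694,
               19000000, 19000000, 20000000, 38335801, 25263006, 18460898,
               27681782, 29369569, 14288129, 16000000)
  arms <- rbind(
    data.frame(chrom = 1:22, arm = "p", start = 0, end = cen_start),
    data.frame(chrom = 1:22, arm = "q", start = cen_end, end = len)
  )
  arms <- arms[order(arms$chrom, arms$start), , drop = FALSE]
  rownames(arms) <- NULL
  validate_arms(arms)
}

#' Read chromosome-arm definitions from a BED file
#'
#' The file must be 4-column BED (0-based half-open): chrom, start, end, name,
#' where name is `"p"` or `"q"`. A `chr` prefix on the chromosome is accepted
#' and stripped; sex chromosomes are rejected.
#'
#' @param path Path to the BED file.
#' @return A `data.frame` as returned by [hg19_arms()].
#' @export
parse_arm_bed <- function(path) {
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("chrom", "start", "end", "arm"),
                           colClasses = c("character", "numeric", "numeric",
                                          "character"))
  arms <- data.frame(chrom = parse_chrom(raw$chrom, context = path),
                     arm = raw$arm, start = raw$start, end = raw$end)
  arms <- arms[order(arms$chrom, arms$start), , drop = FALSE]
  rownames(arms) <- NULL
  validate_arms(arms)
}

validate_arms <- function(arms) {
  stopifnot(is.data.frame(arms),
            all(c("chrom", "arm", "start", "end") %in% names(arms)))
  if (!all(arms$arm %in% c("p", "q")))
    stop("arm names must be 'p' or 'q'")
  if (any(arms$start >= arms$end))
    stop("arm intervals must satisfy start < end")
  for (ch in unique(arms$chrom)) {
    a <- arms[arms$chrom == ch, ]
    p <- a[a$arm == "p", ]
    q <- a[a$arm == "q", ]
    if (nrow(p) > 1L || nrow(q) > 1L)
      stop("duplicated arm for chromosome ", ch)
    if (nrow(p) == 1L && nrow(q) == 1L && p$end > q$start)
      stop("p arm overlaps q arm on chromosome ", ch)
  }
  arms
}

# chromosome extents implied by an arm set (p start to q end), used as the
# simulated genomes' callable territory
arm_chrom_extent <- function(arms) {
  ag <- split(arms, arms$chrom)
  out <- do.call(rbind, lapply(ag, function(a) {
    data.frame(chrom = a$chrom[1], start = min(a$start), end = max(a$end))
  }))
  rownames(out) <- NULL
  out[order(out$chrom), , drop = FALSE]
}
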
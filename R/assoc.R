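# Genome-wide association of alteration types with tumour dissemination on
# the breakpoint-union grid, plus the clinical contingency-table tests.

#' Per-sample alteration matrix on a union grid
#'
#' Evaluates one alteration type for every (interval, sample) cell of a
#' union grid. Relative and high-gain types need each sample's average
#' ploidy, supplied as a named vector (computed from the profiles when
#' omitted at scan time).
#'
#' @param grid A `union_grid` from [build_union_grid()].
#' @param alteration One of [ALTERATION_TYPES].
#' @param ploidies Named numeric vector of average ploidies (one per grid
#'   sample).
#' @param thresholds A [cna_thresholds()] object.
#' @return Logical matrix intervals x samples; `NA` where the sample has no
#'   call.
#' @export
alteration_matrix <- function(grid, alteration, ploidies,
                              thresholds = cna_thresholds()) {
  alteration <- match.arg(alteration, ALTERATION_TYPES)
  stopifnot(all(grid$samples %in% names(ploidies)))
  out <- matrix(NA, nrow = nrow(grid$intervals), ncol = length(grid$samples),
                dimnames = list(NULL, grid$samples))
  for (s in grid$samples) {
    # focality refers to the sample's own segment, not the union interval
    calls <- classify_calls(grid$total[, s], grid$minor[, s],
                            grid$seglen[, s], ploidies[[s]], thresholds)
    out[, s] <- calls[, alteration]
  }
  out
}

#' Fisher exact association scan over the union grid
#'
#' For each union interval, tabulates altered vs unaltered against
#' disseminated vs non-disseminated (samples with a missing call at that
#' interval are excluded from its table) and computes the two-sided Fisher
#' exact p-value (point-probability summation: the sum of all tables, at
#' fixed margins, whose probability does not exceed the observed one) and an
#' odds ratio with 95% confidence interval. Intervals where one group has no
#' informative sample get `p = 1` and an undefined odds ratio, flagged in
#' `degenerate`.
#'
#' @param grid A `union_grid`.
#' @param labels Named logical vector of dissemination flags covering all
#'   grid samples.
#' @param alteration One of [ALTERATION_TYPES].
#' @param thresholds A [cna_thresholds()] object.
#' @param ploidies Optional named average-ploidy vector; required for
#'   ploidy-relative alteration types.
#' @param or_method `"cmle"` (conditional maximum likelihood with exact CI,
#'   default) or `"sample"` (cross-product with Haldane-Anscombe correction
#'   and Woolf CI); see [odds_ratio_ci()].
#' @param adjust_p Add a Benjamini-Hochberg adjusted `q` column (default
#'   `FALSE`; the scan is reported with unadjusted p-values).
#' @return `data.frame`, one row per interval, sorted by position: `chrom`,
#'   `start`, `end`, `alteration`, counts `a` (altered, disseminated), `b`
#'   (altered, non-disseminated), `c` (unaltered, disseminated), `d`
#'   (unaltered, non-disseminated), `freq_pos`, `freq_neg`, `freq_diff`,
#'   `p`, `or_estimate`, `ci_low`, `ci_high`, `degenerate`.
#' @export
fisher_scan <- function(grid, labels, alteration,
                        thresholds = cna_thresholds(), ploidies = NULL,
                        or_method = c("cmle", "sample"), adjust_p = FALSE) {
  or_method <- match.arg(or_method)
  if (!all(grid$samples %in% names(labels)))
    stop("labels missing for sample(s): ",
         paste(setdiff(grid$samples, names(labels)), collapse = ", "))
  labels <- labels[grid$samples]
  if (is.null(ploidies)) {
    ploidies <- colSums(grid$total * (grid$intervals$end - grid$intervals$start),
                        na.rm = TRUE) /
      colSums((!is.na(grid$total)) * (grid$intervals$end - grid$intervals$start))
  }
  alt <- alteration_matrix(grid, alteration, ploidies, thresholds)
  pos <- matrix(rep(labels, each = nrow(alt)), nrow = nrow(alt))
  a <- rowSums(alt & pos, na.rm = TRUE)
  b <- rowSums(alt & !pos, na.rm = TRUE)
  c_ <- rowSums(!alt & pos, na.rm = TRUE)
  d <- rowSums(!alt & !pos, na.rm = TRUE)
  degenerate <- (a + c_) == 0L | (b + d) == 0L
  freq_pos <- ifelse(a + c_ > 0, a / (a + c_), NA_real_)
  freq_neg <- ifelse(b + d > 0, b / (b + d), NA_real_)

  # many intervals share the same 2x2 table; test each distinct table once
  key <- paste(a, b, c_, d)
  uniq <- !duplicated(key)
  tabstats <- matrix(NA_real_, nrow = sum(uniq), ncol = 4,
                     dimnames = list(key[uniq], c("p", "or", "lo", "hi")))
  for (i in which(uniq)) {
    tab <- matrix(c(a[i], b[i], c_[i], d[i]), nrow = 2, byrow = TRUE)
    if (degenerate[i]) {
      tabstats[key[i], ] <- c(1, NA, NA, NA)
    } else {
      ft <- stats::fisher.test(tab)
      or <- odds_ratio_ci(a[i], b[i], c_[i], d[i], method = or_method)
      tabstats[key[i], ] <- c(ft$p.value, or$estimate, or$ci_low, or$ci_high)
    }
  }
  st <- tabstats[key, , drop = FALSE]
  out <- data.frame(
    chrom = grid$intervals$chrom, start = grid$intervals$start,
    end = grid$intervals$end, alteration = alteration,
    a = a, b = b, c = c_, d = d,
    freq_pos = freq_pos, freq_neg = freq_neg,
    freq_diff = freq_pos - freq_neg,
    p = st[, "p"], or_estimate = st[, "or"],
    ci_low = st[, "lo"], ci_high = st[, "hi"],
    degenerate = degenerate)
  if (adjust_p) out$q <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}

#' Odds ratio of a 2x2 table with 95% confidence interval
#'
#' `method = "cmle"`: conditional maximum-likelihood estimate under the
#' noncentral hypergeometric model with the exact confidence interval of the
#' Fisher framework (tolerates zero cells; bounds may be 0 or infinite).
#' `method = "sample"`: the cross-product ratio `ad/bc`, with the
#' Haldane-Anscombe +0.5 correction applied to every cell when any cell is
#' zero, and the Woolf logit-scale interval.
#'
#' @param a,b,c,d Non-negative cell counts (altered/disseminated,
#'   altered/non-disseminated, unaltered/disseminated,
#'   unaltered/non-disseminated).
#' @param method `"cmle"` or `"sample"`.
#' @param conf_level Confidence level (default 0.95).
#' @return List with `estimate`, `ci_low`, `ci_high` (all `NA` when a row or
#'   column margin is zero).
#' @export
odds_ratio_ci <- function(a, b, c, d, method = c("cmle", "sample"),
                          conf_level = 0.95) {
  method <- match.arg(method)
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  if ((a + b) == 0 || (c + d) == 0 || (a + c) == 0 || (b + d) == 0)
    return(list(estimate = NA_real_, ci_low = NA_real_, ci_high = NA_real_))
  if (method == "cmle") {
    ft <- stats::fisher.test(matrix(c(a, b, c, d), nrow = 2, byrow = TRUE),
                             conf.level = conf_level)
    list(estimate = unname(ft$estimate), ci_low = ft$conf.int[1L],
         ci_high = ft$conf.int[2L])
  } else {
    if (any(c(a, b, c, d) == 0)) {
      a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
    }
    est <- (a * d) / (b * c)
    se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
    z <- stats::qnorm(1 - (1 - conf_level) / 2)
    list(estimate = est, ci_low = exp(log(est) - z * se),
         ci_high = exp(log(est) + z * se))
  }
}

#' Candidate regions from an association scan
#'
#' Selects intervals passing both the significance cut-off (`p < p_max`) and
#' the effect-size cut-off (`or >= or_min`) and merges maximal runs of
#' selected intervals that are consecutive in the scan on the same
#' chromosome into candidate regions.
#'
#' @param records Output of [fisher_scan()] (one alteration type, sorted by
#'   position).
#' @param p_max Significance cut-off (default 0.05).
#' @param or_min Minimum odds ratio (default 4).
#' @return `data.frame` with one row per region: `chrom`, `start`, `end`,
#'   `alteration`, `peak_or`, `min_p`, `n_segments`. Zero rows when nothing
#'   qualifies.
#' @export
candidate_regions <- function(records, p_max = 0.05, or_min = 4) {
  if (length(unique(records$alteration)) > 1L)
    stop("records must contain a single alteration type")
  qual <- !is.na(records$p) & records$p < p_max &
    !is.na(records$or_estimate) & records$or_estimate >= or_min
  empty <- data.frame(chrom = integer(), start = numeric(), end = numeric(),
                      alteration = character(), peak_or = numeric(),
                      min_p = numeric(), n_segments = integer())
  if (!any(qual)) return(empty)
  idx <- which(qual)
  new_run <- c(TRUE, diff(idx) > 1L |
                 records$chrom[idx[-1L]] != records$chrom[idx[-length(idx)]])
  run <- cumsum(new_run)
  out <- do.call(rbind, lapply(split(idx, run), function(i)
    data.frame(chrom = records$chrom[i[1L]], start = records$start[i[1L]],
               end = records$end[i[length(i)]],
               alteration = records$alteration[i[1L]],
               peak_or = max(records$or_estimate[i]),
               min_p = min(records$p[i]), n_segments = length(i))))
  rownames(out) <- NULL
  out
}

#' Write candidate regions as BED
#'
#' 6-column BED: chrom, start, end, name (`alteration;p=<min_p>`), score
#' (peak odds ratio), strand (`.`).
#'
#' @param regions Output of [candidate_regions()].
#' @param path Output path.
#' @export
write_regions_bed <- function(regions, path) {
  if (is.null(regions) || nrow(regions) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  bed <- data.frame(chrom = regions$chrom,
                    start = format(regions$start, scientific = FALSE,
                                   trim = TRUE),
                    end = format(regions$end, scientific = FALSE,
                                 trim = TRUE),
                    name = sprintf("%s;p=%.3g", regions$alteration,
                                   regions$min_p),
                    score = signif(regions$peak_or, 4), strand = ".")
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Clinical contingency-table test
#'
#' One 2x2 test as used for clinical cross-tables: Pearson chi-squared with
#' (`"chi2_yates"`) or without (`"chi2"`) continuity correction, or Fisher's
#' exact test, two-sided (point-probability summation) or one-sided (the
#' smaller of the two hypergeometric tail probabilities).
#'
#' @param table 2x2 matrix of non-negative counts.
#' @param method One of `"chi2"`, `"chi2_yates"`, `"fisher_two_sided"`,
#'   `"fisher_one_sided"`.
#' @return List with `statistic` (chi-squared statistic, `NA` for Fisher)
#'   and `p`.
#' @export
contingency_test <- function(table,
                             method = c("chi2", "chi2_yates",
                                        "fisher_two_sided",
                                        "fisher_one_sided")) {
  method <- match.arg(method)
  stopifnot(is.matrix(table), all(dim(table) == 2L), all(table >= 0),
            sum(table) >= 1)
  if (method %in% c("chi2", "chi2_yates")) {
    if (any(rowSums(table) == 0) || any(colSums(table) == 0))
      stop("chi-squared test undefined with a zero marginal")
    ct <- suppressWarnings(
      stats::chisq.test(table, correct = method == "chi2_yates"))
    list(statistic = unname(ct$statistic), p = ct$p.value)
  } else if (method == "fisher_two_sided") {
    list(statistic = NA_real_, p = stats::fisher.test(table)$p.value)
  } else {
    lower <- stats::fisher.test(table, alternative = "less")$p.value
    upper <- stats::fisher.test(table, alternative = "greater")$p.value
    list(statistic = NA_real_, p = min(lower, upper))
  }
}
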
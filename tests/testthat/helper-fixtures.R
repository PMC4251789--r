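# Fixture builders and independent oracles shared across the suite.

# quick profile builder: seg is a matrix-like of rows
# c(chrom, start, end, total, minor)
make_profile <- function(id, ...) {
  rows <- do.call(rbind, list(...))
  sample_profile(id, data.frame(chrom = rows[, 1], start = rows[, 2],
                                end = rows[, 3], total_cn = rows[, 4],
                                minor_cn = rows[, 5]))
}

# a profile covering every arm of an arm set at a constant state
uniform_profile <- function(id, arms, total, minor) {
  sample_profile(id, data.frame(chrom = arms$chrom, start = arms$start,
                                end = arms$end, total_cn = total,
                                minor_cn = minor))
}

# toy two-chromosome genome for grid and simulation tests (arm lengths in bp)
toy_arms <- function(arm_len = 5000, n_chrom = 2) {
  do.call(rbind, lapply(seq_len(n_chrom), function(ch)
    data.frame(chrom = ch, arm = c("p", "q"),
               start = c(0, arm_len), end = c(arm_len, 2 * arm_len))))
}

# random toy cohort on genomes <= 10 kb: each sample covers a random subset
# of unit intervals split at random breakpoints, with random integer states
random_toy_cohort <- function(n_samples, genome_len = 200, n_chrom = 2) {
  profiles <- lapply(seq_len(n_samples), function(i) {
    segs <- do.call(rbind, lapply(seq_len(n_chrom), function(ch) {
      n_bk <- sample(0:5, 1)
      bounds <- sort(unique(c(0, genome_len,
                              sample.int(genome_len - 1, n_bk))))
      out <- data.frame(chrom = ch, start = bounds[-length(bounds)],
                        end = bounds[-1])
      keep <- runif(nrow(out)) > 0.2  # leave random gaps
      out[keep, , drop = FALSE]
    }))
    segs$total_cn <- sample(0:5, nrow(segs), replace = TRUE)
    segs$minor_cn <- pmin(segs$total_cn %/% 2,
                          sample(0:2, nrow(segs), replace = TRUE))
    if (nrow(segs) == 0)
      segs <- data.frame(chrom = 1, start = 0, end = genome_len,
                         total_cn = 2, minor_cn = 1)
    sample_profile(sprintf("T%02d", i), segs)
  })
  names(profiles) <- vapply(profiles, function(p) p$sample_id, character(1))
  profiles
}

# per-base-pair state lookup, the brute-force oracle for the union grid
bp_state <- function(profile, chrom, pos) {
  seg <- profile$segments
  hit <- seg$chrom == chrom & seg$start <= pos & pos < seg$end
  if (!any(hit)) return(c(NA_integer_, NA_integer_))
  c(seg$total_cn[hit], seg$minor_cn[hit])
}

# two-sided Fisher exact p by direct enumeration of the hypergeometric
# tables at fixed margins (point-probability summation), via choose()
# arithmetic -- independent of stats::fisher.test
fisher_p_oracle <- function(a, b, c, d) {
  m <- a + b          # altered margin
  n1 <- a + c         # disseminated margin
  n <- a + b + c + d
  ks <- max(0, n1 - (n - m)):min(m, n1)
  probs <- choose(m, ks) * choose(n - m, n1 - ks) / choose(n, n1)
  p_obs <- choose(m, a) * choose(n - m, n1 - a) / choose(n, n1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# brute-force weighted median on an expanded per-unit vector (lower median)
expanded_median_low <- function(values, weights) {
  v <- sort(rep(values, times = weights))
  n <- length(v)
  if (n %% 2 == 1) v[(n + 1) / 2] else v[n / 2]
}
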
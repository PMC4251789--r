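test_that("average ploidy is the length-weighted mean and sets hyperploidy", {
  arms <- hg19_arms()
  dip <- uniform_profile("dip", arms, 2, 1)
  expect_equal(average_ploidy(dip), 2.0)

  tet <- uniform_profile("tet", arms, 4, 2)
  expect_equal(average_ploidy(tet), 4.0)
  th <- cna_thresholds()
  expect_true(average_ploidy(tet) > th$hyperploid_above)
  expect_false(average_ploidy(dip) > th$hyperploid_above)

  mix <- make_profile("mix", c(1, 0, 3000e6, 2, 1), c(2, 0, 200e6, 4, 2))
  expect_equal(average_ploidy(mix), (3000 * 2 + 200 * 4) / 3200)

  expect_error(average_ploidy(sample_profile("empty",
    data.frame(chrom = integer(), start = numeric(), end = numeric(),
               total_cn = integer(), minor_cn = integer()))), "empty")
})

test_that("segment classification implements the nine alteration types", {
  flags <- function(t, m, ploidy, len = 5e6)
    classify_segment(data.frame(start = 0, end = len, total_cn = t,
                                minor_cn = m), ploidy)
  # single-copy deletion in a diploid genome: absolute + relative + LOH
  expect_setequal(flags(1, 0, 2.0), c("LOSS", "REL_LOSS", "LOH"))
  # 3 copies in a near-tetraploid genome: absolute gain, no relative change
  expect_setequal(flags(3, 1, 3.8), "GAIN")
  # copy-neutral LOH
  expect_setequal(flags(2, 0, 2.0), "LOH")
  # homozygous deletion implies loss and LOH
  expect_setequal(flags(0, 0, 2.0), c("LOSS", "REL_LOSS", "HOMDEL", "LOH"))
  # focality requires < 1 Mb
  expect_true("FOCAL_GAIN" %in% flags(3, 1, 2.0, len = 9e5))
  expect_false("FOCAL_GAIN" %in% flags(3, 1, 2.0, len = 1e6))
  # high gain compares to ploidy + 3 on the real-valued ploidy
  expect_true("HIGH_GAIN" %in% flags(6, 1, 2.9))
  expect_false("HIGH_GAIN" %in% flags(6, 1, 3.0))
})

test_that("classification is internally consistent at diploid ploidy", {
  for (t in 0:8) for (m in 0:(t %/% 2)) {
    f <- classify_segment(data.frame(start = 0, end = 5e6, total_cn = t,
                                     minor_cn = m), 2.0)
    if ("LOSS" %in% f) expect_true("REL_LOSS" %in% f)   # 1 < 0.67*2
    if (t >= 3) expect_true("REL_GAIN" %in% f)          # 3 > 1.25*2
    if ("HOMDEL" %in% f) expect_true(all(c("LOSS", "LOH") %in% f))
  }
})

test_that("arm medians are length-weighted with the lower-median tie rule", {
  arms <- toy_arms(arm_len = 1000, n_chrom = 1)
  p_arm <- arms[arms$arm == "p", ]

  full <- make_profile("f", c(1, 0, 2000, 2, 1))
  st <- arm_median_states(full, arms)
  expect_equal(st$median_total, c(2, 2))
  expect_equal(st$median_minor, c(1, 1))

  maj <- make_profile("m", c(1, 0, 600, 4, 2), c(1, 600, 2000, 2, 1))
  st <- arm_median_states(maj, arms)[1, ]   # p arm: 60% 4m2, 40% 2m1
  expect_equal(c(st$median_total, st$median_minor), c(4, 2))

  tie <- make_profile("t", c(1, 0, 500, 4, 2), c(1, 500, 1000, 2, 1))
  st <- arm_median_states(tie, arms)[1, ]   # exact 50/50 -> lower median
  expect_equal(c(st$median_total, st$median_minor), c(2, 1))
  # cross-check against the expanded per-unit brute force
  expect_equal(st$median_total, expanded_median_low(c(4, 2), c(500, 500)))
  expect_equal(st$median_minor, expanded_median_low(c(2, 1), c(500, 500)))

  # uncovered arm -> missing state
  p_only <- make_profile("p", c(1, 0, 900, 2, 0))
  st <- arm_median_states(p_only, arms)
  expect_equal(st$median_total, c(2, NA))
})

test_that("weighted arm medians match brute force on random segmentations", {
  withr::local_seed(41)
  arms <- toy_arms(arm_len = 100, n_chrom = 1)
  for (case in 1:25) {
    bounds <- sort(unique(c(0, 100, sample.int(99, sample(1:6, 1)))))
    t_states <- sample(0:5, length(bounds) - 1, replace = TRUE)
    m_states <- pmin(t_states %/% 2, sample(0:2, length(bounds) - 1, TRUE))
    prof <- sample_profile("r", data.frame(
      chrom = 1, start = bounds[-length(bounds)], end = bounds[-1],
      total_cn = t_states, minor_cn = m_states))
    st <- arm_median_states(prof, arms)[1, ]
    w <- diff(bounds)
    expect_equal(st$median_total, expanded_median_low(t_states, w))
    expect_equal(st$median_minor,
                 expanded_median_low(pmin(m_states, t_states - m_states), w))
  }
})

test_that("the duplication score counts balanced-duplication vs heterozygous-diploid arms", {
  arms <- hg19_arms()
  expect_equal(wgd_score(arm_median_states(
    uniform_profile("d", arms, 2, 1), arms)), -44)
  expect_equal(wgd_score(arm_median_states(
    uniform_profile("t", arms, 4, 2), arms)), 44)

  # states outside {2m0, 4m2, 2m1, 4m1} contribute 0
  st <- data.frame(median_total = rep(c(2, 2, 3), c(10, 30, 4)),
                   median_minor = rep(c(0, 1, 1), c(10, 30, 4)))
  expect_equal(wgd_score(st), 10 - 30)

  # 4m1 arms count against duplication
  st41 <- data.frame(median_total = c(4, 4), median_minor = c(1, 2))
  expect_equal(wgd_score(st41), 0)

  expect_error(wgd_score(data.frame(median_total = NA_real_,
                                    median_minor = NA_real_)), "missing")
})

test_that("doubling a heterozygous diploid genome flips the score sign", {
  arms <- hg19_arms()
  p <- uniform_profile("d", arms, 2, 1)
  doubled <- uniform_profile("dd", arms, 4, 2)
  expect_equal(wgd_score(arm_median_states(p, arms)), -44)
  expect_equal(wgd_score(arm_median_states(doubled, arms)), 44)
})

test_that("average ploidy is invariant under segment splitting", {
  withr::local_seed(51)
  for (p in random_toy_cohort(5, genome_len = 500)) {
    seg <- p$segments
    split_seg <- do.call(rbind, lapply(seq_len(nrow(seg)), function(i) {
      s <- seg[i, ]
      if (s$end - s$start < 2) return(s)
      mid <- s$start + sample.int(s$end - s$start - 1, 1)
      rbind(data.frame(chrom = s$chrom, start = s$start, end = mid,
                       total_cn = s$total_cn, minor_cn = s$minor_cn),
            data.frame(chrom = s$chrom, start = mid, end = s$end,
                       total_cn = s$total_cn, minor_cn = s$minor_cn))
    }))
    q <- sample_profile(p$sample_id, split_seg)
    expect_equal(average_ploidy(q), average_ploidy(p))
  }
})

test_that("chromosomal instability needs >= 10 Mb alterations on >= 5 chromosomes", {
  arms <- hg19_arms()
  expect_false(classify_cin(uniform_profile("quiet", arms, 2, 1)))

  with_losses <- function(n_chrom, len) {
    seg <- arms[c("chrom", "start", "end")]
    seg$total_cn <- 2L
    seg$minor_cn <- 1L
    prof <- do.call(rbind, lapply(seq_len(nrow(seg)), function(i) {
      s <- seg[i, ]
      if (s$chrom <= n_chrom && arms$arm[i] == "q") {
        rbind(data.frame(chrom = s$chrom, start = s$start,
                         end = s$start + len, total_cn = 1, minor_cn = 0),
              data.frame(chrom = s$chrom, start = s$start + len, end = s$end,
                         total_cn = 2, minor_cn = 1))
      } else s
    }))
    sample_profile("x", prof)
  }
  expect_true(classify_cin(with_losses(5, 12e6)))
  expect_false(classify_cin(with_losses(4, 12e6)))
  expect_false(classify_cin(with_losses(5, 8e6)))

  # adjacent equal-state pieces are merged before the length test
  split12 <- make_profile("s",
    c(1, 0, 6e6, 1, 0), c(1, 6e6, 12e6, 1, 0),
    c(2, 0, 12e6, 1, 0), c(3, 0, 12e6, 1, 0),
    c(4, 0, 12e6, 1, 0), c(5, 0, 12e6, 1, 0))
  expect_true(classify_cin(split12))
})

test_that("alteration burden counts non-2m1 bases and affected chromosomes", {
  arms <- hg19_arms()
  expect_equal(cna_burden(uniform_profile("q", arms, 2, 1)),
               list(chromosomes_affected = 0, mb_altered = 0))

  loh <- make_profile("l", c(1, 0, 87e6, 2, 0), c(1, 87e6, 200e6, 2, 1),
                      c(2, 0, 100e6, 2, 1))
  expect_equal(cna_burden(loh),
               list(chromosomes_affected = 1, mb_altered = 87))
  # with LOH excluded the same genome carries no altered base
  expect_equal(cna_burden(loh, loh_as_altered = FALSE)$mb_altered, 0)

  tet <- uniform_profile("t", arms, 4, 2)
  b <- cna_burden(tet)
  expect_equal(b$chromosomes_affected, 22)
  expect_equal(b$mb_altered, sum(arms$end - arms$start) / 1e6)
})

test_that("sample summaries assemble ploidy, duplication, CIN and burden", {
  arms <- hg19_arms()
  profs <- list(d = uniform_profile("d", arms, 2, 1),
                t = uniform_profile("t", arms, 4, 2))
  s <- sample_summary(profs, arms)
  expect_equal(s$avg_ploidy, c(2, 4))
  expect_equal(s$hyperploid, c(FALSE, TRUE))
  expect_equal(s$wgd_score, c(-44, 44))
  expect_equal(s$wgd_call, c(FALSE, TRUE))
  expect_equal(s$cin, c(FALSE, TRUE))
})
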
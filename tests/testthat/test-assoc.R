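test_that("odds ratios match arithmetic and Haldane-corrected oracles", {
  or <- odds_ratio_ci(17, 7, 35, 57, method = "sample")
  expect_equal(or$estimate, (17 * 57) / (7 * 35))
  expect_lt(or$ci_low, or$estimate)
  expect_gt(or$ci_high, or$estimate)

  # zero cell: +0.5 on every cell
  or0 <- odds_ratio_ci(5, 0, 5, 10, method = "sample")
  expect_equal(or0$estimate, (5.5 * 10.5) / (0.5 * 5.5))

  sym <- odds_ratio_ci(1, 1, 1, 1, method = "cmle")
  expect_equal(sym$estimate, 1.0, tolerance = 1e-6)
  expect_true(sym$ci_low <= 1 && 1 <= sym$ci_high)

  # zero margin is undefined
  expect_true(is.na(odds_ratio_ci(0, 0, 3, 4)$estimate))
})

test_that("conditional-ML odds ratios sit inside their exact intervals", {
  withr::local_seed(61)
  for (i in 1:25) {
    cells <- rpois(4, 5)
    if (sum(cells[1:2]) == 0 || sum(cells[3:4]) == 0 ||
        sum(cells[c(1, 3)]) == 0 || sum(cells[c(2, 4)]) == 0) next
    or <- odds_ratio_ci(cells[1], cells[2], cells[3], cells[4])
    expect_true(or$ci_low <= or$estimate && or$estimate <= or$ci_high)
  }
})

test_that("two-sided Fisher p equals hypergeometric enumeration on random tables", {
  withr::local_seed(71)
  for (i in 1:200) {
    n <- sample(4:30, 1)
    a <- sample(0:n, 1)
    b <- sample(0:(n - a), 1)
    c_ <- sample(0:(n - a - b), 1)
    d <- n - a - b - c_
    if ((a + b) == 0 || (c_ + d) == 0 || (a + c_) == 0 || (b + d) == 0) next
    got <- contingency_test(matrix(c(a, b, c_, d), 2, byrow = TRUE),
                            "fisher_two_sided")$p
    expect_equal(got, fisher_p_oracle(a, b, c_, d), tolerance = 1e-9)
  }
})

test_that("contingency tests expose both chi-squared variants and Fisher sidedness", {
  tab <- matrix(c(24, 24, 29, 39), 2, byrow = TRUE)
  chi <- contingency_test(tab, "chi2")
  yates <- contingency_test(tab, "chi2_yates")
  expect_lt(chi$p, yates$p)   # continuity correction is conservative
  expect_gt(chi$statistic, 0)

  same <- matrix(c(10, 5, 10, 5), 2, byrow = TRUE)
  expect_equal(contingency_test(same, "chi2")$statistic, 0)
  expect_equal(contingency_test(same, "chi2")$p, 1)

  one <- contingency_test(matrix(c(0, 3, 53, 60), 2, byrow = TRUE),
                          "fisher_one_sided")
  expect_equal(one$p, choose(63, 3) / choose(116, 3), tolerance = 1e-9)

  expect_error(contingency_test(matrix(c(0, 0, 3, 4), 2), "chi2"),
               "marginal")
})

test_that("the scan computes per-interval tables excluding missing calls", {
  # three samples; B has a gap on [10,20)
  profs <- list(
    A = make_profile("A", c(1, 0, 10, 1, 0), c(1, 10, 20, 1, 0)),
    B = make_profile("B", c(1, 0, 10, 2, 1)),
    C = make_profile("C", c(1, 0, 10, 2, 1), c(1, 10, 20, 2, 1)))
  grid <- build_union_grid(profs)
  labels <- c(A = TRUE, B = TRUE, C = FALSE)
  rec <- fisher_scan(grid, labels, "LOSS")
  expect_equal(rec$a, c(1, 1))
  expect_equal(rec$c, c(1, 0))  # B missing on the second interval
  expect_equal(rec$freq_pos, c(0.5, 1))
  expect_equal(rec$freq_neg, c(0, 0))
  oracle <- vapply(seq_len(2), function(i)
    fisher_p_oracle(rec$a[i], rec$b[i], rec$c[i], rec$d[i]), numeric(1))
  expect_equal(rec$p, oracle, tolerance = 1e-9)

  # nobody altered -> p = 1, freq_diff = 0
  quiet <- list(A = make_profile("A", c(1, 0, 10, 2, 1)),
                B = make_profile("B", c(1, 0, 10, 2, 1)))
  rq <- fisher_scan(build_union_grid(quiet), c(A = TRUE, B = FALSE), "LOSS")
  expect_equal(rq$p, 1)
  expect_equal(rq$freq_diff, 0)
})

test_that("a group without informative samples yields a degenerate record", {
  profs <- list(A = make_profile("A", c(1, 0, 10, 1, 0)),
                B = make_profile("B", c(1, 20, 30, 2, 1)))
  grid <- build_union_grid(profs)
  rec <- fisher_scan(grid, c(A = TRUE, B = FALSE), "LOSS")
  expect_true(all(rec$degenerate))
  expect_equal(rec$p, c(1, 1))
  expect_true(all(is.na(rec$or_estimate)))
})

test_that("sample odds ratio is monotone in the altered-disseminated cell", {
  ors <- vapply(1:9, function(a)
    odds_ratio_ci(a, 5, 10 - a, 5, method = "sample")$estimate, numeric(1))
  expect_true(all(diff(ors) > 0))
})

test_that("candidate regions merge adjacent qualifying intervals", {
  rec <- data.frame(
    chrom = c(1, 1, 1, 1, 1, 2), start = c(0, 10, 20, 30, 40, 0),
    end = c(10, 20, 30, 40, 50, 10), alteration = "REL_LOSS",
    p = c(0.01, 0.02, 0.5, 0.03, 0.01, 0.04),
    or_estimate = c(5, 8, 9, 6, 4, 12))
  reg <- candidate_regions(rec)
  expect_equal(nrow(reg), 3)   # run split by the non-qualifying interval
  expect_equal(reg$n_segments, c(2, 2, 1))
  expect_equal(reg$start, c(0, 30, 0))
  expect_equal(reg$end, c(20, 50, 10))
  expect_equal(reg$peak_or[1], 8)
  expect_equal(reg$min_p[1], 0.01)

  # chromosome change breaks a run even for consecutive rows
  expect_equal(reg$chrom, c(1, 1, 2))

  none <- candidate_regions(transform(rec, p = 0.9))
  expect_equal(nrow(none), 0)

  expect_error(candidate_regions(transform(rec,
    alteration = c("LOSS", rep("REL_LOSS", 5)))), "single alteration")
})
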
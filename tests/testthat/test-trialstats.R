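paper_design <- function(...) {
  sample_size_params(z_alpha_half = 1.96, z_beta = 0.84, mu1 = 11.0,
                     mu2 = 10.0, sigma = 5.5, margin_fraction = 0.40, ...)
}

# raw (un-ceiled) formula, re-derived independently for scaling checks
raw_n <- function(za, zb, mu1, mu2, sigma, frac) {
  (za + zb)^2 * 2 * sigma^2 / ((abs(mu1 - mu2) + frac * sigma)^2)
}

test_that("the design parameters give 47 per group, 59 after dropout", {
  n <- noninferiority_sample_size(paper_design())
  expect_identical(n, 47L)
  expect_identical(inflate_for_dropout(n, 0.20), 59L)
})

test_that("sample size scales quadratically in the denominator and sigma", {
  base <- raw_n(1.96, 0.84, 11, 10, 5.5, 0.4)
  # doubling (|mu1-mu2| + delta) divides the un-ceiled n by 4
  delta <- 0.4 * 5.5
  doubled <- (1.96 + 0.84)^2 * 2 * 5.5^2 / ((2 * (1 + delta))^2)
  expect_equal(base / doubled, 4)
  # doubling sigma at a fixed absolute margin quadruples the un-ceiled n
  d_fixed <- 2.2
  n1 <- (1.96 + 0.84)^2 * 2 * 5.5^2 / ((1 + d_fixed)^2)
  n2 <- (1.96 + 0.84)^2 * 2 * 11^2 / ((1 + d_fixed)^2)
  expect_equal(n2 / n1, 4)
  expect_identical(
    noninferiority_sample_size(
      sample_size_params(1.96, 0.84, 11, 10, 5.5,
                         margin_fraction = d_fixed / 5.5)),
    as.integer(ceiling(n1)))
})

test_that("sample size is monotone in margin, effect, and sigma", {
  set.seed(31)
  for (i in 1:25) {
    mu1 <- stats::runif(1, 5, 15)
    mu2 <- stats::runif(1, 5, 15)
    sg <- stats::runif(1, 1, 10)
    fr <- stats::runif(1, 0.1, 0.8)
    n0 <- noninferiority_sample_size(sample_size_params(
      mu1 = mu1, mu2 = mu2, sigma = sg, margin_fraction = fr))
    # wider margin -> no more cases
    expect_lte(noninferiority_sample_size(sample_size_params(
      mu1 = mu1, mu2 = mu2, sigma = sg, margin_fraction = fr * 1.5)), n0)
    # larger effect -> no more cases
    expect_lte(noninferiority_sample_size(sample_size_params(
      mu1 = mu2 + abs(mu1 - mu2) + 1, mu2 = mu2, sigma = sg,
      margin_fraction = fr)), n0)
    # more variability (margin fraction fixed in absolute terms) -> no fewer
    d_abs <- fr * sg
    expect_gte(noninferiority_sample_size(sample_size_params(
      mu1 = mu1, mu2 = mu2, sigma = 2 * sg,
      margin_fraction = d_abs / (2 * sg))), n0)
  }
})

test_that("dropout inflation matches the printed and degenerate cases", {
  expect_identical(inflate_for_dropout(47, 0.20), 59L)
  expect_identical(inflate_for_dropout(123, 0), 123L)
  expect_identical(inflate_for_dropout(10, 0.5), 20L)
  expect_error(inflate_for_dropout(10, 1), "rate")
})

test_that("Student-t CIs reproduce the published group intervals", {
  expect_equal(group_ci(group_summary(55, 11.98, 8.46)),
               c(lower = 9.69, upper = 14.27))
  expect_equal(group_ci(group_summary(54, 6.28, 5.28)),
               c(lower = 4.84, upper = 7.72))
  expect_equal(group_ci(group_summary(54, 17.56, 11.65))[["upper"]], 20.74)
  # degenerate spread collapses the interval to the mean
  expect_equal(group_ci(group_summary(10, 5, 0)), c(lower = 5, upper = 5))
  expect_error(group_summary(1, 5, 1), "n")
})

test_that("CI width shrinks as 1/sqrt(n) and contains the mean", {
  w <- vapply(c(10, 40, 160, 640), function(n) {
    ci <- group_ci(group_summary(n, 0, 3), digits = NULL)
    expect_lt(ci[["lower"]], 0)
    expect_gt(ci[["upper"]], 0)
    diff(ci)
  }, numeric(1))
  ratios <- w[-length(w)] / w[-1]
  # t quantile also shrinks with df, so ratios slightly exceed 2
  expect_true(all(ratios > 2 & ratios < 2.3))
})

test_that("the Welch test reproduces the published total-change comparison", {
  g_ctl <- group_summary(55, 11.98, 8.46)
  g_exp <- group_summary(54, 17.56, 11.65)
  expect_equal(round(two_sample_test(g_ctl, g_exp)$p_value, 3), 0.005)
  expect_equal(round(two_sample_test(g_ctl, g_exp,
                                     var_equal = TRUE)$p_value, 3), 0.005)
  same <- two_sample_test(g_ctl, g_ctl)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  far <- two_sample_test(g_ctl, group_summary(55, 11.98 + 10 * 8.46, 8.46))
  expect_lt(far$p_value, 1e-6)
})

test_that("the Welch p-value matches a numeric tail-integration oracle", {
  set.seed(17)
  for (i in 1:10) {
    g1 <- group_summary(sample(5:80, 1), stats::rnorm(1, 10, 3),
                        stats::runif(1, 1, 12))
    g2 <- group_summary(sample(5:80, 1), stats::rnorm(1, 10, 3),
                        stats::runif(1, 1, 12))
    res <- two_sample_test(g1, g2)
    dens <- function(x) {
      gamma((res$df + 1) / 2) / (sqrt(res$df * pi) * gamma(res$df / 2)) *
        (1 + x^2 / res$df)^(-(res$df + 1) / 2)
    }
    tail <- stats::integrate(dens, abs(res$statistic), Inf,
                             rel.tol = 1e-10)$value
    expect_equal(res$p_value, 2 * tail, tolerance = 1e-6)
  }
})

test_that("proportion comparisons reproduce published rows", {
  gender <- compare_proportions(43, 60, 43, 60)
  expect_equal(gender$chisq_statistic, 0)
  expect_equal(gender$chisq_p, 1)
  expect_gt(gender$fisher_p, 0.99)
  ae <- compare_proportions(28, 60, 22, 60)
  expect_equal(ae$incidence, c(46.67, 36.67))
  # sparse hyperlipidemia row: exact test reproduces the published p
  hyper <- compare_proportions(7, 60, 4, 60)
  expect_equal(round(hyper$fisher_p, 2), 0.53)
  extreme <- compare_proportions(0, 30, 30, 30)
  expect_lt(extreme$fisher_p, 1e-10)
  expect_error(compare_proportions(5, 0, 1, 10), "positive")
  expect_error(compare_proportions(11, 10, 1, 10), "0 <= k <= n")
})

test_that("block randomization balances every complete block and stratum", {
  al <- block_randomize(c(center1 = 60, center2 = 60), block_length = 4,
                        seed = 42)
  tab <- table(al$stratum, al$arm)
  expect_true(all(tab == 30))
  expect_equal(nrow(al), 120)
  expect_equal(al$rand_number, 1:120)
  for (s in unique(al$stratum)) {
    sub <- al[al$stratum == s, ]
    for (b in unique(sub$block)) {
      blk <- sub$arm[sub$block == b]
      expect_equal(sum(blk == "experimental"), 2)
      expect_equal(sum(blk == "control"), 2)
    }
  }
})

test_that("prefix imbalance never exceeds half the block length", {
  for (seed in 1:5) {
    al <- block_randomize(c(a = 37), block_length = 6, seed = seed)
    running <- cumsum(al$arm == "experimental") -
      cumsum(al$arm == "control")
    expect_true(all(abs(running) <= 3))
  }
  # smallest block: every even prefix is exactly balanced
  al2 <- block_randomize(c(a = 20), block_length = 2, seed = 9)
  running <- cumsum(al2$arm == "experimental") - cumsum(al2$arm == "control")
  expect_true(all(running[seq(2, 20, 2)] == 0))
})

test_that("randomization is deterministic per seed and rejects odd blocks", {
  a <- block_randomize(c(x = 24, y = 24), 4, seed = 7)
  b <- block_randomize(c(x = 24, y = 24), 4, seed = 7)
  expect_identical(a, b)
  expect_false(identical(a, block_randomize(c(x = 24, y = 24), 4, seed = 8)))
  expect_error(block_randomize(c(x = 10), 3, seed = 1), "even")
})

test_that("FMA totals follow the 33/17 item partition", {
  expect_equal(fma_totals(fma_assessment(rep(2, 33), rep(2, 17))),
               c(upper = 66, lower = 34, total = 100))
  expect_equal(fma_totals(fma_assessment(rep(0, 33), rep(0, 17))),
               c(upper = 0, lower = 0, total = 0))
  expect_equal(fma_totals(fma_assessment(rep(1, 33), rep(0, 17))),
               c(upper = 33, lower = 0, total = 33))
  expect_error(fma_assessment(rep(3, 33), rep(0, 17)), "0, 1, or 2")
  expect_error(fma_assessment(rep(1, 32), rep(0, 17)), "33")
})
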
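# Trial design computations and summary-statistics reproduction:
# noninferiority sample size for two means, dropout inflation, stratified
# permuted-block randomization, the Fugl-Meyer assessment data model, and
# confidence intervals / two-sample / proportion comparisons computed
# from group summaries (n, mean, SD) rather than raw patient data.

#' Design parameters for a two-mean noninferiority sample size
#'
#' @param z_alpha_half Standard-normal quantile for the one-sided type I
#'   error (1.96 at alpha = 0.025).
#' @param z_beta Quantile for the type II error (0.84 at beta = 0.2, i.e.
#'   80\% power).
#' @param mu1 Expected mean change in the experimental arm.
#' @param mu2 Expected mean change in the control arm.
#' @param sigma Common standard deviation of the change (> 0).
#' @param margin_fraction Noninferiority margin delta expressed as a
#'   fraction of \code{sigma} (default 0.40).
#' @return An object of class \code{sample_size_params}.
#' @examples
#' sample_size_params(mu1 = 11, mu2 = 10, sigma = 5.5)
#' @export
sample_size_params <- function(z_alpha_half = 1.96, z_beta = 0.84,
                               mu1, mu2, sigma, margin_fraction = 0.40) {
  assert_scalar_number(z_alpha_half, "z_alpha_half", lower = 0,
                       strict_lower = TRUE)
  assert_scalar_number(z_beta, "z_beta", lower = 0, strict_lower = TRUE)
  assert_scalar_number(mu1, "mu1")
  assert_scalar_number(mu2, "mu2")
  assert_scalar_number(sigma, "sigma", lower = 0, strict_lower = TRUE)
  assert_scalar_number(margin_fraction, "margin_fraction", lower = 0,
                       strict_lower = TRUE)
  structure(
    list(z_alpha_half = z_alpha_half, z_beta = z_beta, mu1 = mu1,
         mu2 = mu2, sigma = sigma, margin_fraction = margin_fraction),
    class = "sample_size_params"
  )
}

#' Per-group sample size for a noninferiority comparison of two means
#'
#' \deqn{n = \left\lceil \frac{(z_{\alpha/2} + z_\beta)^2 \; 2\sigma^2}
#'   {(|\mu_1 - \mu_2| + \delta)^2} \right\rceil,\qquad
#'   \delta = \mathrm{margin\_fraction} \times \sigma}
#'
#' @param p A \code{\link{sample_size_params}} object.
#' @return Integer cases per group.
#' @examples
#' noninferiority_sample_size(
#'   sample_size_params(1.96, 0.84, mu1 = 11, mu2 = 10, sigma = 5.5,
#'                      margin_fraction = 0.40))  # 47
#' @export
noninferiority_sample_size <- function(p) {
  if (!inherits(p, "sample_size_params")) {
    stop_param("`p` must come from sample_size_params()")
  }
  delta <- p$margin_fraction * p$sigma
  denom <- (abs(p$mu1 - p$mu2) + delta)^2
  if (denom == 0) stop_param("effect plus margin must be nonzero")
  as.integer(ceiling((p$z_alpha_half + p$z_beta)^2 * 2 * p$sigma^2 / denom))
}

#' Inflate a per-group sample size for expected dropout
#'
#' @param n Cases per group before dropout.
#' @param rate Anticipated dropout fraction in [0, 1).
#' @return \code{ceiling(n / (1 - rate))}.
#' @examples
#' inflate_for_dropout(47, 0.20)  # 59
#' @export
inflate_for_dropout <- function(n, rate) {
  assert_scalar_number(n, "n", lower = 0)
  assert_scalar_number(rate, "rate", lower = 0)
  if (rate >= 1) stop_param("`rate` must be < 1")
  as.integer(ceiling(n / (1 - rate)))
}

#' Summary statistics of one group
#'
#' @param n Group size (>= 2).
#' @param mean Group mean.
#' @param sd Group standard deviation (>= 0).
#' @return An object of class \code{group_summary}.
#' @export
group_summary <- function(n, mean, sd) {
  assert_scalar_number(n, "n", lower = 2)
  assert_scalar_number(mean, "mean")
  assert_scalar_number(sd, "sd", lower = 0)
  structure(list(n = as.integer(n), mean = mean, sd = sd),
            class = "group_summary")
}

#' Student-t confidence interval for a group mean
#'
#' \code{mean +/- t(1 - (1-level)/2, n-1) * sd / sqrt(n)}. Limits are
#' rounded to \code{digits} decimals, matching report conventions; pass
#' \code{digits = NULL} for full precision.
#'
#' @param g A \code{\link{group_summary}}.
#' @param level Confidence level (default 0.95).
#' @param digits Decimals for the reported limits (default 2).
#' @return Named numeric vector \code{c(lower, upper)}.
#' @examples
#' group_ci(group_summary(55, 11.98, 8.46))  # 9.69 14.27
#' @export
group_ci <- function(g, level = 0.95, digits = 2) {
  if (!inherits(g, "group_summary")) {
    stop_param("`g` must come from group_summary()")
  }
  assert_scalar_number(level, "level", lower = 0, upper = 1)
  half <- stats::qt(1 - (1 - level) / 2, df = g$n - 1) * g$sd / sqrt(g$n)
  ci <- c(lower = g$mean - half, upper = g$mean + half)
  if (!is.null(digits)) ci <- round(ci, digits)
  ci
}

#' Two-sample t test from group summaries
#'
#' Welch's unequal-variance test by default (\code{var_equal = FALSE});
#' the pooled-variance Student test is available via
#' \code{var_equal = TRUE}.
#'
#' @param g1,g2 \code{\link{group_summary}} objects.
#' @param var_equal Assume equal variances (pooled test)?
#' @return List with \code{statistic}, \code{df}, and two-sided
#'   \code{p_value}.
#' @examples
#' two_sample_test(group_summary(55, 11.98, 8.46),
#'                 group_summary(54, 17.56, 11.65))$p_value  # ~0.005
#' @export
two_sample_test <- function(g1, g2, var_equal = FALSE) {
  if (!inherits(g1, "group_summary") || !inherits(g2, "group_summary")) {
    stop_param("both groups must come from group_summary()")
  }
  if (var_equal) {
    df <- g1$n + g2$n - 2
    sp2 <- ((g1$n - 1) * g1$sd^2 + (g2$n - 1) * g2$sd^2) / df
    se <- sqrt(sp2 * (1 / g1$n + 1 / g2$n))
  } else {
    v1 <- g1$sd^2 / g1$n
    v2 <- g2$sd^2 / g2$n
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (g1$n - 1) + v2^2 / (g2$n - 1))
  }
  tstat <- if (se == 0) 0 else (g1$mean - g2$mean) / se
  list(statistic = tstat, df = df,
       p_value = 2 * stats::pt(-abs(tstat), df = df))
}

#' Compare two proportions (2x2 counts)
#'
#' Chi-square test (with Yates continuity correction, as conventional for
#' 2x2 tables) and Fisher's exact test on the 2x2 table of events by
#' group, plus per-group incidence percentages. The Fisher p-value is the
#' recommended one when any expected cell count is below 5.
#'
#' @param k1,n1 Events and group size in group 1.
#' @param k2,n2 Events and group size in group 2.
#' @param correct Apply the continuity correction in the chi-square test?
#' @return List with \code{chisq_statistic}, \code{chisq_p},
#'   \code{fisher_p}, \code{incidence} (percentages, rounded to 2
#'   decimals), \code{min_expected}, and \code{recommended} ("fisher" when
#'   \code{min_expected} < 5, else "chisq").
#' @examples
#' compare_proportions(28, 60, 22, 60)$incidence  # 46.67 36.67
#' @export
compare_proportions <- function(k1, n1, k2, n2, correct = TRUE) {
  for (v in list(c(k1, n1), c(k2, n2))) {
    if (v[2] <= 0) stop_param("group sizes must be positive")
    if (v[1] < 0 || v[1] > v[2]) stop_param("counts must satisfy 0 <= k <= n")
  }
  tab <- matrix(c(k1, n1 - k1, k2, n2 - k2), nrow = 2, byrow = TRUE)
  cs <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  fi <- stats::fisher.test(tab)
  min_exp <- min(cs$expected)
  list(
    chisq_statistic = unname(cs$statistic),
    chisq_p = cs$p.value,
    fisher_p = fi$p.value,
    incidence = round(100 * c(k1 / n1, k2 / n2), 2),
    min_expected = min_exp,
    recommended = if (min_exp < 5) "fisher" else "chisq"
  )
}

#' Stratified permuted-block randomization
#'
#' Generates a 1:1 allocation list per stratum (study center) using
#' permuted blocks: within each complete block of \code{block_length},
#' each arm appears exactly \code{block_length/2} times in seeded-random
#' order. Randomization numbers are consecutive across strata.
#'
#' @param n_per_stratum Named (or unnamed) integer vector of cases per
#'   stratum.
#' @param block_length Even block size >= 2 (default 4).
#' @param seed Integer seed; the same seed reproduces the same list.
#' @param arms Two arm labels (default experimental/control).
#' @return Data.frame of class \code{allocation_list} with columns
#'   \code{rand_number}, \code{stratum}, \code{block}, \code{arm}, and
#'   attributes \code{block_length} and \code{seed}.
#' @examples
#' al <- block_randomize(c(center1 = 60, center2 = 60), 4, seed = 42)
#' table(al$stratum, al$arm)  # 30/30 per center
#' @export
block_randomize <- function(n_per_stratum, block_length = 4, seed = 1,
                            arms = c("experimental", "control")) {
  if (!is.numeric(block_length) || length(block_length) != 1 ||
      block_length < 2 || block_length %% 2 != 0) {
    stop_param("`block_length` must be an even count >= 2")
  }
  stopifnot(length(arms) == 2, all(n_per_stratum >= 0))
  if (is.null(names(n_per_stratum))) {
    names(n_per_stratum) <- paste0("stratum", seq_along(n_per_stratum))
  }
  half <- block_length / 2
  with_seed(seed, {
    rows <- list()
    for (s in names(n_per_stratum)) {
      n <- n_per_stratum[[s]]
      n_blocks <- ceiling(n / block_length)
      alloc <- character(0)
      blk <- integer(0)
      for (b in seq_len(n_blocks)) {
        alloc <- c(alloc, sample(rep(arms, each = half)))
        blk <- c(blk, rep(b, block_length))
      }
      rows[[s]] <- data.frame(stratum = s, block = blk[seq_len(n)],
                              arm = alloc[seq_len(n)],
                              stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    out <- cbind(rand_number = seq_len(nrow(out)), out)
    rownames(out) <- NULL
    attr(out, "block_length") <- as.integer(block_length)
    attr(out, "seed") <- as.integer(seed)
    class(out) <- c("allocation_list", "data.frame")
    out
  })
}

#' A Fugl-Meyer assessment
#'
#' The simplified FMA motor scale: 50 items (33 upper extremity, 17 lower
#' extremity), each scored 0 (unable), 1 (partial), or 2 (full); maximum
#' subtotals 66 and 34, maximum total 100.
#'
#' @param upper_items 33 item scores in \{0, 1, 2\}.
#' @param lower_items 17 item scores in \{0, 1, 2\}.
#' @return An object of class \code{fma_assessment}.
#' @export
fma_assessment <- function(upper_items, lower_items) {
  if (length(upper_items) != 33) stop_param("need 33 upper-extremity items")
  if (length(lower_items) != 17) stop_param("need 17 lower-extremity items")
  all_items <- c(upper_items, lower_items)
  if (!all(all_items %in% c(0, 1, 2))) {
    stop_param("every item score must be 0, 1, or 2")
  }
  structure(list(upper_items = as.integer(upper_items),
                 lower_items = as.integer(lower_items)),
            class = "fma_assessment")
}

#' FMA subtotals and total
#'
#' @param a An \code{\link{fma_assessment}}.
#' @return Named vector \code{c(upper, lower, total)} with maxima
#'   66/34/100.
#' @examples
#' fma_totals(fma_assessment(rep(2, 33), rep(2, 17)))  # 66 34 100
#' @export
fma_totals <- function(a) {
  if (!inherits(a, "fma_assessment")) {
    stop_param("`a` must come from fma_assessment()")
  }
  up <- sum(a$upper_items)
  lo <- sum(a$lower_items)
  c(upper = up, lower = lo, total = up + lo)
}
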
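## Group-comparison statistics: pooled-variance unpaired t tests (from raw
## samples or from printed mean/SEM/n summaries), Mann-Whitney U and one-way
## ANOVA. The pooled (not Welch) test matches printed df = n1 + n2 - 2.

#' Pooled-variance unpaired t test from printed summaries
#'
#' Reconstructs the two-sample pooled-variance t test from group means,
#' standard errors of the mean and sample sizes as printed in publications
#' (mean +/- SEM convention): SD_i = SEM_i * sqrt(n_i), pooled variance
#' s2 = ((n1-1) SD1^2 + (n2-1) SD2^2) / (n1+n2-2),
#' t = (m1 - m2) / sqrt(s2 (1/n1 + 1/n2)) on n1 + n2 - 2 df, two-tailed.
#'
#' @param m1,sem1,n1 first group mean, SEM, size.
#' @param m2,sem2,n2 second group mean, SEM, size.
#' @return a [StatResult-class]; the sign of t follows `m1 - m2`.
#' @examples
#' tFromSummary(15.23, 2.41, 6, 3.87, 0.73, 6)  # t close to 4.51, df 10
#' @export
tFromSummary <- function(m1, sem1, n1, m2, sem2, n2) {
  if (n1 < 2 || n2 < 2) stop("group sizes must be >= 2")
  if (sem1 <= 0 || sem2 <= 0) stop("SEMs must be > 0")
  sd1 <- sem1 * sqrt(n1); sd2 <- sem2 * sqrt(n2)
  df <- n1 + n2 - 2
  s2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  t <- (m1 - m2) / sqrt(s2 * (1 / n1 + 1 / n2))
  stat_result("Unpaired t test (pooled, from summaries)",
              c(t = t), df, 2 * pt(-abs(t), df))
}

#' Pooled-variance unpaired t test from raw samples
#'
#' Standard two-sample t test assuming equal variances (df = n1 + n2 - 2,
#' two-tailed); agrees with [tFromSummary()] applied to the samples' own
#' mean/SEM/n.
#'
#' @param x,y numeric samples (each length >= 2).
#' @return a [StatResult-class].
#' @export
tFromSamples <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) stop("each sample needs >= 2 values")
  if (var(x) == 0 && var(y) == 0)
    stop("zero pooled variance: samples are constant")
  ht <- t.test(x, y, var.equal = TRUE, alternative = "two.sided")
  stat_result("Unpaired t test (pooled)",
              c(t = unname(ht$statistic)), unname(ht$parameter), ht$p.value)
}

#' Mann-Whitney U test
#'
#' U is the smaller of U1 and U2 under the rank-sum definition with
#' midranks for ties. The two-tailed p-value is exact (from the Wilcoxon
#' rank-sum null distribution) when n1 + n2 <= 16 and there are no ties,
#' otherwise a normal approximation with tie correction and continuity
#' correction is used.
#'
#' @param x,y numeric samples (each length >= 1).
#' @return a [StatResult-class] with statistic `U`.
#' @export
mannWhitneyU <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 1 || n2 < 1) stop("both samples must be non-empty")
  rk <- rank(c(x, y))
  r1 <- sum(rk[seq_len(n1)])
  u1 <- r1 - n1 * (n1 + 1) / 2
  u2 <- n1 * n2 - u1
  u <- min(u1, u2)
  ties <- anyDuplicated(c(x, y)) > 0
  if (!ties && n1 + n2 <= 16) {
    p <- if (u1 == u2) 1 else min(1, 2 * pwilcox(u, n1, n2))
    method <- "Mann-Whitney U (exact)"
  } else {
    nn <- n1 + n2
    tie_tab <- table(c(x, y))
    tie_term <- sum(tie_tab^3 - tie_tab) / (nn * (nn - 1))
    sig2 <- n1 * n2 / 12 * ((nn + 1) - tie_term)
    if (sig2 <= 0) {
      p <- 1
    } else {
      z <- (u - n1 * n2 / 2 + 0.5) / sqrt(sig2)   # u <= n1 n2 / 2
      p <- min(1, 2 * pnorm(z))
    }
    method <- "Mann-Whitney U (normal approximation)"
  }
  stat_result(method, c(U = u), NA_real_, p)
}

#' One-way analysis of variance
#'
#' Standard between/within decomposition with the F statistic on
#' (k - 1, N - k) degrees of freedom; equivalent to the pooled two-sample
#' t test (F = t^2) for two groups.
#'
#' @param groups list of numeric vectors (>= 2 groups, each n >= 2).
#' @return a [StatResult-class] with statistic `F` and a df pair.
#' @export
oneWayAnova <- function(groups) {
  if (!is.list(groups) || length(groups) < 2)
    stop("need a list of at least two groups")
  if (any(vapply(groups, length, integer(1)) < 2))
    stop("each group needs n >= 2")
  within_ss <- sum(vapply(groups, function(g) sum((g - mean(g))^2),
                          numeric(1)))
  if (within_ss == 0)
    stop("zero within-group variance in every group; F undefined")
  values <- unlist(groups)
  fac <- factor(rep(seq_along(groups), lengths(groups)))
  ht <- oneway.test(values ~ fac, var.equal = TRUE)
  stat_result("One-way ANOVA", c(F = unname(ht$statistic)),
              unname(ht$parameter), ht$p.value)
}

#' Published group summaries for the summary-statistics t reconstructions
#'
#' The printed mean/SEM/n pairs whose pooled-variance t statistics are
#' recomputable from summaries alone: percent Drd2+ serotonergic neurons in
#' controls versus conditional knockouts, wild-type Gad2 puncta per cell and
#' percent Gad2+ by sex, percent Drd2-E7/8+ cells by genotype, and the
#' knockout percent-Gad2, Gad2-puncta and nucleus-area comparisons by sex.
#'
#' @return data.frame with columns `comparison`, `m1`, `sem1`, `n1`, `m2`,
#'   `sem2`, `n2`, `t_printed`, `df`.
#' @export
publishedGroupSummaries <- function() {
  path <- system.file("extdata", "group_summaries.csv",
                      package = "raphequant", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
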
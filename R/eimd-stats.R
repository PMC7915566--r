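# Muscle-damage indicator statistics: test-retest reliability (CV, SEm,
# ICC), one-way repeated-measures ANOVA, paired t-tests, percent change,
# and paired-design power from Cohen's dz.

#' Test-retest reliability: CV, SEm and ICC(3,1)
#'
#' Coefficient of variation (mean over subjects of the within-subject SD of
#' the two visits divided by the subject mean, as a percent; 0/0 counts as
#' 0), intraclass correlation coefficient ICC(3,1) (two-way mixed effects,
#' consistency, single measurement, from the two-way ANOVA mean squares)
#' and the standard error of measurement SEm = SD * sqrt(1 - ICC) with the
#' SD pooled over all observations. Identical visits with zero
#' between-subject variance are reported as CV 0, SEm 0, ICC 1 (degenerate
#' perfect agreement), with a flag.
#'
#' @param visit1,visit2 paired measurements (same subjects, same order)
#' @return list of class `reliability_report`: `cv_pct`, `sem`, `icc`,
#'   `n`, `degenerate`
#' @examples
#' test_retest_reliability(c(10, 12, 14, 16), c(11, 12, 13, 17))
#' @export
test_retest_reliability <- function(visit1, visit2) {
  n <- length(visit1)
  if (length(visit2) != n) stop("visits must have equal length")
  if (n < 2) stop("need at least 2 subjects")

  m <- (visit1 + visit2) / 2
  s <- abs(visit2 - visit1) / sqrt(2)
  cv_each <- ifelse(s == 0, 0, {
    if (any(m == 0 & s > 0))
      stop("CV undefined: a subject has mean 0 with nonzero variability")
    ifelse(m == 0, 0, s / m * 100)
  })
  cv <- mean(cv_each)

  all_vals <- c(visit1, visit2)
  degenerate <- var(all_vals) == 0 || identical(visit1, visit2)
  if (degenerate && all(visit1 == visit2)) {
    icc <- 1
    sem <- 0
  } else {
    icc <- icc31(cbind(visit1, visit2))
    sem <- sd(all_vals) * sqrt(max(0, 1 - icc))
  }
  structure(list(cv_pct = cv, sem = sem, icc = icc, n = n,
                 degenerate = degenerate),
            class = "reliability_report")
}

#' @export
print.reliability_report <- function(x, ...) {
  cat(sprintf("<reliability_report> n = %d: CV %.2f%%, SEm %.3g, ICC %.3f%s\n",
              x$n, x$cv_pct, x$sem, x$icc,
              if (x$degenerate) " (degenerate: identical visits)" else ""))
  invisible(x)
}

# ICC(3,1) from two-way (subject x measurement) ANOVA mean squares:
# (MSR - MSE) / (MSR + (k - 1) MSE).
icc31 <- function(mat) {
  n <- nrow(mat); k <- ncol(mat)
  grand <- mean(mat)
  row_m <- rowMeans(mat)
  col_m <- colMeans(mat)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_tot <- sum((mat - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  if (msr + (k - 1) * mse == 0) return(1)
  (msr - mse) / (msr + (k - 1) * mse)
}

#' One-way repeated-measures ANOVA
#'
#' Classical within-subject F test across timepoints (sphericity assumed):
#' `F = MS_time / MS_error` with df `(t - 1)` and `(n - 1)(t - 1)`, fitted
#' through [stats::aov()] with a subject error stratum.
#'
#' @param data numeric matrix or data frame, subjects in rows, timepoints
#'   in columns, complete
#' @return list with `F`, `df1`, `df2`, `p`
#' @export
rm_anova_oneway <- function(data) {
  mat <- as.matrix(data)
  if (anyNA(mat)) stop("repeated-measures ANOVA requires a complete matrix")
  n <- nrow(mat); k <- ncol(mat)
  if (n < 2 || k < 2) stop("need >= 2 subjects and >= 2 timepoints")
  df1 <- k - 1; df2 <- (n - 1) * (k - 1)
  if (var(as.numeric(mat)) == 0)
    return(list(F = 0, df1 = df1, df2 = df2, p = 1))
  d <- data.frame(
    y = as.numeric(mat),
    subject = factor(rep(seq_len(n), times = k)),
    time = factor(rep(seq_len(k), each = n))
  )
  fit <- stats::aov(y ~ time + Error(subject), data = d)
  tab <- summary(fit)[["Error: Within"]][[1]]
  Fv <- tab["time", "F value"]
  p <- tab["time", "Pr(>F)"]
  if (!is.finite(Fv)) { Fv <- 0; p <- 1 }
  list(F = unname(Fv), df1 = df1, df2 = df2, p = unname(p))
}

#' Paired t-test
#'
#' Two-tailed paired t statistic via [stats::t.test()]. Degenerate cases:
#' identical vectors give `t = 0, p = 1`; a constant nonzero difference
#' gives infinite `t` and `p = 0` with a diagnostic message.
#'
#' @param pre,post paired measurements
#' @return list with `t`, `df`, `p`, `mean_diff`
#' @export
paired_t <- function(pre, post) {
  n <- length(pre)
  if (length(post) != n) stop("pre and post must have equal length")
  if (n < 2) stop("need at least 2 pairs")
  d <- post - pre
  # near-constant differences (t.test's own degeneracy threshold)
  if (sd(d) / sqrt(n) <= 10 * .Machine$double.eps * abs(mean(d)) ||
      sd(d) == 0) {
    if (all(d == 0)) return(list(t = 0, df = n - 1, p = 1, mean_diff = 0))
    message("paired_t: differences have zero variance; t is infinite")
    return(list(t = sign(mean(d)) * Inf, df = n - 1, p = 0,
                mean_diff = mean(d)))
  }
  ht <- stats::t.test(post, pre, paired = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, mean_diff = unname(ht$estimate))
}

#' Percent change
#'
#' `100 * (post - pre) / pre`; negative for a decrease. Reported decrease
#' magnitudes are the absolute value.
#'
#' @param pre,post scalar values, `pre != 0`
#' @return percent change
#' @examples
#' percent_change(2.04, 1.79)  # -12.3
#' @export
percent_change <- function(pre, post) {
  if (any(pre == 0)) stop("percent change undefined for pre = 0")
  100 * (post - pre) / pre
}

#' Power and sample size for a paired two-tailed t-test
#'
#' Exact power from the noncentral t distribution with noncentrality
#' `dz * sqrt(n)` and `n - 1` degrees of freedom.
#'
#' @param d Cohen's dz (paired effect size, > 0)
#' @param n number of pairs (for `power_paired_t`)
#' @param power target power (for `n_for_power_paired_t`)
#' @param alpha two-tailed significance level
#' @return `power_paired_t`: the power; `n_for_power_paired_t`: the
#'   smallest `n` reaching the target power
#' @export
power_paired_t <- function(d, n, alpha = 0.05) {
  stopifnot(d > 0, n >= 2, alpha > 0, alpha < 1)
  tcrit <- qt(1 - alpha / 2, df = n - 1)
  ncp <- d * sqrt(n)
  1 - pt(tcrit, df = n - 1, ncp = ncp) + pt(-tcrit, df = n - 1, ncp = ncp)
}

#' @rdname power_paired_t
#' @export
n_for_power_paired_t <- function(d, power = 0.8, alpha = 0.05) {
  stopifnot(d > 0, power > 0, power < 1)
  for (n in 2:10000)
    if (power_paired_t(d, n, alpha) >= power) return(n)
  stop("target power not reachable with n <= 10000")
}
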
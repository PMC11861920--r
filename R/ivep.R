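#' IVEP outcome rates from raw counts
#'
#' In vitro embryo production (IVEP) rates: the cleavage rate is the
#' percentage of inseminated oocytes with two or more cells 48 h after IVF;
#' the embryonic development rate is day-7 embryos relative to *cleaved*
#' oocytes; the blastocyst rate is blastocysts relative to the oocytes
#' placed in maturation.
#'
#' @param n_oocytes oocytes placed in maturation (> 0).
#' @param n_cleaved zygotes with >= 2 cells at 48 h.
#' @param n_day7_embryos embryos at day 7 (requires `n_cleaved > 0`).
#' @param n_blastocysts blastocysts obtained.
#' @return list with `cleavage`, `embryonic_development`, `blastocyst`
#'   (percent).
#' @export
compute_rates <- function(n_oocytes, n_cleaved, n_day7_embryos,
                          n_blastocysts) {
  stopifnot(n_oocytes > 0, n_cleaved >= 0, n_cleaved <= n_oocytes,
            n_blastocysts >= 0, n_blastocysts <= n_oocytes)
  if (n_cleaved == 0 && n_day7_embryos > 0)
    cd_stop("embryonic development rate undefined with zero cleaved oocytes",
            "cd_undefined_rate")
  stopifnot(n_day7_embryos <= max(n_cleaved, 0))
  list(cleavage = 100 * n_cleaved / n_oocytes,
       embryonic_development = if (n_cleaved > 0)
         100 * n_day7_embryos / n_cleaved else NA_real_,
       blastocyst = 100 * n_blastocysts / n_oocytes)
}

#' Normalize a rate against the reference bull
#'
#' The reference bull is a fertile bull of stable IVEP performance run in
#' every plate; expressing a tested bull's rate as a percentage of the
#' reference rate obtained in the same IVEP routine cancels uncontrolled
#' routine-level variables. Reported at two decimals (round-half-even).
#'
#' @param test_rate tested bull's rate (percent).
#' @param reference_rate reference bull's rate in the same routine (> 0).
#' @return `100 * test_rate / reference_rate`, rounded to two decimals.
#' @export
normalize_rate <- function(test_rate, reference_rate) {
  if (any(reference_rate <= 0))
    cd_stop("reference rate must be positive", "cd_undefined_normalization")
  round(100 * test_rate / reference_rate, 2)
}

#' Per-bull IVEP rates with paired reference-bull rates
#'
#' Loads the packaged example table of cleavage, embryonic development and
#' blastocyst rates for four tested bulls, each paired with the reference
#' bull's rate from the same IVEP routine.
#'
#' @param path CSV path; defaults to the packaged table.
#' @return data.frame with columns `bull`, `cleavage_rate`, `ref_cleavage`,
#'   `embryo_dev_rate`, `ref_embryo_dev`, `blastocyst_rate`,
#'   `ref_blastocyst`.
#' @export
bull_ivep_rates <- function(path = system.file("extdata",
                                               "bull_ivep_rates.csv",
                                               package = "chromadens")) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' Reference-normalize a table of IVEP rates
#'
#' @param rates a data.frame as returned by [bull_ivep_rates()].
#' @return the input with `norm_cleavage`, `norm_embryo_dev`,
#'   `norm_blastocyst` columns appended (percent of reference, two
#'   decimals).
#' @export
normalize_ivep_table <- function(rates = bull_ivep_rates()) {
  rates$norm_cleavage <- normalize_rate(rates$cleavage_rate,
                                        rates$ref_cleavage)
  rates$norm_embryo_dev <- normalize_rate(rates$embryo_dev_rate,
                                          rates$ref_embryo_dev)
  rates$norm_blastocyst <- normalize_rate(rates$blastocyst_rate,
                                          rates$ref_blastocyst)
  rates
}

#' Pearson correlation with exact t-transform p-value
#'
#' Sample Pearson r with the two-sided p-value from
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom.
#' Exactly collinear input (`|r| = 1`) reports `p = 0`.
#'
#' @param x,y numeric vectors of equal length `n >= 3`, each with nonzero
#'   variance.
#' @return list with `r`, `p_value`, `n`.
#' @export
pearson_cor <- function(x, y) {
  n <- length(x)
  if (length(y) != n || n < 3L)
    cd_stop("x and y must have equal length >= 3", "cd_param_error")
  if (var(x) == 0 || var(y) == 0)
    cd_stop("zero variance: correlation undefined", "cd_undefined_correlation")
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  r <- max(min(r, 1), -1)
  p <- if (1 - r^2 < .Machine$double.eps) 0 else {
    t_stat <- r * sqrt((n - 2) / (1 - r^2))
    2 * pt(-abs(t_stat), df = n - 2)
  }
  list(r = r, p_value = p, n = n)
}

#' Odds ratio with Woolf confidence interval
#'
#' For a 2x2 table `(a, b; c, d)`, `OR = (a d) / (b c)` with the Woolf
#' log-normal interval `exp(log(OR) +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`
#' and a two-sided p-value from the normal statistic `log(OR) / SE`. Any
#' zero cell triggers the Haldane-Anscombe correction (+0.5 to all cells),
#' flagged in the result.
#'
#' @param a,b,c,d non-negative cell counts; `a + b > 0` and `c + d > 0`.
#'   Alternatively `a` may be a 2x2 matrix.
#' @param alpha interval level (default 0.05 for a 95% CI).
#' @return list with `or_value`, `ci_low`, `ci_high`, `p_value`,
#'   `continuity_corrected`.
#' @export
odds_ratio <- function(a, b = NULL, c = NULL, d = NULL, alpha = 0.05) {
  if (is.matrix(a)) {
    stopifnot(all(dim(a) == 2L))
    b <- a[1, 2]; c <- a[2, 1]; d <- a[2, 2]; a <- a[1, 1]
  }
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  if (a + b == 0 || c + d == 0)
    cd_stop("a row of the 2x2 table is entirely zero", "cd_degenerate_table")
  corrected <- any(c(a, b, c, d) == 0)
  if (corrected) { a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5 }
  or <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  z <- qnorm(1 - alpha / 2)
  list(or_value = or,
       ci_low = exp(log(or) - z * se),
       ci_high = exp(log(or) + z * se),
       p_value = 2 * pnorm(-abs(log(or) / se)),
       continuity_corrected = corrected)
}

#' Pairwise two-proportion z-tests
#'
#' Pooled-variance two-proportion z-statistics and two-sided p-values for
#' every pair of groups, unadjusted by default.
#'
#' @param successes,totals integer vectors, one entry per group
#'   (`totals > 0`).
#' @param adjust `"none"` (default) or `"bonferroni"`.
#' @return list with matrices `z` (antisymmetric) and `p` (symmetric), and
#'   the group proportions `prop`.
#' @export
compare_proportions_pairwise <- function(successes, totals,
                                         adjust = c("none", "bonferroni")) {
  adjust <- match.arg(adjust)
  k <- length(successes)
  stopifnot(k >= 2L, length(totals) == k, all(totals > 0),
            all(successes >= 0), all(successes <= totals))
  p_hat <- successes / totals
  z <- matrix(0, k, k)
  p <- matrix(1, k, k)
  npairs <- k * (k - 1) / 2
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      pool <- (successes[i] + successes[j]) / (totals[i] + totals[j])
      se <- sqrt(pool * (1 - pool) * (1 / totals[i] + 1 / totals[j]))
      zij <- if (se == 0) 0 else (p_hat[i] - p_hat[j]) / se
      pij <- 2 * pnorm(-abs(zij))
      if (adjust == "bonferroni") pij <- min(1, pij * npairs)
      z[i, j] <- zij; z[j, i] <- -zij
      p[i, j] <- pij; p[j, i] <- pij
    }
  }
  rn <- names(successes) %||% paste0("g", seq_len(k))
  dimnames(z) <- dimnames(p) <- list(rn, rn)
  list(z = z, p = p, prop = stats::setNames(p_hat, rn))
}

#' Scott-Knott clustering of treatment means
#'
#' Partitions treatment means into non-overlapping homogeneous groups by
#' recursive binary splitting of the sorted means. At each node the split
#' maximizing the between-group sum of squares B0 is tested with the
#' likelihood-ratio statistic `lambda = pi / (2 * (pi - 2)) * B0 / s0^2`
#' against the chi-squared critical value on `k / (pi - 2)` degrees of
#' freedom, where `s0^2` pools the dispersion of the node's means with the
#' externally supplied error mean square (MSE / replicates, weighted by the
#' error degrees of freedom). A significant split recurses into both halves;
#' otherwise the node is one homogeneous group. Groups are always contiguous
#' in sorted-mean order.
#'
#' @param means treatment means.
#' @param treatment_sizes replicates per treatment (used as `MSE / r` for
#'   the variance of a mean; unequal sizes enter through their mean).
#' @param error_mean_square error mean square from the surrounding ANOVA.
#' @param error_df its degrees of freedom.
#' @param alpha significance level (default 0.05).
#' @return A `scott_knott` list: data.frame `groups` with `treatment`,
#'   `mean`, `group` (1 = highest-mean group; contiguous in sorted order),
#'   plus `alpha`.
#' @export
scott_knott <- function(means, treatment_sizes, error_mean_square, error_df,
                        alpha = 0.05) {
  k_all <- length(means)
  stopifnot(k_all >= 2L, error_mean_square > 0, error_df >= 1,
            length(treatment_sizes) == k_all || length(treatment_sizes) == 1L)
  if (length(treatment_sizes) == 1L)
    treatment_sizes <- rep(treatment_sizes, k_all)
  trt <- names(means) %||% paste0("t", seq_len(k_all))
  ord <- order(means, decreasing = TRUE)
  m_sorted <- means[ord]
  s2y <- error_mean_square / mean(treatment_sizes)
  v <- error_df
  groups_sorted <- integer(k_all)
  next_group <- 1L
  recurse <- function(lo, hi) {
    k <- hi - lo + 1L
    if (k == 1L) {
      groups_sorted[lo] <<- next_group
      next_group <<- next_group + 1L
      return(invisible())
    }
    m <- m_sorted[lo:hi]
    # best split maximizing between-group sum of squares
    b0 <- -Inf; jbest <- 1L
    tot <- sum(m)
    for (j in seq_len(k - 1L)) {
      t1 <- sum(m[1:j])
      b <- t1^2 / j + (tot - t1)^2 / (k - j) - tot^2 / k
      if (b > b0) { b0 <- b; jbest <- j }
    }
    s0_2 <- (sum((m - mean(m))^2) + v * s2y) / (k + v)
    lambda <- if (s0_2 > 0) pi / (2 * (pi - 2)) * b0 / s0_2 else 0
    crit <- qchisq(1 - alpha, df = k / (pi - 2))
    if (b0 > 0 && lambda > crit) {
      recurse(lo, lo + jbest - 1L)
      recurse(lo + jbest, hi)
    } else {
      groups_sorted[lo:hi] <<- next_group
      next_group <<- next_group + 1L
    }
    invisible()
  }
  recurse(1L, k_all)
  df <- data.frame(treatment = trt[ord], mean = as.numeric(m_sorted),
                   group = groups_sorted)
  structure(list(groups = df, alpha = alpha), class = "scott_knott")
}

#' @export
print.scott_knott <- function(x, ...) {
  cat(sprintf("<scott_knott> %d treatments in %d groups (alpha = %g)\n",
              nrow(x$groups), max(x$groups$group), x$alpha))
  print(x$groups, row.names = FALSE)
  invisible(x)
}
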
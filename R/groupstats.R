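#' Genotype group comparison of regional SUVRs
#'
#' Unpaired two-tailed t-test between wild-type and transgenic SUVRs of one
#' region. The default is the pooled-variance (Student) test with
#' `df = n1 + n2 - 2`; Welch's unequal-variance test is available behind
#' `welch = TRUE`. The percent difference is WT-referenced and computed
#' from group means, `100 (mean_WT - mean_TG) / mean_WT`, and no
#' multiple-comparison correction is applied. Significance tiers:
#' `***` p < 0.001, `**` p < 0.01, `*` p <= 0.05, `ns` otherwise.
#'
#' @param values numeric SUVR (or any per-subject summary) values.
#' @param genotype character/factor, `"WT"` or `"APP/PS1"`, per value.
#' @param region region label carried into the result.
#' @param welch use Welch's test instead of the pooled test.
#' @return An object of class `group_comparison`.
#' @export
compare_groups <- function(values, genotype, region = "", welch = FALSE) {
  genotype <- as.character(genotype)
  bad <- setdiff(unique(genotype), c("WT", "APP/PS1"))
  if (length(bad) > 0L)
    stop("unknown genotype label(s): ", paste(bad, collapse = ", "))
  g1 <- values[genotype == "WT"]
  g2 <- values[genotype == "APP/PS1"]
  if (length(g1) < 2L || length(g2) < 2L)
    stop("each genotype group needs at least 2 subjects")
  compare_from_summary(length(g1), mean(g1), stats::sd(g1),
                       length(g2), mean(g2), stats::sd(g2),
                       region = region, welch = welch)
}

#' Group comparison from printed summary statistics
#'
#' The same comparison as [compare_groups()] but computed from group sizes,
#' means and standard deviations — e.g. the moments printed in a paper's
#' summary table. Group 1 is the wild-type/control group, group 2 the
#' transgenic group.
#'
#' @param n1,mean1,sd1 size, mean and SD of the WT group.
#' @param n2,mean2,sd2 size, mean and SD of the transgenic group.
#' @inheritParams compare_groups
#' @return An object of class `group_comparison` with the group moments,
#'   `mean_difference`, `pct_difference`, `t_statistic`, `df`, `p_value`
#'   and `significance`.
#' @examples
#' compare_from_summary(9, 1.47, 0.04, 9, 1.36, 0.08, region = "HC")
#' @export
compare_from_summary <- function(n1, mean1, sd1, n2, mean2, sd2,
                                 region = "", welch = FALSE) {
  if (n1 < 2 || n2 < 2) stop("group sizes must be at least 2")
  if (!is.finite(sd1) || !is.finite(sd2) || sd1 <= 0 || sd2 <= 0)
    stop("group SDs must be positive")
  diff <- mean1 - mean2
  if (welch) {
    v1 <- sd1^2 / n1
    v2 <- sd2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  }
  tstat <- diff / se
  p <- 2 * stats::pt(-abs(tstat), df)
  structure(list(region = region, n1 = n1, mean1 = mean1, sd1 = sd1,
                 n2 = n2, mean2 = mean2, sd2 = sd2,
                 mean_difference = diff,
                 pct_difference = 100 * diff / mean1,
                 t_statistic = tstat, df = df, p_value = p,
                 significance = significance_tier(p),
                 welch = isTRUE(welch)),
            class = "group_comparison")
}

significance_tier <- function(p) {
  if (p < 0.001) "***" else if (p < 0.01) "**" else if (p <= 0.05) "*"
  else "ns"
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf(
    "Group comparison%s (%s t-test)\n  WT: n = %d, %.3f +/- %.3f; APP/PS1: n = %d, %.3f +/- %.3f\n  diff = %.3f (%.1f%% lower in APP/PS1), t(%.4g) = %.3f, p = %.4g %s\n",
    if (nzchar(x$region)) paste0(", region ", x$region) else "",
    if (x$welch) "Welch" else "pooled", x$n1, x$mean1, x$sd1,
    x$n2, x$mean2, x$sd2, x$mean_difference, x$pct_difference,
    x$df, x$t_statistic, x$p_value, x$significance))
  invisible(x)
}

#' Cohen's d from group moments
#'
#' Standardized mean difference with the equal-allocation pooled SD
#' `sqrt((sd1^2 + sd2^2) / 2)` — the convention of a priori power analysis
#' for two independent means.
#'
#' @param mean1,sd1,mean2,sd2 group means and SDs (SDs > 0).
#' @return Nonnegative effect size `d`.
#' @examples
#' cohens_d(1.47, 0.04, 1.36, 0.08) # about 1.739
#' @export
cohens_d <- function(mean1, sd1, mean2, sd2) {
  if (!is.finite(sd1) || !is.finite(sd2) || sd1 <= 0 || sd2 <= 0)
    stop("SDs must be positive")
  abs(mean1 - mean2) / sqrt((sd1^2 + sd2^2) / 2)
}

#' Exact power of the two-sample t-test
#'
#' Power of an unpaired t-test with `n` subjects per group at effect size
#' `d`, computed exactly from the noncentral t distribution:
#' `df = 2n - 2`, noncentrality `d sqrt(n/2)`, critical value from the
#' central t at `alpha` (one-tailed) or `alpha/2` (two-tailed; both
#' rejection regions counted).
#'
#' @param n per-group sample size (>= 2).
#' @param d Cohen's d.
#' @param alpha significance level.
#' @param tails 1 or 2.
#' @return Power in (0, 1).
#' @export
power_t2 <- function(n, d, alpha = 0.05, tails = 2) {
  if (any(n < 2)) stop("n must be at least 2 per group")
  if (!(tails %in% c(1, 2))) stop("tails must be 1 or 2")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  df <- 2 * n - 2
  ncp <- d * sqrt(n / 2)
  if (tails == 1) {
    tcrit <- stats::qt(1 - alpha, df)
    stats::pt(tcrit, df, ncp, lower.tail = FALSE)
  } else {
    tcrit <- stats::qt(1 - alpha / 2, df)
    stats::pt(tcrit, df, ncp, lower.tail = FALSE) + stats::pt(-tcrit, df, ncp)
  }
}

#' Minimal per-group sample size for target power
#'
#' Smallest integer `n >= 2` such that the exact noncentral-t power of the
#' unpaired t-test reaches the target, found by increment-and-test. The
#' returned object also certifies minimality: the power at `n - 1` is below
#' the target.
#'
#' @param d Cohen's d (> 0).
#' @param power target power in (0, 1).
#' @inheritParams power_t2
#' @param n_max search cap.
#' @return An object of class `power_result`: `cohen_d`, `n_per_group`,
#'   `achieved_power`, `alpha`, `tails`, `power_target`.
#' @examples
#' required_n(cohens_d(1.47, 0.04, 1.36, 0.08), power = 0.9, tails = 2)
#' @export
required_n <- function(d, power = 0.80, alpha = 0.05, tails = 2,
                       n_max = 10000L) {
  if (!is.finite(d) || d <= 0) stop("d must be positive")
  if (power <= 0 || power >= 1) stop("target power must be in (0, 1)")
  n <- 2L
  while (power_t2(n, d, alpha, tails) < power) {
    n <- n + 1L
    if (n > n_max) stop("no n <= ", n_max, " reaches the target power")
  }
  structure(list(cohen_d = d, n_per_group = n,
                 achieved_power = power_t2(n, d, alpha, tails),
                 alpha = alpha, tails = tails, power_target = power),
            class = "power_result")
}

#' @export
print.power_result <- function(x, ...) {
  cat(sprintf(
    "Power analysis (d = %.3f, alpha = %g, %d-tailed)\n  n = %d per group for %.0f%% power (achieved %.1f%%)\n",
    x$cohen_d, x$alpha, x$tails, x$n_per_group, 100 * x$power_target,
    100 * x$achieved_power))
  invisible(x)
}

#' Sample-size grid from group moments
#'
#' The full a priori sample-size table for one comparison: minimal
#' per-group n for every combination of tails and target power, from the
#' group means and SDs.
#'
#' @inheritParams cohens_d
#' @param powers target powers.
#' @param tails tail options.
#' @param alpha significance level.
#' @return Data frame with columns `tails`, `power`, `n_per_group`,
#'   `achieved_power` and attribute `cohen_d`.
#' @export
power_grid <- function(mean1, sd1, mean2, sd2, powers = c(0.80, 0.90),
                       tails = c(1, 2), alpha = 0.05) {
  d <- cohens_d(mean1, sd1, mean2, sd2)
  grid <- expand.grid(power = powers, tails = tails)[, c("tails", "power")]
  res <- mapply(function(tl, pw) required_n(d, pw, alpha, tl),
                grid$tails, grid$power, SIMPLIFY = FALSE)
  grid$n_per_group <- vapply(res, function(r) r$n_per_group, integer(1))
  grid$achieved_power <- vapply(res, function(r) r$achieved_power, numeric(1))
  attr(grid, "cohen_d") <- d
  grid
}

#' Association between brain uptake and injected tracer mass
#'
#' Ordinary least-squares slope and Pearson correlation (with two-tailed p)
#' of per-subject brain SUV against the administered tracer mass — the
#' standard check that the injected mass stayed in the tracer-dose regime
#' (no detectable mass effect on uptake).
#'
#' @param suv per-subject brain SUV values.
#' @param mass injected mass per subject (microgram/kg).
#' @return List of class `mass_association` with `slope`, `intercept`, `r`,
#'   `p_value`, `n`.
#' @export
mass_association <- function(suv, mass) {
  if (length(suv) != length(mass)) stop("suv and mass lengths differ")
  if (length(suv) < 3L) stop("need at least 3 subjects")
  if (stats::sd(mass) == 0) stop("injected mass has zero variance")
  slope <- stats::cov(mass, suv) / stats::var(mass)
  if (stats::sd(suv) == 0) {
    r <- 0; p <- 1  # flat response: no association by definition
  } else {
    ct <- stats::cor.test(mass, suv, method = "pearson")
    r <- unname(ct$estimate); p <- ct$p.value
  }
  structure(list(slope = slope,
                 intercept = mean(suv) - slope * mean(mass),
                 r = r, p_value = p,
                 n = length(suv)),
            class = "mass_association")
}

#' @export
print.mass_association <- function(x, ...) {
  cat(sprintf(
    "SUV ~ injected mass (n = %d): slope = %.4g, r = %.3f, p = %.3g\n",
    x$n, x$slope, x$r, x$p_value))
  invisible(x)
}
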
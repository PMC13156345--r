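#' Geometric mean with confidence interval
#'
#' `exp` of the mean log value, with the t-based confidence interval on
#' the log scale: `exp(mean(ln x) +/- t * sd(ln x) / sqrt(n))`.
#'
#' @param values Positive values.
#' @param level Confidence level (default 0.90, the standard level for
#'   pharmacokinetic interaction assessment).
#' @return Named vector `c(gm, ci_low, ci_high)`; the CI is NA at n = 1.
#' @export
geometric_mean_ci <- function(values, level = 0.90) {
  if (any(!is.finite(values)) || any(values <= 0))
    stop("all values must be positive", call. = FALSE)
  n <- length(values)
  lx <- log(values)
  gm <- exp(mean(lx))
  if (n < 2L)
    return(c(gm = gm, ci_low = NA_real_, ci_high = NA_real_))
  half <- stats::qt((1 + level) / 2, n - 1) * stats::sd(lx) / sqrt(n)
  c(gm = gm, ci_low = exp(mean(lx) - half),
    ci_high = exp(mean(lx) + half))
}

#' No-effect decision against equivalence bounds
#'
#' The interaction call of the crossover analysis: no pharmacokinetic
#' interaction is evident if and only if the whole confidence interval
#' of the geometric mean ratio lies inside the pre-defined no-effect
#' range (closed bounds).
#'
#' @param ci_low,ci_high Confidence bounds of the GMR.
#' @param bounds No-effect range, default `c(0.80, 1.25)`.
#' @return `"no_interaction"` or `"interaction_possible"`; NA when a
#'   bound is missing.
#' @export
no_effect_decision <- function(ci_low, ci_high, bounds = c(0.80, 1.25)) {
  if (is.na(ci_low) || is.na(ci_high)) return(NA_character_)
  if (ci_low > ci_high) stop("'ci_low' must be <= 'ci_high'", call. = FALSE)
  if (ci_low >= bounds[1L] && ci_high <= bounds[2L]) "no_interaction"
  else "interaction_possible"
}

#' Paired geometric-mean-ratio analysis of a crossover endpoint
#'
#' The within-subject analysis of a two-period crossover: for paired
#' positive endpoint values, the log differences `d_i = ln(exposure_i) -
#' ln(baseline_i)` give the geometric mean ratio `exp(mean d)`, its
#' t-based confidence interval, the two-sided paired t-test p-value, and
#' the no-effect decision. Per-period geometric means with their own
#' intervals are reported alongside.
#'
#' @param baseline,exposure Positive paired endpoint values, one pair
#'   per subject (same order).
#' @param level Confidence level (default 0.90).
#' @param bounds No-effect range for the decision.
#' @return Object of class `paired_gmr`.
#' @export
paired_gmr <- function(baseline, exposure, level = 0.90,
                       bounds = c(0.80, 1.25)) {
  if (length(baseline) != length(exposure))
    stop("'baseline' and 'exposure' must be paired", call. = FALSE)
  ok <- !is.na(baseline) & !is.na(exposure)
  baseline <- baseline[ok]; exposure <- exposure[ok]
  n <- length(baseline)
  if (n < 2L) stop("need at least 2 complete pairs", call. = FALSE)
  if (any(baseline <= 0) || any(exposure <= 0))
    stop("all endpoint values must be positive", call. = FALSE)

  d <- log(exposure) - log(baseline)
  gmr <- exp(mean(d))
  sd_d <- stats::sd(d)
  degenerate <- sd_d < 1e-12
  if (degenerate) {
    ci <- c(gmr, gmr)
    p <- if (abs(mean(d)) < 1e-12) 1 else NA_real_
  } else {
    half <- stats::qt((1 + level) / 2, n - 1) * sd_d / sqrt(n)
    ci <- exp(mean(d) + c(-1, 1) * half)
    p <- stats::t.test(d)$p.value
  }
  structure(list(n = n, gmr = gmr, ci_low = ci[1L], ci_high = ci[2L],
                 p_value = p, level = level, bounds = bounds,
                 decision = no_effect_decision(ci[1L], ci[2L], bounds),
                 degenerate_variance = degenerate,
                 gm_baseline = geometric_mean_ci(baseline, level),
                 gm_exposure = geometric_mean_ci(exposure, level)),
            class = "paired_gmr")
}

#' @export
print.paired_gmr <- function(x, digits = 3, ...) {
  fmt <- function(v) if (is.na(v)) "-" else format(signif(v, digits))
  cat(sprintf("Paired GMR (n = %d, %g%% CI)\n", x$n, 100 * x$level))
  cat("  baseline GM ", fmt(x$gm_baseline["gm"]), " (",
      fmt(x$gm_baseline["ci_low"]), "-", fmt(x$gm_baseline["ci_high"]),
      ")\n", sep = "")
  cat("  exposure GM ", fmt(x$gm_exposure["gm"]), " (",
      fmt(x$gm_exposure["ci_low"]), "-", fmt(x$gm_exposure["ci_high"]),
      ")\n", sep = "")
  cat("  GMR ", fmt(x$gmr), " (", fmt(x$ci_low), "-", fmt(x$ci_high),
      "), p = ", if (is.na(x$p_value)) "-" else
        format(round(x$p_value, 4)), "\n", sep = "")
  cat("  decision vs (", x$bounds[1L], ", ", x$bounds[2L], "): ",
      x$decision, "\n", sep = "")
  invisible(x)
}

# effect size (noncentrality per sqrt(n)) for the paired design
.paired_effect <- function(cv, delta, scale) {
  switch(scale,
         proportional = delta / cv,
         log = log(1 + delta) / sqrt(log(1 + cv^2)))
}

#' Power of the two-tailed paired t-test for a proportional change
#'
#' Noncentral-t power of detecting a `delta` proportional change in an
#' endpoint whose intra-individual coefficient of variation is `cv`,
#' with n paired subjects: `P(|T'| > t_{1-alpha/2, n-1})` for a
#' noncentral t with df `n - 1` and noncentrality `(delta / cv) *
#' sqrt(n)`. The default effect-size convention works on the
#' proportional-change scale; `scale = "log"` substitutes the
#' log-normal convention `d = ln(1 + delta) / sqrt(ln(1 + cv^2))`.
#'
#' @param n Number of paired subjects (>= 2).
#' @param cv Intra-individual CV (fraction), > 0.
#' @param delta Detectable proportional change (fraction), default 0.20.
#' @param alpha Two-sided type-I error, default 0.05.
#' @param scale Effect-size convention, `"proportional"` or `"log"`.
#' @return Power in (0, 1).
#' @export
power_paired <- function(n, cv, delta = 0.20, alpha = 0.05,
                         scale = c("proportional", "log")) {
  scale <- match.arg(scale)
  if (n < 2) stop("'n' must be at least 2", call. = FALSE)
  if (cv <= 0 || delta < 0 || alpha <= 0 || alpha >= 1)
    stop("invalid cv/delta/alpha", call. = FALSE)
  ncp <- .paired_effect(cv, delta, scale) * sqrt(n)
  crit <- stats::qt(1 - alpha / 2, n - 1)
  1 - stats::pt(crit, n - 1, ncp) + stats::pt(-crit, n - 1, ncp)
}

#' Sample size of the paired design
#'
#' The smallest n >= 2 whose [power_paired()] reaches the target.
#'
#' @inheritParams power_paired
#' @param power_target Required power, in (0, 1); default 0.80.
#' @param n_max Search bound.
#' @return Integer sample size.
#' @export
sample_size_paired <- function(cv, delta = 0.20, alpha = 0.05,
                               power_target = 0.80,
                               scale = c("proportional", "log"),
                               n_max = 1e6) {
  scale <- match.arg(scale)
  if (power_target <= 0 || power_target >= 1)
    stop("'power_target' must lie in (0, 1)", call. = FALSE)
  for (n in 2:n_max) {
    if (power_paired(n, cv, delta, alpha, scale) >= power_target)
      return(as.integer(n))
  }
  stop("power target unattainable within n <= ", n_max, call. = FALSE)
}

#' Monte-Carlo power of the paired t-test
#'
#' Validation twin of [power_paired()]: simulates per-subject paired
#' differences as Normal(`true_shift`, `cv`) and returns the fraction of
#' replicates in which the two-sided one-sample t-test rejects at
#' `alpha`.
#'
#' @param n Paired subjects per replicate.
#' @param cv Standard deviation of the differences (the intra-individual
#'   CV on the proportional scale).
#' @param true_shift True mean difference (0 gives the type-I error).
#' @param alpha Two-sided significance level.
#' @param n_reps Number of replicates (>= 1000).
#' @param seed RNG seed.
#' @return Rejection fraction.
#' @export
empirical_power <- function(n, cv, true_shift = 0.20, alpha = 0.05,
                            n_reps = 10000, seed = 1L) {
  if (n_reps < 1000) stop("'n_reps' must be at least 1000", call. = FALSE)
  set.seed(seed)
  draws <- matrix(stats::rnorm(n * n_reps, true_shift, cv), n, n_reps)
  means <- colMeans(draws)
  sds <- sqrt(colSums(sweep(draws, 2, means)^2) / (n - 1))
  tstat <- means / (sds / sqrt(n))
  crit <- stats::qt(1 - alpha / 2, n - 1)
  mean(abs(tstat) > crit)
}
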
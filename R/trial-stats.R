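#' Trial summary statistics
#'
#' Geometric means with confidence intervals, per-participant relative
#' bioavailability, paired log-scale tests with Bonferroni adjustment, the
#' paired sample-size calculation on the log scale, and one-way ANOVA with
#' Bonferroni-corrected pairwise comparisons. All ratio-scale quantities
#' (FIA, bioavailability ratios) are analysed on the log scale, matching their
#' lognormal-like distribution.
#'
#' @name trial_stats
NULL

#' Geometric mean with a t-based confidence interval
#'
#' `GM = exp(mean(log x))`; the CI exponentiates the usual t interval for the
#' mean of the logs.
#'
#' @param values positive numeric vector, length >= 2.
#' @param level confidence level (default 0.95).
#' @return list with `gm`, `ci_lo`, `ci_hi`, `n`, `level`.
#' @export
#' @examples
#' geometric_mean_ci(c(1, 100))$gm # 10
geometric_mean_ci <- function(values, level = 0.95) {
  if (any(!is.finite(values)) || any(values <= 0)) {
    stop("all values must be positive and finite")
  }
  n <- length(values)
  if (n < 2) stop("need at least 2 values for a confidence interval")
  lx <- log(values)
  m <- mean(lx)
  se <- stats::sd(lx) / sqrt(n)
  tq <- stats::qt(1 - (1 - level) / 2, df = n - 1)
  list(gm = exp(m), ci_lo = exp(m - tq * se), ci_hi = exp(m + tq * se),
       n = n, level = level)
}

#' Relative bioavailability of a test compound versus a reference
#'
#' Per-participant ratios `FIA_test / FIA_ref`, summarized as a geometric
#' mean with CI. For complete pairs the GM of the individual ratios equals
#' the ratio of the two condition GMs exactly; both are reported so the
#' identity can be audited.
#'
#' @param fia_test,fia_ref equal-length positive vectors, paired by
#'   participant.
#' @param level confidence level for the summary.
#' @return list with `ratios`, `summary` (from [geometric_mean_ci()]) and
#'   `gm_ratio_of_gms`.
#' @export
relative_bioavailability <- function(fia_test, fia_ref, level = 0.95) {
  if (length(fia_test) != length(fia_ref)) {
    stop("paired vectors must have equal length")
  }
  if (any(fia_test <= 0) || any(fia_ref <= 0)) {
    stop("FIA values must be positive")
  }
  ratios <- fia_test / fia_ref
  list(ratios = ratios,
       summary = geometric_mean_ci(ratios, level = level),
       gm_ratio_of_gms = exp(mean(log(fia_test))) / exp(mean(log(fia_ref))))
}

#' Paired t-test on log-transformed values with Bonferroni adjustment
#'
#' Two-sided paired t-test of `log(test) - log(ref)`; the raw p-value is
#' multiplied by the number of prespecified comparisons `k` and capped at 1.
#'
#' @param fia_test,fia_ref equal-length positive paired vectors, n >= 3.
#' @param k number of comparisons in the Bonferroni family.
#' @return list with `t`, `df`, `p_raw`, `p_adj`, `gm_ratio`.
#' @export
paired_test_bonferroni <- function(fia_test, fia_ref, k = 1) {
  if (length(fia_test) != length(fia_ref)) {
    stop("paired vectors must have equal length")
  }
  if (length(fia_test) < 3) stop("need at least 3 pairs")
  if (k < 1) stop("k must be at least 1")
  if (any(fia_test <= 0) || any(fia_ref <= 0)) {
    stop("values must be positive for log transformation")
  }
  d <- log(fia_test) - log(fia_ref)
  if (stats::sd(d) == 0) {
    if (all(d == 0)) {
      return(list(t = 0, df = length(d) - 1, p_raw = 1, p_adj = 1,
                  gm_ratio = exp(mean(d))))
    }
    stop("degenerate paired differences: zero variance with nonzero shift")
  }
  tt <- stats::t.test(d)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_raw = tt$p.value, p_adj = min(1, k * tt$p.value),
       gm_ratio = exp(mean(d)))
}

#' Sample size for a paired test of a log-scale ratio
#'
#' Smallest number of pairs giving at least the target power for a two-sided
#' paired test of the shift `log(detect_ratio)` when the SD of the paired
#' log-differences is `sd_log_diff`. The log base and an optional Bonferroni
#' division of alpha are explicit arguments because published power
#' statements often leave both implicit; `sample_size_conventions()` sweeps
#' the standard combinations.
#'
#' @param sd_log_diff SD of paired differences of log FIA, in `log_base`
#'   units.
#' @param detect_ratio ratio to resolve (> 1), e.g. 1.30 for a 30%
#'   difference.
#' @param power target power (default 0.80).
#' @param alpha two-sided type-I error (default 0.05).
#' @param n_comparisons Bonferroni divisor applied to alpha (default 1).
#' @param log_base base in which `sd_log_diff` is expressed (default
#'   `exp(1)`; use 10 for common logs).
#' @param method `"normal"` for the closed-form normal approximation
#'   `ceiling((z_{1-a/2} + z_{power})^2 (sd/delta)^2)` or `"noncentral_t"`
#'   for the iterative exact paired-t solver.
#' @return required n (integer, minimum 2).
#' @export
sample_size_paired_log <- function(sd_log_diff, detect_ratio, power = 0.80,
                                   alpha = 0.05, n_comparisons = 1,
                                   log_base = exp(1),
                                   method = c("normal", "noncentral_t")) {
  method <- match.arg(method)
  if (detect_ratio <= 1) stop("detect_ratio must exceed 1")
  if (!(power > 0 && power < 1) || !(alpha > 0 && alpha < 1)) {
    stop("power and alpha must lie in (0, 1)")
  }
  if (sd_log_diff < 0) stop("sd_log_diff must be non-negative")
  delta <- log(detect_ratio, base = log_base)
  a <- alpha / n_comparisons
  if (sd_log_diff == 0) return(2L)
  n <- if (method == "normal") {
    ceiling((stats::qnorm(1 - a / 2) + stats::qnorm(power))^2 *
              (sd_log_diff / delta)^2)
  } else {
    ceiling(stats::power.t.test(delta = delta, sd = sd_log_diff,
                                sig.level = a, power = power,
                                type = "paired")$n)
  }
  max(2L, as.integer(n))
}

#' Sweep the standard conventions of the paired sample-size calculation
#'
#' Evaluates [sample_size_paired_log()] over natural vs common logs, with and
#' without a Bonferroni division of alpha by the number of prespecified
#' comparisons, and both solvers. Published sample sizes frequently omit
#' which combination was used; the sweep shows the bracket the conventions
#' span rather than asserting one.
#'
#' @inheritParams sample_size_paired_log
#' @param n_comparisons Bonferroni divisors to sweep (default `c(1, 4)`).
#' @return data.frame with `log_base`, `n_comparisons`, `method`, `n`.
#' @export
sample_size_conventions <- function(sd_log_diff = 0.223, detect_ratio = 1.30,
                                    power = 0.80, alpha = 0.05,
                                    n_comparisons = c(1, 4)) {
  grid <- expand.grid(log_base = c(exp(1), 10), n_comparisons = n_comparisons,
                      method = c("normal", "noncentral_t"),
                      stringsAsFactors = FALSE)
  grid$n <- vapply(seq_len(nrow(grid)), function(i) {
    sample_size_paired_log(sd_log_diff, detect_ratio, power, alpha,
                           n_comparisons = grid$n_comparisons[i],
                           log_base = grid$log_base[i],
                           method = grid$method[i])
  }, integer(1))
  grid
}

#' Inflate a sample size for expected dropout
#'
#' `floor(n * (1 + rate))` by default (multiply-then-floor); dividing by
#' `1 - rate` is available behind `method = "divide"`.
#'
#' @param n estimated completers.
#' @param rate expected dropout fraction in \[0, 1).
#' @param method `"multiply"` (default) or `"divide"`.
#' @return recruited n.
#' @export
#' @examples
#' inflate_for_dropout(44, 0.20) # 52
inflate_for_dropout <- function(n, rate, method = c("multiply", "divide")) {
  method <- match.arg(method)
  if (rate < 0 || rate >= 1) stop("dropout rate must lie in [0, 1)")
  if (n < 1) stop("n must be at least 1")
  if (method == "multiply") as.integer(floor(n * (1 + rate)))
  else as.integer(ceiling(n / (1 - rate)))
}

#' One-way ANOVA with Bonferroni-corrected pairwise comparisons
#'
#' Overall F-test across groups plus all pairwise Welch t-tests, each p-value
#' multiplied by the number of pairs and capped at 1.
#'
#' @param values numeric response.
#' @param groups grouping factor/character, each level with n >= 2.
#' @return list with `f`, `p_f`, and `pairwise` (data.frame `group1`,
#'   `group2`, `p_raw`, `p_adj`).
#' @export
groupwise_anova_bonferroni <- function(values, groups) {
  groups <- as.factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  sizes <- table(groups)
  if (any(sizes < 2)) {
    stop("every group needs n >= 2 (violated by: ",
         paste(names(sizes)[sizes < 2], collapse = ", "), ")")
  }
  fit <- stats::aov(values ~ groups)
  s <- summary(fit)[[1]]
  pairs <- utils::combn(levels(groups), 2)
  k <- ncol(pairs)
  pw <- do.call(rbind, lapply(seq_len(k), function(i) {
    g1 <- pairs[1, i]; g2 <- pairs[2, i]
    p <- stats::t.test(values[groups == g1], values[groups == g2])$p.value
    data.frame(group1 = g1, group2 = g2, p_raw = p, p_adj = min(1, k * p))
  }))
  list(f = s[["F value"]][1], p_f = s[["Pr(>F)"]][1], pairwise = pw)
}

#' Summarize absorption records per condition
#'
#' @param records as from [process_trial()].
#' @param level confidence level.
#' @return data.frame with one row per condition: `condition_id`, `gm`,
#'   `ci_lo`, `ci_hi`, `n`.
#' @export
summarize_fia <- function(records, level = 0.95) {
  out <- do.call(rbind, lapply(split(records, records$condition_id),
                               function(g) {
    s <- geometric_mean_ci(g$fia, level = level)
    data.frame(condition_id = g$condition_id[1], gm = s$gm, ci_lo = s$ci_lo,
               ci_hi = s$ci_hi, n = s$n)
  }))
  rownames(out) <- NULL
  out
}
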
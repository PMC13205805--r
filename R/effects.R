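#' Daily wound-area reduction
#'
#' The per-period healing rate: `(area_start - area_end) / period_days`, in
#' cm^2/day. Negative values indicate wound enlargement and are returned as
#' such.
#'
#' @param area_start,area_end Wound areas (cm^2) at the start and end of the
#'   period; must be >= 0. Vectorized.
#' @param period_days Period length in days; must be > 0.
#' @return Numeric vector of daily reductions (cm^2/day).
#' @export
#' @examples
#' daily_reduction(10, 8.6, 14)  # 0.1
daily_reduction <- function(area_start, area_end, period_days = 14) {
  if (any(!is.finite(period_days)) || any(period_days <= 0)) {
    stop("period_days must be > 0", call. = FALSE)
  }
  if (any(area_start < 0) || any(area_end < 0)) {
    stop("wound areas must be >= 0", call. = FALSE)
  }
  (area_start - area_end) / period_days
}

#' Per-patient daily reductions of a cohort
#'
#' Convenience accessor returning one row per patient with the ES and placebo
#' daily reductions, their within-subject difference, and the reductions
#' arranged by trial period (period 1 is whichever treatment the patient's
#' sequence delivered first).
#'
#' @param cohort A [pi_cohort].
#' @return Data frame with columns `patient_id`, `sequence`, `red_es`,
#'   `red_pl`, `diff` (ES minus placebo), `red_p1`, `red_p2`.
#' @export
daily_reductions <- function(cohort) {
  validate_pi_cohort(cohort)
  rec <- cohort$records
  L <- cohort$period_length_days
  red_es <- daily_reduction(rec$area_es_start, rec$area_es_end, L)
  red_pl <- daily_reduction(rec$area_pl_start, rec$area_pl_end, L)
  es_first <- rec$sequence == "ES_first"
  data.frame(
    patient_id = rec$patient_id,
    sequence = rec$sequence,
    red_es = red_es,
    red_pl = red_pl,
    diff = red_es - red_pl,
    red_p1 = ifelse(es_first, red_es, red_pl),
    red_p2 = ifelse(es_first, red_pl, red_es),
    stringsAsFactors = FALSE
  )
}

#' Primary within-subject effect estimates for a crossover cohort
#'
#' Computes the primary crossover-appropriate effect: the mean within-subject
#' difference in daily wound-area reduction (ES minus placebo), with a
#' two-sided Student-t confidence interval on n-1 degrees of freedom, the
#' paired t-test p-value, and the exact Wilcoxon signed-rank p-value as a
#' robustness check (zero differences dropped, ties mid-ranked). Also returns
#' the period means and the secondary healing acceleration ratios.
#'
#' @param cohort A [pi_cohort] with at least 2 patients.
#' @param confidence Two-sided confidence level (default 0.95).
#' @return An object of class `pi_effects` with elements `delta_mean`,
#'   `delta_ci_low`, `delta_ci_high`, `p_paired_t`, `p_wilcoxon`,
#'   `mean_red_es`, `mean_red_pl`, `r_mean`, `r_median_based`, `r_trimmed`
#'   (`NA` until filled from a bootstrap), `n`, and `degenerate` flags.
#' @export
estimate_effects <- function(cohort, confidence = 0.95) {
  reds <- daily_reductions(cohort)
  n <- nrow(reds)
  if (n < 2) stop("inference error: need >= 2 patients", call. = FALSE)
  d <- reds$diff
  delta <- mean(d)
  degenerate <- stats::sd(d) == 0

  if (degenerate) {
    ci <- c(delta, delta)
    p_t <- if (delta == 0) 1 else NA_real_
    p_w <- NA_real_
  } else {
    tt <- stats::t.test(d, conf.level = confidence)
    ci <- as.numeric(tt$conf.int)
    p_t <- tt$p.value
    p_w <- signed_rank_p(d)
  }

  mean_es <- mean(reds$red_es)
  mean_pl <- mean(reds$red_pl)
  r_mean <- if (mean_pl != 0) mean_es / mean_pl else NA_real_
  med_pl <- stats::median(reds$red_pl)
  r_median <- if (med_pl != 0) stats::median(reds$red_es) / med_pl else NA_real_

  structure(
    list(delta_mean = delta,
         delta_ci_low = ci[1], delta_ci_high = ci[2],
         p_paired_t = p_t, p_wilcoxon = p_w,
         mean_red_es = mean_es, mean_red_pl = mean_pl,
         r_mean = r_mean, r_median_based = r_median,
         r_trimmed = NA_real_,
         confidence = confidence, n = n, degenerate = degenerate),
    class = "pi_effects"
  )
}

#' @export
print.pi_effects <- function(x, ...) {
  cat("<pi_effects>  within-subject crossover effect (ES minus placebo)\n")
  cat(sprintf("  Delta = %.3f cm^2/day (%.0f%% CI %.3f to %.3f)\n",
              x$delta_mean, 100 * x$confidence, x$delta_ci_low, x$delta_ci_high))
  cat(sprintf("  paired t p = %.4g; Wilcoxon signed-rank p = %.4g\n",
              x$p_paired_t, x$p_wilcoxon))
  cat(sprintf("  period means: ES %.3f, placebo %.3f cm^2/day\n",
              x$mean_red_es, x$mean_red_pl))
  cat(sprintf("  acceleration ratio r: mean-based %.3f, median-based %.3f\n",
              x$r_mean, x$r_median_based))
  if (!is.na(x$r_trimmed)) cat(sprintf("  trimmed ratio %.3f\n", x$r_trimmed))
  if (x$degenerate) cat("  note: all within-subject differences identical\n")
  invisible(x)
}

# Two-sided Wilcoxon signed-rank p-value. Zero differences are dropped and
# tied absolute differences mid-ranked; for n <= 15 the exact null
# distribution is enumerated over all 2^n sign assignments (valid with ties,
# where the tabulated distribution does not apply), beyond that
# stats::wilcox.test takes over.
signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(NA_real_)
  if (n > 15) {
    return(suppressWarnings(stats::wilcox.test(d, exact = n <= 25)$p.value))
  }
  rk <- rank(abs(d))
  w_obs <- sum(rk[d > 0])
  signs <- (outer(0:(2^n - 1), 2^(seq_len(n) - 1), `%/%`) %% 2 == 1)
  w_all <- as.vector(signs %*% rk)
  mu <- n * (n + 1) / 4
  if (w_obs > mu) {
    min(1, 2 * mean(w_all >= w_obs))
  } else {
    min(1, 2 * mean(w_all <= w_obs))
  }
}

#' Healing acceleration ratio summary
#'
#' The secondary translation parameter r: how many times faster the wound
#' area shrinks per day under ES than under placebo. The `"mean"` method is
#' the ratio of cohort mean reductions; `"median_based"` is the ratio of
#' cohort median reductions (the default robust variant);
#' `"per_patient_median"` is the median of per-patient ratios, provided for
#' comparison but unstable when a patient's placebo reduction is near zero.
#'
#' @param cohort A [pi_cohort].
#' @param method One of `"mean"`, `"median_based"`, `"per_patient_median"`.
#' @return The ratio (dimensionless). If the denominator is negative the
#'   value is returned with attribute `polarity_warning = TRUE` and a warning.
#' @export
ratio_summary <- function(cohort,
                          method = c("mean", "median_based",
                                     "per_patient_median")) {
  method <- match.arg(method)
  reds <- daily_reductions(cohort)
  if (method == "mean") {
    num <- mean(reds$red_es); den <- mean(reds$red_pl)
  } else if (method == "median_based") {
    num <- stats::median(reds$red_es); den <- stats::median(reds$red_pl)
  } else {
    if (any(reds$red_pl == 0)) {
      stop("undefined-ratio error: a patient has zero placebo reduction",
           call. = FALSE)
    }
    ratios <- reds$red_es / reds$red_pl
    return(stats::median(ratios))
  }
  if (den == 0) {
    stop("undefined-ratio error: zero denominator (",
         method, " placebo reduction is 0)", call. = FALSE)
  }
  r <- num / den
  if (den < 0) {
    warning("placebo-period ", method,
            " reduction is negative; ratio polarity is inverted")
    attr(r, "polarity_warning") <- TRUE
  }
  r
}

#' Classical 2x2 crossover diagnostics
#'
#' Grizzle-style contrasts for a two-period, two-sequence crossover:
#' the treatment effect from the between-sequence comparison of within-patient
#' period differences, the period effect from the same differences with the
#' second sequence sign-flipped, and the sequence (carryover) effect from the
#' between-sequence comparison of within-patient period sums. All p-values are
#' from equal-variance two-sample t-tests, as appropriate for a small simple
#' crossover. Also reports the first-period-only treatment effect (a parallel
#' two-group contrast using period-1 data alone).
#'
#' @param cohort A [pi_cohort] with both sequence groups non-empty (>= 2
#'   patients per group for p-values).
#' @return An object of class `pi_crossover` with effects (cm^2/day) and
#'   p-values: `treatment_effect`, `period_effect`, `sequence_effect`,
#'   `p_treatment`, `p_period`, `p_sequence`, `first_period_only_effect`,
#'   `p_first_period`.
#' @export
crossover_diagnostics <- function(cohort) {
  reds <- daily_reductions(cohort)
  a <- reds[reds$sequence == "ES_first", , drop = FALSE]
  b <- reds[reds$sequence == "placebo_first", , drop = FALSE]
  if (nrow(a) == 0 || nrow(b) == 0) {
    stop("crossover diagnostics unavailable: a sequence group is empty",
         call. = FALSE)
  }
  d_a <- a$red_p1 - a$red_p2   # = ES - placebo - period contrast
  d_b <- b$red_p1 - b$red_p2   # = placebo - ES - period contrast
  s_a <- a$red_p1 + a$red_p2
  s_b <- b$red_p1 + b$red_p2

  treatment <- (mean(d_a) - mean(d_b)) / 2
  period <- -(mean(d_a) + mean(d_b)) / 2
  sequence <- mean(s_a) - mean(s_b)
  first_period <- mean(a$red_p1) - mean(b$red_p1)

  two_sample_p <- function(x, y) {
    if (length(x) < 2 || length(y) < 2 ||
        (stats::sd(x) == 0 && stats::sd(y) == 0)) return(NA_real_)
    stats::t.test(x, y, var.equal = TRUE)$p.value
  }
  structure(
    list(treatment_effect = treatment,
         period_effect = period,
         sequence_effect = sequence,
         first_period_only_effect = first_period,
         p_treatment = two_sample_p(d_a, d_b),
         p_period = two_sample_p(d_a, -d_b),
         p_sequence = two_sample_p(s_a, s_b),
         p_first_period = two_sample_p(a$red_p1, b$red_p1),
         n_es_first = nrow(a), n_placebo_first = nrow(b)),
    class = "pi_crossover"
  )
}

#' @export
print.pi_crossover <- function(x, ...) {
  cat("<pi_crossover>  2x2 crossover diagnostics (cm^2/day)\n")
  cat(sprintf("  treatment effect  %+.4f  (p = %.3g)\n",
              x$treatment_effect, x$p_treatment))
  cat(sprintf("  period effect     %+.4f  (p = %.3g)\n",
              x$period_effect, x$p_period))
  cat(sprintf("  sequence effect   %+.4f  (p = %.3g)\n",
              x$sequence_effect, x$p_sequence))
  cat(sprintf("  first-period-only %+.4f  (p = %.3g)\n",
              x$first_period_only_effect, x$p_first_period))
  cat(sprintf("  groups: %d ES-first, %d placebo-first\n",
              x$n_es_first, x$n_placebo_first))
  invisible(x)
}
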
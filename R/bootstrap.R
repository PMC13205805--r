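#' Patient-level nonparametric bootstrap of the full economic model
#'
#' Resamples patients with replacement (default 10,000 iterations). In each
#' iteration the healing acceleration ratio r is recomputed as the ratio of
#' resampled mean daily reductions (ES over placebo), the mean baseline time
#' to heal is re-imputed from the resample's stratum composition (unless
#' `t_placebo_fixed` pins it, as in the stratum tables), and every downstream
#' output — time to heal under ES, days saved, gross offset, implementation
#' cost, average implementation cost per day, and net impact — is recomputed.
#' 95% uncertainty intervals are the 2.5th and 97.5th percentiles of the
#' retained draws (linear interpolation between order statistics,
#' `quantile(type = 7)`).
#'
#' Resamples whose placebo mean reduction is <= 0 leave r (and T_ES)
#' undefined; they are excluded from the percentile computation and counted
#' in `n_degenerate`, with a warning when they exceed 1% of iterations.
#' Baseline translation is applied per patient and averaged (identical to
#' translating the mean under constant-ratio mode).
#'
#' @param cohort A [pi_cohort] with >= 2 patients.
#' @param table A [healing_time_table()].
#' @param translation A [translation_spec()]; its `r` is replaced per draw,
#'   its mode/kappa/window are honoured.
#' @param params A [cost_parameters()].
#' @param n_iterations Bootstrap iterations (default 10000).
#' @param seed Integer seed; identical inputs and seed give a bit-identical
#'   result.
#' @param t_placebo_fixed Optional fixed baseline (days); when supplied the
#'   stratum-mix uncertainty is switched off and only r varies.
#' @return An object of class `pi_bootstrap`: list with `outcomes` (data
#'   frame `outcome`, `point`, `ui_low`, `ui_high` for r, t_es, days_saved,
#'   gross_offset, impl_total, c_impl_per_day, net_impact), `r_draws`
#'   (retained draws), `n_iterations`, `n_degenerate`, `seed`.
#' @export
bootstrap_model <- function(cohort,
                            table = healing_time_table(),
                            translation = translation_spec(),
                            params = cost_parameters(),
                            n_iterations = 10000,
                            seed = 1L,
                            t_placebo_fixed = NULL) {
  validate_pi_cohort(cohort)
  n <- n_patients(cohort)
  if (n < 2) stop("bootstrap needs >= 2 patients", call. = FALSE)
  if (n_iterations < 1) stop("n_iterations must be >= 1", call. = FALSE)

  reds <- daily_reductions(cohort)
  rec <- cohort$records
  baseline <- if (is.null(t_placebo_fixed)) {
    impute_baseline(rec$design_r_total, rec$depth, table)
  } else {
    rep(t_placebo_fixed, n)
  }

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  idx <- matrix(sample.int(n, n * n_iterations, replace = TRUE),
                nrow = n, ncol = n_iterations)

  es_mat <- matrix(reds$red_es[idx], nrow = n)
  pl_mat <- matrix(reds$red_pl[idx], nrow = n)
  bl_mat <- matrix(baseline[idx], nrow = n)

  r_all <- colMeans(es_mat) / colMeans(pl_mat)
  keep <- is.finite(r_all) & r_all > 0
  n_degenerate <- sum(!keep)
  if (n_degenerate == n_iterations) {
    stop("estimation error: every bootstrap iteration had a non-positive ",
         "placebo mean reduction", call. = FALSE)
  }
  if (n_degenerate > 0.01 * n_iterations) {
    warning(sprintf(
      "%d of %d bootstrap iterations (%.1f%%) had non-positive placebo mean reduction and were excluded",
      n_degenerate, n_iterations, 100 * n_degenerate / n_iterations))
  }

  r <- r_all[keep]
  bl_keep <- bl_mat[, keep, drop = FALSE]
  t_pl <- colMeans(bl_keep)

  # per-patient translation, then average within each resample
  t_es <- colMeans(translate_matrix(bl_keep, r, translation))
  saved <- t_pl - t_es
  gross <- gross_offset(saved, params$per_day_value)
  fixed <- round_jpy(params$device_cost / params$cases_per_device) +
    params$consumables_per_case
  lab <- labor_per_day(params)
  impl_total <- fixed + lab * t_es
  c_per_day <- fixed / t_es + lab
  net <- gross - impl_total

  point <- bootstrap_point(cohort, baseline, translation, params)

  ui <- function(x) stats::quantile(x, c(0.025, 0.975), names = FALSE, type = 7)
  draws <- list(r = r, t_es = t_es, days_saved = saved, gross_offset = gross,
                impl_total = impl_total, c_impl_per_day = c_per_day,
                net_impact = net)
  qs <- vapply(draws, ui, numeric(2))
  outcomes <- data.frame(
    outcome = names(draws),
    point = unlist(point[names(draws)], use.names = FALSE),
    ui_low = qs[1, ],
    ui_high = qs[2, ],
    stringsAsFactors = FALSE
  )
  rownames(outcomes) <- NULL

  structure(
    list(outcomes = outcomes, r_draws = r,
         n_iterations = n_iterations, n_degenerate = n_degenerate,
         seed = seed),
    class = "pi_bootstrap"
  )
}

# Vectorized diminishing/constant translation of a baseline matrix with one
# ratio per column.
translate_matrix <- function(bl, r, translation) {
  rmat <- matrix(r, nrow = nrow(bl), ncol = ncol(bl), byrow = TRUE)
  if (translation$mode == "constant_ratio") return(bl / rmat)
  w <- translation$accel_window_days
  r_late <- 1 + translation$kappa * (rmat - 1)
  ifelse(bl <= rmat * w, bl / rmat, w + (bl - rmat * w) / r_late)
}

# Point estimates on the observed cohort, matching the per-draw computation.
bootstrap_point <- function(cohort, baseline, translation, params) {
  reds <- daily_reductions(cohort)
  mean_pl <- mean(reds$red_pl)
  r <- if (mean_pl != 0) mean(reds$red_es) / mean_pl else NA_real_
  if (is.na(r) || r <= 0) {
    # observed ratio undefined: point estimates unavailable, intervals still
    # come from the retained draws
    na <- NA_real_
    return(list(r = na, t_es = na, days_saved = na, gross_offset = na,
                impl_total = na, c_impl_per_day = na, net_impact = na))
  }
  tr <- translation
  tr$r <- r
  t_pl <- mean(baseline)
  t_es <- mean(translate_time(baseline, tr))
  saved <- t_pl - t_es
  gross <- gross_offset(saved, params$per_day_value)
  impl <- implementation_cost(t_es, params)
  list(r = r, t_es = t_es, days_saved = saved, gross_offset = gross,
       impl_total = impl$impl_total, c_impl_per_day = impl$c_impl_per_day,
       net_impact = net_impact(gross, impl$impl_total))
}

#' @export
print.pi_bootstrap <- function(x, ...) {
  cat(sprintf("<pi_bootstrap>  %d iterations (seed %d), %d degenerate draw(s) excluded\n",
              x$n_iterations, x$seed, x$n_degenerate))
  df <- x$outcomes
  df$point <- signif(df$point, 6)
  df$ui_low <- signif(df$ui_low, 6)
  df$ui_high <- signif(df$ui_high, 6)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Trimmed bootstrap ratio
#'
#' Robust summary of the bootstrap r distribution: the mean of the draws
#' strictly inside the 2.5th-97.5th percentile band (percentiles by linear
#' interpolation). Requires at least 40 retained draws so the band is
#' non-trivial.
#'
#' @param r_draws Numeric vector of retained bootstrap r draws, or a
#'   `pi_bootstrap` object.
#' @return The trimmed mean ratio.
#' @export
trimmed_ratio <- function(r_draws) {
  if (inherits(r_draws, "pi_bootstrap")) r_draws <- r_draws$r_draws
  if (length(r_draws) < 40) {
    stop("estimation error: need >= 40 draws to trim the 2.5%/97.5% tails",
         call. = FALSE)
  }
  q <- stats::quantile(r_draws, c(0.025, 0.975), names = FALSE, type = 7)
  inside <- r_draws > q[1] & r_draws < q[2]
  if (!any(inside)) {
    stop("estimation error: no draws strictly inside the percentile band",
         call. = FALSE)
  }
  mean(r_draws[inside])
}
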
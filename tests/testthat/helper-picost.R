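# Fixture builders and independent oracles used across the suite.

withr_local_file <- function(name, env = parent.frame()) {
  file.path(withr::local_tempdir(.local_envir = env), name)
}

# Build a cohort directly from per-patient daily reductions; start areas are
# chosen large enough that no end area is negative.
cohort_from_reductions <- function(red_es, red_pl,
                                   design_r = NULL, depth = "deep",
                                   sequence = NULL, period = 14) {
  n <- length(red_es)
  stopifnot(length(red_pl) == n)
  if (is.null(design_r)) design_r <- rep(20L, n)
  if (is.null(sequence)) sequence <- rep(c("ES_first", "placebo_first"),
                                         length.out = n)
  start_es <- pmax(10, period * red_es + 1)
  start_pl <- pmax(10, period * red_pl + 1)
  pi_cohort(data.frame(
    patient_id = sprintf("P%02d", seq_len(n)),
    sequence = rep_len(sequence, n),
    area_es_start = start_es,
    area_es_end = start_es - period * red_es,
    area_pl_start = start_pl,
    area_pl_end = start_pl - period * red_pl,
    design_r_total = design_r,
    depth = rep_len(depth, n),
    stringsAsFactors = FALSE
  ), period_length_days = period)
}

# The default 12-patient study cohort (5 x deep 10-18, 7 x deep >=19),
# calibrated to mean reductions 0.179 / 0.051 cm^2/day.
study_cohort <- function(seed = 1) generate_cohort(generator_spec(seed = seed))

# Exact two-sided Wilcoxon signed-rank p-value by exhaustive enumeration of
# all 2^n sign assignments (no zeros, no tied |d| expected from callers).
wilcoxon_enum_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  rk <- rank(abs(d))
  w_obs <- sum(rk[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% rk)
  mu <- n * (n + 1) / 4
  if (w_obs > mu) {
    min(1, 2 * mean(w_all >= w_obs))
  } else {
    min(1, 2 * mean(w_all <= w_obs))
  }
}

# Brute-force day-stepping healing simulator for the diminishing-acceleration
# translation: progress accrues at rate r for the first w days, then at
# 1 + kappa * (r - 1), in dt-day increments until t_placebo days of baseline
# progress are accumulated.
diminishing_step_oracle <- function(t_placebo, r, kappa, w, dt = 0.001) {
  t_max <- w + t_placebo + 1
  times <- seq(dt, t_max, by = dt)
  rate <- ifelse(times <= w, r, 1 + kappa * (r - 1))
  progress <- cumsum(rate * dt)
  times[which(progress >= t_placebo)[1]]
}

# Compare an empirical sample against a finite atom distribution: the
# empirical CDF, evaluated between consecutive atoms (midpoints avoid
# floating-point ties at the atoms themselves), must match the exact CDF
# within `tol`.
expect_cdf_match <- function(draws, atoms, tol = 0.01) {
  a <- sort(unique(atoms))
  cuts <- if (length(a) > 1) (a[-1] + a[-length(a)]) / 2 else a
  for (v in cuts) {
    expect_lt(abs(mean(draws <= v) - mean(atoms <= v)), tol)
  }
  expect_gte(min(draws), min(a) - 1e-9)
  expect_lte(max(draws), max(a) + 1e-9)
}

# Exhaustive distribution of the bootstrap acceleration ratio for an
# n-patient cohort: every ordered resample with replacement, each equally
# likely (n^n atoms).
exhaustive_r_distribution <- function(red_es, red_pl) {
  n <- length(red_es)
  grid <- as.matrix(expand.grid(rep(list(seq_len(n)), n)))
  apply(grid, 1, function(ix) mean(red_es[ix]) / mean(red_pl[ix]))
}
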
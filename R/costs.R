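#' Unit-cost parameters of the economic model
#'
#' Holds the per-day healing-related monetary value proxy (JPY/day, the sum of
#' its care components) and the ES implementation cost inputs: device
#' acquisition cost allocated over a number of cases, single-use per-case
#' consumables, and incremental ES staff time valued at a wage rate.
#'
#' If `per_day_value` is supplied and differs from the component sum, the
#' components are rescaled proportionally so the invariant
#' `per_day_value == sum(per_day_components)` always holds (the scenario
#' grids vary the total without re-specifying the split).
#'
#' @param per_day_components Named JPY/day components of the healing-related
#'   proxy; defaults procedures 1000, labor 1500, support_surface 500,
#'   nutrition 1000.
#' @param per_day_value Total proxy (JPY/day); default the component sum
#'   (4000).
#' @param device_cost Device acquisition cost, JPY (default 77000).
#' @param cases_per_device Cases sharing one device (default 12).
#' @param consumables_per_case Per-case consumables, JPY (default 3600 =
#'   lead 1800 + electrodes 1800).
#' @param es_staff_minutes_per_day Incremental ES staff time, min/day
#'   (default 15).
#' @param wage_per_minute Wage rate, JPY/min (default 50).
#' @return An object of class `cost_parameters`.
#' @export
#' @examples
#' cost_parameters()
#' cost_parameters(per_day_value = 8000)  # components rescaled x2
cost_parameters <- function(per_day_components = c(procedures = 1000,
                                                   labor = 1500,
                                                   support_surface = 500,
                                                   nutrition = 1000),
                            per_day_value = sum(per_day_components),
                            device_cost = 77000,
                            cases_per_device = 12,
                            consumables_per_case = 3600,
                            es_staff_minutes_per_day = 15,
                            wage_per_minute = 50) {
  comp_sum <- sum(per_day_components)
  if (!isTRUE(all.equal(per_day_value, comp_sum))) {
    if (comp_sum > 0) {
      per_day_components <- per_day_components * per_day_value / comp_sum
    } else {
      per_day_components <- c(total = per_day_value)
    }
  }
  p <- structure(
    list(per_day_components = per_day_components,
         per_day_value = per_day_value,
         device_cost = device_cost,
         cases_per_device = cases_per_device,
         consumables_per_case = consumables_per_case,
         es_staff_minutes_per_day = es_staff_minutes_per_day,
         wage_per_minute = wage_per_minute),
    class = "cost_parameters"
  )
  vals <- unlist(p[c("per_day_value", "device_cost", "cases_per_device",
                     "consumables_per_case", "es_staff_minutes_per_day",
                     "wage_per_minute")])
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("cost parameters must be finite and >= 0", call. = FALSE)
  }
  if (p$cases_per_device < 1) stop("cases_per_device must be >= 1", call. = FALSE)
  p
}

#' @export
print.cost_parameters <- function(x, ...) {
  cat("<cost_parameters>\n")
  cat(sprintf("  per-day healing value proxy: JPY %s/day (%s)\n",
              format(x$per_day_value, big.mark = ","),
              paste(names(x$per_day_components), x$per_day_components,
                    sep = "=", collapse = ", ")))
  cat(sprintf("  device JPY %s over %d cases; consumables JPY %s/case\n",
              format(x$device_cost, big.mark = ","), x$cases_per_device,
              format(x$consumables_per_case, big.mark = ",")))
  cat(sprintf("  ES staff time %g min/day x JPY %g/min = JPY %g/day\n",
              x$es_staff_minutes_per_day, x$wage_per_minute, labor_per_day(x)))
  invisible(x)
}

#' Incremental ES labor cost per treatment day
#' @param params A [cost_parameters()].
#' @return JPY/day (`es_staff_minutes_per_day * wage_per_minute`; 750 at
#'   defaults).
#' @export
labor_per_day <- function(params = cost_parameters()) {
  params$es_staff_minutes_per_day * params$wage_per_minute
}

#' Round to whole JPY, half away from zero
#'
#' Reporting convention for monetary outputs; internal arithmetic keeps full
#' precision.
#'
#' @param x Numeric JPY amounts.
#' @return Whole-yen values.
#' @export
round_jpy <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Gross monetary value offset
#'
#' Values days saved with the per-day healing-related monetary proxy:
#' `days_saved * per_day_value` (JPY/case). Negative days saved yield a
#' negative offset, reported rather than clipped.
#'
#' @param days_saved Days saved (may be negative). Vectorized.
#' @param per_day_value JPY/day proxy, >= 0.
#' @return Gross offset, JPY/case (full precision).
#' @export
#' @examples
#' round_jpy(gross_offset(185.4205, 4000))  # 741682
gross_offset <- function(days_saved, per_day_value = 4000) {
  if (any(per_day_value < 0)) stop("per_day_value must be >= 0", call. = FALSE)
  days_saved * per_day_value
}

#' ES implementation cost for one case
#'
#' Splits the implementation cost into a fixed per-case part — the device
#' allocation `round(device_cost / cases_per_device)` (rounded to whole JPY
#' before summing, so the default chain is 6417 + 3600 = 10017) plus
#' consumables — and a variable part, the incremental ES labor accruing over
#' every day of the estimated healing time under ES. The average
#' implementation cost per treatment day amortizes the fixed part over
#' `t_es`: `c_impl_per_day = impl_fixed / t_es + labor_per_day`.
#'
#' @param t_es Estimated time(s) to heal under ES, days, > 0. Vectorized.
#' @param params A [cost_parameters()].
#' @return Data frame with columns `t_es`, `impl_fixed`, `impl_variable`,
#'   `impl_total`, `c_impl_per_day` (all JPY at full precision).
#' @export
#' @examples
#' implementation_cost(73.5795)$impl_total  # ~65202
implementation_cost <- function(t_es, params = cost_parameters()) {
  if (any(t_es <= 0)) {
    stop("domain error: t_es must be > 0 (per-day amortization undefined)",
         call. = FALSE)
  }
  fixed <- round_jpy(params$device_cost / params$cases_per_device) +
    params$consumables_per_case
  lab <- labor_per_day(params)
  variable <- lab * t_es
  data.frame(
    t_es = t_es,
    impl_fixed = fixed,
    impl_variable = variable,
    impl_total = fixed + variable,
    c_impl_per_day = fixed / t_es + lab
  )
}

#' Net financial impact per case
#'
#' `gross_offset - impl_total` (JPY/case). The two published formulations —
#' gross minus `c_impl_per_day * t_es`, and gross minus
#' `(fixed + labor_per_day * t_es)` — are algebraically identical; this
#' function takes the already-computed totals.
#'
#' @param gross_offset Gross offset, JPY/case.
#' @param impl_total Total implementation cost, JPY/case.
#' @return Net impact, JPY/case (full precision).
#' @export
net_impact <- function(gross_offset, impl_total) {
  gross_offset - impl_total
}

#' Break-even average implementation cost per ES treatment day
#'
#' The maximum average per-day implementation cost at which the net financial
#' impact is zero: `per_day_value * (t_placebo - t_es) / t_es`. Under
#' constant-ratio translation this equals `per_day_value * (r - 1)`.
#'
#' @param t_placebo,t_es Times to heal, days; `t_es > 0`.
#' @param per_day_value JPY/day proxy.
#' @return JPY/day threshold.
#' @export
#' @examples
#' break_even_per_day(3.52, 1, 4000)  # 10080
break_even_per_day <- function(t_placebo, t_es, per_day_value = 4000) {
  if (any(t_es <= 0)) stop("domain error: t_es must be > 0", call. = FALSE)
  per_day_value * (t_placebo - t_es) / t_es
}

#' Project the economic model for one case or stratum
#'
#' Composes the full base-case chain: translate the baseline time to heal,
#' compute days saved, value them with the per-day proxy, cost the ES
#' implementation, and derive the net financial impact and break-even
#' threshold.
#'
#' @param t_placebo Baseline time to heal, days, > 0.
#' @param translation A [translation_spec()].
#' @param params A [cost_parameters()].
#' @return A one-row data frame of class `case_projection` with columns
#'   `t_placebo`, `t_es`, `days_saved`, `gross_offset`, `impl_fixed`,
#'   `impl_variable`, `impl_total`, `c_impl_per_day`, `net_impact`,
#'   `break_even_per_day` (all full precision).
#' @export
#' @examples
#' project_case(177.3333, translation_spec(r = 3.52))
project_case <- function(t_placebo,
                         translation = translation_spec(),
                         params = cost_parameters()) {
  t_es <- translate_time(t_placebo, translation)
  saved <- days_saved(t_placebo, t_es)
  gross <- gross_offset(saved, params$per_day_value)
  impl <- implementation_cost(t_es, params)
  out <- data.frame(
    t_placebo = t_placebo,
    t_es = t_es,
    days_saved = saved,
    gross_offset = gross,
    impl_fixed = impl$impl_fixed,
    impl_variable = impl$impl_variable,
    impl_total = impl$impl_total,
    c_impl_per_day = impl$c_impl_per_day,
    net_impact = net_impact(gross, impl$impl_total),
    break_even_per_day = break_even_per_day(t_placebo, t_es,
                                            params$per_day_value)
  )
  class(out) <- c("case_projection", "data.frame")
  out
}

#' @export
print.case_projection <- function(x, digits = 1, ...) {
  cat("<case_projection>\n")
  df <- as.data.frame(x)
  day_cols <- intersect(c("t_placebo", "t_es", "days_saved"), names(df))
  jpy_cols <- intersect(c("gross_offset", "impl_fixed", "impl_variable",
                          "impl_total", "net_impact"), names(df))
  rate_cols <- intersect(c("c_impl_per_day", "break_even_per_day"), names(df))
  for (col in day_cols) df[[col]] <- round(df[[col]], digits)
  for (col in jpy_cols) df[[col]] <- round_jpy(df[[col]])
  for (col in rate_cols) df[[col]] <- round_jpy(df[[col]])
  print(df, row.names = FALSE)
  invisible(x)
}

#' Severity-stratified projections
#'
#' Groups the cohort by (depth, DESIGN-R category), fixes each stratum's
#' baseline time to heal to the stratum's published median from the table,
#' and emits one [project_case()] row per occupied stratum plus the patient
#' count.
#'
#' @param cohort A non-empty [pi_cohort].
#' @param table A [healing_time_table()].
#' @param translation A [translation_spec()].
#' @param params A [cost_parameters()].
#' @return Data frame with `depth`, `category`, `n` and the projection
#'   columns, ordered by depth then category.
#' @export
project_strata <- function(cohort,
                           table = healing_time_table(),
                           translation = translation_spec(),
                           params = cost_parameters()) {
  validate_pi_cohort(cohort)
  if (n_patients(cohort) == 0) stop("empty cohort", call. = FALSE)
  rec <- cohort$records
  cat <- design_r_category(rec$design_r_total)
  key <- data.frame(depth = rec$depth, category = as.character(cat),
                    stringsAsFactors = FALSE)
  grp <- unique(key)
  grp <- grp[order(match(grp$depth, DEPTH_LEVELS),
                   match(grp$category, DESIGN_R_CATEGORIES)), , drop = FALSE]
  rows <- lapply(seq_len(nrow(grp)), function(i) {
    in_grp <- key$depth == grp$depth[i] & key$category == grp$category[i]
    t_pl <- table[grp$depth[i], grp$category[i]]
    proj <- project_case(t_pl, translation, params)
    cbind(data.frame(depth = grp$depth[i], category = grp$category[i],
                     n = sum(in_grp), stringsAsFactors = FALSE),
          as.data.frame(proj))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
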
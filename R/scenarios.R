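#' Declare a sensitivity scenario
#'
#' A declarative description of one run of the economic model: where the
#' acceleration ratio comes from, multiplicative perturbations of the ratio
#' and of the baseline healing-time table, the translation mode, the per-day
#' monetary value, and optionally an alternative healing-time table (e.g. a
#' depth-unstratified variant).
#'
#' @param name Scenario label.
#' @param per_day_value JPY/day healing-related proxy (default 4000).
#' @param ratio_source One of `"base_case_constant"` (the constant
#'   [base_case_ratio()], 3.52), `"mean"`, `"median_based"` (both computed
#'   from the cohort), `"trimmed"` (needs bootstrap draws), `"explicit"`.
#' @param ratio Explicit ratio when `ratio_source = "explicit"`.
#' @param ratio_multiplier Multiplier on the resolved ratio (default 1;
#'   +/-20% variants use 0.8 and 1.2).
#' @param baseline_multiplier Multiplier applied to every healing-time table
#'   entry (default 1; variants 0.7, 0.8, 1.2, 1.3).
#' @param translation_mode `"constant_ratio"` or `"diminishing"`.
#' @param kappa,accel_window_days Diminishing-mode attenuation parameters,
#'   see [translation_spec()].
#' @param depth_stratified Keep depth strata (default `TRUE`). When `FALSE`
#'   an `alternative_table` must be supplied explicitly; no pooled default is
#'   invented.
#' @param alternative_table Optional [healing_time_table()] replacing the
#'   default table before the baseline multiplier is applied.
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(name,
                          per_day_value = 4000,
                          ratio_source = c("base_case_constant", "mean",
                                           "median_based", "trimmed",
                                           "explicit"),
                          ratio = NULL,
                          ratio_multiplier = 1,
                          baseline_multiplier = 1,
                          translation_mode = c("constant_ratio", "diminishing"),
                          kappa = 0.5,
                          accel_window_days = 14,
                          depth_stratified = TRUE,
                          alternative_table = NULL) {
  ratio_source <- match.arg(ratio_source)
  translation_mode <- match.arg(translation_mode)
  if (ratio_source == "explicit" && (is.null(ratio) || ratio <= 0)) {
    stop("explicit ratio_source needs a positive `ratio`", call. = FALSE)
  }
  if (ratio_multiplier <= 0 || baseline_multiplier <= 0) {
    stop("multipliers must be > 0", call. = FALSE)
  }
  if (per_day_value < 0) stop("per_day_value must be >= 0", call. = FALSE)
  if (!depth_stratified && is.null(alternative_table)) {
    stop("depth-unstratified scenarios require an explicit alternative_table",
         call. = FALSE)
  }
  if (!is.null(alternative_table)) validate_healing_time_table(alternative_table)
  structure(
    list(name = name, per_day_value = per_day_value,
         ratio_source = ratio_source, ratio = ratio,
         ratio_multiplier = ratio_multiplier,
         baseline_multiplier = baseline_multiplier,
         translation_mode = translation_mode,
         kappa = kappa, accel_window_days = accel_window_days,
         depth_stratified = depth_stratified,
         alternative_table = alternative_table),
    class = "scenario_spec"
  )
}

resolve_ratio <- function(spec, cohort = NULL, bootstrap = NULL) {
  r <- switch(spec$ratio_source,
    base_case_constant = base_case_ratio(),
    explicit = spec$ratio,
    mean = {
      if (is.null(cohort)) stop("ratio_source 'mean' needs a cohort",
                                call. = FALSE)
      as.numeric(ratio_summary(cohort, "mean"))
    },
    median_based = {
      if (is.null(cohort)) stop("ratio_source 'median_based' needs a cohort",
                                call. = FALSE)
      as.numeric(ratio_summary(cohort, "median_based"))
    },
    trimmed = {
      if (is.null(bootstrap)) {
        stop("dependency error: ratio_source 'trimmed' needs bootstrap draws",
             call. = FALSE)
      }
      trimmed_ratio(bootstrap)
    }
  )
  r * spec$ratio_multiplier
}

#' Run one declared scenario
#'
#' Resolves the acceleration ratio from its declared source, applies the
#' ratio and baseline multipliers, and delegates to [project_case()] on the
#' cohort mean baseline plus [project_strata()] for the stratum rows.
#'
#' @param cohort A [pi_cohort] (needed for cohort-derived ratios, the mean
#'   baseline, and stratum counts).
#' @param table Base [healing_time_table()] (replaced by the scenario's
#'   `alternative_table` when present).
#' @param spec A [scenario_spec()].
#' @param params Base [cost_parameters()]; the scenario's `per_day_value`
#'   overrides the total proxy.
#' @param bootstrap Optional `pi_bootstrap` supplying trimmed-ratio draws.
#' @return A list of class `pi_scenario`: `name`, `r` (resolved, after
#'   multiplier), `case` (cohort-level [project_case()] row), `strata`
#'   (per-stratum rows).
#' @export
run_scenario <- function(cohort,
                         table = healing_time_table(),
                         spec,
                         params = cost_parameters(),
                         bootstrap = NULL) {
  stopifnot(inherits(spec, "scenario_spec"))
  r <- resolve_ratio(spec, cohort, bootstrap)
  if (!is.null(spec$alternative_table)) table <- spec$alternative_table
  tab <- healing_time_table(
    superficial = spec$baseline_multiplier * table["superficial", ],
    deep = spec$baseline_multiplier * table["deep", ]
  )
  p <- cost_parameters(
    per_day_components = params$per_day_components,
    per_day_value = spec$per_day_value,
    device_cost = params$device_cost,
    cases_per_device = params$cases_per_device,
    consumables_per_case = params$consumables_per_case,
    es_staff_minutes_per_day = params$es_staff_minutes_per_day,
    wage_per_minute = params$wage_per_minute
  )
  tr <- translation_spec(mode = spec$translation_mode, r = r,
                         kappa = spec$kappa,
                         accel_window_days = spec$accel_window_days)
  t_pl <- mean_baseline(cohort, tab)
  structure(
    list(name = spec$name, r = r,
         case = project_case(t_pl, tr, p),
         strata = project_strata(cohort, tab, tr, p)),
    class = "pi_scenario"
  )
}

#' @export
print.pi_scenario <- function(x, ...) {
  cat(sprintf("<pi_scenario> '%s' (r = %.3f)\n", x$name, x$r))
  print(x$case)
  invisible(x)
}

#' One-way sensitivity grid over the per-day monetary value
#'
#' Re-values fixed healing times across a grid of per-day proxies. The gross
#' offset is exactly proportional to the value; the net impact is affine in
#' it (the implementation cost does not depend on the proxy).
#'
#' @param t_placebo,t_es Fixed healing times, days.
#' @param values Non-empty vector of JPY/day values, e.g.
#'   `c(3000, 5000, 7000, 8000, 9000, 10000)`.
#' @param params [cost_parameters()] for the implementation-cost side.
#' @return Data frame with one row per value: `per_day_value`, `days_saved`,
#'   `gross_offset`, `impl_total`, `net_impact`, `break_even_per_day`.
#' @export
one_way_value_grid <- function(t_placebo, t_es,
                               values = c(3000, 5000, 7000, 8000, 9000, 10000),
                               params = cost_parameters()) {
  if (length(values) == 0) stop("values must be non-empty", call. = FALSE)
  saved <- days_saved(t_placebo, t_es)
  impl <- implementation_cost(t_es, params)
  data.frame(
    per_day_value = values,
    days_saved = saved,
    gross_offset = gross_offset(saved, values),
    impl_total = impl$impl_total,
    net_impact = net_impact(gross_offset(saved, values), impl$impl_total),
    break_even_per_day = break_even_per_day(t_placebo, t_es, values)
  )
}

#' Baseline healing-time sweep
#'
#' Scales every healing-time table entry by each multiplier and re-runs the
#' cohort-level projection. Under constant-ratio translation, days saved and
#' gross offset scale exactly by the multiplier; the fixed component of the
#' implementation cost does not, so net impact is affine rather than
#' proportional.
#'
#' @param cohort A [pi_cohort].
#' @param table Base [healing_time_table()].
#' @param translation A [translation_spec()].
#' @param params [cost_parameters()].
#' @param multipliers Positive multipliers (default `c(0.7, 0.8, 1, 1.2, 1.3)`).
#' @return Data frame with `multiplier` plus the [project_case()] columns.
#' @export
baseline_sweep <- function(cohort,
                           table = healing_time_table(),
                           translation = translation_spec(),
                           params = cost_parameters(),
                           multipliers = c(0.7, 0.8, 1, 1.2, 1.3)) {
  if (any(multipliers <= 0)) stop("multipliers must be > 0", call. = FALSE)
  rows <- lapply(multipliers, function(k) {
    tab <- healing_time_table(superficial = k * table["superficial", ],
                              deep = k * table["deep", ])
    cbind(data.frame(multiplier = k),
          as.data.frame(project_case(mean_baseline(cohort, tab),
                                     translation, params)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' The bundled deterministic scenario set
#'
#' The prespecified sensitivity family as declarative [scenario_spec()]s:
#' the base case; per-day values 3000-10000 JPY; ratio +/-20%; baseline
#' +/-20% and +/-30%; the median-based and trimmed ratio variants; and the
#' conservative diminishing-acceleration scenario. The depth-unstratified
#' structural variant is excluded by default because it needs an explicit
#' alternative table (see [scenario_spec()]).
#'
#' @return Named list of `scenario_spec` objects.
#' @export
standard_scenarios <- function() {
  specs <- list(
    scenario_spec("base_case"),
    scenario_spec("value_3000", per_day_value = 3000),
    scenario_spec("value_5000", per_day_value = 5000),
    scenario_spec("value_7000", per_day_value = 7000),
    scenario_spec("value_8000", per_day_value = 8000),
    scenario_spec("value_9000", per_day_value = 9000),
    scenario_spec("value_10000", per_day_value = 10000),
    scenario_spec("ratio_minus20", ratio_multiplier = 0.8),
    scenario_spec("ratio_plus20", ratio_multiplier = 1.2),
    scenario_spec("baseline_minus30", baseline_multiplier = 0.7),
    scenario_spec("baseline_minus20", baseline_multiplier = 0.8),
    scenario_spec("baseline_plus20", baseline_multiplier = 1.2),
    scenario_spec("baseline_plus30", baseline_multiplier = 1.3),
    scenario_spec("ratio_median_based", ratio_source = "median_based"),
    scenario_spec("ratio_trimmed", ratio_source = "trimmed"),
    scenario_spec("diminishing", translation_mode = "diminishing")
  )
  stats::setNames(specs, vapply(specs, `[[`, character(1), "name"))
}

#' Run a list of scenarios
#'
#' Pure convenience wrapper: applies [run_scenario()] to each spec and binds
#' the cohort-level rows into one table. Scenario runs share no state; the
#' same inputs always give the same outputs.
#'
#' @param cohort,table,params,bootstrap Passed to [run_scenario()].
#' @param specs List of [scenario_spec()]s (default [standard_scenarios()],
#'   minus the trimmed-ratio entry when no `bootstrap` is given).
#' @return Data frame with `scenario`, `r` and the cohort-level projection
#'   columns, one row per scenario.
#' @export
run_scenarios <- function(cohort,
                          table = healing_time_table(),
                          specs = standard_scenarios(),
                          params = cost_parameters(),
                          bootstrap = NULL) {
  if (is.null(bootstrap)) {
    specs <- Filter(function(s) s$ratio_source != "trimmed", specs)
  }
  rows <- lapply(specs, function(s) {
    res <- run_scenario(cohort, table, s, params, bootstrap)
    cbind(data.frame(scenario = res$name, r = res$r,
                     stringsAsFactors = FALSE),
          as.data.frame(res$case))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
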
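test_that("cost parameter invariants hold, including proportional rescaling", {
  p <- cost_parameters()
  expect_equal(p$per_day_value, 4000)
  expect_equal(sum(p$per_day_components), p$per_day_value)
  expect_equal(labor_per_day(p), 750)

  p8 <- cost_parameters(per_day_value = 8000)
  expect_equal(sum(p8$per_day_components), 8000)
  expect_equal(unname(p8$per_day_components["labor"]), 3000)

  expect_error(cost_parameters(device_cost = -1), ">= 0")
  expect_error(cost_parameters(cases_per_device = 0), ">= 1")
})

test_that("gross offset reproduces the published per-stratum values", {
  expect_equal(round_jpy(gross_offset(185.4205, 4000)), 741682)
  expect_equal(round_jpy(gross_offset(45.1023, 4000)), 180409)
  expect_equal(gross_offset(0, 4000), 0)
  expect_equal(gross_offset(-10, 4000), -40000)  # downside passes through
  expect_equal(gross_offset(126.9, 8000), 2 * gross_offset(126.9, 4000))
})

test_that("implementation cost splits into the published fixed and variable parts", {
  impl <- implementation_cost(73.5795)
  expect_equal(impl$impl_fixed, 10017)
  expect_equal(round_jpy(impl$impl_total), 65202)
  expect_equal(impl$impl_total, impl$impl_fixed + impl$impl_variable)
  expect_equal(impl$c_impl_per_day * impl$t_es, impl$impl_total,
               tolerance = 1e-12)

  expect_equal(round_jpy(implementation_cost(17.8977)$impl_total), 23440)

  free <- cost_parameters(device_cost = 0, consumables_per_case = 0,
                          es_staff_minutes_per_day = 0)
  impl0 <- implementation_cost(42, free)
  expect_equal(impl0$impl_total, 0)
  expect_equal(impl0$c_impl_per_day, 0)

  expect_error(implementation_cost(0), "> 0")
})

test_that("net impact matches the published stratum arithmetic", {
  expect_equal(round_jpy(net_impact(741682.1, 65201.7)), 676480)
  expect_equal(round_jpy(net_impact(180409.1, 23440.3)), 156969)
  expect_equal(net_impact(0, 23440), -23440)
})

test_that("the two net-impact formulations agree on randomized inputs", {
  set.seed(42)
  params <- cost_parameters()
  fixed <- 10017
  lab <- labor_per_day(params)
  for (i in 1:200) {
    t_pl <- runif(1, 20, 400)
    r <- runif(1, 0.5, 8)
    v <- runif(1, 0, 12000)
    t_es <- t_pl / r
    saved <- t_pl - t_es
    gross <- saved * v
    impl <- implementation_cost(t_es, params)
    # formulation 1: gross - C_impl/day * T_ES
    net1 <- gross - impl$c_impl_per_day * t_es
    # formulation 2: gross - [(device allocation + consumables) + labor/day * T_ES]
    net2 <- gross - (fixed + lab * t_es)
    expect_equal(net1, net2, tolerance = 1e-9)
  }
})

test_that("break-even threshold matches its closed form and a root-finding oracle", {
  expect_equal(break_even_per_day(3.52 * 50, 50, 4000), 10080)
  # under constant-ratio translation: v * (r - 1)
  t_pl <- 177.3333
  t_es <- t_pl / 3.52
  expect_equal(break_even_per_day(t_pl, t_es, 4000), 4000 * (3.52 - 1),
               tolerance = 1e-9)
  expect_equal(break_even_per_day(100, 100, 4000), 0)  # r = 1

  set.seed(7)
  for (i in 1:25) {
    t_pl <- runif(1, 30, 300); t_es <- runif(1, 5, t_pl); v <- runif(1, 500, 9000)
    net_at <- function(c) (t_pl - t_es) * v - c * t_es
    root <- uniroot(net_at, c(0, 1e7), tol = 1e-9)$root
    expect_equal(break_even_per_day(t_pl, t_es, v), root, tolerance = 1e-6)
  }
})

test_that("project_case composes the base-case chain to the published values", {
  proj <- project_case(177.3333, translation_spec(r = 3.52))
  expect_equal(proj$t_es, 50.4, tolerance = 0.05)
  expect_equal(proj$days_saved, 126.9, tolerance = 0.06)
  expect_equal(proj$impl_total / proj$t_es, 949, tolerance = 1)
  expect_equal(proj$break_even_per_day, 10080)
  expect_equal(proj$net_impact, proj$gross_offset - proj$impl_total)

  null <- project_case(100, translation_spec(r = 1))
  expect_equal(null$days_saved, 0)
  expect_equal(null$net_impact, -null$impl_total)
})

test_that("project_strata reproduces the severity-stratified table rows", {
  strata <- project_strata(study_cohort())
  expect_equal(nrow(strata), 2)
  expect_equal(strata$n, c(5L, 7L))
  expect_equal(strata$category, c("10-18", ">=19"))

  lo <- strata[strata$category == "10-18", ]
  hi <- strata[strata$category == ">=19", ]
  expect_equal(lo$t_placebo, 63)
  expect_equal(round(lo$t_es, 1), 17.9)
  expect_equal(round_jpy(lo$gross_offset), 180409)
  expect_equal(round_jpy(lo$impl_total), 23440)
  expect_equal(round_jpy(lo$net_impact), 156969)
  expect_equal(hi$t_placebo, 259)
  expect_equal(round(hi$t_es, 1), 73.6)
  expect_equal(round(hi$days_saved, 1), 185.4)
  expect_equal(round_jpy(hi$gross_offset), 741682)
  expect_equal(round_jpy(hi$impl_total), 65202)
  expect_equal(round_jpy(hi$net_impact), 676480)
})

test_that("project_strata rows equal project_case on each stratum median", {
  spec <- generator_spec(
    n_patients = 6,
    strata = data.frame(category = rep(c("<=9", "10-18", ">=19"), 2),
                        depth = rep(c("superficial", "deep"), each = 3),
                        count = rep(1L, 6)),
    seed = 33)
  coh <- generate_cohort(spec)
  tab <- healing_time_table()
  tr <- translation_spec(r = 2.5)
  strata <- project_strata(coh, tab, tr)
  expect_equal(nrow(strata), 6)
  for (i in seq_len(nrow(strata))) {
    ref <- project_case(tab[strata$depth[i], strata$category[i]], tr)
    expect_equal(strata$net_impact[i], ref$net_impact, tolerance = 1e-9)
    expect_equal(strata$t_es[i], ref$t_es, tolerance = 1e-12)
  }

  single <- cohort_from_reductions(c(0.2, 0.1), c(0.1, 0.05),
                                   design_r = c(20L, 25L))
  one <- project_strata(single, tab, tr)
  expect_equal(nrow(one), 1)
  expect_equal(one$net_impact, project_case(259, tr)$net_impact)
})

test_that("net impact is positive exactly when average cost is below break-even", {
  set.seed(11)
  for (i in 1:100) {
    t_pl <- runif(1, 20, 400)
    r <- runif(1, 0.8, 6)
    v <- runif(1, 100, 9000)
    p <- cost_parameters(per_day_value = v)
    proj <- project_case(t_pl, translation_spec(r = r), p)
    avg_cost <- proj$impl_total / proj$t_es
    expect_equal(proj$net_impact > 0, avg_cost < proj$break_even_per_day)
  }
})
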
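test_that("scenario A rewrites rates to the forecast table", {
  p <- default_parameter_set()
  ab <- build_scenario_a(p)
  expect_equal(vapply(ab, function(x) x$id, ""), c("A2017", "A2018"))
  a17 <- apply_scenario(ab[[1]], p)
  expect_equal(unname(a17$annual_rates[["NMHA"]]), 61995)
  expect_equal(unname(a17$annual_rates[["mood"]]), 1027)
  # substance subgroups rescale proportionally to the aggregate forecast
  subs <- c("alcohol", "opioid", "cannabis", "multiple", "substance_other")
  expect_equal(sum(a17$annual_rates[subs]), 3206, tolerance = 1e-9)
  expect_equal(unname(a17$annual_rates[["alcohol"]]), 2119 * 3206 / 2879)
  a18 <- apply_scenario(ab[[2]], p)
  expect_equal(sum(a18$annual_rates[subs]), 3471, tolerance = 1e-9)
  # a forecast equal to current demand leaves the baseline unchanged
  ft <- default_forecast_table()
  ft$forecast_2017 <- ft$demand_2016
  same <- apply_scenario(build_scenario_a(p, ft)[[1]], p)
  expect_equal(same$annual_rates, p$annual_rates)
  # missing classes are rejected
  expect_error(build_scenario_a(p, ft[-1, ]), "missing class forecast")
})

test_that("scenario B thins the alcohol and opioid streams only", {
  p <- default_parameter_set()
  b30 <- apply_scenario(build_scenario_b(p, 30), p)
  expect_equal(unname(b30$annual_rates[["alcohol"]]), 2119 * 0.7)
  expect_equal(unname(b30$annual_rates[["opioid"]]), 74 * 0.7)
  expect_equal(unname(b30$annual_rates[["cannabis"]]), 73)
  # the 30% reduction removes 1.0% of the total annual volume
  removed <- (2119 + 74) * 0.30
  expect_equal(removed, 657.9)
  expect_equal(share(removed, sum(p$annual_rates)), 1.0)
  b63 <- apply_scenario(build_scenario_b(p, 63), p)
  expect_equal(unname(b63$annual_rates[["alcohol"]]), 2119 * 0.37)
  expect_error(build_scenario_b(p, 0), "reduction_pct")
  expect_error(build_scenario_b(p, 100), "reduction_pct")
})

test_that("scenario C applies the sequential cannabis adjustments", {
  p <- default_parameter_set()
  cc <- build_scenario_c(p)
  y1 <- apply_scenario(cc[[1]], p)
  y2 <- apply_scenario(cc[[2]], p)
  expect_equal(unname(y1$annual_rates[["cannabis"]]), 73 * 1.19)
  expect_equal(unname(y2$annual_rates[["cannabis"]]), 73 * 1.19 * 0.73)
  expect_lt(y2$annual_rates[["cannabis"]], y1$annual_rates[["cannabis"]])
  zero <- p
  zero$annual_rates[["cannabis"]] <- 0
  expect_equal(unname(apply_scenario(cc[[1]], zero)$annual_rates[["cannabis"]]), 0)
})

test_that("scenarios D and E compose capacity and demand changes", {
  p <- default_parameter_set()
  d7 <- build_scenario_d(p, 7)
  pd <- apply_scenario(d7, p)
  expect_equal(pd$pesu_capacity, 7L)
  expect_equal(pd$annual_rates, p$annual_rates)
  expect_error(build_scenario_d(p, 6), "must exceed")
  ee <- build_scenario_e(p, 7:10)
  expect_length(ee, 8)
  e17_10 <- ee[[which(vapply(ee, function(x) x$id, "") == "E2017_10")]]
  pe <- apply_scenario(e17_10, p)
  expect_equal(unname(pe$annual_rates[["NMHA"]]), 61995)
  expect_equal(pe$pesu_capacity, 10L)
  # E is the componentwise composition of A's rates with D's capacity
  a17 <- apply_scenario(build_scenario_a(p)[[1]], p)
  expect_equal(pe$annual_rates, a17$annual_rates)
  d10 <- apply_scenario(build_scenario_d(p, 10), p)
  expect_equal(pe$pesu_capacity, d10$pesu_capacity)
})

test_that("scenario transformations never mutate the baseline", {
  p <- fixture_baseline()
  p$n_replications <- 3L
  before <- unserialize(serialize(p, NULL))
  invisible(build_scenario_b(p, 45))
  invisible(run_scenario(build_scenario_d(p, 8), p, 3, 5))
  expect_identical(p, before)
})

test_that("a no-op scenario reproduces the baseline exactly under CRN", {
  p <- fixture_baseline()
  noop <- pesuflow:::new_scenario_config("noop",
                                         rate_multipliers = c(cannabis = 1))
  r <- run_scenario(noop, p, 3, 9)
  expect_equal(r$deltas$delta_los, rep(0, 3))
  expect_equal(r$deltas$delta_share, rep(0, 3))
})

test_that("large demand removals and bed additions move paired KPIs", {
  p <- fixture_baseline()
  base <- run_experiment(p, 5, 11)
  b63 <- run_scenario(build_scenario_b(p, 63), p, 5, 11, baseline = base)
  expect_true(all(b63$deltas$delta_los <= 0))
  d10 <- run_scenario(build_scenario_d(p, 10), p, 5, 11, baseline = base)
  expect_true(all(d10$deltas$delta_share > 0))
})

test_that("the suite table lines up scenarios against one CRN baseline", {
  p <- mini_params(n_replications = 3)
  p$pesu_eligibility <- 0.5
  suite <- run_scenario_suite(p, list(build_scenario_b(p, 30),
                                      build_scenario_d(p, 2)), 3, 21)
  expect_equal(suite$table$scenario, c("baseline", "B30", "D2"))
  expect_equal(suite$table$delta_los[1], 0)
  expect_equal(nrow(suite$reports$B30$deltas), 3)
})
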
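test_that("interarrival fit is observation window over count", {
  h <- fixture_history()
  yr <- h[h$fiscal_year == "2016", ]
  fit <- fit_interarrival(yr, "NMHA", 8760)
  expect_equal(fit$mean_interarrival, 8760 / 58947)
  one <- yr[match("NMHA", yr$category), ]
  expect_equal(fit_interarrival(one, "NMHA", 8760)$mean_interarrival, 8760)
  expect_error(fit_interarrival(yr, "no_such_class", 8760), "no records")
})

test_that("interarrival fit recovers a known Poisson rate", {
  set.seed(7)
  horizon <- 20000
  arr <- simulate_arrivals(2, horizon)
  rec <- data.frame(arrival_time = arr, fiscal_year = "2016",
                    icd_code = "K35", category = "NMHA",
                    substance_subgroup = "none", ctas = 3L,
                    disposition = "discharged", los_hours = 1)
  fit <- fit_interarrival(rec, "NMHA", horizon)
  se <- 2 / sqrt(nrow(rec))
  expect_lt(abs(fit$mean_interarrival - 2), 3 * se)
})

test_that("lognormal service fit recovers known parameters by moments", {
  set.seed(11)
  n <- 10000
  x <- rlnorm(n, meanlog = 1, sdlog = 0.5)
  rec <- data.frame(arrival_time = seq_len(n), fiscal_year = "2016",
                    icd_code = "K35", category = "NMHA",
                    substance_subgroup = "none", ctas = 3L,
                    disposition = "discharged", los_hours = x)
  fit <- fit_service(rec, "NMHA")
  true_mean <- exp(1 + 0.5^2 / 2)
  se <- sd(x) / sqrt(n)
  expect_lt(abs(fit$mean_hours - true_mean), 3 * se)
  expect_equal(fit$meanlog, 1, tolerance = 0.05)
  expect_equal(fit$sdlog, 0.5, tolerance = 0.05)
  # MLE variant fits on the log scale
  mle <- fit_service(rec, "NMHA", method = "mle")
  expect_equal(mle$meanlog, mean(log(x)), tolerance = 1e-12)
})

test_that("constant-LOS strata give a flagged degenerate fit", {
  rec <- data.frame(arrival_time = 1:5, fiscal_year = "2016",
                    icd_code = "K35", category = "NMHA",
                    substance_subgroup = "none", ctas = 3L,
                    disposition = "discharged", los_hours = 7)
  fit <- fit_service(rec, "NMHA")
  expect_true(fit$degenerate)
  expect_equal(fit$sdlog, 0)
  expect_equal(fit$mean_hours, 7)
})

test_that("sparse strata fall back hierarchically with a message", {
  rec <- data.frame(arrival_time = 1:6, fiscal_year = "2016",
                    icd_code = "F32", category = "mood",
                    substance_subgroup = "none",
                    ctas = c(1L, 3L, 3L, 3L, 3L, 3L),
                    disposition = c("admitted", rep("discharged", 5)),
                    los_hours = c(20, 9, 10, 11, 12, 13))
  expect_message(fit <- fit_service(rec, "mood", ctas = 1,
                                    disposition = "admitted"),
                 "falling back")
  expect_equal(fit$stratum, "class")
  expect_error(fit_service(rec[1, ], "mood"), "fewer than two")
})

test_that("discharged substance LOS matches its anchored mean", {
  h <- fixture_history()
  fit <- fit_service(h, "substance", disposition = "discharged")
  se <- 5.8 / sqrt(fit$n) # lognormal cv = 1 so sd = mean
  expect_lt(abs(fit$mean_hours - 5.8), 3 * se)
})

test_that("empirical proportions are simplex-valued and track the config", {
  h <- fixture_history()
  cfg <- default_synthetic_config()
  props <- estimate_proportions(h)
  expect_equal(unname(rowSums(props$ctas)), rep(1, nrow(props$ctas)))
  expect_equal(unname(apply(props$disposition, c(1, 2), sum)),
               matrix(1, nrow(props$ctas), 5))
  for (cat_ in rownames(cfg$ctas_prob)) {
    n <- sum(h$category == cat_)
    p <- cfg$ctas_prob[cat_, ]
    se <- sqrt(p * (1 - p) / n)
    expect_true(all(abs(props$ctas[cat_, ] - p) <= 3 * se + 1e-12))
  }
  expect_error(estimate_proportions(h[0, ]), "at least one record")
})

test_that("all-CTAS-3 records give the degenerate CTAS vector", {
  rec <- data.frame(arrival_time = 1:4, fiscal_year = "2016",
                    icd_code = "K35", category = "NMHA",
                    substance_subgroup = "none", ctas = 3L,
                    disposition = "discharged", los_hours = 2)
  props <- estimate_proportions(rec)
  expect_equal(unname(props$ctas["NMHA", ]), c(0, 0, 1, 0, 0))
})

test_that("annual summary counts are exact and subgroups sum to substance", {
  h <- fixture_history()
  s <- annual_summary(h)
  pick <- function(yr, cat_, sg = "all") {
    s$count[s$fiscal_year == yr & s$category == cat_ &
              s$substance_subgroup == sg]
  }
  expect_equal(pick("2016", "substance"), 2879)
  expect_equal(pick("2016", "substance", "alcohol"), 2119)
  expect_equal(pick("2012", "substance", "alcohol"), 1569)
  expect_equal(pick("2016", "total"), 65078)
  for (yr in unique(s$fiscal_year)) {
    subs <- s$count[s$fiscal_year == yr & s$category == "substance" &
                      s$substance_subgroup != "all"]
    expect_equal(sum(subs), pick(yr, "substance"))
  }
  one <- annual_summary(h[1, ])
  expect_true(all(one$count == 1))
})

test_that("fitting a parameter set from a history reproduces its inputs", {
  h <- fixture_history()
  p <- fit_simulation_parameters(h)
  expect_s3_class(p, "sim_params")
  expect_equal(p$ed_beds, 32L)
  expect_equal(p$pesu_capacity, 6L)
  expect_equal(unname(p$annual_rates[["NMHA"]]), 58947)
  expect_equal(unname(p$annual_rates[["alcohol"]]), 2119)
  expect_equal(unname(p$annual_rates[["schizophrenia"]]), 484)
  svc <- p$service
  sub_d <- svc[svc$category == "substance" & svc$disposition == "discharged", ]
  expect_equal(sub_d$mean_hours, 5.8, tolerance = 0.1)
})
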
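test_that("Poisson arrival generator matches its distributional oracles", {
  expect_equal(simulate_arrivals(Inf, 100), numeric(0))
  expect_error(simulate_arrivals(0, 100), "positive")
  expect_error(simulate_arrivals(-1, 100), "positive")
  set.seed(21)
  arr <- simulate_arrivals(8760 / 58947, 8760)
  expect_true(!is.unsorted(arr, strictly = TRUE))
  expect_true(all(arr > 0 & arr <= 8760))
  # count within the Poisson 99% band
  expect_lt(abs(length(arr) - 58947), 2.58 * sqrt(58947))
  # gap distribution: KS against the exponential, alpha = 0.01
  set.seed(22)
  gaps <- diff(simulate_arrivals(2, 2100))
  expect_gt(length(gaps), 999)
  expect_gt(ks.test(gaps, "pexp", rate = 0.5)$p.value, 0.01)
})

test_that("single-server queue matches the M/M/1 sojourn-time formula", {
  lambda <- 0.7
  mu <- 1
  w_theory <- 1 / (mu - lambda) # = 3.333 h
  los <- sapply(1:8, function(s) {
    pat <- exp_patients(20000, lambda, mu, seed = 100 + s)
    sim <- simulate_patient_flow(pat, ed_beds = 1, pesu_capacity = 0,
                                 horizon = 20000, warmup = 2000)
    mean(sim$los[sim$arrival > 2000 & !is.na(sim$los)])
  })
  se <- sd(los) / sqrt(length(los))
  expect_lt(abs(mean(los) - w_theory), 3 * se)
})

test_that("with ample beds the LOS equals the service requirement exactly", {
  pat <- exp_patients(5000, lambda = 1, mu = 0.5, seed = 42)
  sim <- simulate_patient_flow(pat, ed_beds = 10 * ceiling(1 / 0.5) * 10,
                               pesu_capacity = 0, horizon = 5000)
  done <- !is.na(sim$los)
  expect_true(all(sim$service_start[done] == sim$arrival[done]))
  expect_equal(sim$los[done], sim$treat_total[done])
})

test_that("every trace conserves flow and respects capacity bounds", {
  p <- fixture_baseline()
  r <- run_replication(p, 4, detail = TRUE)
  expect_equal(r$arrivals_total, r$departures + r$censored)
  pat <- attr(r, "patients")
  expect_equal(nrow(pat), r$arrivals_total)

  # reconstruct ED and PESU occupancy step functions from the trace
  occupancy_max <- function(starts, ends) {
    ev <- rbind(data.frame(t = starts, d = 1), data.frame(t = ends, d = -1))
    ev <- ev[is.finite(ev$t), ]
    ev <- ev[order(ev$t, ev$d), ] # releases before seizes on ties
    max(cumsum(ev$d))
  }
  in_bed <- !is.na(pat$service_start)
  bed_end <- ifelse(pat$transferred & !is.na(pat$transfer_time),
                    pmin(pat$transfer_time,
                         pat$service_start + pat$bed_hold, na.rm = TRUE),
                    pat$service_start + pat$bed_hold)
  expect_lte(occupancy_max(pat$service_start[in_bed], bed_end[in_bed]),
             p$ed_beds)
  pesu_start <- ifelse(pat$transferred, pat$transfer_time, pat$arrival)
  expect_lte(occupancy_max(pesu_start[pat$in_pesu], pat$depart[pat$in_pesu]),
             p$pesu_capacity)

  # LOS accounting: ED-path LOS = wait + total requirement
  ed_done <- pat$status == 2 & !is.na(pat$los)
  expect_equal(pat$los[ed_done],
               (pat$service_start - pat$arrival + pat$treat_total)[ed_done])
  # PESU direct entrants: LOS is exactly the drawn stay
  direct <- pat$in_pesu & !pat$transferred & !is.na(pat$los)
  expect_equal(pat$los[direct], pat$stay_direct[direct])
})

test_that("replications are bit-identical under a fixed seed", {
  p <- mini_params()
  r1 <- run_replication(p, 12)
  r2 <- run_replication(p, 12)
  expect_identical(r1, r2)
  r3 <- run_replication(p, 13)
  expect_false(identical(r1$mean_los_overall, r3$mean_los_overall))
})

test_that("zero arrival rates give all-zero KPI counts", {
  p <- mini_params()
  p$annual_rates[] <- 0
  r <- run_replication(p, 1)
  expect_equal(r$arrivals_total, 0)
  expect_equal(r$pesu_treated, 0)
  expect_true(is.na(r$mean_los_overall))
})

test_that("load and capacity move the KPIs in the expected direction", {
  p <- mini_params(warmup_hours = 504)
  p$pesu_eligibility <- 0.5
  base <- run_experiment(p, 4, 31)
  up <- p
  up$annual_rates <- p$annual_rates * 3
  more <- run_experiment(up, 4, 31)
  expect_gte(kpi_mean(more, "mean_los_overall"),
             kpi_mean(base, "mean_los_overall"))
  cap <- p
  cap$pesu_capacity <- 4L
  wide <- run_experiment(cap, 4, 31)
  expect_gte(kpi_mean(wide, "pesu_share") + 1e-9,
             kpi_mean(base, "pesu_share"))
})

test_that("experiment summaries behave like t intervals", {
  p <- mini_params()
  expect_error(run_experiment(p, 1), ">= 2")
  # degenerate single-class model with ample capacity: every LOS equals
  # the same constant, so the interval has zero width
  d <- mini_params()
  d$ed_beds <- 10000L
  d$pesu_eligibility <- 0
  d$annual_rates[setdiff(names(d$annual_rates), "NMHA")] <- 0
  d$service$sdlog <- 0
  d$service$meanlog <- log(5)
  d$service$mean_hours <- 5
  rep <- run_experiment(d, 3, 5)
  los <- rep$kpis[rep$kpis$kpi == "mean_los_overall", ]
  expect_equal(los$mean, 5)
  expect_lt(los$upper - los$lower, 1e-9)
  # doubling replications narrows the interval roughly as 1/sqrt(2)
  p2 <- mini_params()
  w1 <- run_experiment(p2, 6, 7)$kpis
  w2 <- run_experiment(p2, 12, 7)$kpis
  width <- function(k, name) {
    r <- k[k$kpi == name, ]
    r$upper - r$lower
  }
  ratio <- width(w2, "mean_los_overall") / width(w1, "mean_los_overall")
  expect_lt(ratio, 1)
})
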
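# Shared fixtures, built once per test run and memoised.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, force(expr), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# Full five-year default synthetic history (~300k records).
fixture_history <- function() {
  memo("history", generate_visit_history(default_synthetic_config(), seed = 1))
}

# A scaled-down hospital (1/40th demand, 4 ED beds, 1 PESU space) for tests
# that exercise search or many experiments.
mini_params <- function(...) {
  p <- default_parameter_set(...)
  p$annual_rates <- round(p$annual_rates / 40)
  p$ed_beds <- 4L
  p$pesu_capacity <- 1L
  p
}

# A plausible calibrated-like baseline, used where the tests need realistic
# knob values without paying for a full calibration run.
fixture_baseline <- function() {
  memo("baseline", {
    p <- default_parameter_set()
    p$pesu_eligibility <- 0.38
    p$service_scale <- 0.525
    p
  })
}

# Patient table for direct engine tests: a single non-eligible class with
# exponential interarrival and service times.
exp_patients <- function(n_or_horizon, lambda, mu, seed, horizon = NULL) {
  set.seed(seed)
  if (is.null(horizon)) horizon <- n_or_horizon
  arr <- cumsum(rexp(ceiling(horizon * lambda * 1.3) + 50, rate = lambda))
  arr <- arr[arr <= horizon]
  n <- length(arr)
  data.frame(arrival = arr, eligible = FALSE,
             bed_hold = rexp(n, rate = mu), stay_direct = 0,
             stay_transfer = 0) -> d
  d$treat_total <- d$bed_hold
  d[, c("arrival", "eligible", "bed_hold", "treat_total",
        "stay_direct", "stay_transfer")]
}
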
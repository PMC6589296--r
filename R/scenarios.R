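#' Published demand forecasts used by scenarios A and E
#'
#' The forecast table for fiscal 2017 and 2018 that the growth scenarios
#' consume: per patient class, the fiscal-2016 demand and the selected
#' method's forecasts. The substance class is forecast as an aggregate; the
#' scenario builders rescale its five subgroup streams proportionally.
#'
#' @return data.frame with columns `class`, `demand_2016`, `forecast_2017`,
#'   `forecast_2018`.
#' @export
default_forecast_table <- function() {
  data.frame(
    class = c("NMHA", "substance", "schizophrenia", "mood", "anxiety", "others"),
    demand_2016 = c(58947, 2879, 484, 1155, 1454, 159),
    forecast_2017 = c(61995, 3206, 486, 1027, 1424, 159),
    forecast_2018 = c(63800, 3471, 486, 1131, 1467, 177),
    stringsAsFactors = FALSE)
}

new_scenario_config <- function(id, rate_multipliers = NULL,
                                absolute_rates = NULL, pesu_capacity = NULL) {
  if (!is.null(rate_multipliers) && any(rate_multipliers <= 0)) {
    stop("rate multipliers must be positive")
  }
  structure(list(id = id, rate_multipliers = rate_multipliers,
                 absolute_rates = absolute_rates,
                 pesu_capacity = pesu_capacity),
            class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("<scenario_config>", x$id, "\n")
  if (!is.null(x$rate_multipliers)) {
    cat("  multipliers:", paste(names(x$rate_multipliers),
                                round(x$rate_multipliers, 3), sep = "=",
                                collapse = ", "), "\n")
  }
  if (!is.null(x$absolute_rates)) {
    cat("  absolute annual rates:",
        paste(names(x$absolute_rates), round(x$absolute_rates, 1), sep = "=",
              collapse = ", "), "\n")
  }
  if (!is.null(x$pesu_capacity)) cat("  PESU capacity:", x$pesu_capacity, "\n")
  invisible(x)
}

# Per-class annual demands -> per-stream absolute rates. The substance
# aggregate is split over its subgroup streams proportionally to their
# current rates.
class_demands_to_rates <- function(params, demands) {
  need <- c("NMHA", "substance", "schizophrenia", "mood", "anxiety", "others")
  if (!all(need %in% names(demands))) {
    stop("missing class forecast(s): ",
         paste(setdiff(need, names(demands)), collapse = ", "))
  }
  rates <- params$annual_rates
  sub_streams <- c("alcohol", "opioid", "cannabis", "multiple", "substance_other")
  sub_total <- sum(rates[sub_streams])
  if (sub_total > 0) {
    rates[sub_streams] <- rates[sub_streams] * demands[["substance"]] / sub_total
  }
  for (cl in c("NMHA", "schizophrenia", "mood", "anxiety", "others")) {
    rates[[cl]] <- demands[[cl]]
  }
  rates
}

#' Scenario A: forecasted demand for fiscal 2017 and 2018
#'
#' Replaces each class's annual arrival rate with its forecast; substance
#' subgroup rates are scaled proportionally within the substance total.
#'
#' @param params baseline `sim_params`.
#' @param forecast_table per-class forecasts
#'   (default [default_forecast_table()]).
#' @return list of two `scenario_config`s, ids `A2017` and `A2018`.
#' @export
build_scenario_a <- function(params, forecast_table = default_forecast_table()) {
  lapply(c("2017", "2018"), function(yr) {
    col <- paste0("forecast_", yr)
    if (!col %in% names(forecast_table)) stop("forecast table lacks ", col)
    demands <- setNames(forecast_table[[col]], forecast_table$class)
    new_scenario_config(paste0("A", yr),
                        absolute_rates = class_demands_to_rates(params, demands))
  })
}

#' Scenario B: alcohol/opioid diversion programs
#'
#' Decreases the alcohol and opioid arrival rates by `reduction_pct`
#' percent (deterministic thinning of the Poisson streams, distributionally
#' equivalent to removing each arrival independently with that
#' probability); everything else is unchanged.
#'
#' @param params baseline `sim_params`.
#' @param reduction_pct percentage reduction in (0, 100); the study ladder
#'   is 10, 30, 45, 63.
#' @return a `scenario_config` with id `B<pct>`.
#' @export
build_scenario_b <- function(params, reduction_pct) {
  if (reduction_pct <= 0 || reduction_pct >= 100) {
    stop("reduction_pct must lie in (0, 100)")
  }
  if (params$annual_rates[["alcohol"]] + params$annual_rates[["opioid"]] <= 0) {
    stop("alcohol and opioid streams are absent from the baseline")
  }
  m <- 1 - reduction_pct / 100
  new_scenario_config(paste0("B", reduction_pct),
                      rate_multipliers = c(alcohol = m, opioid = m))
}

#' Scenario C: cannabis legalization
#'
#' Adjusts the cannabis arrival rate by +19% in year one and by -27% in
#' year two, the second change applied sequentially to the year-one level
#' (mirroring the two post-legalization years it emulates).
#'
#' @param params baseline `sim_params`.
#' @return list of two `scenario_config`s, ids `C_year1` and `C_year2`.
#' @export
build_scenario_c <- function(params) {
  list(new_scenario_config("C_year1", rate_multipliers = c(cannabis = 1.19)),
       new_scenario_config("C_year2",
                           rate_multipliers = c(cannabis = 1.19 * 0.73)))
}

#' Scenarios D and E: PESU bed expansion
#'
#' Scenario D increases the PESU capacity only (baseline demand); scenario
#' E combines each bed count with scenario A's forecasted demand, one
#' config per (year, bed count).
#'
#' @param params baseline `sim_params`.
#' @param beds new PESU capacities (each must exceed the current capacity);
#'   the study ladder is 7, 8, 9, 10.
#' @param forecast_table per-class forecasts for scenario E.
#' @return `build_scenario_d`: a `scenario_config` (or list if `beds` has
#'   length > 1); `build_scenario_e`: list of `scenario_config`s.
#' @export
build_scenario_d <- function(params, beds) {
  if (any(beds <= params$pesu_capacity)) {
    stop("beds must exceed the current PESU capacity (",
         params$pesu_capacity, ")")
  }
  out <- lapply(beds, function(b) {
    new_scenario_config(paste0("D", b), pesu_capacity = as.integer(b))
  })
  if (length(out) == 1) out[[1]] else out
}

#' @rdname build_scenario_d
#' @export
build_scenario_e <- function(params, beds,
                             forecast_table = default_forecast_table()) {
  if (any(beds <= params$pesu_capacity)) {
    stop("beds must exceed the current PESU capacity (",
         params$pesu_capacity, ")")
  }
  a_configs <- build_scenario_a(params, forecast_table)
  out <- list()
  for (a in a_configs) {
    yr <- sub("^A", "", a$id)
    for (b in beds) {
      out[[length(out) + 1]] <- new_scenario_config(
        paste0("E", yr, "_", b),
        absolute_rates = a$absolute_rates, pesu_capacity = as.integer(b))
    }
  }
  out
}

#' Apply a scenario configuration to a parameter set
#'
#' Pure transformation: returns a modified copy, leaving the baseline
#' untouched.
#'
#' @param config a `scenario_config`.
#' @param params baseline `sim_params`.
#' @return transformed `sim_params`.
#' @export
apply_scenario <- function(config, params) {
  stopifnot(inherits(config, "scenario_config"))
  p <- params
  if (!is.null(config$absolute_rates)) {
    p$annual_rates[names(config$absolute_rates)] <- config$absolute_rates
  }
  if (!is.null(config$rate_multipliers)) {
    p$annual_rates[names(config$rate_multipliers)] <-
      p$annual_rates[names(config$rate_multipliers)] * config$rate_multipliers
  }
  if (!is.null(config$pesu_capacity)) {
    if (config$pesu_capacity <= params$pesu_capacity) {
      stop("scenario PESU capacity must exceed the current capacity")
    }
    p$pesu_capacity <- config$pesu_capacity
  }
  validate_parameters(p)
}

#' Run a scenario with common random numbers against its baseline
#'
#' Applies the scenario to the calibrated baseline, runs the replicated
#' experiment with the same replication seeds as the baseline, and attaches
#' per-replication paired deltas (scenario minus baseline) for the two
#' headline KPIs.
#'
#' @param config a `scenario_config`.
#' @param params calibrated baseline `sim_params`.
#' @param n_replications,base_seed experiment size and first seed.
#' @param baseline optional pre-computed baseline `kpi_report` run with the
#'   same `n_replications` and `base_seed` (avoids re-running it per
#'   scenario).
#' @return a `kpi_report` with extra elements `scenario` (id), `deltas`
#'   (per-replication paired differences in `mean_los_overall` and
#'   `pesu_share`) and `baseline_kpis`.
#' @export
run_scenario <- function(config, params,
                         n_replications = params$n_replications,
                         base_seed = params$base_seed, baseline = NULL) {
  if (is.null(baseline)) {
    baseline <- run_experiment(params, n_replications, base_seed)
  }
  if (baseline$n_replications != n_replications ||
      baseline$base_seed != base_seed) {
    stop("baseline report was run with different replications or seeds")
  }
  sc <- run_experiment(apply_scenario(config, params), n_replications,
                       base_seed)
  sc$scenario <- config$id
  sc$deltas <- data.frame(
    seed = sc$replications$seed,
    delta_los = sc$replications$mean_los_overall -
      baseline$replications$mean_los_overall,
    delta_share = sc$replications$pesu_share -
      baseline$replications$pesu_share)
  sc$baseline_kpis <- baseline$kpis
  sc
}

#' Run a suite of scenarios and tabulate the comparison
#'
#' Runs every scenario against a single shared baseline (common random
#' numbers) and returns the comparison table used for reporting: one row
#' per scenario with mean overall LOS and PESU share, their 95% CIs, and
#' paired deltas versus baseline.
#'
#' @param params calibrated baseline `sim_params`.
#' @param configs list of `scenario_config`s.
#' @param n_replications,base_seed experiment size and first seed.
#' @return list with `table` (comparison data.frame, baseline row first)
#'   and `reports` (named list of `kpi_report`s).
#' @export
run_scenario_suite <- function(params, configs,
                               n_replications = params$n_replications,
                               base_seed = params$base_seed) {
  baseline <- run_experiment(params, n_replications, base_seed)
  row_of <- function(report, id, deltas = NULL) {
    g <- function(k) report$kpis[report$kpis$kpi == k, ]
    los <- g("mean_los_overall")
    sh <- g("pesu_share")
    data.frame(scenario = id, mean_los = los$mean, los_lower = los$lower,
               los_upper = los$upper, pesu_share = sh$mean,
               share_lower = sh$lower, share_upper = sh$upper,
               delta_los = if (is.null(deltas)) 0 else mean(deltas$delta_los),
               delta_share = if (is.null(deltas)) 0 else mean(deltas$delta_share))
  }
  reports <- list(baseline = baseline)
  rows <- list(row_of(baseline, "baseline"))
  for (cfg in configs) {
    rep <- run_scenario(cfg, params, n_replications, base_seed,
                        baseline = baseline)
    reports[[cfg$id]] <- rep
    rows[[length(rows) + 1]] <- row_of(rep, cfg$id, rep$deltas)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  list(table = tab, reports = reports)
}
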
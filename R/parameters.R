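# Constructor shared by default_parameter_set() and
# fit_simulation_parameters(). Not exported; use those entry points.
new_sim_params <- function(ed_beds, pesu_capacity, annual_rates, ctas_prob,
                           disposition_prob, service,
                           pesu_stay = c(min = 1, mode = 6, max = 17),
                           pesu_eligibility = 1.0, service_scale = 0.6,
                           horizon_hours = HOURS_PER_YEAR,
                           warmup_hours = 504, n_replications = 20,
                           base_seed = 1) {
  rownames(service) <- NULL
  p <- structure(list(
    ed_beds = as.integer(ed_beds), pesu_capacity = as.integer(pesu_capacity),
    annual_rates = annual_rates, ctas_prob = ctas_prob,
    disposition_prob = disposition_prob, service = service,
    pesu_stay = pesu_stay, pesu_eligibility = pesu_eligibility,
    service_scale = service_scale, horizon_hours = horizon_hours,
    warmup_hours = warmup_hours, n_replications = as.integer(n_replications),
    base_seed = as.integer(base_seed)), class = "sim_params")
  validate_parameters(p)
}

#' Default (baseline fiscal-2016) simulation parameters
#'
#' Baseline parameter set for the ED/PESU model: 32 ED beds, 6 PESU spaces,
#' per-stream annual arrival rates equal to the fiscal-2016 demand (NMHA
#' 58,947; substance split into its five subgroup rates 2,119 / 74 / 73 /
#' 453 / 160; schizophrenia 484; mood 1,155; anxiety 1,454; others 159),
#' routing proportions and disposition-specific lognormal service
#' distributions taken from [default_synthetic_config()], a triangular PESU
#' stay with default (min 1, mode 6, max 17) hours (mean 8 h -- the true
#' unit parameters are unpublished; these are documented defaults subject
#' to [calibrate_baseline()]), PESU eligibility 1.0 and bed-holding scale
#' `service_scale = 0.6`, both calibration knobs.
#'
#' @param ... overrides passed to the internal constructor
#'   (e.g. `pesu_capacity = 10`, `base_seed = 7`).
#' @return a `sim_params` object.
#' @examples
#' p <- default_parameter_set()
#' p$ed_beds          # 32
#' p$pesu_capacity    # 6
#' p$annual_rates[["schizophrenia"]]  # 484
#' @export
default_parameter_set <- function(...) {
  cfg <- default_synthetic_config()
  rates <- cfg$volumes[, "2016"]
  service <- do.call(rbind, lapply(CATEGORIES, function(cat_) {
    do.call(rbind, lapply(DISPOSITIONS, function(d) {
      lp <- lnorm_params(cfg$los_mean[cat_, d], cfg$los_cv[cat_])
      data.frame(category = cat_, ctas = NA_integer_, disposition = d,
                 meanlog = lp$meanlog, sdlog = lp$sdlog,
                 mean_hours = cfg$los_mean[cat_, d], stringsAsFactors = FALSE)
    }))
  }))
  disp <- array(rep(cfg$disposition_prob, each = 5),
                c(5, length(CATEGORIES), length(DISPOSITIONS)))
  disp <- aperm(disp, c(2, 1, 3))
  dimnames(disp) <- list(CATEGORIES, 1:5, DISPOSITIONS)
  new_sim_params(ed_beds = 32, pesu_capacity = 6, annual_rates = rates,
                 ctas_prob = cfg$ctas_prob, disposition_prob = disp,
                 service = service, ...)
}

#' Validate simulation parameters
#'
#' Enforces the structural invariants of the model: at least one ED bed,
#' non-negative PESU capacity, non-negative arrival rates, proportion
#' vectors summing to one, positive service scales, eligibility in
#' \[0, 1\], `service_scale` in (0, 1\], and an ordered triangular stay
#' (min <= mode <= max).
#'
#' @param params a `sim_params` object.
#' @return the params, invisibly; errors on any violation.
#' @export
validate_parameters <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  if (params$ed_beds < 1) stop("ed_beds must be >= 1")
  if (params$pesu_capacity < 0) stop("pesu_capacity must be >= 0")
  if (any(params$annual_rates < 0)) stop("annual arrival rates must be >= 0")
  if (!all(STREAMS %in% names(params$annual_rates))) {
    stop("annual_rates must be named for all streams: ",
         paste(STREAMS, collapse = ", "))
  }
  active <- unique(stream_category(names(params$annual_rates)[params$annual_rates > 0]))
  cs <- rowSums(params$ctas_prob)[active]
  ds <- apply(params$disposition_prob, c(1, 2), sum)[active, , drop = FALSE]
  if (any(abs(cs - 1) > 1e-9)) stop("CTAS proportions of active categories must sum to 1")
  if (any(abs(ds - 1) > 1e-9)) stop("disposition proportions of active categories must sum to 1")
  if (any(params$service$sdlog < 0)) stop("service sdlog must be >= 0")
  tri <- params$pesu_stay
  if (!(tri[["min"]] <= tri[["mode"]] && tri[["mode"]] <= tri[["max"]]) ||
      tri[["min"]] < 0) {
    stop("pesu_stay must satisfy 0 <= min <= mode <= max")
  }
  if (params$pesu_eligibility < 0 || params$pesu_eligibility > 1) {
    stop("pesu_eligibility must be in [0, 1]")
  }
  if (params$service_scale <= 0 || params$service_scale > 1) {
    stop("service_scale must be in (0, 1]")
  }
  if (params$horizon_hours <= params$warmup_hours) {
    stop("horizon_hours must exceed warmup_hours")
  }
  invisible(params)
}

#' @export
print.sim_params <- function(x, ...) {
  cat("<sim_params> ED beds:", x$ed_beds, "| PESU spaces:", x$pesu_capacity,
      "\n  annual arrivals:", sum(x$annual_rates),
      sprintf("(NMHA %d, MHA %d)", x$annual_rates[["NMHA"]],
              sum(x$annual_rates) - x$annual_rates[["NMHA"]]), "\n")
  cat(sprintf("  PESU stay tri(%g, %g, %g) h | eligibility %.3f | service scale %.3f\n",
              x$pesu_stay[["min"]], x$pesu_stay[["mode"]], x$pesu_stay[["max"]],
              x$pesu_eligibility, x$service_scale))
  cat(sprintf("  horizon %g h, warm-up %g h, %d replications, base seed %d\n",
              x$horizon_hours, x$warmup_hours, x$n_replications, x$base_seed))
  invisible(x)
}
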
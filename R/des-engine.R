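#' Run the ED/PESU patient-flow simulation on a prepared patient table
#'
#' Low-level deterministic entry point to the event engine: takes one row
#' per patient with all stochastic quantities already drawn, and returns
#' the table augmented with the simulated trajectory. Used directly in
#' analytic-oracle tests (e.g. M/M/1 comparisons); [run_replication()] is
#' the usual entry point.
#'
#' @param patients data.frame with columns `arrival` (sorted ascending),
#'   `eligible` (logical: medically stable MHA patient who may use the
#'   PESU), `bed_hold` (ED bed-holding time, hours), `treat_total` (total
#'   treatment requirement `T`; ED-path LOS is wait + `treat_total`),
#'   `stay_direct` and `stay_transfer` (PESU stay draws, hours).
#' @param ed_beds,pesu_capacity resource capacities.
#' @param horizon,warmup simulation horizon and warm-up, hours.
#' @return the input data.frame with added columns `status`,
#'   `service_start`, `depart`, `in_pesu`, `transferred`, `transfer_time`,
#'   `los` (NA while censored) and attributes `ed_utilization`,
#'   `pesu_utilization` (mean over the post-warm-up window). Capacity
#'   violations (never expected) raise an error.
#' @export
simulate_patient_flow <- function(patients, ed_beds, pesu_capacity,
                                  horizon, warmup = 0) {
  stopifnot(is.data.frame(patients))
  need <- c("arrival", "eligible", "bed_hold", "treat_total",
            "stay_direct", "stay_transfer")
  missing <- setdiff(need, names(patients))
  if (length(missing)) stop("patients lacks column(s): ",
                            paste(missing, collapse = ", "))
  if (is.unsorted(patients$arrival)) stop("patients must be sorted by arrival")
  res <- des_core(patients$arrival, patients$eligible, patients$bed_hold,
                  patients$treat_total, patients$stay_direct,
                  patients$stay_transfer, as.integer(ed_beds),
                  as.integer(pesu_capacity), horizon, warmup)
  if (!res$capacity_ok) stop("internal error: resource capacity bound violated")
  patients$status <- res$status
  patients$service_start <- res$service_start
  patients$depart <- res$depart
  patients$in_pesu <- res$in_pesu
  patients$transferred <- res$transferred
  patients$transfer_time <- res$transfer_time
  patients$los <- ifelse(!is.na(patients$depart) & patients$depart <= horizon,
                         patients$depart - patients$arrival, NA_real_)
  attr(patients, "ed_utilization") <- res$ed_utilization
  attr(patients, "pesu_utilization") <- res$pesu_utilization
  patients
}

# Draw the full patient table for one replication. Every stream consumes
# two private RNG substreams (arrival gaps; per-patient marks laid out one
# row of six uniforms per arrival), so common random numbers survive both
# rate rescaling (exponential gaps scale) and capacity changes (marks are
# untouched).
draw_patients <- function(params, seed) {
  set.seed(as.integer(seed))
  subseeds <- matrix(sample.int(2147483646L, 2L * length(STREAMS)),
                     nrow = 2, dimnames = list(c("arrival", "marks"), STREAMS))
  svc <- params$service
  svc_key <- paste(svc$category, ifelse(is.na(svc$ctas), "any", svc$ctas),
                   svc$disposition)
  pieces <- list()
  for (stream in STREAMS) {
    rate <- params$annual_rates[[stream]]
    if (rate <= 0) next
    mean_ia <- HOURS_PER_YEAR / rate
    set.seed(subseeds["arrival", stream])
    arr <- simulate_arrivals(mean_ia, params$horizon_hours)
    n <- length(arr)
    if (n == 0) next
    set.seed(subseeds["marks", stream])
    u <- matrix(runif(6L * n), ncol = 6, byrow = TRUE)
    cat_ <- stream_category(stream)
    ctas <- pmin(findInterval(u[, 1], cumsum(params$ctas_prob[cat_, ])) + 1L, 5L)
    disp_idx <- integer(n)
    for (lev in 1:5) {
      s <- ctas == lev
      if (!any(s)) next
      disp_idx[s] <- pmin(findInterval(
        u[s, 2], cumsum(params$disposition_prob[cat_, lev, ])) + 1L,
        length(DISPOSITIONS))
    }
    disp <- DISPOSITIONS[disp_idx]
    # service lookup: class x ctas x disposition, then class x disposition
    key <- paste(cat_, ctas, disp)
    row <- match(key, svc_key)
    fallback <- is.na(row)
    if (any(fallback)) {
      row[fallback] <- match(paste(cat_, "any", disp[fallback]), svc_key)
    }
    if (anyNA(row)) stop("no service distribution for category '", cat_, "'")
    treat <- exp(svc$meanlog[row] + svc$sdlog[row] * qnorm(u[, 3]))
    is_mha <- cat_ != "NMHA"
    pieces[[stream]] <- data.frame(
      stream = stream, category = cat_, arrival = arr, ctas = ctas,
      disposition = disp, is_mha = is_mha,
      eligible = is_mha & u[, 4] <= params$pesu_eligibility,
      bed_hold = params$service_scale * treat, treat_total = treat,
      stay_direct = qtriangular(u[, 5], params$pesu_stay[["min"]],
                                params$pesu_stay[["mode"]],
                                params$pesu_stay[["max"]]),
      stay_transfer = qtriangular(u[, 6], params$pesu_stay[["min"]],
                                  params$pesu_stay[["mode"]],
                                  params$pesu_stay[["max"]]),
      stringsAsFactors = FALSE)
  }
  if (length(pieces) == 0) {
    return(data.frame(stream = character(), category = character(),
                      arrival = numeric(), ctas = integer(),
                      disposition = character(), is_mha = logical(),
                      eligible = logical(), bed_hold = numeric(),
                      treat_total = numeric(), stay_direct = numeric(),
                      stay_transfer = numeric(), stringsAsFactors = FALSE))
  }
  all <- do.call(rbind, pieces)
  all <- all[order(all$arrival), ]
  rownames(all) <- NULL
  all
}

#' Run one replication of the ED/PESU model
#'
#' Draws the arrival streams and patient marks for one replication seed,
#' runs the event engine, and summarises the replication's key performance
#' indicators. Patients arriving during the warm-up period are excluded
#' from LOS and PESU-share statistics; arrival counts are reported over the
#' full horizon. Patients still in the system at the horizon are censored
#' (excluded from LOS means, counted in `censored`).
#'
#' @param params a validated `sim_params` object.
#' @param seed integer replication seed; identical (params, seed) pairs
#'   give bit-identical results.
#' @param detail if `TRUE`, attach the per-patient trajectory table as
#'   attribute `"patients"`.
#' @return one-row data.frame of replication KPIs: per-stream arrival
#'   counts (`arrivals_*`), total/NMHA/MHA arrivals, departures, censored
#'   count, LOS means (overall, NMHA, MHA, per MHA category), PESU-treated
#'   count, `pesu_share` (%), and mean ED/PESU utilization.
#' @export
run_replication <- function(params, seed, detail = FALSE) {
  validate_parameters(params)
  pat <- draw_patients(params, seed)
  horizon <- params$horizon_hours
  warmup <- params$warmup_hours
  if (nrow(pat) == 0) {
    sim <- pat
    sim$los <- numeric(0)
    sim$in_pesu <- logical(0)
    attr(sim, "ed_utilization") <- NA_real_
    attr(sim, "pesu_utilization") <- NA_real_
  } else {
    sim <- simulate_patient_flow(pat, params$ed_beds, params$pesu_capacity,
                                 horizon, warmup)
  }

  post <- sim$arrival > warmup
  done <- !is.na(sim$los)
  kpi_los <- function(sel) {
    sel <- sel & post & done
    if (!any(sel)) NA_real_ else mean(sim$los[sel])
  }
  arr_by_stream <- sapply(STREAMS, function(s) sum(sim$stream == s))
  names(arr_by_stream) <- paste0("arrivals_", STREAMS)
  mha_post <- sum(sim$is_mha & post)
  pesu_treated <- sum(sim$in_pesu & post)

  out <- data.frame(
    seed = as.integer(seed),
    arrivals_total = nrow(sim),
    arrivals_nmha = sum(!sim$is_mha),
    arrivals_mha = sum(sim$is_mha),
    t(arr_by_stream),
    departures = sum(done),
    censored = nrow(sim) - sum(done),
    mean_los_overall = kpi_los(rep(TRUE, nrow(sim))),
    mean_los_nmha = kpi_los(!sim$is_mha),
    mean_los_mha = kpi_los(sim$is_mha),
    mean_los_substance = kpi_los(sim$category == "substance"),
    mean_los_schizophrenia = kpi_los(sim$category == "schizophrenia"),
    mean_los_mood = kpi_los(sim$category == "mood"),
    mean_los_anxiety = kpi_los(sim$category == "anxiety"),
    mean_los_others = kpi_los(sim$category == "others"),
    pesu_treated = pesu_treated,
    pesu_share = if (mha_post > 0) 100 * pesu_treated / mha_post else NA_real_,
    ed_utilization = attr(sim, "ed_utilization"),
    pesu_utilization = attr(sim, "pesu_utilization"))
  if (detail) attr(out, "patients") <- sim
  out
}

#' Run a replicated simulation experiment
#'
#' Runs `n_replications` independent replications with seeds
#' `base_seed + 0 ... base_seed + n - 1` and summarises every KPI with its
#' cross-replication mean and 95% t confidence interval.
#'
#' @param params a `sim_params` object.
#' @param n_replications number of replications (>= 2; default from
#'   `params`).
#' @param base_seed first replication seed (default from `params`).
#' @return a `kpi_report`: list with `kpis` (data.frame of name, mean,
#'   lower, upper, n) and `replications` (per-replication KPI table).
#' @export
run_experiment <- function(params, n_replications = params$n_replications,
                           base_seed = params$base_seed) {
  if (n_replications < 2) {
    stop("n_replications must be >= 2 (confidence intervals undefined)")
  }
  reps <- do.call(rbind, lapply(seq_len(n_replications) - 1L, function(i) {
    run_replication(params, base_seed + i)
  }))
  kpi_cols <- setdiff(names(reps), "seed")
  kpis <- do.call(rbind, lapply(kpi_cols, function(col) {
    x <- reps[[col]]
    x <- x[!is.na(x)]
    if (length(x) < 2) {
      return(data.frame(kpi = col, mean = if (length(x)) mean(x) else NA_real_,
                        lower = NA_real_, upper = NA_real_, n = length(x)))
    }
    ci <- ci95(x)
    data.frame(kpi = col, mean = ci[["mean"]], lower = ci[["lower"]],
               upper = ci[["upper"]], n = length(x))
  }))
  structure(list(kpis = kpis, replications = reps,
                 n_replications = n_replications, base_seed = base_seed),
            class = "kpi_report")
}

#' @export
print.kpi_report <- function(x, ...) {
  cat("<kpi_report>", x$n_replications, "replications (base seed",
      paste0(x$base_seed, ")\n"))
  main <- x$kpis[x$kpis$kpi %in%
                   c("arrivals_nmha", "arrivals_mha", "mean_los_overall",
                     "mean_los_nmha", "mean_los_mha", "pesu_share"), ]
  print(transform(main, mean = round(mean, 2), lower = round(lower, 2),
                  upper = round(upper, 2)), row.names = FALSE)
  invisible(x)
}

# Convenience accessor: mean of one KPI from a kpi_report.
kpi_mean <- function(report, kpi) {
  report$kpis$mean[report$kpis$kpi == kpi]
}
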
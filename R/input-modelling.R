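#' Fit an exponential interarrival distribution for one patient class
#'
#' Under a homogeneous Poisson arrival model the maximum-likelihood estimate
#' of the mean interarrival time is the observation window divided by the
#' arrival count.
#'
#' @param records visit-record data.frame (see [generate_visit_history()]).
#' @param patient_class a stream name (`"NMHA"`, a substance subgroup
#'   stream, or one of the other MHA categories) or a category name.
#' @param observation_hours length of the observation window, hours.
#' @return list with `patient_class` and `mean_interarrival` (hours).
#' @export
fit_interarrival <- function(records, patient_class, observation_hours) {
  stopifnot(observation_hours > 0)
  n <- sum(record_stream(records) == patient_class |
             records$category == patient_class)
  if (n == 0) stop("no records of class '", patient_class, "'")
  list(patient_class = patient_class,
       mean_interarrival = observation_hours / n)
}

# Stream label of each record (substance records keyed by subgroup).
record_stream <- function(records) {
  ifelse(records$category == "substance",
         ifelse(records$substance_subgroup == "other", "substance_other",
                records$substance_subgroup),
         records$category)
}

#' Fit a lognormal service (LOS) distribution for one stratum
#'
#' Fits a lognormal to `los_hours` in the (class, CTAS, disposition)
#' stratum, by default with method-of-moments on the arithmetic mean and
#' variance; maximum likelihood on the log scale is available via
#' `method = "mle"`. Strata with fewer than two records fall back
#' hierarchically -- class x disposition, then class -- and the fallback is
#' recorded in the returned `stratum` element (and signalled as a message).
#' A zero-variance stratum yields a degenerate fit (`sdlog = 0`), flagged
#' via `degenerate = TRUE`.
#'
#' @param records visit-record data.frame.
#' @param patient_class visit category (e.g. `"substance"`).
#' @param ctas CTAS level 1--5, or `NULL` to pool over acuity.
#' @param disposition disposition label, or `NULL` to pool.
#' @param method `"moments"` (default) or `"mle"`.
#' @return list with `patient_class`, `ctas`, `disposition`, `meanlog`,
#'   `sdlog`, `mean_hours` (implied arithmetic mean), `n`, `stratum`
#'   (the stratum actually used) and `degenerate`.
#' @export
fit_service <- function(records, patient_class, ctas = NULL,
                        disposition = NULL, method = c("moments", "mle")) {
  method <- match.arg(method)
  sel_class <- records$category == patient_class
  if (!any(sel_class)) stop("no records of class '", patient_class, "'")

  strata <- list(
    list(ctas = ctas, disposition = disposition, label = "class x ctas x disposition"),
    list(ctas = NULL, disposition = disposition, label = "class x disposition"),
    list(ctas = NULL, disposition = NULL, label = "class"))
  for (i in seq_along(strata)) {
    st <- strata[[i]]
    sel <- sel_class
    if (!is.null(st$ctas)) sel <- sel & records$ctas == st$ctas
    if (!is.null(st$disposition)) sel <- sel & records$disposition == st$disposition
    if (sum(sel) >= 2) {
      if (i > 1) {
        message("fit_service: stratum (", patient_class, ", ",
                ctas %||% "any", ", ", disposition %||% "any",
                ") too sparse; falling back to ", st$label)
      }
      x <- records$los_hours[sel]
      if (method == "mle") {
        meanlog <- mean(log(x))
        sdlog <- sqrt(mean((log(x) - meanlog)^2))
      } else {
        m <- mean(x)
        v <- var(x)
        cv2 <- v / m^2
        sdlog <- sqrt(log(1 + cv2))
        meanlog <- log(m) - sdlog^2 / 2
      }
      degenerate <- !is.finite(sdlog) || sdlog < 1e-12
      if (degenerate) {
        sdlog <- 0
        meanlog <- log(mean(x))
      }
      return(list(patient_class = patient_class, ctas = ctas,
                  disposition = disposition, meanlog = meanlog,
                  sdlog = sdlog,
                  mean_hours = exp(meanlog + sdlog^2 / 2),
                  n = sum(sel), stratum = st$label,
                  degenerate = degenerate))
    }
  }
  stop("fewer than two records of class '", patient_class,
       "' at any fallback level")
}

#' Empirical CTAS and disposition proportions
#'
#' Computes, per visit category, the empirical CTAS distribution and the
#' per-(category, CTAS) disposition distribution. CTAS levels unobserved in
#' a category get probability zero; (category, CTAS) cells with no records
#' inherit the category-level disposition mix so every returned vector sums
#' to one.
#'
#' @param records visit-record data.frame; every category present must have
#'   at least one record.
#' @return list with `ctas` (category x 5 matrix) and `disposition`
#'   (category x 5 x 5 array, dims category, CTAS, disposition).
#' @export
estimate_proportions <- function(records) {
  if (nrow(records) == 0) stop("at least one record per class is required")
  cats <- unique(records$category)
  ctas <- matrix(0, length(cats), 5, dimnames = list(cats, 1:5))
  disp <- array(0, c(length(cats), 5, length(DISPOSITIONS)),
                dimnames = list(cats, 1:5, DISPOSITIONS))
  for (cat_ in cats) {
    sel <- records$category == cat_
    if (!any(sel)) stop("no records for category '", cat_, "'")
    tc <- tabulate(records$ctas[sel], nbins = 5)
    ctas[cat_, ] <- tc / sum(tc)
    marg <- table(factor(records$disposition[sel], levels = DISPOSITIONS))
    marg <- as.numeric(marg) / sum(marg)
    for (lev in 1:5) {
      s2 <- sel & records$ctas == lev
      if (any(s2)) {
        td <- table(factor(records$disposition[s2], levels = DISPOSITIONS))
        disp[cat_, lev, ] <- as.numeric(td) / sum(td)
      } else {
        disp[cat_, lev, ] <- marg
      }
    }
  }
  list(ctas = ctas, disposition = disp)
}

#' Annual visit counts by category and substance subgroup
#'
#' @param records visit-record data.frame.
#' @return data.frame with one row per (fiscal_year, category,
#'   substance_subgroup) and a `count` column, plus per-year `total` rows
#'   (category `"total"`).
#' @examples
#' h <- generate_visit_history(default_synthetic_config(), seed = 1)
#' s <- annual_summary(h)
#' s$count[s$fiscal_year == "2016" & s$category == "substance" &
#'         s$substance_subgroup == "all"]  # 2879
#' @export
annual_summary <- function(records) {
  stopifnot(nrow(records) >= 1)
  agg <- aggregate(list(count = records$arrival_time),
                   by = list(fiscal_year = records$fiscal_year,
                             category = records$category,
                             substance_subgroup = records$substance_subgroup),
                   FUN = length)
  # category-level rollups (subgroup = "all") and per-year totals
  cat_agg <- aggregate(list(count = agg$count),
                       by = list(fiscal_year = agg$fiscal_year,
                                 category = agg$category),
                       FUN = sum)
  cat_agg$substance_subgroup <- "all"
  tot <- aggregate(list(count = cat_agg$count),
                   by = list(fiscal_year = cat_agg$fiscal_year), FUN = sum)
  tot$category <- "total"
  tot$substance_subgroup <- "all"
  out <- rbind(agg[agg$category == "substance", ],
               cat_agg[, names(agg)], tot[, names(agg)])
  out <- out[order(out$fiscal_year, out$category, out$substance_subgroup), ]
  rownames(out) <- NULL
  out
}

#' Fit a full simulation parameter set from a visit history
#'
#' Convenience wrapper reproducing the study's input-modelling stage:
#' per-stream exponential interarrival fits, per (category, CTAS,
#' disposition) lognormal LOS fits with hierarchical fallback, and
#' empirical routing proportions, assembled into a simulation parameter
#' object. Arrival rates are fitted on the records of `fiscal_year` only
#' (default: the latest year present).
#'
#' @param records visit-record data.frame.
#' @param fiscal_year fiscal-year label used for arrival rates.
#' @param ed_beds,pesu_capacity resource capacities.
#' @param ... further arguments stored into the parameter object (e.g.
#'   `pesu_stay`, `pesu_eligibility`, `service_scale`).
#' @return a `sim_params` object (see [default_parameter_set()]).
#' @export
fit_simulation_parameters <- function(records, fiscal_year = NULL,
                                      ed_beds = 32, pesu_capacity = 6, ...) {
  fiscal_year <- fiscal_year %||% max(records$fiscal_year)
  yr <- records[records$fiscal_year == fiscal_year, ]
  if (nrow(yr) == 0) stop("no records in fiscal year ", fiscal_year)
  streams <- record_stream(yr)
  rates <- sapply(STREAMS, function(s) sum(streams == s))

  props <- estimate_proportions(records)
  # densify to the canonical category set (absent categories keep zeros and
  # zero rates, so they are never sampled)
  ctas <- matrix(0, length(CATEGORIES), 5, dimnames = list(CATEGORIES, 1:5))
  disp <- array(0, c(length(CATEGORIES), 5, length(DISPOSITIONS)),
                dimnames = list(CATEGORIES, 1:5, DISPOSITIONS))
  ctas[rownames(props$ctas), ] <- props$ctas
  disp[rownames(props$ctas), , ] <- props$disposition

  service <- do.call(rbind, lapply(CATEGORIES, function(cat_) {
    if (!any(records$category == cat_)) return(NULL)
    do.call(rbind, lapply(DISPOSITIONS, function(d) {
      fit <- suppressMessages(fit_service(records, cat_, disposition = d))
      data.frame(category = cat_, ctas = NA_integer_, disposition = d,
                 meanlog = fit$meanlog, sdlog = fit$sdlog,
                 mean_hours = fit$mean_hours, stringsAsFactors = FALSE)
    }))
  }))

  new_sim_params(ed_beds = ed_beds, pesu_capacity = pesu_capacity,
                 annual_rates = rates, ctas_prob = ctas,
                 disposition_prob = disp, service = service, ...)
}
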
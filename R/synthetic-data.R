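# ICD-10 code pools used when materialising synthetic records. Each pool
# maps back to its own stream under categorize_icd() (tested invariant).
ICD_POOLS <- list(
  NMHA            = c("A09", "I10", "I21", "J06", "J18", "K35", "M54",
                      "R07", "R10", "S72", "T14", "Z00"),
  alcohol         = c("F10", "F10.0", "F10.1", "F10.2"),
  opioid          = c("F11", "F11.0", "F11.2"),
  cannabis        = c("F12", "F12.0", "F12.5"),
  multiple        = c("F19", "F19.2"),
  substance_other = c("F13", "F14", "F15", "F16", "F17", "F18", "F55"),
  schizophrenia   = c("F20", "F20.0", "F21", "F22", "F23", "F25", "F28", "F29"),
  mood            = c("F30", "F31", "F32", "F33", "F34", "F39"),
  anxiety         = c("F40", "F41", "F42", "F43", "F44", "F45", "F48"),
  others          = c("F50", "F52", "F59", "F60", "F63", "F65", "F68",
                      "F69", "X60", "X75", "X84"))

# Lognormal(meanlog, sdlog) parameters from an arithmetic mean and a
# coefficient of variation.
lnorm_params <- function(mean, cv) {
  sdlog <- sqrt(log(1 + cv^2))
  list(meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

#' Generate a synthetic visit history
#'
#' Materialises one visit record per configured arrival: for every fiscal
#' year and stream the record count equals the configured annual volume
#' exactly; arrival timestamps are uniform within the year (8,760 h per
#' fiscal year, hours since the start of the first fiscal year); lengths of
#' stay are lognormal with the configured disposition-specific mean and
#' category-level coefficient of variation; CTAS levels and discharge
#' dispositions are drawn from the configured proportions. The output is
#' reproducible: two calls with the same config and seed return identical
#' tables.
#'
#' @param config a [default_synthetic_config()]-style `synthetic_config`.
#' @param seed integer random seed.
#' @return data.frame with one row per visit and columns `arrival_time`
#'   (hours), `fiscal_year`, `icd_code`, `category`, `substance_subgroup`,
#'   `ctas`, `disposition`, `los_hours`.
#' @examples
#' cfg <- default_synthetic_config()
#' h <- generate_visit_history(cfg, seed = 1)
#' nrow(h) == sum(cfg$volumes)
#' @export
generate_visit_history <- function(config, seed) {
  validate_synthetic_config(config)
  stopifnot(is.numeric(seed), length(seed) == 1)
  set.seed(as.integer(seed))

  pieces <- vector("list", length(STREAMS) * length(config$years))
  k <- 0L
  for (yi in seq_along(config$years)) {
    y0 <- (yi - 1) * HOURS_PER_YEAR
    for (stream in STREAMS) {
      n <- config$volumes[stream, yi]
      if (n == 0) next
      cat_ <- stream_category(stream)
      ctas <- sample.int(5L, n, replace = TRUE,
                         prob = config$ctas_prob[cat_, ])
      disp <- sample(DISPOSITIONS, n, replace = TRUE,
                     prob = config$disposition_prob[cat_, ])
      lp <- lnorm_params(config$los_mean[cat_, disp],
                         config$los_cv[cat_])
      los <- exp(lp$meanlog + lp$sdlog * rnorm(n))
      k <- k + 1L
      pieces[[k]] <- data.frame(
        arrival_time = sort(runif(n, y0, y0 + HOURS_PER_YEAR)),
        fiscal_year = config$years[yi],
        icd_code = sample(ICD_POOLS[[stream]], n, replace = TRUE),
        category = cat_,
        substance_subgroup = if (cat_ == "substance") stream_subgroup(stream) else "none",
        ctas = ctas,
        disposition = disp,
        los_hours = los,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, pieces[seq_len(k)])
  out <- out[order(out$arrival_time), ]
  rownames(out) <- NULL
  out
}

# Subgroup label carried on substance records.
stream_subgroup <- function(stream) {
  ifelse(stream == "substance_other", "other", stream)
}

#' Write / read a visit history as CSV
#'
#' Plain-text interchange format for visit records: a header row followed by
#' one row per visit, columns exactly as produced by
#' [generate_visit_history()].
#'
#' @param records visit-record data.frame.
#' @param path file path.
#' @return `read_visit_history` returns the validated data.frame;
#'   `write_visit_history` returns `path` invisibly.
#' @export
write_visit_history <- function(records, path) {
  stopifnot(is.data.frame(records))
  write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_visit_history
#' @export
read_visit_history <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  records <- read.csv(path, stringsAsFactors = FALSE)
  needed <- c("arrival_time", "fiscal_year", "icd_code", "category",
              "substance_subgroup", "ctas", "disposition", "los_hours")
  missing <- setdiff(needed, names(records))
  if (length(missing)) {
    stop("visit history is missing column(s): ", paste(missing, collapse = ", "))
  }
  records$fiscal_year <- as.character(records$fiscal_year)
  if (any(records$los_hours <= 0)) stop("los_hours must be positive")
  if (!all(records$ctas %in% 1:5)) stop("ctas must be in 1..5")
  records
}
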
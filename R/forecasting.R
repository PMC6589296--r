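# Assemble a forecast_result, clamping negative forecasts at zero (clamping
# is recorded so it is never silent).
new_forecast_result <- function(method, series, fitted, forecasts, skip) {
  clamped <- any(forecasts < 0)
  if (clamped) {
    message("forecast_", method, ": negative forecast(s) clamped to 0")
    forecasts <- pmax(forecasts, 0)
  }
  err <- abs(series - fitted)
  use <- seq_along(series) > skip
  structure(list(method = method, series = series, fitted = fitted,
                 forecasts = forecasts, mad = mean(err[use]),
                 clamped = clamped),
            class = "forecast_result")
}

#' @export
print.forecast_result <- function(x, ...) {
  cat(sprintf("<forecast_result> %s | MAD %.2f | forecasts: %s\n", x$method,
              x$mad, paste(round(x$forecasts, 1), collapse = ", ")))
  invisible(x)
}

check_series <- function(series, min_len) {
  series <- as.numeric(series)
  if (length(series) < min_len) {
    stop("series must have at least ", min_len, " points")
  }
  if (any(!is.finite(series))) stop("series must be finite")
  series
}

#' Annual demand forecasting methods
#'
#' The forecasting battery used to project annual ED demand: two trend
#' methods (ordinary-least-squares linear regression and Holt's linear
#' exponential smoothing) that extrapolate, and three stationary methods
#' (simple exponential smoothing, moving average, weighted moving average)
#' whose multi-step forecasts are flat. Each method reports its in-sample
#' one-step fitted values and the mean absolute deviation (MAD) of the
#' fitted errors, the criterion used by [select_best_method()]. Points that
#' have no fitted value are excluded from the MAD: none for linear
#' regression (in-sample residuals), the two initialization points for
#' Holt, the first point for simple exponential smoothing, and the first
#' `k` points for the window methods. Negative forecasts are clamped to
#' zero with a message.
#'
#' @param series numeric vector of annual demand values, in fiscal-year
#'   order.
#' @param h forecast horizon (number of future years).
#' @param alpha,beta smoothing constants in (0, 1).
#' @param k window length (`>= 1`, at most the series length).
#' @param weights length-`k` weight vector, oldest to newest within the
#'   window; normalized to sum to one (a message reports the raw and
#'   normalized weights when normalization changes them).
#' @return a `forecast_result`: list with `method`, `fitted`, `forecasts`,
#'   `mad`, `clamped`.
#' @examples
#' forecast_linear(c(10, 20, 30, 40, 50), h = 2)$forecasts  # 60, 70
#' forecast_wma(c(1, 2, 3), k = 3, weights = c(0.2, 0.3, 0.5), h = 1)
#' @export
forecast_linear <- function(series, h) {
  series <- check_series(series, 3)
  t_idx <- seq_along(series)
  fit <- lm(series ~ t_idx)
  fitted_vals <- as.numeric(fitted(fit))
  fc <- as.numeric(predict(fit, data.frame(t_idx = length(series) + seq_len(h))))
  new_forecast_result("linear_regression", series, fitted_vals, fc, skip = 0)
}

#' @rdname forecast_linear
#' @export
forecast_holt <- function(series, alpha = 0.5, beta = 0.5, h = 1) {
  series <- check_series(series, 2)
  if (alpha <= 0 || alpha >= 1 || beta <= 0 || beta >= 1) {
    stop("alpha and beta must lie in (0, 1)")
  }
  n <- length(series)
  level <- series[1]
  trend <- series[2] - series[1]
  fitted_vals <- rep(NA_real_, n)
  fitted_vals[1:2] <- series[1:2]
  for (t in seq(2, n)) {
    if (t > 2) fitted_vals[t] <- level + trend
    prev <- level
    level <- alpha * series[t] + (1 - alpha) * (level + trend)
    trend <- beta * (level - prev) + (1 - beta) * trend
  }
  fc <- level + seq_len(h) * trend
  new_forecast_result("holts", series, fitted_vals, fc, skip = 2)
}

#' @rdname forecast_linear
#' @export
forecast_ses <- function(series, alpha = 0.5, h = 1) {
  series <- check_series(series, 1)
  if (alpha <= 0 || alpha > 1) stop("alpha must lie in (0, 1]")
  n <- length(series)
  level <- series[1]
  fitted_vals <- rep(NA_real_, n)
  fitted_vals[1] <- series[1]
  for (t in seq_len(n)[-1]) {
    fitted_vals[t] <- level
    level <- alpha * series[t] + (1 - alpha) * level
  }
  new_forecast_result("exp_smoothing", series, fitted_vals,
                      rep(level, h), skip = 1)
}

#' @rdname forecast_linear
#' @export
forecast_ma <- function(series, k = 3, h = 1) {
  series <- check_series(series, 1)
  if (k < 1 || k > length(series)) {
    stop("window k must satisfy 1 <= k <= length(series)")
  }
  n <- length(series)
  fitted_vals <- rep(NA_real_, n)
  for (t in seq_len(n)) {
    if (t > k) fitted_vals[t] <- mean(series[(t - k):(t - 1)])
  }
  fitted_vals[seq_len(min(k, n))] <- series[seq_len(min(k, n))]
  fc <- rep(mean(series[(n - k + 1):n]), h)
  new_forecast_result("moving_average", series, fitted_vals, fc, skip = k)
}

#' @rdname forecast_linear
#' @export
forecast_wma <- function(series, k = 3, weights, h = 1) {
  series <- check_series(series, 1)
  if (k < 1 || k > length(series)) {
    stop("window k must satisfy 1 <= k <= length(series)")
  }
  if (length(weights) != k) stop("weights must have length k")
  if (any(weights < 0) || sum(weights) <= 0) stop("weights must be non-negative, not all zero")
  if (abs(sum(weights) - 1) > 1e-9) {
    message("forecast_wma: weights (", paste(weights, collapse = ", "),
            ") normalized to (",
            paste(round(weights / sum(weights), 4), collapse = ", "), ")")
  }
  w <- weights / sum(weights)
  n <- length(series)
  fitted_vals <- rep(NA_real_, n)
  for (t in seq_len(n)) {
    if (t > k) fitted_vals[t] <- sum(w * series[(t - k):(t - 1)])
  }
  fitted_vals[seq_len(min(k, n))] <- series[seq_len(min(k, n))]
  fc <- rep(sum(w * series[(n - k + 1):n]), h)
  new_forecast_result("weighted_moving_average", series, fitted_vals, fc,
                      skip = k)
}

#' Default forecasting candidate battery
#'
#' The five-method battery evaluated by [select_best_method()]: linear
#' regression, Holt (alpha = beta = 0.5), simple exponential smoothing
#' (alpha = 0.5), 3-year moving average, and 3-year weighted moving average
#' with raw weights (0.2, 8.0, 0.8) normalized to sum to one (the published
#' weights cannot sum to one as printed and are treated as raw weights).
#'
#' @return list of candidate configurations (each a list with `method` and
#'   its parameters).
#' @export
default_forecast_candidates <- function() {
  list(list(method = "linear_regression"),
       list(method = "holts", alpha = 0.5, beta = 0.5),
       list(method = "exp_smoothing", alpha = 0.5),
       list(method = "moving_average", k = 3),
       list(method = "weighted_moving_average", k = 3,
            weights = c(0.2, 8.0, 0.8)))
}

apply_candidate <- function(series, cand, h) {
  switch(cand$method,
         linear_regression = forecast_linear(series, h),
         holts = forecast_holt(series, cand$alpha %||% 0.5,
                               cand$beta %||% 0.5, h),
         exp_smoothing = forecast_ses(series, cand$alpha %||% 0.5, h),
         moving_average = forecast_ma(series, cand$k %||% 3, h),
         weighted_moving_average = forecast_wma(series, cand$k %||% 3,
                                                cand$weights, h),
         stop("unknown forecasting method '", cand$method, "'"))
}

#' Select the forecasting method with the lowest MAD
#'
#' Runs every applicable candidate on the series and returns the result
#' with minimal in-sample MAD; ties are broken by candidate order.
#' Candidates whose preconditions fail on the series (e.g. a window longer
#' than the series) are skipped.
#'
#' @param series numeric vector of annual demand values.
#' @param candidates list of candidate configurations
#'   (default [default_forecast_candidates()]).
#' @param h forecast horizon.
#' @return the winning `forecast_result`, with the full candidate MAD table
#'   attached as attribute `"mad_table"`.
#' @export
select_best_method <- function(series, candidates = default_forecast_candidates(),
                               h = 1) {
  results <- list()
  for (cand in candidates) {
    res <- tryCatch(suppressMessages(apply_candidate(series, cand, h)),
                    error = function(e) NULL)
    if (!is.null(res)) results[[length(results) + 1]] <- res
  }
  if (length(results) == 0) stop("no applicable forecasting candidate")
  mads <- vapply(results, function(r) r$mad, numeric(1))
  # MADs equal up to float noise are ties, broken by candidate order
  best <- results[[which(mads <= min(mads) + 1e-9 * (1 + min(mads)))[1]]]
  attr(best, "mad_table") <- data.frame(
    method = vapply(results, function(r) r$method, character(1)),
    mad = mads, stringsAsFactors = FALSE)
  best
}
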
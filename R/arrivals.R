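#' Simulate a homogeneous Poisson arrival process
#'
#' Draws i.i.d. exponential interarrival gaps with the given mean and
#' returns the strictly increasing arrival times not exceeding the horizon.
#' Uses the current RNG state (seed management belongs to the caller). An
#' infinite mean interarrival time yields an empty process.
#'
#' @param mean_interarrival mean gap between arrivals, hours (> 0; may be
#'   `Inf`).
#' @param horizon length of the observation window, hours.
#' @return numeric vector of arrival times in (0, horizon].
#' @examples
#' set.seed(1)
#' length(simulate_arrivals(8760 / 58947, 8760))  # ~ 58947
#' @export
simulate_arrivals <- function(mean_interarrival, horizon) {
  if (!is.numeric(mean_interarrival) || length(mean_interarrival) != 1 ||
      is.na(mean_interarrival) || mean_interarrival <= 0) {
    stop("mean_interarrival must be a single positive number")
  }
  if (!is.finite(mean_interarrival)) return(numeric(0))
  times <- numeric(0)
  t_end <- 0
  repeat {
    k <- max(64L, ceiling((horizon - t_end) / mean_interarrival * 1.2) + 16L)
    gaps <- rexp(k) * mean_interarrival
    times <- c(times, t_end + cumsum(gaps))
    t_end <- times[length(times)]
    if (t_end > horizon) break
  }
  times[times <= horizon]
}

# Triangular(min, mode, max) quantile function (inverse-CDF sampling keeps
# the draws coupled to a fixed uniform stream across scenarios).
qtriangular <- function(p, min, mode, max) {
  if (max == min) return(rep(min, length(p)))
  fc <- (mode - min) / (max - min)
  ifelse(p < fc,
         min + sqrt(p * (max - min) * (mode - min)),
         max - sqrt((1 - p) * (max - min) * (max - mode)))
}
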
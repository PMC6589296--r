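#' Percent change between two values
#'
#' `100 * (new - old) / old`, rounded to one decimal by default (the
#' presentation precision used for all reported percentages); pass
#' `digits = NULL` for the unrounded value.
#'
#' @param old reference value (> 0).
#' @param new comparison value.
#' @param digits decimals to round to, or `NULL`.
#' @return percent change.
#' @examples
#' percent_change(3923, 6131)  # 56.3
#' percent_change(6.2, 16.7)   # 169.4
#' @export
percent_change <- function(old, new, digits = 1) {
  if (any(old <= 0)) stop("old value must be positive")
  out <- 100 * (new - old) / old
  if (!is.null(digits)) out <- round(out, digits)
  out
}

#' Share of a part in a whole, as a percentage
#'
#' @param part count or amount (0 <= part <= whole).
#' @param whole total (> 0).
#' @param digits decimals to round to, or `NULL`.
#' @return `100 * part / whole`.
#' @examples
#' share(25114, 308016)  # 8.2
#' share(6, 24)          # 25
#' @export
share <- function(part, whole, digits = 1) {
  if (any(whole <= 0)) stop("whole must be positive")
  if (any(part < 0) || any(part > whole)) stop("part must lie in [0, whole]")
  out <- 100 * part / whole
  if (!is.null(digits)) out <- round(out, digits)
  out
}

#' Mean and 95% t confidence interval of replicate values
#'
#' `mean +- t[0.975, n-1] * sd / sqrt(n)`, the interval reported for every
#' cross-replication simulation KPI.
#'
#' @param x numeric vector of replicate values (length >= 2).
#' @return named numeric vector `mean`, `lower`, `upper`.
#' @examples
#' ci95(c(5, 7))  # half-width 12.706
#' @export
ci95 <- function(x) {
  n <- length(x)
  if (n < 2) stop("at least two replicate values are required")
  m <- mean(x)
  hw <- qt(0.975, n - 1) * sd(x) / sqrt(n)
  c(mean = m, lower = m - hw, upper = m + hw)
}

#' Trend report: first-to-last-year changes and substance subgroup shares
#'
#' From an [annual_summary()] table covering the first and last fiscal
#' years, computes the percent change per category and substance subgroup
#' and, for the last year, each subgroup's share of all substance visits
#' and the MHA share of all visits.
#'
#' @param summary an [annual_summary()] data.frame.
#' @param first_year,last_year fiscal-year labels (defaults: the earliest
#'   and latest years present).
#' @return data.frame with columns `unit`, `level` (category/subgroup),
#'   `first`, `last`, `pct_change`, `share_last` (subgroup share of
#'   substance visits, MHA share of the total; NA elsewhere).
#' @examples
#' h <- generate_visit_history(default_synthetic_config(), seed = 1)
#' trend_report(annual_summary(h))
#' @export
trend_report <- function(summary, first_year = NULL, last_year = NULL) {
  years <- sort(unique(summary$fiscal_year))
  first_year <- first_year %||% years[1]
  last_year <- last_year %||% years[length(years)]
  if (first_year == last_year || !all(c(first_year, last_year) %in% years)) {
    stop("summary must cover two distinct fiscal years (",
         first_year, ", ", last_year, ")")
  }
  get <- function(year, category, subgroup = "all") {
    v <- summary$count[summary$fiscal_year == year &
                         summary$category == category &
                         summary$substance_subgroup == subgroup]
    if (length(v) == 0) 0 else sum(v)
  }
  mha_cats <- setdiff(CATEGORIES, "NMHA")
  rows <- list()
  add <- function(unit, level, v1, v2, share_last = NA_real_) {
    rows[[length(rows) + 1]] <<- data.frame(
      unit = unit, level = level, first = v1, last = v2,
      pct_change = if (v1 > 0) percent_change(v1, v2) else NA_real_,
      share_last = share_last, stringsAsFactors = FALSE)
  }
  tot1 <- get(first_year, "total")
  tot2 <- get(last_year, "total")
  mha1 <- sum(sapply(mha_cats, get, year = first_year))
  mha2 <- sum(sapply(mha_cats, get, year = last_year))
  add("total", "aggregate", tot1, tot2)
  add("MHA", "aggregate", mha1, mha2, share(mha2, tot2))
  add("NMHA", "category", get(first_year, "NMHA"), get(last_year, "NMHA"))
  for (cat_ in mha_cats) {
    add(cat_, "category", get(first_year, cat_), get(last_year, cat_))
  }
  sub2 <- get(last_year, "substance")
  for (sg in SUBGROUPS) {
    v1 <- get(first_year, "substance", sg)
    v2 <- get(last_year, "substance", sg)
    add(sg, "subgroup", v1, v2, share(v2, sub2))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Bar-chart comparison of scenario KPIs
#'
#' Optional graphical summary of a [run_scenario_suite()] table: one panel
#' per KPI (mean overall LOS, PESU share) with 95% CI error bars, scenarios
#' in table order. Requires ggplot2.
#'
#' @param suite_table the `table` element of a [run_scenario_suite()]
#'   result.
#' @return a ggplot object.
#' @export
plot_scenario_comparison <- function(suite_table) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_scenario_comparison requires the ggplot2 package")
  }
  tab <- suite_table
  long <- rbind(
    data.frame(scenario = tab$scenario, kpi = "mean overall ED LOS (h)",
               mean = tab$mean_los, lower = tab$los_lower,
               upper = tab$los_upper),
    data.frame(scenario = tab$scenario, kpi = "PESU share (%)",
               mean = tab$pesu_share, lower = tab$share_lower,
               upper = tab$share_upper))
  long$scenario <- factor(long$scenario, levels = tab$scenario)
  ggplot2::ggplot(long, ggplot2::aes(x = scenario, y = mean)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = lower, ymax = upper),
                           width = 0.25) +
    ggplot2::facet_wrap(~kpi, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
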
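# Interval reports (min/max/best) -> mean +/- SE quantities.
#
# National reports give population sizes and total trends as min/max ranges,
# sometimes with a best single value. Means for multiplicative quantities
# (trends, population sizes) are taken on the log scale, so the mean of a
# range is its geometric mean; calendar years are averaged arithmetically.

#' Mean of a min/max/best interval report
#'
#' Returns the best single value when one is given; otherwise the midpoint
#' of the reported range, taken on the log scale (geometric mean) for
#' multiplicative quantities such as trends and population sizes, or on the
#' natural scale for calendar years.
#'
#' @param min,max Lower and upper reported values (either may be `NA`).
#' @param best Best single value, if reported (`NA` or `NULL` otherwise).
#' @param scale `"log"` (geometric mean, default) or `"natural"`
#'   (arithmetic midpoint).
#' @return The mean on the measurement scale (vectorised).
#' @examples
#' mean_of_range(100, 400)                     # 200
#' mean_of_range(2, 8, best = 3)               # 3
#' mean_of_range(1990, 2000, scale = "natural") # 1995
#' @export
mean_of_range <- function(min, max, best = NULL, scale = c("log", "natural")) {
  scale <- match.arg(scale)
  if (is.null(best)) best <- NA_real_
  n <- max(length(min), length(max), length(best))
  min <- rep_len(as.numeric(min), n)
  max <- rep_len(as.numeric(max), n)
  best <- rep_len(as.numeric(best), n)
  if (any(stats::complete.cases(min, max) & min > max)) {
    stop("mean_of_range(): min > max")
  }
  if (any(is.na(min) != is.na(max))) {
    # one-sided ranges: fall back on the available endpoint
    one <- ifelse(is.na(min), max, min)
    min <- ifelse(is.na(min), one, min)
    max <- ifelse(is.na(max), one, max)
  }
  if (scale == "log") {
    if (any(!is.na(min) & min <= 0) || any(!is.na(best) & best <= 0)) {
      stop("mean_of_range(): log-scale values must be positive")
    }
    mid <- exp((log(min) + log(max)) / 2)
  } else {
    mid <- (min + max) / 2
  }
  out <- ifelse(is.na(best), mid, best)
  if (any(is.na(out))) stop("mean_of_range(): no values supplied")
  out
}

#' Standard error from a reported min/max range
#'
#' Approximates the standard error of an interval report as a sixth of the
#' span between the maximum and minimum (a range of plus/minus three
#' standard errors covers 99.7% of a normal distribution). Values are taken
#' on the working scale of the quantity: pass log-transformed endpoints for
#' quantities whose mean is a geometric mean. An absent range yields 0.
#'
#' @param min,max Range endpoints on the working scale (`NA` allowed).
#' @return `(max - min) / 6`, or 0 where the range is absent or degenerate.
#' @examples
#' se_from_minmax(100, 700) # 100
#' se_from_minmax(5, 5)     # 0
#' @export
se_from_minmax <- function(min, max) {
  n <- max(length(min), length(max))
  min <- rep_len(as.numeric(min), n)
  max <- rep_len(as.numeric(max), n)
  if (any(stats::complete.cases(min, max) & min > max)) {
    stop("se_from_minmax(): min > max")
  }
  se <- (max - min) / 6
  se[is.na(se)] <- 0
  se
}

#' Standard error from a reported 95% confidence interval
#'
#' Where a reported range is known to be a 95% confidence interval the
#' standard error is a quarter of its width (the interval spans roughly
#' 1.96 standard errors either side of the mean).
#'
#' @param lower,upper Interval endpoints on the working scale.
#' @return `(upper - lower) / 4`.
#' @examples
#' se_from_ci95(90, 110) # 5
#' @export
se_from_ci95 <- function(lower, upper) {
  n <- max(length(lower), length(upper))
  lower <- rep_len(as.numeric(lower), n)
  upper <- rep_len(as.numeric(upper), n)
  if (any(stats::complete.cases(lower, upper) & lower > upper)) {
    stop("se_from_ci95(): lower > upper")
  }
  se <- (upper - lower) / 4
  se[is.na(se)] <- 0
  se
}

#' Pool national population reports into one EU-level estimate
#'
#' National min/max/best population reports for one species (already
#' converted to individuals) are pooled by summing the national minima and
#' maxima across countries and taking the geometric mean of the two sums.
#' A best single value stands in for both endpoints of its national range.
#' The estimate period is the median national start year to the median
#' national end year; its midpoint is the anchor year for rescaling index
#' series, with a sixth-of-span standard error.
#'
#' @param pops Data frame of national reports for a single species with
#'   columns `pop_min`, `pop_max`, `pop_best` (individuals), `period_start`,
#'   `period_end`.
#' @return A list: `mean` (individuals, geometric mean of the summed
#'   range), `se` (individuals, sixth of the summed range), `se_log`
#'   (sixth of the log-range span; used when sampling the estimate on the
#'   log scale), `period_start`, `period_end` (median years), `mid_year`
#'   and `mid_year_se`.
#' @export
eu_population_estimate <- function(pops) {
  if (is.null(pops) || nrow(pops) == 0) {
    stop("eu_population_estimate(): no national population records")
  }
  # a best single value stands in for both endpoints only where the range
  # itself is absent
  lo <- ifelse(is.na(pops$pop_min), pops$pop_best, pops$pop_min)
  hi <- ifelse(is.na(pops$pop_max), pops$pop_best, pops$pop_max)
  lo <- ifelse(is.na(lo), hi, lo)
  hi <- ifelse(is.na(hi), lo, hi)
  if (any(is.na(lo))) {
    stop("eu_population_estimate(): record with no population values")
  }
  sum_min <- sum(lo)
  sum_max <- sum(hi)
  mean_nat <- sqrt(sum_min * sum_max)
  se_log <- if (sum_min > 0) (log(sum_max) - log(sum_min)) / 6 else 0
  ps <- stats::median(pops$period_start)
  pe <- stats::median(pops$period_end)
  list(
    mean = mean_nat,
    se = (sum_max - sum_min) / 6,
    se_log = se_log,
    period_start = ps,
    period_end = pe,
    mid_year = (ps + pe) / 2,
    mid_year_se = (pe - ps) / 6
  )
}

#' Pool EU population estimates for many species at once
#'
#' Applies [eu_population_estimate()] per species and returns a tidy table.
#'
#' @param pops Data frame of national population reports (individuals) with
#'   a `species_id` column.
#' @return A tibble with one row per species: `species_id`, `eu_mean`,
#'   `eu_se`, `eu_se_log`, `period_start`, `period_end`, `anchor_year`,
#'   `anchor_se`.
#' @export
eu_population_table <- function(pops) {
  split(pops, pops$species_id) |>
    purrr::imap(function(df, sp) {
      est <- eu_population_estimate(df)
      tibble::tibble(
        species_id = sp,
        eu_mean = est$mean,
        eu_se = est$se,
        eu_se_log = est$se_log,
        period_start = est$period_start,
        period_end = est$period_end,
        anchor_year = est$mid_year,
        anchor_se = est$mid_year_se
      )
    }) |>
    purrr::list_rbind() |>
    dplyr::arrange(.data$species_id)
}
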
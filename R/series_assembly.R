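# From national trend + population reports to EU-level annual series.
#
# Each national long-term trend is annualised into a constant multiplier
# lambda = T^(1/trend period) and anchored at the national population
# estimate in its mean estimate year, giving a projected national series
#   E_i = E(ybar) * lambda^(i - ybar)
# for 1980-2017. National series are summed to the EU level; uncertainty
# is propagated by resampling T and E on the log scale and the anchor year
# on the natural scale.

#' Annualise a total trend into a yearly multiplier
#'
#' A multiplicative total change `T` over a trend period of `p` years
#' corresponds to a constant annual multiplier `lambda = T^(1/p)`.
#'
#' @param mean_change Multiplicative total change over the trend period
#'   (dimensionless, > 0; e.g. 2 for a doubling).
#' @param trend_period Length of the trend period in years (> 0).
#' @return The annual multiplier lambda (vectorised).
#' @examples
#' annual_multiplier(2, 10) # 2^0.1
#' annual_multiplier(1, 38) # 1
#' @export
annual_multiplier <- function(mean_change, trend_period) {
  if (any(!is.na(mean_change) & mean_change <= 0)) {
    stop("annual_multiplier(): mean_change must be > 0", call. = FALSE)
  }
  if (any(!is.na(trend_period) & trend_period <= 0)) {
    stop("annual_multiplier(): trend_period must be > 0", call. = FALSE)
  }
  mean_change^(1 / trend_period)
}

#' Project a national abundance series from an anchored trend
#'
#' Evaluates `E_i = anchor_abundance * lambda^(i - anchor_year)` over a
#' year grid. The anchor year may be non-integer (it is the midpoint of a
#' reporting period); the exponent is evaluated as a real power.
#'
#' @param anchor_abundance Abundance (individuals) in the anchor year.
#' @param anchor_year Calendar year of the population estimate (real).
#' @param lambda Annual multiplier (> 0).
#' @param years Integer year grid to evaluate over.
#' @return Numeric vector of abundances, one per year.
#' @examples
#' project_series(1000, 2000, 2^0.1, 2010) # 2000
#' @export
project_series <- function(anchor_abundance, anchor_year, lambda, years) {
  if (any(anchor_abundance < 0)) {
    stop("project_series(): anchor_abundance must be >= 0", call. = FALSE)
  }
  anchor_abundance * lambda^(years - anchor_year)
}

#' Per-country projection parameters from trend and population reports
#'
#' Joins validated trend records with national population estimates
#' (individuals) and derives, for every species x country: the mean log
#' trend and its standard error (sixth of the log range span), the annual
#' multiplier lambda, the mean log national population estimate with its
#' standard error, and the anchor year (midpoint of the estimate period)
#' with a sixth-of-span standard error. Fluctuating trends, and stable
#' trends without a quantitative value, are assigned no overall change
#' (lambda = 1, zero trend SE).
#'
#' @param trends Trend records (see [read_trend_records()]).
#' @param pops Population estimates in individuals
#'   (see [read_population_estimates()]).
#' @return A tibble with one row per species x country holding
#'   `mean_lnT`, `se_lnT`, `trend_period`, `lambda`, `mean_lnE`, `se_lnE`,
#'   `anchor_year`, `anchor_se`.
#' @export
projection_params <- function(trends, pops) {
  tr <- tibble::as_tibble(trends)
  quantitative <- !is.na(tr$change_best) |
    (!is.na(tr$change_min) & !is.na(tr$change_max))
  no_change <- tr$direction == "fluctuating" |
    (tr$direction == "stable" & !quantitative)
  use_quant <- !no_change & quantitative
  mean_lnT <- rep(0, nrow(tr))
  se_lnT <- rep(0, nrow(tr))
  if (any(use_quant)) {
    mean_lnT[use_quant] <- log(mean_of_range(
      tr$change_min[use_quant], tr$change_max[use_quant],
      tr$change_best[use_quant], scale = "log"
    ))
    se_lnT[use_quant] <- se_from_minmax(
      log(tr$change_min[use_quant]), log(tr$change_max[use_quant])
    )
  }
  tr <- dplyr::mutate(
    tr,
    mean_lnT = mean_lnT,
    se_lnT = se_lnT,
    trend_period = .data$period_end - .data$period_start,
    lambda = exp(.data$mean_lnT / .data$trend_period)
  )
  pp <- dplyr::mutate(
    tibble::as_tibble(pops),
    mean_lnE = log(mean_of_range(.data$pop_min, .data$pop_max,
      .data$pop_best, scale = "log")),
    se_lnE = ifelse(
      !is.na(.data$pop_min) & !is.na(.data$pop_max) & .data$pop_min > 0,
      se_from_minmax(log(pmax(.data$pop_min, 1e-12)), log(.data$pop_max)),
      0
    ),
    anchor_year = (.data$period_start + .data$period_end) / 2,
    anchor_se = (.data$period_end - .data$period_start) / 6
  )
  dplyr::inner_join(
    dplyr::select(tr, "species_id", "country", "direction", "mean_lnT",
      "se_lnT", "trend_period", "lambda"),
    dplyr::select(pp, "species_id", "country", "mean_lnE", "se_lnE",
      "anchor_year", "anchor_se"),
    by = c("species_id", "country")
  ) |>
    dplyr::arrange(.data$species_id, .data$country)
}

#' Filter trend-derived candidates by period length and population share
#'
#' Country trend records covering fewer than `min_trend_years` years are
#' dropped; a species is eligible only if the countries holding a usable
#' trend account for at least `min_fraction` of its EU population (shares
#' computed from the national population point estimates).
#'
#' @param params Per-country projection parameters
#'   (see [projection_params()]).
#' @param pops National population estimates in individuals, used to weight
#'   country shares; records for countries without trends still count
#'   toward the species' total population.
#' @param min_trend_years Minimum trend period length (years).
#' @param min_fraction Minimum covered share of the EU population.
#' @return The eligible rows of `params`, with a `coverage` column (species
#'   population share covered) and a [drop_log()] of rejections.
#' @export
filter_trend_derived <- function(params, pops, min_trend_years = 16,
                                 min_fraction = 1 / 3) {
  pop_points <- dplyr::mutate(
    tibble::as_tibble(pops),
    pop_point = mean_of_range(.data$pop_min, .data$pop_max, .data$pop_best,
      scale = "log")
  ) |>
    dplyr::select("species_id", "country", "pop_point")
  long_enough <- dplyr::filter(params, .data$trend_period >= min_trend_years)
  short <- dplyr::filter(params, .data$trend_period < min_trend_years)
  shares <- pop_points |>
    dplyr::left_join(
      dplyr::mutate(
        dplyr::select(long_enough, "species_id", "country"),
        has_trend = TRUE
      ),
      by = c("species_id", "country")
    ) |>
    dplyr::mutate(has_trend = !is.na(.data$has_trend)) |>
    dplyr::summarise(
      coverage = sum(.data$pop_point[.data$has_trend]) /
        sum(.data$pop_point),
      .by = "species_id"
    )
  keep <- dplyr::filter(shares, .data$coverage >= min_fraction)
  out <- dplyr::inner_join(long_enough, keep, by = "species_id")
  log <- dplyr::bind_rows(
    tibble::tibble(
      species_id = short$species_id, country = short$country,
      row = NA_integer_,
      reason = sprintf("trend period < %d years", min_trend_years)
    ),
    tibble::tibble(
      species_id = dplyr::filter(
        shares, .data$coverage < min_fraction)$species_id,
      country = NA_character_, row = NA_integer_,
      reason = sprintf("trend coverage below %.3f of EU population",
        min_fraction)
    )
  )
  set_drop_log(out, log)
}

# one bootstrap draw set for a species: n_boot x n_years matrix of EU totals
trend_boot_totals <- function(sp_params, years, n_boot) {
  n_c <- nrow(sp_params)
  n_y <- length(years)
  totals <- matrix(0, nrow = n_boot, ncol = n_y)
  for (ci in seq_len(n_c)) {
    p <- sp_params[ci, ]
    lnT <- stats::rnorm(n_boot, p$mean_lnT, p$se_lnT)
    lnE <- stats::rnorm(n_boot, p$mean_lnE, p$se_lnE)
    y0 <- stats::rnorm(n_boot, p$anchor_year, p$anchor_se)
    # E_i = exp(lnE) * exp(lnT/period)^(i - y0), vectorised over years
    offs <- outer(-y0, years, `+`) # n_boot x n_y: (i - y0)
    totals <- totals + exp(lnE + offs * (lnT / p$trend_period))
  }
  totals
}

#' Bootstrap confidence limits for a trend-derived species series
#'
#' Repeats the anchored projection with the trend and population estimate
#' resampled on the log scale and the anchor year on the natural scale,
#' each from a normal distribution with the derived mean and standard
#' error, then takes the 2.5% and 97.5% quantiles of the EU totals per
#' year. Also returns the per-year standard deviation of the log totals,
#' used as the series' log-scale standard error downstream.
#'
#' @param sp_params Projection parameters for one species (rows = its
#'   countries; see [projection_params()]).
#' @param years Year grid.
#' @param n_boot Number of bootstrap iterations (>= 2; default 100).
#' @param seed Optional integer seed for reproducibility.
#' @param probs Quantiles for the limits.
#' @return A tibble with `year`, `lcl`, `ucl`, `se_log`.
#' @export
bootstrap_trend_series <- function(sp_params, years = default_years(),
                                   n_boot = 100, seed = NULL,
                                   probs = c(0.025, 0.975)) {
  if (n_boot < 2) stop("bootstrap_trend_series(): n_boot must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  totals <- trend_boot_totals(sp_params, years, n_boot)
  q <- apply(totals, 2, stats::quantile, probs = probs, names = FALSE)
  tibble::tibble(
    year = years,
    lcl = q[1, ],
    ucl = q[2, ],
    se_log = apply(log(totals), 2, stats::sd)
  )
}

#' Assemble EU-level series from national trends (with bootstrap limits)
#'
#' For every eligible species, projects each national series from its
#' anchored trend, sums across countries per year, and attaches bootstrap
#' confidence limits and log-scale standard errors. Coverage is the share
#' of the species' EU population held by the contributing countries
#' (constant over years for trend-derived series).
#'
#' @param params Eligible per-country projection parameters, with a
#'   `coverage` column (see [filter_trend_derived()]).
#' @param years Year grid.
#' @param n_boot Bootstrap iterations per species (default 100).
#' @param seed Integer seed; draws are made species by species in
#'   `species_id` order, countries in `country` order, so results are
#'   reproducible.
#' @return An index-series tibble (`species_id`, `year`, `index`,
#'   `index_se`, `lcl`, `ucl`, `coverage`, `source = "trend_derived"`).
#' @export
eu_series_from_trends <- function(params, years = default_years(),
                                  n_boot = 100, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  split(params, params$species_id)[order(unique(params$species_id))] |>
    purrr::imap(function(sp, id) {
      sp <- dplyr::arrange(sp, .data$country)
      point <- colSums(do.call(rbind, lapply(seq_len(nrow(sp)), function(ci) {
        project_series(exp(sp$mean_lnE[ci]), sp$anchor_year[ci],
          sp$lambda[ci], years)
      })))
      boot <- bootstrap_trend_series(sp, years, n_boot = n_boot)
      tibble::tibble(
        species_id = id,
        year = years,
        index = point,
        index_se = boot$se_log,
        lcl = boot$lcl,
        ucl = boot$ucl,
        coverage = sp$coverage[1],
        source = "trend_derived"
      )
    }) |>
    purrr::list_rbind()
}

#' Coverage filters for monitoring-scheme series
#'
#' A species' monitoring-scheme series is retained only if its most recent
#' observed year represents at least `min_latest` of the species' current
#' EU population. Individual years representing less than `min_year` of
#' the EU population are set to missing. An explicit exclusion list (by
#' `species_id`) is honoured regardless of coverage.
#'
#' @param series Index-series tibble (`source = "monitoring_scheme"` rows).
#' @param min_latest Minimum coverage in the most recent observed year
#'   (default 0.5).
#' @param min_year Minimum per-year coverage (default 0.05); years below it
#'   are masked.
#' @param exclude Character vector of species to drop outright.
#' @return The filtered tibble, with a [drop_log()] of rejections and a
#'   count of masked years per species in the log.
#' @export
filter_monitoring_series <- function(series, min_latest = 0.5,
                                     min_year = 0.05,
                                     exclude = character()) {
  logs <- list()
  series <- tibble::as_tibble(series)
  if (length(exclude) > 0) {
    hit <- unique(series$species_id[series$species_id %in% exclude])
    logs$excluded <- tibble::tibble(
      species_id = hit, country = NA_character_, row = NA_integer_,
      reason = "on explicit exclusion list"
    )
    series <- dplyr::filter(series, !.data$species_id %in% exclude)
  }
  latest <- series |>
    dplyr::filter(!is.na(.data$index)) |>
    dplyr::slice_max(.data$year, n = 1, by = "species_id") |>
    dplyr::select("species_id", latest_coverage = "coverage")
  rejected <- dplyr::filter(latest, .data$latest_coverage < min_latest)
  logs$low_latest <- tibble::tibble(
    species_id = rejected$species_id, country = NA_character_,
    row = NA_integer_,
    reason = sprintf("latest-year coverage below %.2f", min_latest)
  )
  out <- series |>
    dplyr::filter(!.data$species_id %in% rejected$species_id) |>
    dplyr::mutate(index = ifelse(
      !is.na(.data$coverage) & .data$coverage < min_year,
      NA_real_, .data$index
    ))
  masked <- out |>
    dplyr::filter(!is.na(.data$coverage) & .data$coverage < min_year) |>
    dplyr::count(.data$species_id)
  if (nrow(masked) > 0) {
    logs$masked <- tibble::tibble(
      species_id = masked$species_id, country = NA_character_,
      row = NA_integer_,
      reason = sprintf("%d year(s) masked: coverage below %.2f",
        masked$n, min_year)
    )
  }
  set_drop_log(out, purrr::list_rbind(logs))
}

#' Select one series per species
#'
#' Where both a monitoring-scheme series and a trend-derived series exist
#' for a species, the monitoring-scheme series is used; otherwise whichever
#' is available. Provenance is retained in the `source` column.
#'
#' @param series Index-series tibble possibly holding both sources.
#' @return One series per species.
#' @export
select_series <- function(series) {
  series |>
    tibble::as_tibble() |>
    dplyr::mutate(
      .priority = ifelse(.data$source == "monitoring_scheme", 1L, 2L)
    ) |>
    dplyr::filter(.data$.priority == min(.data$.priority),
      .by = "species_id") |>
    dplyr::select(-".priority")
}
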
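# Synthetic input generator with known ground truth.
#
# Emulates the two real input streams: Article-12-style national trend and
# population reports (min/max ranges, mixed units, heterogeneous periods)
# and PECBMS-style annual index series (log-scale observation noise,
# late-starting series, population-coverage fractions). Every species has
# a known exponential trajectory, so pipeline output can be compared with
# truth exactly (noiseless settings) or in distribution (calibrated noise).

#' Scenario configuration for the synthetic generator
#'
#' Defaults describe a plausible EU-like assemblage: species abundances
#' lognormal over several orders of magnitude (rare to abundant), species
#' growth rates centred slightly below zero with most species changing
#' less than a few percent a year, national shares from a Dirichlet
#' partition, population reports as min/max ranges around a noisy
#' observation, and index series observed with log-scale noise and
#' occasional late starts.
#'
#' @param n_species Number of species (>= 4).
#' @param n_countries Number of countries.
#' @param abundance_meanlog,abundance_sdlog Lognormal parameters of the
#'   species' true EU abundance in the first year (ln individuals).
#' @param growth_mean,growth_sd Mean and SD of species' true annual log
#'   growth rates (ln units per year). `growth_mean` may be a named vector
#'   keyed by habitat class for group-structured trends.
#' @param pop_range_factor National population reports span
#'   `obs / f` to `obs * f`; the reporting observation itself is drawn as
#'   `truth * exp(N(0, log(f)/3))` so the implied sixth-of-log-span SE is
#'   consistent with the noise actually present.
#' @param trend_range_factor Same convention for trend reports.
#' @param index_noise_sd Log-scale SD of annual index observation noise.
#' @param frac_pairs Fraction of population reports expressed as pairs.
#' @param best_prob Probability a report carries a best single value.
#' @param stable_threshold Reports whose observed total change is within
#'   this fraction of no-change may be coded "stable" without numbers.
#' @param stable_prob Probability such a report is coded stable.
#' @param fluct_prob Probability a trend report is coded fluctuating.
#' @param short_trend_prob Probability a national trend covers a short
#'   (< 16 year) period only.
#' @param monitoring_frac Fraction of species with a monitoring-scheme
#'   index series.
#' @param gap_prob Probability a monitoring series starts after the first
#'   grid year.
#' @param gap_latest_start Latest possible first observed year.
#' @param coverage_latest_range Range of the most-recent-year coverage
#'   fraction (uniform draw).
#' @param coverage_start_frac Early-series coverage as a fraction of the
#'   latest coverage (linear ramp).
#' @param pop_period,trend_start_range,trend_end_range Reporting periods:
#'   population estimate periods are drawn within `pop_period`, trend
#'   periods between the start and end ranges.
#' @param dirichlet_alpha Concentration of the country partition.
#' @param years Year grid.
#' @param seed Integer seed; all randomness flows from it.
#' @return A list of class `scenario_config`.
#' @export
scenario_config <- function(n_species = 40,
                            n_countries = 10,
                            abundance_meanlog = log(5e5),
                            abundance_sdlog = 2,
                            growth_mean = -0.005,
                            growth_sd = 0.015,
                            pop_range_factor = 1.5,
                            trend_range_factor = 1.3,
                            index_noise_sd = 0.05,
                            frac_pairs = 0.7,
                            best_prob = 0.2,
                            stable_threshold = 0.05,
                            stable_prob = 0.5,
                            fluct_prob = 0.05,
                            short_trend_prob = 0.05,
                            monitoring_frac = 0.5,
                            gap_prob = 0.3,
                            gap_latest_start = 1995,
                            coverage_latest_range = c(0.4, 1),
                            coverage_start_frac = 0.1,
                            pop_period = c(2013, 2018),
                            trend_start_range = c(1980, 1984),
                            trend_end_range = c(2013, 2018),
                            dirichlet_alpha = 1,
                            years = default_years(),
                            seed = 1) {
  cfg <- as.list(environment())
  stopifnot(
    cfg$n_species >= 4, cfg$n_countries >= 1,
    cfg$abundance_sdlog >= 0, cfg$growth_sd >= 0,
    cfg$pop_range_factor >= 1, cfg$trend_range_factor >= 1,
    cfg$index_noise_sd >= 0,
    cfg$frac_pairs >= 0, cfg$frac_pairs <= 1,
    cfg$gap_prob >= 0, cfg$gap_prob <= 1,
    cfg$monitoring_frac >= 0, cfg$monitoring_frac <= 1
  )
  structure(cfg, class = "scenario_config")
}

#' Noiseless scenario preset
#'
#' Degenerate reporting ranges, no observation noise, complete coverage, a
#' single common estimate period with an integer midpoint, and no
#' stable/fluctuating coding: the full pipeline should reproduce the true
#' totals exactly (up to floating point).
#'
#' @param ... Overrides passed to [scenario_config()].
#' @export
scenario_noiseless <- function(...) {
  scenario_config(
    pop_range_factor = 1, trend_range_factor = 1, index_noise_sd = 0,
    frac_pairs = 0, best_prob = 0, stable_threshold = 0, stable_prob = 0,
    fluct_prob = 0, short_trend_prob = 0, gap_prob = 0,
    coverage_latest_range = c(1, 1), coverage_start_frac = 1,
    pop_period = c(2015, 2015), trend_start_range = c(1980, 1980),
    trend_end_range = c(2017, 2017),
    ...
  )
}

#' Self-consistent-noise scenario preset for interval calibration checks
#'
#' Reporting noise matches exactly what the bootstrap assumes: index noise
#' is lognormal with the SD written into `index_se`, population reports
#' are lognormal observations with the range factor implying the same
#' log-scale SE, the estimate period is common with an integer midpoint,
#' and series are complete. Used to check bootstrap interval coverage.
#'
#' @param ... Overrides passed to [scenario_config()].
#' @export
scenario_calibration <- function(...) {
  scenario_config(
    n_species = 8, n_countries = 5,
    pop_range_factor = 1.4, index_noise_sd = 0.05,
    frac_pairs = 0, best_prob = 0, stable_threshold = 0, stable_prob = 0,
    fluct_prob = 0, short_trend_prob = 0, gap_prob = 0,
    coverage_latest_range = c(1, 1), coverage_start_frac = 1,
    pop_period = c(2015, 2015), monitoring_frac = 1,
    ...
  )
}

runif_int <- function(n, range) {
  if (range[1] == range[2]) rep(range[1], n) else
    sample(seq(range[1], range[2]), n, replace = TRUE)
}

#' Generate ground-truth trajectories and traits
#'
#' Species' true EU abundances in the first grid year are lognormal;
#' each species carries a constant true annual log growth rate (optionally
#' structured by habitat group) and a Dirichlet country partition, giving
#' exponential national and EU trajectories over the grid.
#'
#' @param config A [scenario_config()].
#' @return A list: `species` (tibble with `species_id`, `n0`, `growth`,
#'   traits), `shares` (species x country matrix), `national` (tibble
#'   `species_id`, `country`, `year`, `abundance`), `eu` (tibble
#'   `species_id`, `year`, `abundance`), `config`.
#' @export
generate_truth <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(config$seed)
  n_s <- config$n_species
  n_c <- config$n_countries
  ids <- sprintf("sp%03d", seq_len(n_s))
  countries <- sprintf("C%02d", seq_len(n_c))
  habitat <- sample(HABITAT_CLASSES, n_s, replace = TRUE,
    prob = c(0.05, 0.08, 0.12, 0.08, 0.2, 0.08, 0.25, 0.04, 0.1))
  migration <- sample(MIGRATION_CLASSES, n_s, replace = TRUE,
    prob = c(0.3, 0.2, 0.25, 0.25))
  bird_group <- sample(BIRD_GROUPS, n_s, replace = TRUE,
    prob = c(0.7, 0.1, 0.1, 0.1))
  gm <- config$growth_mean
  mu <- if (!is.null(names(gm))) {
    unname(gm[habitat])
  } else {
    rep(gm, n_s)
  }
  growth <- stats::rnorm(n_s, mu, config$growth_sd)
  n0 <- stats::rlnorm(n_s, config$abundance_meanlog, config$abundance_sdlog)
  # Dirichlet partition of each species' population across countries
  g <- matrix(stats::rgamma(n_s * n_c, shape = config$dirichlet_alpha),
    nrow = n_s)
  shares <- g / rowSums(g)
  dimnames(shares) <- list(ids, countries)
  years <- config$years
  species <- tibble::tibble(
    species_id = ids, n0 = n0, growth = growth,
    habitat = habitat, migration = migration, bird_group = bird_group
  )
  eu <- tidyr::expand_grid(species_id = ids, year = years) |>
    dplyr::left_join(species[, c("species_id", "n0", "growth")],
      by = "species_id") |>
    dplyr::mutate(
      abundance = .data$n0 * exp(.data$growth * (.data$year - years[1]))
    ) |>
    dplyr::select("species_id", "year", "abundance")
  national <- tidyr::expand_grid(
    species_id = ids, country = countries
  ) |>
    dplyr::mutate(share = shares[cbind(.data$species_id, .data$country)]) |>
    dplyr::left_join(eu, by = "species_id",
      relationship = "many-to-many") |>
    dplyr::mutate(abundance = .data$abundance * .data$share) |>
    dplyr::select("species_id", "country", "year", "abundance")
  list(species = species, shares = shares, national = national, eu = eu,
    config = config)
}

# true national abundance at a (possibly non-integer) year
national_at <- function(truth, species_id, country, year) {
  sp <- truth$species[truth$species$species_id == species_id, ]
  share <- truth$shares[species_id, country]
  share * sp$n0 * exp(sp$growth * (year - truth$config$years[1]))
}

#' Render Article-12-style national trend and population reports
#'
#' National trend reports carry a multiplicative total change over a
#' heterogeneous trend period as a min/max range (and sometimes a best
#' value) around a noisy observation of the true change; reports with
#' little observed change may be coded stable without numbers, and a
#' small fraction are coded fluctuating. Population reports give min/max
#' ranges around a noisy observation of the true national abundance at
#' the midpoint of the estimate period, a configured fraction expressed
#' as pairs.
#'
#' @param truth Output of [generate_truth()].
#' @return A list of tibbles `trends` and `populations` in the CSV input
#'   schemas.
#' @export
render_article12 <- function(truth) {
  config <- truth$config
  set.seed(config$seed + 1L)
  sp <- truth$species
  countries <- colnames(truth$shares)
  f_t <- config$trend_range_factor
  f_p <- config$pop_range_factor
  sd_t <- log(f_t) / 3
  sd_p <- log(f_p) / 3
  rows_t <- list()
  rows_p <- list()
  for (si in seq_len(nrow(sp))) {
    id <- sp$species_id[si]
    for (co in countries) {
      # trend report
      t_start <- runif_int(1, config$trend_start_range)
      t_end <- runif_int(1, config$trend_end_range)
      if (stats::runif(1) < config$short_trend_prob) {
        t_start <- t_end - sample(5:14, 1)
      }
      period <- t_end - t_start
      true_change <- exp(sp$growth[si] * period)
      obs <- true_change * exp(stats::rnorm(1, 0, sd_t))
      fluct <- stats::runif(1) < config$fluct_prob
      stable <- !fluct &&
        abs(obs - 1) <= config$stable_threshold &&
        stats::runif(1) < config$stable_prob
      if (fluct || stable) {
        rows_t[[length(rows_t) + 1]] <- tibble::tibble(
          species_id = id, country = co,
          direction = if (fluct) "fluctuating" else "stable",
          change_min = NA_real_, change_max = NA_real_,
          change_best = NA_real_,
          period_start = t_start, period_end = t_end
        )
      } else {
        best <- if (stats::runif(1) < config$best_prob) obs else NA_real_
        rows_t[[length(rows_t) + 1]] <- tibble::tibble(
          species_id = id, country = co,
          direction = if (obs >= 1) "increasing" else "decreasing",
          change_min = obs / f_t, change_max = obs * f_t,
          change_best = best,
          period_start = t_start, period_end = t_end
        )
      }
      # population report
      p_start <- runif_int(1, config$pop_period)
      p_end <- runif_int(1, c(p_start, config$pop_period[2]))
      ybar <- (p_start + p_end) / 2
      true_pop <- national_at(truth, id, co, ybar)
      obs_pop <- true_pop * exp(stats::rnorm(1, 0, sd_p))
      unit <- if (stats::runif(1) < config$frac_pairs) "pairs" else
        "individuals"
      scale_u <- if (unit == "pairs") 0.5 else 1
      best_p <- if (stats::runif(1) < config$best_prob)
        obs_pop * scale_u else NA_real_
      rows_p[[length(rows_p) + 1]] <- tibble::tibble(
        species_id = id, country = co,
        pop_min = obs_pop / f_p * scale_u,
        pop_max = obs_pop * f_p * scale_u,
        pop_best = best_p, unit = unit,
        period_start = p_start, period_end = p_end
      )
    }
  }
  list(
    trends = purrr::list_rbind(rows_t),
    populations = purrr::list_rbind(rows_p)
  )
}

#' Render PECBMS-style annual index series
#'
#' A configured fraction of species carries a monitoring-scheme series:
#' the true EU trajectory observed with independent lognormal noise per
#' year, rebased so the first observed year is 100, possibly starting
#' late, with a per-year coverage fraction ramping up to a most-recent
#' value. `index_se` is the log-scale noise SD actually used.
#'
#' @param truth Output of [generate_truth()].
#' @return A tibble in the index-series CSV schema
#'   (`source = "monitoring_scheme"`).
#' @export
render_indices <- function(truth) {
  config <- truth$config
  set.seed(config$seed + 2L)
  years <- config$years
  n_y <- length(years)
  sp_ids <- truth$species$species_id
  n_mon <- round(config$monitoring_frac * length(sp_ids))
  mon_ids <- sp_ids[seq_len(n_mon)]
  purrr::map(mon_ids, function(id) {
    eu <- truth$eu[truth$eu$species_id == id, ]
    noise <- exp(stats::rnorm(n_y, 0, config$index_noise_sd))
    idx <- eu$abundance[match(years, eu$year)] * noise
    start <- years[1]
    if (stats::runif(1) < config$gap_prob) {
      start <- sample(seq(years[1] + 1, config$gap_latest_start), 1)
    }
    idx[years < start] <- NA_real_
    first_obs <- idx[which(!is.na(idx))[1]]
    idx <- idx / first_obs * 100
    latest <- stats::runif(1, config$coverage_latest_range[1],
      config$coverage_latest_range[2])
    ramp <- seq(config$coverage_start_frac, 1, length.out = n_y)
    coverage <- pmin(latest * ramp, 1)
    tibble::tibble(
      species_id = id, year = years, index = idx,
      index_se = config$index_noise_sd,
      coverage = coverage, source = "monitoring_scheme"
    )
  }) |>
    purrr::list_rbind()
}

#' Generate a complete synthetic dataset (optionally written to disk)
#'
#' Runs [generate_truth()], [render_article12()] and [render_indices()]
#' and, when `dir` is given, writes the four input CSVs plus ground-truth
#' tables.
#'
#' @param config A [scenario_config()].
#' @param dir Output directory (created if needed), or `NULL` to keep the
#'   dataset in memory only.
#' @return A list: `truth`, `trends`, `populations`, `indices`, `traits`.
#' @export
simulate_dataset <- function(config, dir = NULL) {
  truth <- generate_truth(config)
  a12 <- render_article12(truth)
  indices <- render_indices(truth)
  traits <- truth$species[, c("species_id", "habitat", "migration",
    "bird_group")]
  out <- list(
    truth = truth, trends = a12$trends, populations = a12$populations,
    indices = indices, traits = traits
  )
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    readr::write_csv(a12$trends, file.path(dir, "trends.csv"))
    readr::write_csv(a12$populations, file.path(dir, "populations.csv"))
    readr::write_csv(indices, file.path(dir, "indices.csv"))
    readr::write_csv(traits, file.path(dir, "traits.csv"))
    readr::write_csv(truth$eu, file.path(dir, "truth_eu.csv"))
    readr::write_csv(truth$species, file.path(dir, "truth_species.csv"))
  }
  out
}
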
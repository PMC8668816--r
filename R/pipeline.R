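# End-to-end pipeline: read -> filter -> assemble -> select -> assemblage
# model -> summaries, with every exclusion logged and a manifest recording
# the seed and settings so runs are reproducible.

#' Run the full abundance-change pipeline
#'
#' Executes, in order: input reading and validation; the coverage filters
#' on monitoring-scheme series (50% latest-year rule, 5% per-year masking,
#' explicit exclusions); derivation of trend-projected series for species
#' with enough national trend coverage (16-year and one-third rules);
#' selection of one series per species (monitoring scheme preferred); the
#' imputed assemblage model with its bootstrap; and the change summaries
#' (overall, by abundance quartile and by each trait, growth-rate
#' distribution, extreme contributions, piecewise fit).
#'
#' @param trends,populations,indices,traits Input CSV paths or data
#'   frames.
#' @param out_dir Output directory for result CSVs, the exclusion log and
#'   the manifest; `NULL` to skip writing.
#' @param config Optional schema config (see [read_schema_config()]).
#' @param years Year grid.
#' @param n_boot_trend Bootstrap iterations for trend-derived series
#'   (default 100).
#' @param n_boot_assemblage Bootstrap iterations for the assemblage total
#'   (default 1000).
#' @param seed Integer seed for all bootstraps.
#' @param min_latest_coverage,min_year_coverage Monitoring-series filters
#'   (defaults 0.5 and 0.05).
#' @param min_trend_years,min_trend_fraction Trend-derived filters
#'   (defaults 16 years and one third of the EU population).
#' @param exclude_species Species dropped outright.
#' @param y0,y1 Comparison years for change summaries.
#' @param extreme_k Top-k species per sign in the contribution ranking.
#' @return A list: `series` (selected per-species series), `estimates`
#'   (EU population table), `assemblage`, `summary`, `gross`,
#'   `growth` (rates and stats), `quartiles`, `group_summaries` (by
#'   abundance class, habitat, migration, bird group), `extremes`,
#'   `piecewise`, `species_changes`, `log`, `manifest`.
#' @export
run_pipeline <- function(trends, populations, indices, traits,
                         out_dir = NULL, config = NULL,
                         years = default_years(),
                         n_boot_trend = 100, n_boot_assemblage = 1000,
                         seed = 1,
                         min_latest_coverage = 0.5,
                         min_year_coverage = 0.05,
                         min_trend_years = 16,
                         min_trend_fraction = 1 / 3,
                         exclude_species = character(),
                         y0 = NULL, y1 = NULL, extreme_k = 8) {
  if (is.null(y0)) y0 <- years[1]
  if (is.null(y1)) y1 <- years[length(years)]
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s': %s", what, conditionMessage(e)),
        call. = FALSE)
    })
  }
  inputs <- stage("read_inputs",
    read_inputs(trends, populations, indices, traits, config))
  logs <- list(trends_read = drop_log(inputs$trends))

  mon <- stage("filter_monitoring_series", filter_monitoring_series(
    inputs$indices, min_latest = min_latest_coverage,
    min_year = min_year_coverage, exclude = exclude_species
  ))
  logs$monitoring <- drop_log(mon)

  params <- stage("projection_params",
    projection_params(inputs$trends, inputs$populations))
  eligible <- stage("filter_trend_derived", filter_trend_derived(
    params, inputs$populations, min_trend_years = min_trend_years,
    min_fraction = min_trend_fraction
  ))
  logs$trend_derived <- drop_log(eligible)
  trend_series <- if (nrow(eligible) > 0) {
    stage("eu_series_from_trends", eu_series_from_trends(
      eligible, years, n_boot = n_boot_trend, seed = seed
    ))
  } else {
    NULL
  }

  selected <- stage("select_series",
    select_series(dplyr::bind_rows(mon, trend_series)))
  estimates <- stage("eu_population_table",
    eu_population_table(inputs$populations)) |>
    dplyr::filter(.data$species_id %in% unique(selected$species_id))
  selected <- dplyr::filter(selected,
    .data$species_id %in% estimates$species_id)

  assemblage <- stage("bootstrap_assemblage", bootstrap_assemblage(
    selected, estimates, n_boot = n_boot_assemblage, seed = seed,
    years = years
  ))
  summary <- stage("change_metrics", change_metrics(assemblage, y0, y1))
  sp_changes <- stage("species_net_changes",
    species_net_changes(selected, estimates, y0, y1, years))
  gross <- gross_split(sp_changes)
  growth <- stage("growth_rates", growth_rates(selected, y0, y1, years))
  quart <- stage("abundance_quartiles", abundance_quartiles(estimates))
  traits_tab <- dplyr::filter(inputs$traits,
    .data$species_id %in% estimates$species_id)
  grouping <- list(
    abundance_class = tibble::tibble(
      species_id = quart$species_id,
      group = as.character(quart$abundance_class)
    ),
    habitat = tibble::tibble(species_id = traits_tab$species_id,
      group = traits_tab$habitat),
    migration = tibble::tibble(species_id = traits_tab$species_id,
      group = traits_tab$migration),
    bird_group = tibble::tibble(species_id = traits_tab$species_id,
      group = traits_tab$bird_group)
  )
  group_sums <- purrr::imap(grouping, function(g, nm) {
    stage(paste0("group_summaries:", nm),
      group_summaries(selected, estimates, g, y0, y1, years))
  })
  extremes <- stage("extreme_contributions",
    extreme_contributions(sp_changes, k = extreme_k))
  piecewise <- stage("piecewise_fit", piecewise_fit(assemblage))

  manifest <- list(
    seed = seed, years = range(years), y0 = y0, y1 = y1,
    n_boot_trend = n_boot_trend, n_boot_assemblage = n_boot_assemblage,
    min_latest_coverage = min_latest_coverage,
    min_year_coverage = min_year_coverage,
    min_trend_years = min_trend_years,
    min_trend_fraction = min_trend_fraction,
    n_species = nrow(estimates),
    n_monitoring = sum(selected$source == "monitoring_scheme") /
      length(years),
    n_trend_derived = sum(selected$source == "trend_derived") /
      length(years),
    package_version = as.character(utils::packageVersion("birdabund"))
  )
  result <- list(
    series = selected, estimates = estimates, assemblage = assemblage,
    summary = summary, gross = gross, growth = growth, quartiles = quart,
    group_summaries = group_sums, extremes = extremes,
    piecewise = piecewise, species_changes = sp_changes,
    log = purrr::list_rbind(purrr::imap(
      logs, function(l, nm) dplyr::mutate(l, stage = nm)
    )),
    manifest = manifest
  )
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

#' Write pipeline outputs to a directory
#'
#' Emits tidy CSVs (per-species series, assemblage series, overall and
#' grouped change summaries, species net changes, growth rates, piecewise
#' fit), the exclusion log, and a YAML manifest.
#'
#' @param result A [run_pipeline()] result list.
#' @param out_dir Directory (created if needed).
#' @return `result`, invisibly.
#' @export
write_pipeline_outputs <- function(result, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  readr::write_csv(result$series, p("species_series.csv"))
  readr::write_csv(result$assemblage, p("assemblage.csv"))
  readr::write_csv(
    dplyr::bind_cols(result$summary, result$gross, .name_repair = "minimal"),
    p("change_summary.csv"))
  readr::write_csv(result$species_changes, p("species_changes.csv"))
  readr::write_csv(result$growth$rates, p("growth_rates.csv"))
  readr::write_csv(result$growth$stats, p("growth_rate_stats.csv"))
  readr::write_csv(
    purrr::list_rbind(purrr::imap(result$group_summaries,
      function(g, nm) dplyr::mutate(g, grouping = nm))),
    p("group_summaries.csv"))
  readr::write_csv(result$piecewise, p("piecewise_fit.csv"))
  readr::write_csv(result$log, p("exclusion_log.csv"))
  yaml::write_yaml(result$manifest, p("manifest.yaml"))
  invisible(result)
}
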
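# Input schemas, validation and unit normalisation.
#
# Three CSV inputs drive the pipeline:
#   * national long-term trend reports (one row per species x country),
#   * national population-size reports (one row per species x country),
#   * annual index series (one row per species x year).
# Readers validate every structural invariant up front and keep a log of
# rows that had to be dropped, so exclusions are auditable.

TREND_DIRECTIONS <- c("increasing", "decreasing", "stable", "fluctuating")
POPULATION_UNITS <- c("pairs", "males", "females", "individuals")
HABITAT_CLASSES <- c(
  "marine", "coastal", "inland_wetland", "tundra_mires_moorland",
  "boreal_temperate_forest", "mediterranean", "agricultural_grassland",
  "montane_grassland", "unclassified"
)
MIGRATION_CLASSES <- c("resident", "partial", "short_distance", "long_distance")
BIRD_GROUPS <- c("landbirds", "shorebirds", "waterbirds", "waterfowl")

#' Default year grid of the analysis window
#' @return Integer years 1980 to 2017.
#' @export
default_years <- function() 1980:2017

# attach a drop log to a table without disturbing dplyr verbs downstream
set_drop_log <- function(x, log) {
  attr(x, "drop_log") <- log
  x
}

#' Retrieve the log of rows dropped while reading or filtering
#' @param x A table returned by a `read_*` or filter function.
#' @return A tibble with columns describing each dropped row and the reason,
#'   or an empty tibble when nothing was dropped.
#' @export
drop_log <- function(x) {
  log <- attr(x, "drop_log")
  if (is.null(log)) {
    tibble::tibble(
      species_id = character(), country = character(),
      row = integer(), reason = character()
    )
  } else {
    log
  }
}

require_columns <- function(df, cols, what, file = "<data>") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop(sprintf(
      "%s (%s): missing required column(s): %s",
      what, file, paste(missing, collapse = ", ")
    ), call. = FALSE)
  }
  invisible(df)
}

rename_by_config <- function(df, mapping) {
  if (is.null(mapping)) return(df)
  for (canonical in names(mapping)) {
    found <- mapping[[canonical]]
    if (found %in% names(df)) names(df)[names(df) == found] <- canonical
  }
  df
}

#' Read a schema-mapping configuration
#'
#' The configuration is a YAML file (or list) with optional entries
#' `trends`, `populations`, `indices`, `traits`, each mapping canonical
#' column names to the column names found in the file, plus an optional
#' `trend_dialect` (`"multiplicative"`, the default, or `"percent"` where
#' trends are reported as percent change over the period and are converted
#' to multiplicative total change on load).
#'
#' @param config Path to a YAML file, a list, or `NULL`.
#' @return A named list (possibly empty).
#' @export
read_schema_config <- function(config = NULL) {
  if (is.null(config)) return(list())
  if (is.character(config)) return(yaml::read_yaml(config))
  stopifnot(is.list(config))
  config
}

percent_to_multiplicative <- function(x) 1 + x / 100

#' Read national long-term trend reports
#'
#' Expects columns `species_id`, `country`, `direction`, `change_min`,
#' `change_max`, `change_best`, `period_start`, `period_end`. Quantitative
#' change is multiplicative total change over the trend period (e.g. +25%
#' over the period is 1.25); a percent dialect can be declared in the
#' schema config. Increasing/decreasing records whose quantitative range is
#' entirely missing cannot be projected and are dropped to the log;
#' fluctuating records, and stable records without a quantitative value,
#' are retained with no overall change assumed.
#'
#' @param path CSV file path, or a data frame already in memory.
#' @param config Schema config (see [read_schema_config()]).
#' @return A tibble of validated trend records, with a [drop_log()].
#' @export
read_trend_records <- function(path, config = NULL) {
  config <- read_schema_config(config)
  df <- if (is.data.frame(path)) tibble::as_tibble(path) else
    readr::read_csv(path, show_col_types = FALSE)
  file <- if (is.data.frame(path)) "<data>" else path
  df <- rename_by_config(df, config$trends)
  require_columns(df, c(
    "species_id", "country", "direction", "change_min", "change_max",
    "change_best", "period_start", "period_end"
  ), "trend records", file)
  df <- dplyr::mutate(
    df,
    species_id = as.character(.data$species_id),
    country = as.character(.data$country),
    direction = as.character(.data$direction),
    dplyr::across(
      c("change_min", "change_max", "change_best"), as.numeric
    ),
    dplyr::across(c("period_start", "period_end"), as.integer)
  )
  if (identical(config$trend_dialect, "percent")) {
    df <- dplyr::mutate(df, dplyr::across(
      c("change_min", "change_max", "change_best"),
      percent_to_multiplicative
    ))
  }
  validate_trend_records(df, file)
}

validate_trend_records <- function(df, file = "<data>") {
  bad_dir <- which(!df$direction %in% TREND_DIRECTIONS)
  if (length(bad_dir) > 0) {
    stop(sprintf(
      "trend records (%s): unknown direction %s at row(s) %s",
      file, df$direction[bad_dir[1]], paste(bad_dir, collapse = ", ")
    ), call. = FALSE)
  }
  nonpos <- which(
    (!is.na(df$change_min) & df$change_min <= 0) |
      (!is.na(df$change_max) & df$change_max <= 0) |
      (!is.na(df$change_best) & df$change_best <= 0)
  )
  if (length(nonpos) > 0) {
    stop(sprintf(
      paste0(
        "trend records (%s): non-positive multiplicative change for ",
        "species %s country %s (row %d)"
      ),
      file, df$species_id[nonpos[1]], df$country[nonpos[1]], nonpos[1]
    ), call. = FALSE)
  }
  inverted <- which(
    !is.na(df$change_min) & !is.na(df$change_max) &
      df$change_min > df$change_max
  )
  if (length(inverted) > 0) {
    stop(sprintf(
      "trend records (%s): change_min > change_max for species %s country %s (row %d)",
      file, df$species_id[inverted[1]], df$country[inverted[1]], inverted[1]
    ), call. = FALSE)
  }
  bad_period <- which(df$period_end <= df$period_start)
  if (length(bad_period) > 0) {
    stop(sprintf(
      "trend records (%s): period_end <= period_start at row(s) %s",
      file, paste(bad_period, collapse = ", ")
    ), call. = FALSE)
  }
  # directional records need a usable quantitative change: a best value or
  # a two-sided range; one-sided or absent ranges cannot be projected
  quantitative <- !is.na(df$change_best) |
    (!is.na(df$change_min) & !is.na(df$change_max))
  needs_quant <- df$direction %in% c("increasing", "decreasing")
  dropped_idx <- which(needs_quant & !quantitative)
  log <- tibble::tibble(
    species_id = df$species_id[dropped_idx],
    country = df$country[dropped_idx],
    row = dropped_idx,
    reason = "directional trend without usable quantitative change"
  )
  out <- df[setdiff(seq_len(nrow(df)), dropped_idx), , drop = FALSE]
  set_drop_log(out, log)
}

#' Read national population-size reports
#'
#' Expects columns `species_id`, `country`, `pop_min`, `pop_max`,
#' `pop_best`, `unit`, `period_start`, `period_end`. Counts are converted
#' to individuals on load (see [to_individuals()]).
#'
#' @inheritParams read_trend_records
#' @param normalize Convert counts to individuals (default `TRUE`).
#' @return A tibble of validated population records in individuals.
#' @export
read_population_estimates <- function(path, config = NULL, normalize = TRUE) {
  config <- read_schema_config(config)
  df <- if (is.data.frame(path)) tibble::as_tibble(path) else
    readr::read_csv(path, show_col_types = FALSE)
  file <- if (is.data.frame(path)) "<data>" else path
  df <- rename_by_config(df, config$populations)
  require_columns(df, c(
    "species_id", "country", "pop_min", "pop_max", "pop_best", "unit",
    "period_start", "period_end"
  ), "population estimates", file)
  df <- dplyr::mutate(
    df,
    species_id = as.character(.data$species_id),
    country = as.character(.data$country),
    unit = as.character(.data$unit),
    dplyr::across(c("pop_min", "pop_max", "pop_best"), as.numeric),
    dplyr::across(c("period_start", "period_end"), as.integer)
  )
  bad_unit <- which(!df$unit %in% POPULATION_UNITS)
  if (length(bad_unit) > 0) {
    stop(sprintf(
      "population estimates (%s): unknown unit '%s' at row %d",
      file, df$unit[bad_unit[1]], bad_unit[1]
    ), call. = FALSE)
  }
  neg <- which(
    (!is.na(df$pop_min) & df$pop_min < 0) |
      (!is.na(df$pop_max) & df$pop_max < 0) |
      (!is.na(df$pop_best) & df$pop_best < 0)
  )
  if (length(neg) > 0) {
    stop(sprintf(
      "population estimates (%s): negative count at row %d", file, neg[1]
    ), call. = FALSE)
  }
  inverted <- which(
    !is.na(df$pop_min) & !is.na(df$pop_max) & df$pop_min > df$pop_max
  )
  if (length(inverted) > 0) {
    stop(sprintf(
      "population estimates (%s): pop_min > pop_max for species %s country %s (row %d)",
      file, df$species_id[inverted[1]], df$country[inverted[1]], inverted[1]
    ), call. = FALSE)
  }
  if (normalize) {
    df <- dplyr::mutate(
      df,
      pop_min = to_individuals(.data$pop_min, .data$unit),
      pop_max = to_individuals(.data$pop_max, .data$unit),
      pop_best = to_individuals(.data$pop_best, .data$unit),
      unit = "individuals"
    )
  }
  df
}

#' Read annual index series
#'
#' Expects columns `species_id`, `year`, `index`, `index_se`, `coverage`,
#' `source`. `index` is the annual population index (arbitrary base, may be
#' missing at the start of a series), `index_se` its standard error on the
#' log scale, `coverage` the fraction of the species' EU population
#' represented that year, and `source` either `monitoring_scheme` or
#' `trend_derived`.
#'
#' @inheritParams read_trend_records
#' @return A tibble of validated index rows.
#' @export
read_index_series <- function(path, config = NULL) {
  config <- read_schema_config(config)
  df <- if (is.data.frame(path)) tibble::as_tibble(path) else
    readr::read_csv(path, show_col_types = FALSE)
  file <- if (is.data.frame(path)) "<data>" else path
  df <- rename_by_config(df, config$indices)
  require_columns(df, c(
    "species_id", "year", "index", "index_se", "coverage", "source"
  ), "index series", file)
  df <- dplyr::mutate(
    df,
    species_id = as.character(.data$species_id),
    year = as.integer(.data$year),
    dplyr::across(c("index", "index_se", "coverage"), as.numeric),
    source = as.character(.data$source)
  )
  if (any(!df$source %in% c("monitoring_scheme", "trend_derived"))) {
    stop(sprintf("index series (%s): unknown source value", file),
      call. = FALSE)
  }
  if (any(!is.na(df$index) & df$index <= 0)) {
    bad <- which(!is.na(df$index) & df$index <= 0)[1]
    stop(sprintf(
      "index series (%s): non-positive index for species %s year %d",
      file, df$species_id[bad], df$year[bad]
    ), call. = FALSE)
  }
  if (any(!is.na(df$coverage) & (df$coverage < 0 | df$coverage > 1))) {
    stop(sprintf("index series (%s): coverage outside [0, 1]", file),
      call. = FALSE)
  }
  dplyr::arrange(df, .data$species_id, .data$year)
}

#' Read the species traits table
#'
#' Expects columns `species_id`, `habitat`, `migration`, `bird_group`,
#' with values drawn from the fixed vocabularies (nine habitat classes,
#' four migration strategies, four bird groups).
#'
#' @inheritParams read_trend_records
#' @return A tibble with one row per species.
#' @export
read_traits <- function(path, config = NULL) {
  config <- read_schema_config(config)
  df <- if (is.data.frame(path)) tibble::as_tibble(path) else
    readr::read_csv(path, show_col_types = FALSE)
  file <- if (is.data.frame(path)) "<data>" else path
  df <- rename_by_config(df, config$traits)
  require_columns(df, c("species_id", "habitat", "migration", "bird_group"),
    "traits", file)
  df <- dplyr::mutate(df, dplyr::across(dplyr::everything(), as.character))
  checks <- list(
    habitat = HABITAT_CLASSES, migration = MIGRATION_CLASSES,
    bird_group = BIRD_GROUPS
  )
  for (col in names(checks)) {
    bad <- which(!df[[col]] %in% checks[[col]])
    if (length(bad) > 0) {
      stop(sprintf(
        "traits (%s): unknown %s '%s' at row %d",
        file, col, df[[col]][bad[1]], bad[1]
      ), call. = FALSE)
    }
  }
  if (anyDuplicated(df$species_id)) {
    stop(sprintf("traits (%s): duplicated species_id", file), call. = FALSE)
  }
  df
}

#' Read all pipeline inputs at once
#'
#' @param trends,populations,indices,traits CSV paths (or data frames).
#' @param config Schema config applied to every reader.
#' @return A named list `trends`, `populations`, `indices`, `traits`.
#' @export
read_inputs <- function(trends, populations, indices, traits, config = NULL) {
  config <- read_schema_config(config)
  list(
    trends = read_trend_records(trends, config),
    populations = read_population_estimates(populations, config),
    indices = read_index_series(indices, config),
    traits = read_traits(traits, config)
  )
}

#' Convert reported counts to individuals
#'
#' Population sizes are reported as pairs, males, females or individuals.
#' One pair, one male or one female is taken to equal two individuals.
#'
#' @param value Count in the reporting unit (vectorised, `NA` allowed).
#' @param unit One of `"pairs"`, `"males"`, `"females"`, `"individuals"`.
#' @return Count in individuals.
#' @examples
#' to_individuals(10, "pairs") # 20
#' to_individuals(7, "individuals") # 7
#' @export
to_individuals <- function(value, unit) {
  n <- max(length(value), length(unit))
  value <- rep_len(as.numeric(value), n)
  unit <- rep_len(as.character(unit), n)
  if (any(!unit %in% POPULATION_UNITS)) {
    stop(sprintf(
      "to_individuals(): unknown unit '%s'",
      setdiff(unit, POPULATION_UNITS)[1]
    ), call. = FALSE)
  }
  if (any(!is.na(value) & value < 0)) {
    stop("to_individuals(): counts must be >= 0", call. = FALSE)
  }
  ifelse(unit == "individuals", value, 2 * value)
}

#' Write a tidy result table to CSV
#' @param x A data frame.
#' @param path Output file path.
#' @return `x`, invisibly.
#' @export
write_result_csv <- function(x, path) {
  readr::write_csv(x, path)
  invisible(x)
}
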
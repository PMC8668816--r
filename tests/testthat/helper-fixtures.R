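# Small builders and independent brute-force oracles used across tests.
# Oracles are written as plain nested loops so they share no code with the
# vectorised implementation they check.

idx_series <- function(species_id, years, index, index_se = 0,
                       coverage = 1, source = "monitoring_scheme") {
  tibble::tibble(
    species_id = species_id, year = years, index = index,
    index_se = index_se, coverage = coverage, source = source
  )
}

est_row <- function(species_id, eu_mean, eu_se_log = 0, anchor_year,
                    anchor_se = 0) {
  tibble::tibble(
    species_id = species_id, eu_mean = eu_mean, eu_se = 0,
    eu_se_log = eu_se_log, period_start = anchor_year,
    period_end = anchor_year, anchor_year = anchor_year,
    anchor_se = anchor_se
  )
}

# spreadsheet-style recomputation of the imputed assemblage total
oracle_imputed_total <- function(series, estimates, years) {
  totals <- rep(0, length(years))
  for (id in unique(series$species_id)) {
    sp <- series[series$species_id == id, ]
    e <- estimates[estimates$species_id == id, ]
    idx <- rep(NA_real_, length(years))
    for (k in seq_along(years)) {
      row <- sp[sp$year == years[k], ]
      if (nrow(row) == 1) idx[k] <- row$index
    }
    first <- which(!is.na(idx))[1]
    if (first > 1) for (k in 1:(first - 1)) idx[k] <- idx[first]
    anchor <- round(e$anchor_year)
    anchor <- min(max(anchor, years[1]), years[length(years)])
    a_k <- which(years == anchor)
    for (k in seq_along(years)) {
      totals[k] <- totals[k] + idx[k] / idx[a_k] * e$eu_mean
    }
  }
  totals
}

oracle_gross_split <- function(net_changes) {
  inc <- 0
  dec <- 0
  for (x in net_changes) {
    if (x > 0) inc <- inc + x
    if (x < 0) dec <- dec + x
  }
  c(gross_increase = inc, gross_decrease = dec)
}

oracle_extreme_share <- function(net_changes, k, sign) {
  sel <- if (sign > 0) net_changes[net_changes > 0] else
    net_changes[net_changes < 0]
  sel <- sel[order(-abs(sel))]
  100 * sum(sel[seq_len(min(k, length(sel)))]) / sum(sel)
}

# re-application of the monitoring-series coverage rules, one species at
# a time
oracle_monitoring_keep <- function(years, index, coverage, min_latest,
                                   min_year) {
  obs <- which(!is.na(index))
  latest <- obs[length(obs)]
  keep <- coverage[latest] >= min_latest
  masked <- !is.na(coverage) & coverage < min_year
  list(keep = keep, masked = masked)
}

# re-application of the trend-derived eligibility rules for one species
oracle_trend_eligible <- function(pop_points, trend_periods,
                                  min_years, min_fraction) {
  covered <- 0
  total <- 0
  for (i in seq_along(pop_points)) {
    total <- total + pop_points[i]
    if (!is.na(trend_periods[i]) && trend_periods[i] >= min_years) {
      covered <- covered + pop_points[i]
    }
  }
  covered / total >= min_fraction
}

# simple brute-force projection of one species from national reports
oracle_trend_series <- function(anchors, anchor_years, lambdas, years) {
  out <- rep(0, length(years))
  for (c_i in seq_along(anchors)) {
    for (k in seq_along(years)) {
      out[k] <- out[k] +
        anchors[c_i] * lambdas[c_i]^(years[k] - anchor_years[c_i])
    }
  }
  out
}
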
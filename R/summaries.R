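# Reported change statistics: net/gross/percent/per-annum change, the
# distribution of species log growth rates, covariate disaggregation,
# extreme-species contributions, and a two-segment (breakpoint) regression
# on log total abundance.

#' Net, percent and per-annum change of an assemblage series
#'
#' @param assemblage Assemblage series tibble (`year`, `total`), e.g. from
#'   [imputed_total()] or [bootstrap_assemblage()].
#' @param y0,y1 First and last year of the comparison (defaults 1980 and
#'   2017).
#' @return A one-row tibble: `total_y0`, `total_y1`, `net_change`,
#'   `pct_change` (percent), `pct_per_annum` (percent per year, from the
#'   geometric annual rate).
#' @examples
#' a <- tibble::tibble(year = c(1980, 2017), total = c(3197, 2640))
#' change_metrics(a)
#' @export
change_metrics <- function(assemblage, y0 = 1980, y1 = 2017) {
  a0 <- assemblage$total[match(y0, assemblage$year)]
  a1 <- assemblage$total[match(y1, assemblage$year)]
  if (is.na(a0) || is.na(a1)) {
    stop("change_metrics(): comparison years not in series")
  }
  if (a0 <= 0) stop("change_metrics(): non-positive abundance in base year")
  net <- a1 - a0
  tibble::tibble(
    total_y0 = a0,
    total_y1 = a1,
    net_change = net,
    pct_change = 100 * net / a0,
    pct_per_annum = 100 * ((a1 / a0)^(1 / (y1 - y0)) - 1)
  )
}

#' Per-species net abundance changes
#'
#' Rescales every species' series to individuals and returns each species'
#' change between the comparison years.
#'
#' @inheritParams scale_species_series
#' @inheritParams change_metrics
#' @return A tibble `species_id`, `abundance_y0`, `abundance_y1`,
#'   `net_change`.
#' @export
species_net_changes <- function(series, estimates, y0 = 1980, y1 = 2017,
                                years = default_years()) {
  scale_species_series(series, estimates, years) |>
    dplyr::summarise(
      abundance_y0 = .data$abundance[match(y0, .data$year)],
      abundance_y1 = .data$abundance[match(y1, .data$year)],
      .by = "species_id"
    ) |>
    dplyr::mutate(net_change = .data$abundance_y1 - .data$abundance_y0)
}

#' Split assemblage change into gross increase and gross decrease
#'
#' Sums per-species net changes separately over increasing and declining
#' species; species with exactly zero change contribute to neither. The
#' two components always add up to the assemblage net change.
#'
#' @param species_changes Tibble with `species_id` and `net_change`
#'   (individuals), e.g. from [species_net_changes()].
#' @return A one-row tibble: `gross_increase` (>= 0), `gross_decrease`
#'   (<= 0), `net_change`, `n_increasing`, `n_decreasing`.
#' @export
gross_split <- function(species_changes) {
  ch <- species_changes$net_change
  tibble::tibble(
    gross_increase = sum(ch[ch > 0]),
    gross_decrease = sum(ch[ch < 0]),
    net_change = sum(ch),
    n_increasing = sum(ch > 0),
    n_decreasing = sum(ch < 0)
  )
}

#' Species log growth rates and their distribution
#'
#' The average annual growth rate of a species is the log ratio of its
#' (filled) index between the comparison years divided by the elapsed
#' years, `r_s = ln(I_y1 / I_y0) / (y1 - y0)` (natural-log units per
#' year). Species with a non-positive endpoint are excluded and logged.
#' Distribution statistics are the median, the moment-based skewness
#' `m3 / m2^(3/2)` and the plain fourth standardised moment `m4 / m2^2`
#' (reported alongside its excess form).
#'
#' @param series Index-series tibble, one series per species.
#' @inheritParams change_metrics
#' @param years Year grid.
#' @return A list with `rates` (tibble `species_id`, `rate`) and `stats`
#'   (one-row tibble `median`, `skew`, `kurtosis`, `excess_kurtosis`,
#'   `n_species`).
#' @export
growth_rates <- function(series, y0 = 1980, y1 = 2017,
                         years = default_years()) {
  rates <- split(tibble::as_tibble(series), series$species_id) |>
    purrr::imap(function(sp, id) {
      idx <- fill_initial_missing(sp$index[match(years, sp$year)])
      i0 <- idx[match(y0, years)]
      i1 <- idx[match(y1, years)]
      if (is.na(i0) || is.na(i1) || i0 <= 0 || i1 <= 0) {
        return(tibble::tibble(species_id = id, rate = NA_real_))
      }
      tibble::tibble(species_id = id, rate = log(i1 / i0) / (y1 - y0))
    }) |>
    purrr::list_rbind()
  dropped <- rates$species_id[is.na(rates$rate)]
  rates <- dplyr::filter(rates, !is.na(.data$rate))
  r <- rates$rate
  stats <- tibble::tibble(
    median = stats::median(r),
    skew = e1071::skewness(r, type = 1),
    kurtosis = e1071::kurtosis(r, type = 1) + 3,
    excess_kurtosis = e1071::kurtosis(r, type = 1),
    n_species = length(r)
  )
  out <- list(rates = rates, stats = stats)
  attr(out, "dropped") <- dropped
  out
}

#' Split species into abundance quartiles
#'
#' Species are ranked by their EU population estimate (ascending) and
#' split into four contiguous classes of (as near as possible) equal size,
#' labelled rare, scarce, common, abundant. When the species count is not
#' a multiple of four, the lower classes take the extra species; ties in
#' abundance are broken by `species_id` so the split is deterministic.
#'
#' @param estimates EU population table (`species_id`, `eu_mean`).
#' @return A tibble `species_id`, `eu_mean`, `abundance_class` (ordered
#'   factor rare < scarce < common < abundant).
#' @export
abundance_quartiles <- function(estimates) {
  est <- tibble::as_tibble(estimates)
  ord <- order(est$eu_mean, est$species_id)
  n <- nrow(est)
  base <- n %/% 4
  sizes <- base + (seq_len(4) <= n %% 4)
  labels <- c("rare", "scarce", "common", "abundant")
  cls <- rep(labels, times = sizes)
  out <- est[ord, c("species_id", "eu_mean")]
  out$abundance_class <- factor(cls, levels = labels, ordered = TRUE)
  dplyr::arrange(out, .data$species_id)
}

#' Change summaries for groups of species
#'
#' Computes the full change summary (net/gross/percent/per-annum change
#' and growth-rate distribution statistics) on the group-restricted
#' assemblage for each level of a grouping variable (habitat, migration
#' strategy, bird group, or abundance class). Groups with fewer than two
#' species are flagged.
#'
#' @inheritParams scale_species_series
#' @param groups Tibble `species_id`, `group` assigning each species to
#'   one group.
#' @inheritParams change_metrics
#' @return A tibble with one row per group.
#' @export
group_summaries <- function(series, estimates, groups, y0 = 1980,
                            y1 = 2017, years = default_years()) {
  groups <- tibble::as_tibble(groups)
  stopifnot(all(c("species_id", "group") %in% names(groups)))
  split(groups$species_id, groups$group) |>
    purrr::imap(function(ids, label) {
      sub_series <- dplyr::filter(series, .data$species_id %in% ids)
      sub_est <- dplyr::filter(estimates, .data$species_id %in% ids)
      if (nrow(sub_series) == 0) return(NULL)
      total <- imputed_total(sub_series, sub_est, years)
      cm <- change_metrics(total, y0, y1)
      gs <- gross_split(species_net_changes(sub_series, sub_est, y0, y1,
        years))
      gr <- growth_rates(sub_series, y0, y1, years)$stats
      tibble::tibble(
        group = label,
        n_species = dplyr::n_distinct(sub_series$species_id),
        cm,
        gross_increase = gs$gross_increase,
        gross_decrease = gs$gross_decrease,
        median_rate = gr$median,
        skew_rate = gr$skew,
        kurtosis_rate = gr$kurtosis,
        small_group = dplyr::n_distinct(sub_series$species_id) < 2
      )
    }) |>
    purrr::list_rbind()
}

#' Contribution of the most extreme species to gross change
#'
#' Ranks species by the absolute size of their net change separately among
#' decliners and increasers and reports the share of the gross change of
#' that sign carried by the top `k` species.
#'
#' @inheritParams gross_split
#' @param k Number of top species per sign (default 8).
#' @return A list with `declines` and `increases`, each a list holding
#'   `top` (tibble of the k most extreme species with their `net_change`
#'   and individual `share`), `share` (summed share of gross change of
#'   that sign, in percent), and `n_species` (all species of that sign).
#' @export
extreme_contributions <- function(species_changes, k = 8) {
  ch <- tibble::as_tibble(species_changes)
  one_sign <- function(sub) {
    sub <- dplyr::arrange(sub, dplyr::desc(abs(.data$net_change)),
      .data$species_id)
    gross <- sum(sub$net_change)
    top <- utils::head(sub, k)
    top$share <- 100 * top$net_change / gross
    list(
      top = top,
      share = 100 * sum(top$net_change) / gross,
      n_species = nrow(sub)
    )
  }
  list(
    declines = one_sign(dplyr::filter(ch, .data$net_change < 0)),
    increases = one_sign(dplyr::filter(ch, .data$net_change > 0))
  )
}

#' Two-segment (breakpoint) regression on log total abundance
#'
#' Fits a continuous piecewise-linear model to `ln(total)` against year,
#' with one breakpoint chosen by grid search over interior integer years
#' to minimise the residual sum of squares. With the breakpoint at `c` the
#' model is `ln A_i = a + b1 (i - c)` for years up to `c` and
#' `a + b2 (i - c)` after, so the two segments meet at `c`. Slopes are
#' reported as `100 b` (percent per year on the log scale) with
#' least-squares confidence intervals conditional on the selected
#' breakpoint.
#'
#' @inheritParams change_metrics
#' @param level Confidence level for the slope intervals (default 0.95).
#' @return A one-row tibble: `breakpoint_year`, `slope1`, `slope1_lcl`,
#'   `slope1_ucl`, `slope2`, `slope2_lcl`, `slope2_ucl` (percent per
#'   year), `r_squared`.
#' @export
piecewise_fit <- function(assemblage, level = 0.95) {
  a <- dplyr::arrange(tibble::as_tibble(assemblage), .data$year)
  if (nrow(a) < 8) stop("piecewise_fit(): need at least 8 years")
  if (any(a$total <= 0)) stop("piecewise_fit(): non-positive totals")
  yrs <- a$year
  ln_a <- log(a$total)
  candidates <- yrs[2:(length(yrs) - 2)]
  fits <- lapply(candidates, function(cc) {
    stats::lm(ln_a ~ I(pmin(yrs - cc, 0)) + I(pmax(yrs - cc, 0)))
  })
  rss <- vapply(fits, function(f) sum(stats::resid(f)^2), numeric(1))
  best <- which.min(rss)
  fit <- fits[[best]]
  ci <- unname(suppressWarnings(stats::confint(fit, level = level)))
  b <- unname(stats::coef(fit))
  tss <- sum((ln_a - mean(ln_a))^2)
  tibble::tibble(
    breakpoint_year = candidates[best],
    slope1 = 100 * b[2],
    slope1_lcl = 100 * ci[2, 1],
    slope1_ucl = 100 * ci[2, 2],
    slope2 = 100 * b[3],
    slope2_lcl = 100 * ci[3, 1],
    slope2_ucl = 100 * ci[3, 2],
    r_squared = 1 - sum(stats::resid(fit)^2) / tss
  )
}
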
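# The imputed assemblage model: rescale each species' index series to its
# EU population estimate at the estimate year and sum across species,
#   A_i = sum_s I_{s,i} / I_{s,ybar_s} * E_s,
# with a bootstrap over E (log scale), the annual index values (log scale)
# and the anchor year (natural scale) for confidence intervals.

#' Fill leading missing years with the first observed value
#'
#' Index series may start late; the value of initial missing years is set
#' to that of the first year with data. Interior gaps are not produced by
#' the assembly steps and are treated as an error.
#'
#' @param x Numeric vector (a single species' index series in year order).
#' @return `x` with leading `NA`s replaced by the first observed value.
#' @examples
#' fill_initial_missing(c(NA, NA, 3, 4)) # 3 3 3 4
#' @export
fill_initial_missing <- function(x) {
  obs <- which(!is.na(x))
  if (length(obs) == 0) stop("fill_initial_missing(): all values missing")
  first <- obs[1]
  if (any(is.na(x[first:length(x)]))) {
    stop("fill_initial_missing(): interior missing values")
  }
  if (first > 1) x[seq_len(first - 1)] <- x[first]
  x
}

# nearest grid year for a (possibly non-integer) anchor year, clamped
anchor_index <- function(anchor_year, years) {
  pmin(pmax(round(anchor_year), years[1]), years[length(years)]) -
    years[1] + 1
}

# floor exact zeros before taking logs; index values should be positive
floor_index <- function(x, frac = 1e-6) {
  if (any(x == 0, na.rm = TRUE)) {
    x[!is.na(x) & x == 0] <- frac * max(x, na.rm = TRUE)
  }
  x
}

#' Rescale each species' index series to absolute abundance
#'
#' Each species' (filled) index series is expressed as a proportion of its
#' value in the anchor year (the average population estimate year, rounded
#' to the nearest grid year) and multiplied by the species' EU population
#' estimate, giving an abundance series in individuals.
#'
#' @param series Index-series tibble (`species_id`, `year`, `index`,
#'   `index_se`, ...), one series per species.
#' @param estimates EU population table (see [eu_population_table()]):
#'   `species_id`, `eu_mean`, `eu_se_log`, `anchor_year`, `anchor_se`.
#' @param years Year grid (default 1980-2017).
#' @return A tibble `species_id`, `year`, `abundance` (individuals).
#' @export
scale_species_series <- function(series, estimates,
                                 years = default_years()) {
  est <- tibble::as_tibble(estimates)
  split(tibble::as_tibble(series), series$species_id) |>
    purrr::imap(function(sp, id) {
      e <- est[est$species_id == id, ]
      if (nrow(e) == 0) return(NULL)
      idx <- fill_initial_missing(sp$index[match(years, sp$year)])
      idx <- floor_index(idx)
      a <- anchor_index(e$anchor_year[1], years)
      if (is.na(idx[a]) || idx[a] <= 0) {
        stop(sprintf(
          "scale_species_series(): non-positive index at anchor year for %s",
          id
        ))
      }
      tibble::tibble(
        species_id = id, year = years,
        abundance = idx / idx[a] * e$eu_mean[1]
      )
    }) |>
    purrr::list_rbind()
}

#' Assemblage total abundance (point estimate)
#'
#' Sums the rescaled species series across species per year.
#'
#' @inheritParams scale_species_series
#' @return A tibble `year`, `total` (individuals), `n_species`.
#' @export
imputed_total <- function(series, estimates, years = default_years()) {
  scaled <- scale_species_series(series, estimates, years)
  scaled |>
    dplyr::summarise(
      total = sum(.data$abundance),
      n_species = dplyr::n_distinct(.data$species_id),
      .by = "year"
    ) |>
    dplyr::arrange(.data$year)
}

#' Bootstrap confidence intervals for the assemblage total
#'
#' In each iteration the species' EU population estimate and every annual
#' index value are resampled on the log scale, and the anchor year on the
#' natural scale (then rounded to the nearest grid year), from normal
#' distributions with the derived means and standard errors; the assemblage
#' total is recomputed and the 2.5% and 97.5% quantiles across iterations
#' taken as the confidence limits. Index noise is drawn independently per
#' year. Draws are made species by species in `species_id` order so output
#' is reproducible for a given seed.
#'
#' @inheritParams scale_species_series
#' @param n_boot Number of bootstrap iterations (>= 2; default 1000).
#' @param seed Optional integer seed.
#' @param probs Quantiles for the limits (default 2.5% and 97.5%).
#' @param keep_iterations Return the full iteration-by-year matrix as
#'   attribute `"iterations"` for audit (default `FALSE`).
#' @return A tibble `year`, `total` (point estimate), `lcl`, `ucl`,
#'   `n_species`.
#' @export
bootstrap_assemblage <- function(series, estimates, n_boot = 1000,
                                 seed = NULL, probs = c(0.025, 0.975),
                                 years = default_years(),
                                 keep_iterations = FALSE) {
  if (n_boot < 2) stop("bootstrap_assemblage(): n_boot must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  point <- imputed_total(series, estimates, years)
  est <- tibble::as_tibble(estimates)
  n_y <- length(years)
  totals <- matrix(0, nrow = n_boot, ncol = n_y)
  sp_tabs <- split(tibble::as_tibble(series), series$species_id)
  for (id in sort(names(sp_tabs))) {
    sp <- sp_tabs[[id]]
    e <- est[est$species_id == id, ]
    if (nrow(e) == 0) next
    idx <- fill_initial_missing(sp$index[match(years, sp$year)])
    idx <- floor_index(idx)
    se <- sp$index_se[match(years, sp$year)]
    if (all(is.na(se))) {
      se <- rep(0, n_y)
    } else {
      # leading years inherit the first observed year's uncertainty
      se <- fill_initial_missing(se)
    }
    ln_i <- matrix(
      stats::rnorm(n_boot * n_y,
        mean = rep(log(idx), each = n_boot),
        sd = rep(se, each = n_boot)),
      nrow = n_boot, ncol = n_y
    )
    y_draw <- stats::rnorm(n_boot, e$anchor_year[1], e$anchor_se[1])
    a_idx <- anchor_index(y_draw, years)
    ln_anchor <- ln_i[cbind(seq_len(n_boot), a_idx)]
    ln_e <- stats::rnorm(n_boot, log(e$eu_mean[1]), e$eu_se_log[1])
    totals <- totals + exp(ln_e + ln_i - ln_anchor)
  }
  q <- apply(totals, 2, stats::quantile, probs = probs, names = FALSE)
  out <- tibble::tibble(
    year = years,
    total = point$total[match(years, point$year)],
    lcl = q[1, ],
    ucl = q[2, ],
    n_species = point$n_species[match(years, point$year)]
  )
  if (keep_iterations) attr(out, "iterations") <- totals
  out
}
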
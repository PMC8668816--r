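test_that("annualising a total trend", {
  expect_equal(annual_multiplier(2, 10), 2^0.1)
  expect_equal(annual_multiplier(1, 38), 1)
  expect_error(annual_multiplier(0, 10), "> 0")
  expect_error(annual_multiplier(2, 0), "> 0")
})

test_that("anchored projection evaluates the exponential exactly", {
  expect_equal(project_series(1000, 2000, 2^0.1, 2010), 2000)
  expect_equal(project_series(100, 2015, 1.3, 2015), 100) # identity at ybar
  expect_equal(project_series(100, 2017, 1.05, 2015), 100 * 1.05^-2)
  # lambda = 1 is constant; non-integer anchors allowed
  expect_equal(project_series(42, 1999.5, 1, 1980:2017), rep(42, 38))
  # symmetric offsets around ybar multiply to anchor^2 for lambda, 1/lambda
  up <- project_series(100, 2000, 1.07, 2005)
  down <- project_series(100, 2000, 1 / 1.07, 2005)
  expect_equal(up * down, 100^2)
})

make_params <- function(trends, pops) projection_params(trends, pops)

toy_trend <- function(id, co, dir = "increasing", cmin = NA, cmax = NA,
                      cbest = NA, ps = 1980L, pe = 2017L) {
  tibble::tibble(species_id = id, country = co, direction = dir,
    change_min = as.numeric(cmin), change_max = as.numeric(cmax),
    change_best = as.numeric(cbest), period_start = ps, period_end = pe)
}

toy_pop <- function(id, co, pmin, pmax, pbest = NA, ps = 2015L,
                    pe = 2015L) {
  tibble::tibble(species_id = id, country = co, pop_min = pmin,
    pop_max = pmax, pop_best = as.numeric(pbest), unit = "individuals",
    period_start = ps, period_end = pe)
}

test_that("fluctuating and stable-without-numbers records imply no change", {
  trends <- dplyr::bind_rows(
    toy_trend("a", "AT", "fluctuating", 0.5, 2), # numbers ignored
    toy_trend("a", "BE", "stable"),
    toy_trend("a", "CZ", "stable", 1.1, 1.3),
    toy_trend("a", "DE", "increasing", 1.2, 1.8)
  )
  pops <- dplyr::bind_rows(
    toy_pop("a", "AT", 10, 10), toy_pop("a", "BE", 10, 10),
    toy_pop("a", "CZ", 10, 10), toy_pop("a", "DE", 10, 10)
  )
  p <- make_params(trends, pops)
  expect_equal(p$lambda[p$country == "AT"], 1)
  expect_equal(p$se_lnT[p$country == "AT"], 0)
  expect_equal(p$lambda[p$country == "BE"], 1)
  # stable with numbers keeps them
  expect_equal(p$lambda[p$country == "CZ"],
    sqrt(1.1 * 1.3)^(1 / 37))
  expect_equal(p$lambda[p$country == "DE"], sqrt(1.2 * 1.8)^(1 / 37))
})

test_that("EU series from trends: additivity and a brute-force oracle", {
  years <- 2000:2010
  # one flat country -> flat series
  flat <- make_params(toy_trend("a", "AT", "stable"),
    toy_pop("a", "AT", 100, 100, ps = 2005L, pe = 2005L))
  flat$coverage <- 1
  s <- eu_series_from_trends(flat, years, n_boot = 5, seed = 1)
  expect_equal(s$index, rep(100, length(years)))

  # two identical countries double the single-country series
  two <- make_params(
    dplyr::bind_rows(toy_trend("a", "AT", cmin = 1.5, cmax = 1.5),
      toy_trend("a", "BE", cmin = 1.5, cmax = 1.5)),
    dplyr::bind_rows(toy_pop("a", "AT", 100, 100),
      toy_pop("a", "BE", 100, 100))
  )
  two$coverage <- 1
  one <- two[1, ]
  s2 <- eu_series_from_trends(two, years, n_boot = 5, seed = 1)
  s1 <- eu_series_from_trends(one, years, n_boot = 5, seed = 1)
  expect_equal(s2$index, 2 * s1$index)

  # three countries with mixed trends match the loop oracle
  trends <- dplyr::bind_rows(
    toy_trend("a", "AT", cmin = 1.2, cmax = 1.8),
    toy_trend("a", "BE", "decreasing", cmin = 0.4, cmax = 0.9),
    toy_trend("a", "CZ", cbest = 1.1)
  )
  pops <- dplyr::bind_rows(
    toy_pop("a", "AT", 100, 400),
    toy_pop("a", "BE", 50, 50, ps = 2013L, pe = 2017L),
    toy_pop("a", "CZ", 10, 90, pbest = 30)
  )
  p <- make_params(trends, pops)
  p$coverage <- 1
  s3 <- eu_series_from_trends(p, years, n_boot = 5, seed = 1)
  oracle <- oracle_trend_series(
    anchors = exp(p$mean_lnE), anchor_years = p$anchor_year,
    lambdas = p$lambda, years = years
  )
  expect_equal(s3$index, oracle, tolerance = 1e-12)
})

test_that("trend bootstrap: degenerate SEs, determinism, lognormal check", {
  years <- 2000:2005
  p <- make_params(toy_trend("a", "AT", cmin = 1.5, cmax = 1.5),
    toy_pop("a", "AT", 200, 200, ps = 2002L, pe = 2002L))
  b1 <- bootstrap_trend_series(p, years, n_boot = 50, seed = 9)
  point <- project_series(200, 2002, 1.5^(1 / 37), years)
  expect_equal(b1$lcl, point)
  expect_equal(b1$ucl, point)
  b2 <- bootstrap_trend_series(p, years, n_boot = 50, seed = 9)
  expect_identical(b1, b2)
  expect_error(bootstrap_trend_series(p, years, n_boot = 1), ">= 2")

  # population-range noise only: totals are lognormal with the derived
  # log-scale SE, so bootstrap limits should approach the closed-form
  # lognormal quantiles
  pn <- make_params(toy_trend("a", "AT", "stable"),
    toy_pop("a", "AT", 100, 900, ps = 2002L, pe = 2002L))
  sd_log <- (log(900) - log(100)) / 6
  b3 <- bootstrap_trend_series(pn, years, n_boot = 4000, seed = 1)
  expect_equal(b3$lcl[1], qlnorm(0.025, log(300), sd_log),
    tolerance = 0.05)
  expect_equal(b3$ucl[1], qlnorm(0.975, log(300), sd_log),
    tolerance = 0.05)
  expect_equal(b3$se_log[1], sd_log, tolerance = 0.05)
})

test_that("bootstrap limits bracket the point series on benign inputs", {
  trends <- dplyr::bind_rows(
    toy_trend("a", "AT", cmin = 1.1, cmax = 1.6),
    toy_trend("a", "BE", "decreasing", cmin = 0.5, cmax = 0.8)
  )
  pops <- dplyr::bind_rows(
    toy_pop("a", "AT", 100, 300),
    toy_pop("a", "BE", 200, 500, ps = 2013L, pe = 2017L)
  )
  p <- make_params(trends, pops)
  p$coverage <- 1
  years <- 1980:2017
  s <- eu_series_from_trends(p, years, n_boot = 1000, seed = 4)
  expect_gte(mean(s$lcl <= s$index & s$index <= s$ucl), 0.95)
})

test_that("monitoring coverage filters apply the stated rules", {
  years <- 2015:2017
  s <- idx_series("a", years, c(10, 11, 12),
    coverage = c(0.04, 0.30, 0.60))
  f <- filter_monitoring_series(s)
  expect_equal(sum(!is.na(f$index)), 2) # first year masked
  expect_true(is.na(f$index[f$year == 2015]))

  rej <- idx_series("b", years, c(10, 11, 12), coverage = 0.49)
  f2 <- filter_monitoring_series(dplyr::bind_rows(s, rej))
  expect_false("b" %in% f2$species_id)
  expect_match(drop_log(f2)$reason[drop_log(f2)$species_id == "b"],
    "latest-year coverage")

  f3 <- filter_monitoring_series(s, exclude = "a")
  expect_equal(nrow(f3), 0)
})

test_that("coverage filters match a rule oracle on random toys", {
  set.seed(21)
  years <- 1980:1999
  for (rep in 1:10) {
    series <- purrr::map(1:10, function(i) {
      cov <- runif(length(years), 0, 1)
      idx_series(sprintf("s%02d", i), years,
        exp(rnorm(length(years), 3, 0.3)), coverage = cov)
    }) |> purrr::list_rbind()
    got <- filter_monitoring_series(series)
    for (id in unique(series$species_id)) {
      sp <- series[series$species_id == id, ]
      want <- oracle_monitoring_keep(years, sp$index, sp$coverage,
        0.5, 0.05)
      kept <- id %in% got$species_id
      expect_equal(kept, want$keep)
      if (kept) {
        gi <- got$index[got$species_id == id]
        expect_equal(is.na(gi), want$masked)
      }
    }
  }
})

test_that("trend-derived eligibility: period length and population share", {
  # 40% of the population with a 20-year trend -> kept
  trends <- dplyr::bind_rows(
    toy_trend("a", "AT", cmin = 1.2, cmax = 1.4, ps = 1998L, pe = 2018L),
    toy_trend("b", "AT", cmin = 1.2, cmax = 1.4, ps = 2008L, pe = 2018L)
  )
  pops <- dplyr::bind_rows(
    toy_pop("a", "AT", 40, 40), toy_pop("a", "BE", 60, 60),
    toy_pop("b", "AT", 40, 40), toy_pop("b", "BE", 60, 60)
  )
  p <- make_params(trends, pops)
  f <- filter_trend_derived(p, pops)
  expect_true("a" %in% f$species_id)
  expect_false("b" %in% f$species_id) # only a 10-year trend available
  expect_true(any(grepl("trend period", drop_log(f)$reason)))

  # oracle over randomized mixed tables
  set.seed(31)
  for (rep in 1:10) {
    n_c <- 6
    ids <- c("x", "y", "z")
    pops_r <- purrr::map(ids, function(id) {
      v <- runif(n_c, 10, 1000)
      toy_pop(id, sprintf("C%d", 1:n_c), v, v)
    }) |> purrr::list_rbind()
    trends_r <- purrr::map(ids, function(id) {
      have <- which(runif(n_c) < 0.7)
      if (length(have) == 0) return(NULL)
      toy_trend(id, sprintf("C%d", have), cmin = 1.1, cmax = 1.2,
        ps = 2018L - sample(10:30, length(have), replace = TRUE),
        pe = 2018L)
    }) |> purrr::list_rbind()
    p_r <- make_params(trends_r, pops_r)
    f_r <- filter_trend_derived(p_r, pops_r)
    for (id in ids) {
      pr <- p_r[p_r$species_id == id, ]
      po <- pops_r[pops_r$species_id == id, ]
      periods <- pr$trend_period[match(po$country, pr$country)]
      want <- oracle_trend_eligible(po$pop_min, periods, 16, 1 / 3)
      expect_equal(id %in% f_r$species_id, want)
    }
  }
})

test_that("series selection prefers monitoring schemes", {
  years <- 2000:2002
  pool <- dplyr::bind_rows(
    idx_series("a", years, 1:3),
    idx_series("a", years, 4:6, source = "trend_derived"),
    idx_series("b", years, 7:9, source = "trend_derived")
  )
  sel <- select_series(pool)
  expect_equal(unique(sel$source[sel$species_id == "a"]),
    "monitoring_scheme")
  expect_equal(unique(sel$source[sel$species_id == "b"]),
    "trend_derived")
  expect_equal(dplyr::n_distinct(sel$species_id), 2)
})
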
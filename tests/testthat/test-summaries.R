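assemblage_of <- function(years, totals) {
  tibble::tibble(year = years, total = totals)
}

test_that("net, percent and per-annum change", {
  flat <- assemblage_of(c(1980, 2017), c(100, 100))
  cm <- change_metrics(flat)
  expect_equal(cm$net_change, 0)
  expect_equal(cm$pct_change, 0)
  expect_equal(cm$pct_per_annum, 0)
  expect_error(change_metrics(assemblage_of(c(1980, 2017), c(0, 5))),
    "non-positive")
  expect_error(change_metrics(flat, y0 = 1970), "not in series")
})

test_that("percent and per-annum change are mutually consistent", {
  set.seed(29)
  for (i in 1:20) {
    a0 <- runif(1, 10, 1e4)
    a1 <- runif(1, 10, 1e4)
    cm <- change_metrics(assemblage_of(c(1980, 2017), c(a0, a1)))
    expect_equal((1 + cm$pct_change / 100),
      (1 + cm$pct_per_annum / 100)^37, tolerance = 1e-12)
    expect_equal(cm$net_change, a1 - a0)
  }
})

test_that("gross split partitions the net change by sign", {
  ch <- tibble::tibble(species_id = c("a", "b"), net_change = c(5, -3))
  gs <- gross_split(ch)
  expect_equal(gs$gross_increase, 5)
  expect_equal(gs$gross_decrease, -3)
  expect_equal(gs$net_change, 2)

  all_dec <- tibble::tibble(species_id = letters[1:3],
    net_change = c(-1, -2, -3))
  expect_equal(gross_split(all_dec)$gross_increase, 0)

  set.seed(37)
  for (i in 1:20) {
    ch_r <- tibble::tibble(
      species_id = sprintf("s%02d", 1:20),
      net_change = round(rnorm(20, 0, 10), 1)
    )
    gs_r <- gross_split(ch_r)
    want <- oracle_gross_split(ch_r$net_change)
    expect_equal(gs_r$gross_increase, unname(want["gross_increase"]))
    expect_equal(gs_r$gross_decrease, unname(want["gross_decrease"]))
    expect_equal(gs_r$net_change,
      gs_r$gross_increase + gs_r$gross_decrease)
  }
})

test_that("species log growth rates and their distribution statistics", {
  years <- 1980:2017
  flat <- idx_series("a", years, rep(100, 38))
  doubling <- idx_series("b", years, 100 * 2^((years - 1980) / 37))
  gr <- growth_rates(dplyr::bind_rows(flat, doubling))
  expect_equal(gr$rates$rate[gr$rates$species_id == "a"], 0)
  expect_equal(gr$rates$rate[gr$rates$species_id == "b"], log(2) / 37)

  # simulated normal growth rates: median near mu, skew near 0, plain
  # kurtosis near 3
  set.seed(41)
  mu <- -0.004
  r <- rnorm(2000, mu, 0.01)
  series <- purrr::map(seq_along(r), function(i) {
    idx_series(sprintf("s%04d", i), c(1980L, 2017L),
      c(100, 100 * exp(r[i] * 37)))
  }) |> purrr::list_rbind()
  gr2 <- growth_rates(series, years = c(1980L, 2017L))
  expect_lt(abs(gr2$stats$median - mu), 5 * 1.2533 * 0.01 / sqrt(2000))
  expect_lt(abs(gr2$stats$skew), 0.2)
  expect_equal(gr2$stats$kurtosis, 3, tolerance = 0.5)
  expect_equal(gr2$stats$excess_kurtosis, gr2$stats$kurtosis - 3)
})

test_that("abundance quartiles split species into near-equal classes", {
  e8 <- tibble::tibble(species_id = sprintf("s%d", 1:8),
    eu_mean = c(5, 3, 8, 1, 9, 7, 2, 6))
  q <- abundance_quartiles(e8)
  expect_equal(as.vector(table(q$abundance_class)), c(2, 2, 2, 2))
  expect_setequal(
    q$species_id[q$abundance_class == "rare"], c("s4", "s7")
  )

  e378 <- tibble::tibble(species_id = sprintf("s%03d", 1:378),
    eu_mean = runif(378, 1, 1e6))
  q378 <- abundance_quartiles(e378)
  expect_equal(as.vector(table(q378$abundance_class)), c(95, 95, 94, 94))

  ties <- tibble::tibble(species_id = c("d", "c", "b", "a"),
    eu_mean = rep(7, 4))
  q_t <- abundance_quartiles(ties)
  expect_equal(
    q_t$abundance_class[order(q_t$species_id)],
    factor(c("rare", "scarce", "common", "abundant"),
      levels = c("rare", "scarce", "common", "abundant"), ordered = TRUE)
  )
})

test_that("group summaries: partition identity and additivity", {
  set.seed(43)
  years <- 1980:2017
  ids <- sprintf("s%d", 1:6)
  series <- purrr::map(ids, function(id) {
    idx_series(id, years, exp(cumsum(rnorm(38, 0, 0.02))) * 100)
  }) |> purrr::list_rbind()
  ests <- purrr::map(ids, function(id) {
    est_row(id, runif(1, 1e3, 1e5), anchor_year = 2015)
  }) |> purrr::list_rbind()

  whole <- group_summaries(series, ests,
    tibble::tibble(species_id = ids, group = "all"))
  global <- change_metrics(imputed_total(series, ests, years))
  expect_equal(whole$net_change, global$net_change)
  expect_equal(whole$pct_change, global$pct_change)

  two <- group_summaries(series, ests,
    tibble::tibble(species_id = ids, group = rep(c("g1", "g2"), each = 3)))
  expect_equal(sum(two$net_change), global$net_change)
  expect_false(any(two$small_group))
  one <- group_summaries(series, ests,
    tibble::tibble(species_id = ids,
      group = c("solo", rep("rest", 5))))
  expect_true(one$small_group[one$group == "solo"])
})

test_that("extreme species contributions", {
  single <- tibble::tibble(species_id = "a", net_change = -10)
  ec <- extreme_contributions(single)
  expect_equal(ec$declines$share, 100)
  expect_equal(ec$increases$n_species, 0)

  equal10 <- tibble::tibble(species_id = sprintf("s%02d", 1:10),
    net_change = rep(-5, 10))
  expect_equal(extreme_contributions(equal10, k = 8)$declines$share, 80)

  set.seed(47)
  for (i in 1:20) {
    ch <- tibble::tibble(
      species_id = sprintf("s%02d", 1:15),
      net_change = rnorm(15, 0, 20)
    )
    ec_r <- extreme_contributions(ch, k = 4)
    expect_equal(ec_r$declines$share,
      oracle_extreme_share(ch$net_change, 4, -1))
    expect_equal(ec_r$increases$share,
      oracle_extreme_share(ch$net_change, 4, +1))
  }
})

test_that("piecewise regression recovers a constructed two-phase series", {
  years <- 1980:2017
  b1 <- -0.01
  b2 <- 0
  brk <- 2000
  ln_a <- ifelse(years <= brk, b1 * (years - brk), b2 * (years - brk)) +
    log(3000)
  a <- assemblage_of(years, exp(ln_a))
  fit <- piecewise_fit(a)
  expect_equal(fit$breakpoint_year, 2000)
  expect_equal(fit$slope1, -1, tolerance = 1e-6)
  expect_equal(fit$slope2, 0, tolerance = 1e-6)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)

  # single-phase series: the two slopes agree
  one <- assemblage_of(years, 3000 * exp(-0.008 * (years - 1980)))
  f1 <- piecewise_fit(one)
  expect_equal(f1$slope1, f1$slope2, tolerance = 1e-6)
  expect_equal(f1$slope1, -0.8, tolerance = 1e-6)

  # scaling the series leaves the slopes unchanged
  f2 <- piecewise_fit(dplyr::mutate(a, total = total * 7.3))
  expect_equal(f2$slope1, fit$slope1)
  expect_equal(f2$slope2, fit$slope2)
  expect_equal(f2$breakpoint_year, fit$breakpoint_year)

  expect_error(piecewise_fit(assemblage_of(2000:2005, rep(1, 6))),
    "at least 8 years")
  expect_error(piecewise_fit(assemblage_of(years, rep(-1, 38))),
    "non-positive")
})

test_that("breakpoint is recovered within 2 years under known noise", {
  set.seed(53)
  years <- 1980:2017
  brk <- 2000
  truth <- ifelse(years <= brk, -0.01 * (years - brk), 0) + log(3000)
  hits <- 0
  n_rep <- 200
  for (i in seq_len(n_rep)) {
    a <- assemblage_of(years, exp(truth + rnorm(38, 0, 0.01)))
    fit <- piecewise_fit(a)
    if (abs(fit$breakpoint_year - brk) <= 2) hits <- hits + 1
  }
  expect_gte(hits / n_rep, 0.9)
})
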
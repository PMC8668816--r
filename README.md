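# birdabund

Assemblage-level abundance change from multi-scheme bird monitoring data.

National bird monitoring produces two very different kinds of evidence:
annual population **index series** with standard errors and
population-coverage fractions (PECBMS-style), and six-yearly national
reports of **long-term trends and population sizes** as min/max/best
interval estimates in mixed units (Article-12-style). `birdabund` fuses
both into species-level EU abundance time series over 1980–2017 and
aggregates them into assemblage totals with bootstrap confidence
intervals, for anyone asking "how many individual birds have been gained
or lost, and where?"

## The model

For species without an index series, each national report is annualised
and projected. With mean total trend `T̄` (log scale) over a trend period
of `p` years, mean national population estimate `Ē_N` (log scale) and
mean estimate year `ȳ`:

    Ē_N(i) = Ē_N(ȳ) · λ^(i − ȳ),   λ = T̄^(1/p)

and national series are summed across countries to an EU series per
species. Standard errors are approximated as a sixth of the span between
the reported maximum and minimum (a quarter of the width when the range
is a 95% CI), and set to zero where no range was reported.

One series per species is then selected (monitoring-scheme series
preferred) and the **imputed model** turns relative indices into absolute
abundance: each series `Ī_s` is expressed as a proportion of its value in
the average population-estimate year `ȳ_s` and scaled by the species' EU
population estimate `Ē_s` (the geometric mean of the summed national
minima and maxima, in individuals):

    A_i = Σ_s  Ī_{s,i} / Ī_{s,ȳ_s} · Ē_{s,ȳ_s}

Uncertainty is propagated by a bootstrap (default N = 1000; N = 100 for
the trend-projected series) that resamples `E` and `I` on the log scale
and `y` on the natural scale, taking the 2.5%/97.5% quantiles per year.

Inclusion rules: a monitoring-scheme series must represent ≥ 50% of the
species' current EU population in its most recent year, and individual
years below 5% coverage are masked; trend reports must span ≥ 16 years
and cover ≥ 1/3 of the EU population for the species to qualify.

Reported summaries: net change, gross increase/decrease (per-species net
changes summed by sign), percent and percent-per-annum change, the
median/skewness/kurtosis of species' log growth rates, disaggregation by
abundance quartile (rare/scarce/common/abundant), habitat, migration
strategy and bird group, top-k extreme-species contribution shares, and
a continuous two-segment (breakpoint) regression of log total abundance
on year.

## Worked example

Everything is testable without external data via the synthetic generator,
which emulates both input streams with known ground truth:

```r
library(birdabund)

ds <- simulate_dataset(scenario_config(n_species = 20, n_countries = 6,
                                       seed = 42))
res <- run_pipeline(ds$trends, ds$populations, ds$indices, ds$traits,
                    n_boot_trend = 100, n_boot_assemblage = 1000,
                    seed = 42)
res$summary
#> # A tibble: 1 × 5
#>    total_y0  total_y1 net_change pct_change pct_per_annum
#>       <dbl>     <dbl>      <dbl>      <dbl>         <dbl>
#> 1 51746878. 53296742.   1549864.       3.00        0.0798
res$gross
#> # A tibble: 1 × 5
#>   gross_increase gross_decrease net_change n_increasing n_decreasing
#>            <dbl>          <dbl>      <dbl>        <int>        <int>
#> 1       9169858.      -7619994.   1549864.            8           12
res$growth$stats
#> # A tibble: 1 × 5
#>     median   skew kurtosis excess_kurtosis n_species
#>      <dbl>  <dbl>    <dbl>           <dbl>     <int>
#> 1 -0.00694 -0.430     2.56          -0.438        20
```

This 20-species assemblage gained a net 1.55 million individuals (+3.0%,
+0.08%/yr): a gross gain of 9.2 m across the 8 increasing species against
a gross loss of 7.6 m across the 12 declining ones, with the median
species log growth rate slightly negative (−0.0069 ln units/yr) — net
change and the "typical" species can disagree, which is exactly why both
are reported. `res$assemblage` holds the yearly totals with bootstrap
confidence limits, `res$group_summaries` the per-covariate breakdowns,
`res$piecewise` the breakpoint fit, and `res$log` every record excluded
by the filters, with reasons.

A thin command-line wrapper with `simulate` and `run` subcommands is in
`inst/scripts/birdabund.R`.

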
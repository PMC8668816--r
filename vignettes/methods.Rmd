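---
title: "Methods: integrating trend reports and index series into assemblage abundance change"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrating trend reports and index series into assemblage abundance change}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(birdabund)
```

## The estimation problem

Continental-scale statements about bird abundance — "how many individual
birds were lost since 1980, and in which kinds of species?" — cannot be
read off any single monitoring dataset. Structured annual monitoring
(index series with standard errors) exists only for the commoner
species, while mandatory national reporting covers all species but
delivers only interval summaries: a population size range in mixed units
(pairs, males, females, individuals) over some estimate period, and a
long-term multiplicative trend range over some trend period. `birdabund`
converts both evidence streams into one absolute abundance series per
species on a common year grid (1980–2017 by default) and sums them into
assemblage totals with bootstrap uncertainty.

## From interval reports to means and standard errors

Reported ranges carry no distributional information, so the package uses
deliberately rough, transparent conventions:

* the mean of a range is taken on the **log scale** for multiplicative
  quantities (trends, population sizes) — i.e. the geometric mean — and
  on the natural scale for calendar years; a best single value, where
  reported, overrides the range mean;
* the standard error is a **sixth of the span** between maximum and
  minimum on the working scale (±3 SE covers 99.7% of a normal), or a
  quarter of the width when the range is a declared 95% CI; an absent
  range yields SE = 0;
* a best single value stands in for *both* endpoints only where the
  range itself is absent.

Because the means of trends and population sizes live on the log scale,
their sixth-of-span standard errors are computed on the log scale too;
this is what makes the later log-normal resampling coherent. The pooled
EU population estimate additionally reports a natural-scale SE (a sixth
of the summed range span) for descriptive use, but sampling always uses
the log-scale form. For sums across countries the sixth-of-span rule is
conservative: ranges of independent national errors do not shrink the
way a variance of a sum would, so pooled intervals tend to over-cover
(visible in the calibration results below).

## Trend-projected series

For each species × country with a usable trend, the annual multiplier is
`λ = T̄^(1/p)` for total change `T̄` over `p` years, anchored at the
national population estimate in the mean estimate year `ȳ` (midpoint of
the estimate period, possibly non-integer — the projection
`Ē(ȳ)·λ^(i−ȳ)` is evaluated with real exponents). Records coded
*fluctuating* are assigned no overall change regardless of any numbers
reported with them, as are *stable* records without numbers; stable
records with a quantitative range use it. Directional records whose
quantitative range is unusable (one-sided or absent) cannot be projected
at all and are excluded to the log rather than guessed at.

National projections are summed to the EU level. Eligibility mirrors the
reporting rules: trends spanning fewer than 16 years are dropped, and a
species qualifies only if countries holding usable trends account for at
least one third of its EU population (population shares from national
point estimates). Uncertainty comes from a bootstrap (default N = 100)
resampling `T` and `E` on the log scale and `y` on the natural scale;
the per-year SD of the log totals is carried forward as the series'
log-scale SE, since the reports themselves provide no per-year error.

## Coverage filters and series selection

Monitoring-scheme series are kept only when the most recent observed
year represents at least 50% of the species' current EU population;
individual years under 5% coverage are masked (before any rescaling —
masking afterwards would let unrepresentative early years leak into the
anchor normalisation). An explicit per-species exclusion list is
honoured for series known to be unreliable. Where both sources exist,
the monitoring-scheme series wins; provenance is kept in the output.

## The imputed assemblage model

Leading missing years are filled with the first observed value (interior
gaps are an error by construction). Each series is divided by its value
in the anchor year — the species' mean population-estimate year rounded
to the nearest grid year, since indices exist only on integer years —
and multiplied by the species' EU population estimate, then summed
across species. At a common integer anchor year the total equals the sum
of the estimates exactly.

The bootstrap (default N = 1000) resamples, per iteration and species:
`ln E ~ N(ln Ē, se)`, every annual `ln I` independently, and the anchor
year `y ~ N(ȳ, se)` rounded to the grid. Index noise is treated as
independent across years; the alternative (correlated trajectories)
would narrow the intervals of *ratios* between nearby years, but there
is no information in the inputs to estimate that correlation, so
independence is the assumption made and stated. Filled leading years
inherit the first observed year's SE. Index values of exactly zero are
floored at 1e−6 of the series maximum before logs. All draws follow a
fixed order (species in id order; within species: index matrix, anchor
year, estimate), so any seed reproduces results bit for bit.

## Change summaries

* **Net/percent/per-annum change** between the endpoint years, with
  `per-annum = 100·((A_{y1}/A_{y0})^{1/(y1−y0)} − 1)` so that
  `(1+pct/100) = (1+pa/100)^{y1−y0}` exactly.
* **Gross split**: per-species net changes summed by sign. The growth
  rate of a species is defined from its endpoint ratio on the filled
  series, `r_s = ln(I_{y1}/I_{y0})/(y1−y0)`: with leading-year filling,
  endpoints are the stable quantity, whereas a mean of year-on-year logs
  would be dominated by observation noise (it telescopes to the same
  endpoints anyway when no years are missing).
* **Distribution statistics** of `r_s`: median, moment skewness
  `m3/m2^{3/2}`, and the plain fourth standardised moment `m4/m2²`
  reported alongside its excess form, since conventions differ.
* **Abundance quartiles**: rank by EU estimate, four contiguous classes
  with sizes differing by at most one (lower classes take the extras;
  378 species give 95/95/94/94); ties break by species id for
  determinism.
* **Group summaries** recompute all of the above on group-restricted
  assemblages; groups under two species are flagged rather than dropped.
* **Extreme contributions**: within each sign, species ranked by |net
  change|; the top-k share is their summed change over the gross change
  of that sign.
* **Piecewise regression**: `ln A` on year with one breakpoint on the
  integer grid chosen by residual sum of squares, segments constrained
  to meet at the breakpoint (an unconstrained two-line fit can produce a
  jump in abundance at the break year, which has no biological reading);
  slope CIs are conditional on the selected breakpoint. Candidates leave
  at least two years on each side.

Natural logarithms are used throughout.

## The synthetic generator

`scenario_config()` emulates the structure of the real inputs with known
truth: lognormal species abundances (default meanlog `log(5e5)`, sdlog 2
— spanning roughly 10³–10⁸ individuals, rare to super-abundant), species
growth rates `N(−0.005, 0.015)` ln units/yr (centred slightly below
zero, most species within a few percent per year), Dirichlet country
shares (unequal national partitions are what make the 50%/5%/one-third
filters bite), min/max reporting ranges built as `obs/f` to `obs·f`
around a lognormal observation of the truth with `sd = log(f)/3` — so
the sixth-of-log-span SE the pipeline derives equals the noise actually
present — mixed reporting units, heterogeneous trend and estimate
periods, late-starting index series and ramped coverage fractions.

Two presets pin down study conditions used by the tests:
`scenario_noiseless()` (degenerate ranges, zero noise, a common
single-year estimate period) under which the full pipeline must
reproduce the true totals to floating-point accuracy, and
`scenario_calibration()` (8 species, 5 countries, complete series,
self-consistent noise) for interval-coverage checks — 200 replicate
scenarios with N = 500 bootstrap draws each, sizes chosen so the whole
suite re-runs in a few minutes. What the generator does *not* emulate:
spatially correlated national trends, scheme-specific detectability
drift, taxonomic structure, or reporting biases that correlate precision
with trend direction — passing tests therefore demonstrate correctness
of the estimator under its own assumptions, not robustness of the
original survey data.

## Known limitations

* The published analysis fed GAM-smoothed index series into the imputed
  model; this package consumes the assembled series directly, so
  headline numbers computed from equivalent raw inputs can differ at the
  margin, particularly the piecewise slopes near series ends.
* Hierarchical shrinkage of uncertain species toward group means (the
  Bayesian route) is out of scope; all intervals here are bootstrap
  quantiles.
* The sixth-of-span convention over-states pooled uncertainty for sums
  of independent national ranges; assemblage intervals are accordingly
  conservative.
* Bootstrap index noise is independent across years by assumption.
* The trend-code handling assumes the base of the reported log-scale
  means is immaterial (natural log used); only ratios and exponents of
  the back-transformed quantities enter the results.
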
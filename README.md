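# wetgerm

Wet-thermal time modelling of seed germination timing, for restoration
ecologists and seed biologists deciding *when to sow*. In cold-desert and
steppe systems, seeds sown in autumn may germinate before winter and die;
`wetgerm` turns constant-temperature laboratory germination trials plus
field seedbed sensor records into predicted field germination dates, and
scans planting dates for the earliest one that defers germination to spring.

## The model

Germination progress for a population percentile accrues only while the
seedbed is wet enough: with germination rate *r*(*T*) (fraction of the
thermal requirement per day at soil temperature *T*) and base water
potential Ψ<sub>b</sub> (default −1.5 MPa), the percentile germinates at the
first time *t*\* satisfying

> ∫ r(T(t)) · 1{Ψ(t) ≥ Ψ<sub>b</sub>} dt = 1  (from planting to *t*\*).

The rate function is estimated per treatment × percentile from lab trials:
interpolated times to *N*% germination (T<sub>N</sub>) are averaged across
replicate dishes at each incubation temperature, inverted to rates, and fit
with an ordinary least-squares quadratic r<sub>N</sub>(T) = A·T² + B·T + C.
The package also computes the classical single-dish indices — final
germination percentage, mean germination time t̄ = Σnᵢtᵢ/Σnᵢ and its
reciprocal rate, coefficient of variation, uncertainty
U = −Σfᵢlog₂fᵢ (bits), synchrony Z = ΣC(nᵢ,2)/C(Σnᵢ,2), and T<sub>N</sub> —
with grouped means and standard errors.

Everything is tibble-in / tibble-out and pipeable; fitted models support
`tidy()`, `glance()`, and `autoplot()`.

## Worked example

```r
library(wetgerm)

# 1. lab trial (here simulated with known truth; use read_lab_counts() for
#    your own CSV of interval counts)
lab <- simulate_lab_counts(seed = 1)      # 5 temps x 7 dishes x 25 seeds
model <- fit_rate_curves(lab, percents = percentile_grid(10, 90, 10))
model
#> <wet_thermal_model> 9 curve(s), 1 treatment(s), psi_b = -1.5 MPa
#> # A tibble: 9 × 10
#>   treatment percentile        A      B       C    r2 adj_r2 t_min t_max n_points
#> 1 SYN1              10 -2.27e-3 0.0868 -0.280  0.981  0.962     5    25        5
#> 5 SYN1              50 -1.04e-3 0.0416 -0.114  0.991  0.981     5    25        5
#> 9 SYN1              90 -5.88e-4 0.0235 -0.0499 0.993  0.986     5    25        5

glance(model)
#>   n_curves n_treatments min_adj_r2 median_adj_r2 max_adj_r2 psi_b
#> 1        9            1      0.937         0.977      0.986  -1.5

# 2. field series (simulated seedbed; use read_field_series() for sensor CSVs)
series <- simulate_field_series("2015-09-01", "2016-04-30", seed = 2)

# 3. scan daily planting dates for 50% germination
scan <- predict_planting_scan(model, series, 50, "2015-09-01", "2016-03-01")
head(tibble::as_tibble(scan), 3)
#>   site_year treatment percentile planting_date predicted_date      reached
#> 1 SYN-1     SYN1              50 2015-09-01    2015-09-04 16:32:39 TRUE
#> 2 SYN-1     SYN1              50 2015-09-02    2015-09-05 16:58:12 TRUE
#> 3 SYN-1     SYN1              50 2015-09-03    2015-09-06 17:16:46 TRUE

# 4. earliest planting date whose predicted germination falls in spring
spring_planting_date(scan, cutoff = "2016-03-01")
#>   site_year treatment percentile planting_date status cutoff
#> 1 SYN-1     SYN1              50 2015-12-20    met    2016-03-01
```

Reading the output: the fitted table holds one quadratic per percentile with
its (adjusted) R²; a September planting of this simulated seed lot would
reach 50% germination within about 3–4 days of sowing (the seedbed is still
warm and wet), so to keep half the population ungerminated until 1 March,
sowing would have to wait until 20 December under this site-year's weather.
`autoplot(model)`, `autoplot(scan)`, and `plot_germination_curves(lab)` draw
the corresponding figures.

Per-sample indices and the four summary tables (per-sample metrics,
treatment × temperature averages, their standard errors, polynomial
coefficients) come from `germination_metrics()`, `summarize_germination()`,
and `write_metrics_tables()`. A thin command-line wrapper with subcommands
`metrics`, `fit-model`, `predict-date`, `predict-percent`, `plant-window`,
and `simulate` is installed at `inst/cli/wetgerm.R`
(`Rscript <path>/wetgerm.R plant-window --help`-style usage is documented in
the file header).

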
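# bloomphen

Phytoplankton bloom phenology from gridded ocean-colour time series.

In many tropical seas the annual phytoplankton bloom happens in winter:
sustained surface heat loss erodes stratification, convective mixing deepens
the mixed layer into nutrient-rich water, and chlorophyll-a rises well above
its oligotrophic baseline. `bloomphen` detects the timing of that bloom —
initiation, peak, termination and duration — from 8-day composite
chlorophyll-a records, relates the timing to its physical drivers (SST,
mixed-layer depth, air–sea heat flux), and contrasts warm against cold years
with composite difference maps. A synthetic-data generator plants ground
truth for every quantity the pipeline estimates, so the whole analysis is
testable end to end without satellite downloads.

## The method

**Threshold criterion / cumulative sums.** Let `c(t)` be a gap-filled
chlorophyll series on the 8-day grid (46 periods per year, with bloom years
anchored in mid-September so a winter bloom is never split). The bloom
threshold is

```
c* = median(c) × (1 + f),   f = 0.15 by default,
```

computed once on the whole multi-year record. Anomalies `a(t) = c(t) − c*`
are accumulated and the gradient of the cumulative sum — which changes sign
exactly where the series crosses the threshold — marks the transitions.
Within each bloom year:

* **initiation** = first period of the above-threshold episode containing
  the annual maximum (the bloom peak),
* **termination** = first period after the peak in which the gradient turns
  negative (first fall below the threshold),
* **duration** = termination − initiation (in 8-day periods, reported as
  "weeks").

A year whose series never exceeds the threshold, or whose episode is shorter
than a configurable minimum (2 periods), is flagged `no_bloom` and excluded
from interannual statistics. The same detector runs per pixel on gridded
fields, with coastal pixels (bathymetry < 100 m) masked.

**Mixed-layer depth.** From temperature profiles, MLD is the shallowest
depth at which temperature drops more than ΔT = 0.125 °C below the
reference-depth temperature, located by linear interpolation between model
levels.

**Warm/cold composites.** Years are classified warm or cold by their SST
anomaly over the bloom-peak window (neutral band ±0.25 °C); per-pixel
composite difference maps (warm mean − cold mean) express how bloom timing
responds to warmer conditions.

**Statistics.** Relationships are tested with Pearson correlation when both
series pass a one-sample Kolmogorov–Smirnov normality check, Spearman rank
correlation otherwise.

## Worked example

```r
library(bloomphen)

res <- run_pipeline(synthetic_config())
res
#> <bloom_pipeline_result>
#>   threshold: 0.2581 mg m-3; 18/18 years with a detected bloom
#>   mean initiation 10.7, termination 25.1, duration 14.3 periods
#>   composite (warm - cold): initiation +2.04, termination -3.98, duration -6.01 periods
#>   12 driver correlations computed (see $correlations)

print(head(res$correlations[, 1:5], 3), digits = 3)
#>                     comparison   method    rho  p_value   n
#> 1       chl_vs_sst_climatology spearman -0.966 1.54e-27  46
#> 2 chl_vs_mld_monthly_anomalies spearman  0.775 1.70e-44 216
#> 3       winter_heatloss_vs_mld spearman  0.846 9.85e-06  18
```

Reading the output: the bloom initiates on average at 8-day period 10.7 of
the bloom year (early December for a mid-September anchor), terminates
around period 25 (early April), and lasts ~14 periods (~4 months). In warm
years the planted bloom starts 2 periods later, ends 4 periods earlier and
is 6 periods shorter — the composite maps recover exactly that. The
chlorophyll climatology is near-perfectly anti-correlated with the SST
cycle (ρ = −0.97), and deeper winter mixing / stronger heat loss go with
more chlorophyll and a longer bloom.

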
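# mpnoise

How robust is the matrix profile to noisy data?

The matrix profile (MP) of a univariate time series *X* of length *n*
records, for every length-*m* subsequence, the z-normalised Euclidean
distance to the most similar *other* subsequence of the series, together with
that neighbour's position — an array of length *n − m + 1* whose minima mark
**motifs** (repeated patterns) and whose maximum marks the **discord** (the
most anomalous subsequence). It is exact, essentially parameter-free apart
from the window *m*, and widely used on behavioural and sensor streams:
inter-keystroke timings (window 20), collar-accelerometer activity of
new-born calves aggregated to one-minute means (window 60), and hourly
city-centre traffic volumes (window 24).

Real streams are noisy, and in unsupervised settings the noise cannot be
pre-filtered without risking deletion of the very patterns being sought.
`mpnoise` measures the profile's robustness directly: corrupt the series with
a controlled amount of additive noise, recompute the profile, and score how
far it moved. Two corruption schemes are provided —

* **duplicated anomalies**: a random 5% of values each repeated *k* times
  (*k* = 2…6), emulating recording errors;
* **irrelevant features**: a proportion *p* (1%–50%) of values drawn from
  Unif(min *X*, max *X*) inserted at random positions, emulating measurement
  noise —

and because the corrupted profile is longer than the clean one, the two are
aligned with FastDTW (radius 30, local cost |aᵢ − bⱼ|). The dissimilarity is

```
D = Σ |matched differences| / (x₁ · y₁)
```

with *x₁* the clean series length *N* and *y₁* the clean profile's maximum;
identical profiles score exactly 0.

The package is tidyverse-native: functions take a data frame (or numeric
vector) first, return tibbles, and fitted objects have `tidy()`, `glance()`
and `autoplot()` methods. The MP core (exact STOMP-style *O(n²)* pass with
recursively updated sliding dot products) and the windowed DTW dynamic
program are compiled code, held to brute-force oracles by the test suite.

## Worked example

```r
library(mpnoise)

traffic <- gen_traffic_like(n = 3600, seed = 7)   # 150 days of hourly counts
mp <- matrix_profile(traffic, window = 24)
glance(mp)
#>   source_length window n_values  mean   max   min motif_a motif_b discord
#> 1          3600     24     3577 0.226  3.08 0.123    2217    3081    1000
```

The generator planted one anomalous low-volume day; the discord at position
1000 falls inside it (hours 985–1008 of the planted day 42), and the motif
pair links two ordinary days at the same hour of day (positions 2217 and
3081, 36 days apart). Sweeping the standard ten noise conditions:

```r
report <- run_noise_study(traffic, window = 24, seed = 7)
report
#> <noise_study> N = 3600, MP length = 3577, window = 24, y1 = 3.077, radius = 30
#>    condition                 sum_abs_diffs  mean   max    min normalised
#>  1 Original Matrix Profile              0  0.226  3.08 0.123  0.000
#>  2 Duplicated Anomaly x 2             460. 0.383  3.05 0.129  0.041
#>  3 Duplicated Anomaly x 3             648. 0.422  2.89 0.137  0.059
#>  4 Duplicated Anomaly x 4             837. 0.459  2.88 0.112  0.076
#>  5 Duplicated Anomaly x 5             809. 0.444  3.02 0.114  0.073
#>  6 Duplicated Anomaly x 6             876. 0.448  3.16 0.0944 0.079
#>  7 Irrelevant Features - 1%           593. 0.402  3.08 0.126  0.054
#>  8 Irrelevant Features - 5%          2070. 0.918  3.32 0.142  0.187
#>  9 Irrelevant Features - 10%         2808. 1.47   4.99 0.157  0.253
#> 10 Irrelevant Features - 25%         5720. 2.53   4.46 0.515  0.516
#> 11 Irrelevant Features - 50%         9416. 3.13   4.63 1.49   0.850
```

Each row is one corruption condition: the summed absolute DTW-matched
profile difference, the corrupted profile's mean/max/min, and the normalised
dissimilarity. A little noise moves the profile a little (×2 duplication:
0.041); heavy insertion moves it a lot (50% irrelevant features: 0.850), with
the dissimilarity rising monotonically along both arms — the package's
headline trend, asserted over 20 seeds in the test suite. `autoplot(report)`
draws the sweep; `write_report(report, "out", fmt = c("csv", "json"))`
exports it (the JSON reproduces byte-for-byte under the same seed).

Reference measurements for the three real case-study datasets ship as a
plain-text table (`reference_noise_study()`); the suite verifies that the
published normalised dissimilarities are exactly the Σ/(N·y₁) arithmetic.

## Layout

| Where | What |
| --- | --- |
| `R/matrix-profile.R` | exact MP, distance profile, summaries, motif/discord, CSV I/O |
| `R/noise.R` | the two injectors, provenance masks, the ten-condition grid |
| `R/dtw.R` | exact DTW, FastDTW, normalised profile dissimilarity |
| `R/generators.R` | keystroke / calf-accelerometer / traffic / planted generators, A_mag, resampling |
| `R/study.R` | the study pipeline, reports, reference tables |
| `src/kernels.cpp` | STOMP pass and windowed DTW dynamic program |
| `inst/scripts/mpnoise.R` | thin CLI (`generate`, `study`) |
| `vignettes/matrix-profile-noise.Rmd` | methods: model, parameters, generator design, limitations |
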
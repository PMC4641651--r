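# rfidprov

How long does a behavioral observation need to be? Studies of parental care
in nest-box birds routinely score provisioning with one-hour watches, chosen
mostly by convention. Automated RFID (PIT-tag) readers at the nest-box
entrance log every visit a tagged parent makes across the whole day, which
makes the question answerable: how much of the *between-nest* variation in
whole-day visit rate does a window of a given start time and duration
capture, and where do longer watches stop paying for themselves?

`rfidprov` implements that analysis end to end:

1. **Event inference.** Raw detection logs (one row per antenna read, to the
   second) are collapsed into visit events by merging runs of reads separated
   by at most a gap threshold (default 2 s ≈ four 0.5 s reader duty cycles) —
   a perching bird otherwise generates hundreds of spurious "visits".
   Nest-days with fewer than 200 combined reads (malfunctioning tag or
   antenna) are excluded.
2. **Windowed resampling.** For each nest-day, the daily visit rate
   (visits / total recording hours, per sex) and the rate inside every
   observation window on a start × duration grid (defaults: hourly starts,
   durations 15 min – 4 h by 15 min; windows must fit inside the recording
   schedule, which excludes the 22:00–04:00 night shut-off).
3. **Accuracy.** Per (sex, window), the OLS regression of daily rate on
   window rate across nests; accuracy is the R² (= squared Pearson r), with
   a nonparametric bootstrap percentile CI (default 10 000 resamples of
   nests) and standard influence diagnostics.
4. **Saturation fits.** R² as a function of duration is fit with a
   three-parameter Gompertz `d·exp(−exp(b(x−e)))`, Michaelis–Menten
   `c + (d−c)/(1+e/x)`, asymptotic regression `c + (d−c)(1−exp(−x/e))`, and
   a penalized regression spline (GCV, via mgcv); families are ranked by
   AICc and checked with a lack-of-fit F test against per-duration group
   means.
5. **Optimal duration.** Two marginal-value rules: the *Euclidean
   (minimally-important-change)* rule — the grid duration whose min–max
   normalized (cost, benefit) point lies nearest the ideal corner — and the
   *concavity* rule — the local minimum of the Gompertz second derivative,
   located analytically.

A simulator (`simulate_study()`) generates complete synthetic studies —
gamma-distributed per-sex rates (male variance > female), Poisson visit
times at a near-constant diel rate, perching bursts at the 0.5 s duty
cycle, staggered morning deployments, night shut-off — so the entire
pipeline is testable with no field data.

## Worked example

```r
library(rfidprov)

cfg <- sim_config(n_nests = 64, seed = 42)   # paper-scale synthetic study
sim <- simulate_study(cfg)
res <- run_pipeline(sim$detections, sim$registry, sim$schedule,
                    n_boot = 2000, seed = 7)

res$accuracy[res$accuracy$time == "13:00:00",
             c("time", "r2_F", "ci_low_F", "ci_high_F", "r2_M", "n")]
#>       time      r2_F  ci_low_F ci_high_F     r2_M  n
#> 8 13:00:00 0.6422739 0.4925721 0.7631812 0.615858 64

res$model_tables$F[, c("family", "d", "e", "rss", "aicc", "delta_aicc")]
#>      family         d         e       rss      aicc delta_aicc
#> 1       mm3 1.1223293 1.3924997 0.6358451 -481.9978   0.000000
#> 2       ar3 0.9054319 1.5043830 0.6517463 -477.6505   4.347285
#> 3    spline        NA        NA 0.6319897 -473.0321   8.965652
#> 4 gompertz3 0.8724537 0.3345349 0.6834073 -469.3018  12.695961

res$optima
#>   sex    method    family duration_h  objective
#> 1   F euclidean       mm3  1.5000000  0.5044033
#> 2   F concavity gompertz3  1.3408777 -0.1285684
#> 3   M euclidean       mm3  1.5000000  0.4388430
#> 4   M concavity gompertz3  0.9398948 -0.2281588
```

Reading it: a 1 h watch starting at 13:00 explains ~64% of the between-nest
variance in female whole-day visit rate in this simulated study (95%
bootstrap CI 0.49–0.76, n = 64 nests). The Michaelis–Menten curve fits the
R²-vs-duration cloud best by AICc; the Euclidean rule puts the optimal watch
at 1.5 h for both sexes on the 15-min candidate grid, and the Gompertz
concavity rule at ≈ 1.34 h (females) and ≈ 0.94 h (males). On field data the
same surfaces are produced from CSV logs with
`run_pipeline("detections.csv", "registry.csv", "schedule.csv")`.

Pre-binned 15-minute count tables (the common supplementary format for
provisioning data) are supported via `read_interval_counts()` /
`counts_to_series()`; an R-data distribution converts with one line:
`load("counts.RData"); write.csv(x, "counts.csv", row.names = FALSE, na = "")`.

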
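---
title: "Optimal observation durations from continuous visit logs: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Optimal observation durations from continuous visit logs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the estimand

An RFID reader at a nest-box entrance records every pass of a PIT-tagged
parent, giving the whole-day visit count per sex that a human observer could
never collect. A behavioral watch of duration $t$ starting at clock time $s$
yields a rate $w = N_{[s,s+t)}/t$; the whole-day rate is
$y = N_{\text{day}}/T$ with $T$ the recorded hours. The quantity of interest
is *between-nest* accuracy: the $R^2$ of the simple regression of $y$ on $w$
across nests, i.e. the share of among-individual variance in daily
provisioning that the short watch captures. $R^2$ is computed as the squared
Pearson correlation (identical to the OLS $R^2$ in simple regression), with
a percentile bootstrap CI over resampled nests.

Under an idealized model — nest-level true rates $\lambda_i$ with
between-nest variance $\sigma_b^2$ and mean $\mu$, visits Poisson within
nests, window disjoint from the rest of the day — the expected accuracy is
the plug-in expression implemented by `expected_r2()`:
$$R^2(t) \approx \frac{\sigma_b^2}{\sigma_b^2 + \mu/t},$$
a saturating function of $t$. Real windows are *part of* the day they
predict, which inflates the correlation slightly (for an 18 h day and
$t = 1$ h, $(\sigma_b^2+\mu/18)/(\sigma_b^2+\mu)$ rather than
$\sigma_b^2/(\sigma_b^2+\mu)$); the property tests budget for this.

## From reads to visits

A perching bird adjacent to the antenna is read every reader duty cycle
(0.3 s detect + 0.2 s pause = 0.5 s). `collapse_to_visits()` therefore merges
maximal runs of reads with consecutive gaps ≤ `gap_threshold` into single
visits. The threshold defaults to **2 s** — four duty cycles, so up to three
consecutively missed reads do not split a perching bout — and is exposed as a
parameter because the merge rule is a modelling choice, not a measurement: a
bird that leaves and returns after more than the threshold is counted twice,
which is accepted as a mild overestimate of true feeding visits.

Other event-stage rules, all deliberate:

* **Low-read exclusion**: a nest-day with *strictly fewer than* 200 combined
  (M+F) raw reads indicates hardware failure and is dropped before any
  statistics. The boundary case of exactly 200 is kept.
* **Schedules** are explicit lists of half-open on-intervals per nest-day;
  the night shut-off (22:00–04:00) and staggered morning deployments are
  just schedule facts. Visit starts must lie inside on-intervals; window
  membership is half-open `[start, start+t)`.
* **Windows are never pro-rated.** A window not fully inside the schedule
  excludes that nest from that window's regression (this is what makes the
  per-start sample size rise through the morning as late-deployed nests come
  online). Pro-rating would mix unequal variances into the predictor.
* **Binned tables**: 15-min count tables flag bins not fully covered by the
  schedule as *missing*, never zero, so imported rates are not diluted by
  off-time. Round-tripping through the table preserves every bin-aligned
  windowed rate exactly; within-bin timing is the only information lost.
* Timestamps are naive local clock times at 1 s resolution; no time-zone or
  DST arithmetic is attempted.

## Saturation families and model choice

Accuracy versus duration is fit on the pooled cloud of (duration, $R^2$)
points over all start times (11 starts × 16 durations = 176 points per sex
with the default grids). Pooling, rather than averaging per duration, keeps
the start-time replication that the lack-of-fit test uses as pure error;
`profile_means()` provides the averaged alternative when replication is not
needed.

Families (all with lower asymptote behavior appropriate for an $R^2$ in
$[0,1]$):

* Gompertz, $f(x) = d\,e^{-e^{b(x-e)}}$ with lower limit fixed at 0;
  increasing for $b<0$, with an inflection point.
* Michaelis–Menten, $f(x) = c + (d-c)/(1+e/x)$; $e$ is the half-saturation
  duration.
* Asymptotic regression, $f(x) = c + (d-c)(1-e^{-x/e})$.
* Penalized cubic regression spline (mgcv, smoothness by GCV), as the
  assumption-free reference.

**Fitting.** The parametric families are fit by *variable projection*: for
fixed nonlinear parameter(s) the remaining parameters are linear and solved
exactly, so mm3/ar3 reduce to a 1-D profile over $\log e$ (coarse log-grid
scan + golden-section refinement, tolerance 1e-12) and the Gompertz to a 2-D
profile over $(b, e)$ (deterministic multi-start from $b_0 \in
\{-2,-1,-0.5\}$ × data quantiles of $x$ for $e_0$, Nelder–Mead then BFGS
polish). This deviates from a "random restarts" scheme on purpose: it is
reproducible without a seed and recovers noiseless parameters to ~1e-10,
comfortably inside the 1e-6 contract. A fitted asymptote $d \notin [0,1.05]$
warns but does not fail — on noisy profiles far from saturation the
unconstrained asymptote legitimately drifts above 1.

**Ranking.** AICc with the full Gaussian constant,
$n\log(2\pi\,\mathrm{rss}/n) + n + 2p + 2p(p+1)/(n-p-1)$, $p$ = mean
parameters + 1 (variance); for the spline, effective df from mgcv plus the
intercept. The constant cancels in ΔAICc. The lack-of-fit F compares each
fit against the saturated per-duration group-means model.

A caution established while validating: at the residual scale these profiles
actually have (σ ≈ 0.05), the four families are close to statistically
indistinguishable — the generating family wins the AICc ranking only ~80% of
the time in recovery simulations. The test suite asserts ranking consistency
at σ = 0.02, where selection is identifiable, and treats near-ties at
realistic noise as the expected behavior, not a failure: the practical
conclusion (the optimum duration) is robust across families.

## The two optimality rules

**Euclidean (minimally-important-change).** Durations and fitted accuracies
are min–max normalized over the evaluated range; the optimum is the candidate
grid point minimizing $\sqrt{x_n^2 + (1-y_n)^2}$, the distance to the
"free and perfect" corner. Defaults: the 15-min data grid 0.25–4 h (so
optima land on quarter hours, as practitioners schedule watches); ties break
toward the shorter duration; a flat fitted curve returns the shortest
duration with a warning. Because the normalization is over the *fitted curve's*
range — not the theoretical $[0,1]$ of $R^2$ — the rule is invariant to the
duration unit. The `y_norm = "unit"` switch provides the other convention,
since the clinical-trials literature the rule comes from is not explicit
about it; with curves spanning most of their range the two agree.

**Concavity.** For the Gompertz fit only, the local minimum of
$f''(x) = -d\,b^2\,u\,e^{-u}(1-u)$, $u = e^{b(x-e)}$ — the inflection of the
first derivative, where the per-hour accuracy gain begins its asymptotic
decline. Implemented as a dense scan plus golden-section refinement of the
analytic $f''$; in closed form the minimizer is $x^* = e + \log u^*/b$ with
$u^* = (3-\sqrt5)/2$, which the tests use as an independent oracle. The
other families have monotone-decreasing steepness and no such point, hence
the hard error for non-Gompertz fits.

## What the simulator emulates — and what it does not

`simulate_study()` states one fixed world (defaults chosen once, from the
study design it emulates):

| parameter | default | why |
|---|---|---|
| nests | 64 | analysis-scale sample after exclusions |
| on-period | 04:00–22:00 | reader night shut-off |
| full-day nests | fraction 18/64 | rest deployed 07:00–10:00 |
| μ_F, μ_M | 8, 6 visits/h | females feed more on average |
| cv_F, cv_M | 0.35, 0.55 | male among-nest variance exceeds female |
| diel amplitude | 0 | cumulative visits accrue linearly |
| perch bout | prob 0.3, Exp(10 s) mean | bursts at the 0.5 s duty cycle |
| read failure | 0.05 per read | imperfect antenna |

With these defaults a nest-day averages ≈1.3k combined reads, the scale
reported for working readers. Features deliberately *not* modelled: weather
and brood-size covariates, partner coordination, behavior classification
(feeding vs brooding vs defense), battery decay, multi-day dependence. A
green pipeline test on simulations therefore establishes computational
correctness and statistical behavior under the stated model — not field
validity of any particular biological estimate.

Timestamps are floored to whole seconds like real logs; two true visits
landing within the merge threshold are merged, so simulated recovery of true
visit counts is exact only where consecutive true visits are farther apart
than a perch bout plus the threshold — the tests condition on exactly that
precondition rather than hiding it.

## Numerical conventions and degenerate inputs

* Zero predictor variance defines $R^2 = 0$ with a warning (regression on a
  constant explains nothing); degenerate bootstrap resamples likewise score
  0 rather than being dropped, so intervals are never computed on a
  silently reduced replicate count.
* Bootstrap resampling is vectorized in closed form; intervals are
  percentile, clamped to $[0,1]$ by construction. The resampling unit is the
  nest pair. Seeds are explicit arguments; the caller's RNG state is
  restored.
* Influence screens: Cook's distance > 4/n or leverage > 2(k+1)/n; fits with
  numerically zero residual variance carry no influence signal. Flags are
  reported, never used to exclude.
* `fit_curve` requires ≥ 6 distinct durations; `lack_of_fit_test` errors
  without replication; `aicc` errors when $n \le p+1$.
* Pipeline determinism: the full result bundle is reproducible bit-for-bit
  from (inputs, seed), and exclusion counts reconcile
  input = kept + excluded.

## Known limitations

* The bootstrap CI is percentile-only; BCa would shift narrow intervals near
  the $[0,1]$ boundary slightly outward. Measured coverage for $R^2 = 0.5$,
  $n = 60$ is ≈ 93%.
* The accuracy currency is between-nest $R^2$ on one day; within-nest
  repeatability across days is out of scope.
* The Gompertz lower limit is fixed at 0; profiles with a substantial
  accuracy floor at 15 min are better served by mm3/ar3, whose floors are
  free parameters.
* Reading binary R-data supplements directly is out of scope by design; the
  documented one-line conversion to the CSV count-table schema covers that
  interchange.
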
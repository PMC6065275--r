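# fishHMM

Prior-informed hidden Markov models for classifying the daily movement
behaviour of tagged demersal fish (Atlantic cod, European plaice) into
**resident** and **migrating** states, and for scaling the decoded
behaviour of 100+ individuals to population-level patterns.

## Who this is for

Movement ecologists and fisheries scientists with archival-tag (DST)
datasets: a 10-minute depth log and daily geolocation estimates per fish.
Classic per-individual HMMs only work on long tracks and give no guarantee
that "state 1" means the same thing in two fish. This package implements a
two-stage remedy: fit every fish independently, turn the data-rich fits
into species-level priors on the state mean movement rates, and refit the
data-poor fish with those priors — consistent state labels across the
cohort and usable inference from short tracks.

## The model

Per fish, a 2-state hidden Markov model on the daily bivariate series
x_t = (h_t, v_t) of log horizontal step length and log net vertical
movement (both m/day before the natural log):

* latent first-order Markov chain S_t ∈ {R, M}, transition matrix Γ,
  uniform initial distribution ω;
* x_t | S_t = j ~ MVN(μ_j, Σ_j) with Σ_j built from σ_jH, σ_jV, ρ_j
  (h and v conditionally dependent given the state);
* MAP estimation: forward-algorithm likelihood × Beta(99, 1) priors on
  γ_RR, γ_MM (prior mean 0.99 ⇒ expected dwell 1/(1−0.99) = 100 days)
  × optional Gaussian priors N(m_jd, δ_jd) on the state means;
* forward–backward smoothing, per-day argmax state allocation, days with
  winning probability < 0.85 flagged uncertain.

Population layers: weekly cohort state probabilities, state-dominant
seasonal windows (weeks with mean probability > 0.5, wrapping the year
end), 5 km × 5 km equal-area utilization grids of state-classified
fish-days, substock movement-rate tables, geometric dwell-time
diagnostics, and prior-sensitivity / univariate-model comparisons.

## Worked example

Simulate a small cohort with known truth, run the two-stage
classification, and summarise it:

```r
library(fishHMM)

co    <- simulate_cohort(cohort_spec(n_rich = 8, n_poor = 10, seed = 3),
                         species_spec("cod"))
ts    <- run_two_stage(cohort_paths(co))

ts$priors$cod
#> <mean_prior_set cod>
#> m:
#>       H     V
#> R 9.039 3.461
#> M 9.533 5.097
#> delta (variance):
#>        H      V
#> R 0.0133 0.0133
#> M 0.0205 0.0294

head(ts$report[, c("fish_id", "stage", "converged", "T", "frac_R")], 4)
#>   fish_id stage converged   T    frac_R
#> 1  cod001     1      TRUE 460 0.7217391
#> 2  cod002     1      TRUE 385 0.5714286
#> 3  cod003     1      TRUE 339 0.5221239
#> 4  cod004     2      TRUE 235 0.0000000
```

The prior means `m` are the across-fish averages of the fitted state
means on the log m/day scale (exp(9.039) ≈ 8.4 km/day resident horizontal,
exp(9.533) ≈ 13.8 km/day migrating), and `delta` their across-fish
variances; these four Gaussians per species are what stage 2 multiplies
into the likelihood of every data-poor fish. In the report, stage-1 rows
are data-rich fish kept with their unprimed fits; stage-2 rows are
data-poor fish rescued by the priors (`cod004` spends all 235 days
migrating — legitimate under prior-anchored labels). Checking the decoded
states of this run against the generator's truth gives a median per-fish
accuracy of 1.00.

Downstream, `weekly_state_summary(ts$fits)`, `state_dominant_windows()`,
`utilization_grid()`, `substock_rates()` and `dwell_time_analysis()`
produce the population products, and `run_pipeline()` (or the thin CLI in
`inst/cli/fishhmm.R`) runs everything from a YAML config into an output
directory with a reproducibility manifest.

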
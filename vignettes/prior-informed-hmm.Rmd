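---
title: "Prior-informed hidden Markov models for fish movement behaviour"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prior-informed hidden Markov models for fish movement behaviour}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Archival data storage tags (DSTs) recovered from demersal fish such as
Atlantic cod and European plaice yield, after geolocation, one bivariate
daily time series per fish: a horizontal step length (m/day, from
great-circle distances between successive daily position estimates) and a
net vertical movement (m/day, the sum of absolute differences between
successive 10-minute depth records within a day). Both metrics are
natural-log transformed. The ecological question is when each fish is
*resident* (slow, localised) versus *migrating* (fast, directed), and how
those behaviours aggregate over a tagged population across the year.

Fitting an independent hidden Markov model to each fish works only for
long, informative tracks, and nothing guarantees that "state 1" means the
same behaviour in two different fish. This package implements a two-stage
alternative: fit every fish independently, summarise the data-rich fits
into species-level Gaussian priors on the state mean movement rates, and
refit the data-poor fish with those priors in the objective. The priors
anchor the meaning of the states across fish and supply the information
short tracks lack.

## The model

For fish $i$ with path length $T$, a latent first-order Markov chain
$S_1,\dots,S_T \in \{R, M\}$ has transition matrix $\Gamma$ with
self-transition probabilities $\gamma_{RR}$, $\gamma_{MM}$ and a fixed
uniform initial distribution $\omega = (0.5, 0.5)$ — the initial state is
never estimated. Conditional on $S_t = j$ the day's observation
$x_t = (h_t, v_t)$ is bivariate normal with mean $\mu_j = (\mu_{jH},
\mu_{jV})$ and covariance built from standard deviations $\sigma_{jH},
\sigma_{jV}$ and correlation $\rho_j$; $h$ and $v$ are conditionally
dependent given the state. Each fish has 12 free parameters: 2 transition
and $2 \times 5$ emission.

The marginal likelihood is computed with the scaled forward recursion
(implemented in C++, as the field's HMM packages do), state probabilities
with forward–backward smoothing, and the decoded sequence by selecting the
most probable state at each day separately. Days whose winning smoothed
probability falls below 0.85 are flagged as uncertain but still labelled.

Estimation is maximum a posteriori: the log-likelihood plus

* a Beta($\alpha$, $\beta$) log-prior on each self-transition probability,
  default Beta(99, 1). Its mean 0.99 implies a geometric expected dwell of
  $1/(1-0.99) = 100$ days, which makes the states track seasonal shifts
  rather than day-to-day flicker;
* optionally, for each state $j$ and dimension $d$, a Gaussian log-prior
  $N(m_{jd}, \delta_{jd})$ on $\mu_{jd}$. **$\delta$ is a variance**, not a
  standard deviation; the sensitivity tests scale $\delta$ itself by
  $\pm 10\%$.

Optimisation is bounded quasi-Newton (`optim`'s L-BFGS-B) on transformed
parameters — logit for $\gamma$, identity for $\mu$, log for $\sigma$,
Fisher-z for $\rho$ — with 10 restarts by default: one initialisation at
the 25th/75th percentiles of $h$ and $v$ (or at the prior means when mean
priors are active) and the rest jittered, seed-deterministically. The best
posterior wins.

## Design choices in the open corners

Several procedural details are not pinned down by the problem statement;
the package resolves them as follows, and exposes each as configuration.

**Label identifiability.** Unprimed fits are relabelled after optimisation
so that R has the smaller horizontal mean (resident = slow). Prior-informed
fits are *not* relabelled: the priors themselves anchor the labels, which
is the point of the method.

**Convergence and degeneracy.** A fit is non-converged when the optimiser
fails, when any $\hat\sigma$ sits on its floor ($10^{-3}$), or — for
unprimed fits only — when a state's expected occupancy falls below 2 days.
The occupancy rule is deliberately not applied to prior-informed fits:
with externally anchored states, a short track legitimately spending all
its days in one state is a valid classification, not a collapsed model
(single-state fish are an expected minority in real cohorts).

**Data-rich selection.** The defaults — converged, $T \ge 150$ days, both
states occupying $\ge 10\%$ of decoded days — are this package's
reconstruction of "long and informative enough for stable unprimed
fitting". All three knobs sit in `selection_criteria()`. Stage-1 fits of
selected fish are kept as-is rather than refitted with priors partly built
from themselves, avoiding double use of data.

**Prior construction.** $m_{jd}$ and $\delta_{jd}$ are the across-fish
mean and unbiased variance of the *fitted state means* $\hat\mu_{jd}$ of
the selected fish (not of raw classified observations), matching the
prior's role as a distribution over $\mu$. $\delta$ is floored at
$10^{-4}$ so identical fits cannot produce a point-mass prior.

**Preprocessing.** The first 14 days and last day of every series are
trimmed (release/recapture artefacts); fish need 40+ remaining days and a
complete 10-minute depth record (any incomplete day disqualifies the
fish). Days are midnight-to-midnight UTC. Raw daily movements below 1
m/day are floored there before the log — the floor keeps logs finite and
sits far below both states' means; it is configurable
(`preprocess_config()`). Step lengths use the haversine formula on a
6,371 km sphere and are stamped to the earlier of their two days, so day
$k$'s horizontal and vertical metrics describe the same 24 hours.

**Population summaries.** Weeks are $\lfloor (\mathrm{yday}-1)/7 \rfloor
+ 1$, capped at 52. State-dominant windows are maximal runs of weeks with
cohort-mean state probability strictly above 0.5, allowed to wrap across
the year end (winter migration windows do). Utilization grids use 5 km
$\times$ 5 km cells — the conventional reading of "5 km² cells"; pass
`cell_km = sqrt(5)` for the literal reading — after a Lambert azimuthal
equal-area projection centred on the data centroid, which keeps cell areas
honest over a North Sea-scale domain. Substock movement-rate tables
average raw (back-transformed) daily values per fish and state and then
across fish, unweighted. The across-fish standard error of weekly means
excludes fish not at liberty that week.

**Dwell-time diagnostics.** Run lengths touching either end of a decoded
series are censored and excluded from the geometric fit
($\hat p = 1/\overline{\text{dwell}}$); the chi-square goodness-of-fit
bins run lengths greedily so every expected count is at least 5, losing
two degrees of freedom (total and estimated $\hat p$).

## The synthetic-data generator

`simulate_cohort()` produces cohorts with known truth: per-fish parameters
drawn from species-level hyper-distributions (between-fish SD 0.15 on the
log scale by default), Markov state chains, bivariate-normal emissions,
dead-reckoned geolocation tracks whose step lengths invert exactly through
the preprocessing great-circle computation, and optional 10-minute depth
series whose within-day absolute variation sums exactly to $e^{v_t}$.
Default movement scales are anchored to published state-dependent rates
for North Sea cod and plaice (resident horizontal of order 6.5–9 km/day,
migrating 13–14 km/day; vertical tens versus low hundreds of m/day) —
inspiration for realistic magnitudes, not a replication of any dataset.
Cohort sizes default to 34 data-rich plus 73 data-poor fish. Seasonal
cohorts toggle between a residency-favouring and a migration-favouring
transition matrix by calendar week, the simplest mechanism that produces
annual cycles.

What the generator does *not* emulate: geolocation error, tidal and
bathymetric constraints on movement, individual covariates (size, sex,
maturity), tag failure patterns, or non-Markov dwell structure. Passing
tests on synthetic cohorts therefore demonstrate that the estimation,
classification and aggregation machinery is correct under the model's own
assumptions — not that the model is adequate for any particular real
dataset; pseudo-residuals (`pseudo_residuals()`) and the geometric
dwell-time check are the in-package tools for interrogating adequacy on
real data.

## Validation workloads

The test suite and `scripts/acceptance.R` validate the package at fixed
problem sizes chosen to exercise each claim meaningfully: exhaustive
enumeration of all $2^T$ state sequences cross-checks the forward and
smoothing recursions at $T \le 8$; parameter recovery uses 20 fish of
$T = 500$ at realistic movement scales; the two-stage rescue runs a full
34-rich/73-poor cohort; dwell-time geometry pools roughly 250 runs from
12 fish of $T = 2000$ at $\gamma_{jj} = 0.99$; and the prior-sensitivity
scenarios rerun a 12-fish cohort with strongly separated states, where a
decoded-state change can only come from the prior change itself.
Coherence of state labels (every fish's migrating days faster
horizontally than its resident days) is asserted on cohorts whose
horizontal dimension genuinely separates the states; at realistic cod
scales the horizontal separation is weak relative to its spread, and a
few fish violate the inequality through sampling noise alone — visible in
the honest per-cohort percentages the acceptance script reports.

## Known limitations

Two states only; no hidden semi-Markov dwell structure; no covariates on
the transition probabilities; no integrated random-effects (hierarchical)
formulation — the two-stage empirical prior is the deliberate lightweight
alternative. Geolocation estimation itself is out of scope: daily
positions are inputs. Movement-rate tables depend on decoded labels, so
their uncertainty is understated for fish with many low-confidence days;
the `uncertain` flags written alongside every state sequence are the
honest companion to any downstream use.
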
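---
title: "Probabilistic models of cooperative T-cell accumulation and spheroid killing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probabilistic models of cooperative T-cell accumulation and spheroid killing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctlswarm)
```

## The experimental system and its data

ctlswarm analyses droplet-microfluidic killing assays: each of a few
hundred nanolitre droplets holds one tumor spheroid (radius roughly
35–45 µm) in a gel, together with a small, variable number *N* of
cytotoxic T lymphocytes (CTLs).  Time-lapse imaging at one frame every
Δt = 2 min yields, per droplet, (i) CTL migration tracks and (ii) an
occupancy series {n_t}: the number of CTLs in contact with the spheroid
at each frame, together with the time of the first *fragmentation*
event — a burst of shed cellular material that serves as the killing
readout — or a censoring time when the spheroid survives the recording.
"Successful killing" is a first fragmentation before 14 h.

The package starts from those tables (plain CSV, µm and minutes
throughout).  Everything upstream — segmentation, spot detection —
is out of scope, and a synthetic-cohort generator stands in for the raw
data so that every estimator can be checked against a known truth.

## CTL motility

In the gel, CTL migration is super-diffusive: the mean-squared
displacement grows as MSD ∝ τ^α with α ≈ 1.6; on the spheroid surface
the same cells slow to near-diffusive crawling (α ≈ 1.1).  The
generator models this with fractional Brownian motion, whose Hurst
index H gives MSD exponent 2H exactly: presets `gel` (H = 0.8) and
`spheroid` (H = 0.55).  Increments are drawn by Davies–Harte circulant
embedding (`rfgn()`), so the power law is exact in free space.

Two calibration points deserve comment.

* **Step scale.**  The gel preset uses σ = 0.5 µm·min⁻ᴴ per axis.  The
  choice is dictated by the generator's contract that a log-log MSD fit
  over lags 2–60 min recovers 2H inside the default droplet (cylinder,
  r = 400 µm, h = 100 µm, reflecting walls): since cells start uniformly
  in the droplet, a faster walker interacts with the walls — above all
  the 100 µm chamber height — and the fitted exponent is dragged below
  2H.  Real CTLs are faster (~5 µm/min at 1-min sampling); the exponent,
  not the speed, is the recovery target, and attachment dynamics are
  decoupled from the walkers (below), so no downstream inference depends
  on the walker speed.
* **Projection.**  Imaging a single plane projects 3D motion to 2D.
  Under isotropy the projected MSD is exactly 2/3 of the 3D MSD, and a
  diffusion coefficient read off a projected track with the 3D formula
  is 2/3 of the true one; `correct_projection()` applies the inverse
  factors (3/2 for MSD/diffusion, √(3/2) for speeds).  The √(3/2) speed
  factor is an RMS-based convention: for the *mean* magnitude of
  isotropic Gaussian displacements the exact 2D/3D ratio is π/4 ≈ 0.785
  rather than √(2/3) ≈ 0.816, so mean-speed corrections carry a ≤4%
  convention bias.  The test suite asserts both exact ratios.

Because displacements are sub-linear in lag time (|Δr(τ)| ∝ τ^H with
H < 1), measured "velocities" fall with the sampling interval as
τ^(H−1); `velocity_lag_scaling()` quantifies this frame-rate dependence.
First contact with the spheroid is modelled as a pure random search:
`first_contact_null()` simulates first-passage times of preset walkers
to the spheroid surface, and a two-sample Kolmogorov–Smirnov test
compares observed first-contact times against that null (the functional
form of the null has no closed expression, so Monte Carlo is used).

## Attachment and detachment rates

Occupancy dynamics are modelled as a Markov chain on n = 0..N with
per-frame transition probabilities.  The ML estimate of the transition
matrix is the observed fraction p̂(k→l) = a(k,l)/Σ_j a(k,j), where
a(k,l) counts k→l frame pairs pooled over droplets
(`count_transitions()`, `estimate_transition_probabilities()`).
Assuming exponential per-cell waiting times, per-cell rates follow from
λ_in(n) = −log(1 − p(n→n+1)) / ((N−n) Δt) and symmetrically for
λ_out(n) with exposure n.

Implementation choices:

* **Sequential conditioning (default).**  The one-event-per-frame
  observation model means an attachment can only be recorded on a frame
  without a detachment, so the raw attachment fraction estimates
  (1 − p_out)·p_in.  `per_cell_rates(conditioning = "sequential")`
  divides attachment counts by detachment-free frames — the exact
  conditional ML of the single-event chain.  On synthetic cohorts with
  frequent detachments the uncorrected route (`"none"`, provided for
  comparison) biases λ_in by −5 to −15%; the conditioned estimator is
  unbiased within sampling error.
* **Pooling across droplet loads.**  Droplets differ in N, which enters
  the exposure (N−n).  `method = "exposure"` accumulates per-droplet
  cell-frame exposure and uses the small-probability limit;
  `method = "stratified"` applies the exact log inversion within each
  N-stratum and combines strata by exposure.  Both are exposed because
  the right choice depends on whether per-frame probabilities are small;
  at the default rate scale they differ by under 2%.
* **Edge cases.**  Levels never observed are reported missing (never
  zero); p = 1 rows are censored-infinite, not clamped; the affinity
  ratio λ_in/λ_out is flagged undefined where λ_out = 0.  Frames after
  the first fragmentation are excluded by default (killing is modelled
  as independent of the attachment process).
* **Uncertainty.**  `bootstrap_rates()` re-estimates on 50 droplet
  subsamples of 70% drawn without replacement.  Note a structural
  property: without-replacement subsamples spread only ≈ √((1−f)/f) ≈
  0.65 sampling-σ around the full-sample estimate, so the interquartile
  box covers the truth in roughly a third of rows for an unbiased
  estimator — the boxes visualize relative stability, they are not 50%
  confidence intervals.

The same Markov process in continuous time is the birth–death master
equation dP(n,t)/dt = (N−n+1)λ_in(n−1)P(n−1,t) + (n+1)λ_out(n+1)P(n+1,t)
− ((N−n)λ_in(n) + n λ_out(n))P(n,t); `master_equation_forward()`
integrates it (deSolve) and agrees with the discrete-time simulator to
total-variation distance ≤ 0.05, which the tests verify against a
telegraph-process closed form and Monte Carlo.

The cooperative-accumulation signature is read from the fitted profile:
λ_in(n) rising with n at flat λ_out(n), hence an affinity ratio
λ_in/λ_out increasing with the number of CTLs already attached.

## Fragmentation rates and killing models

Killing is a per-frame Bernoulli event whose probability Γ_frag(n)
depends only on the current occupancy.  Maximizing the censored-series
likelihood over all droplets gives the event-fraction estimator
Γ̂(n) = K_death(n) / (K_death(n) + K(n)), where K_death(n) counts
fragmentations observed at occupancy n and K(n) the pre-fragmentation
frames at n.  The boundary identities are exact: no deaths at a level
gives Γ̂ = 0, instant death gives Γ̂ = 1.  Γ_frag is a probability per
frame (of length Δt); estimation and simulation must share Δt.

Two structural models are fitted to the same occupancy levels by
binomial likelihood (exposure-aware — levels have wildly unequal
exposure, so unweighted curve fits are only provided for comparison):

* **Independent killers:** Γ(n) = 1 − (1 − ρ)^n, concave, ≤ nρ.
  Heterogeneity in per-cell efficacy collapses onto the same form with
  ⟨ρ⟩ (`heterogeneous_equivalence()` verifies the collapse by Monte
  Carlo for any supplied efficacy distribution), so a non-concave
  profile cannot be explained by a mixed population.
* **Cooperative (exponential):** Γ(n) = min(γ₀·e^{c·n}, 1), convex for
  c > 0.

Fits are restricted to n ≥ 1 by default: a spheroid with no attached
CTL cannot fragment in the generative truth, and the huge n = 0
exposure would otherwise dominate the exponential intercept; using the
same levels keeps the two log-likelihoods comparable.  Because the
two-parameter exponential can locally mimic the one-parameter
independent curve, raw likelihoods systematically favour it on
independent data; `compare_frag_models()` therefore prefers the
cooperative model only when the likelihood-ratio statistic exceeds the
χ²(1) 5% critical value (Wilks calibration; the families are not
strictly nested, so the calibration is approximate — simulation shows
it selects the generating model in ≥90% of paper-scale cohorts for
well-separated parameters).

## The branching-process fate simulator

`simulate_fate()` couples the two estimated layers into the two-step
discrete-time branching process: at each frame, fragmentation with
probability Γ(n) (start-of-frame n), else one detach draw with
probability 1 − exp(−n λ_out(n) Δt), else one attach draw with
probability 1 − exp(−(N−n) λ_in(n) Δt).  The event order (fragment →
detach → attach, all on start-of-frame n) is one consistent convention
for the one-event-per-frame model; the attach probability uses the
negative exponent (the corresponding published expression omits the
sign, which would put the probability outside [0,1]).  Estimated
profiles are completed by carrying the last defined value into
unobserved occupancies, with the clamped range flagged.

`sweep_cohort()` repeats the simulation over N = 0..20 (50 replicates
each by default) and summarizes killing probability (95% binomial CI)
and first-fragmentation time (mean, 95% interval) versus N.  The
pipeline-closure test estimates profiles from a synthetic cohort, feeds
them to the sweep, and checks that the cohort's own empirical
fragmentation-probability curve is reproduced within confidence
intervals and that the first-fragmentation time decreases with N.

## The synthetic cohort generator

`sim_config()` fixes the study conditions; `generate_cohort()` draws
per-droplet CTL counts from a Poisson(7) truncated at 20, gives each
droplet an independent RNG sub-stream derived from the master seed, and
runs the same chain engine as the fate simulator with the generative
truth.  Condition presets:

| quantity | OVA-like (cooperative) | WT-like (control) |
|---|---|---|
| λ_in(n) (min⁻¹ per gel cell) | 0.002·e^{0.25·min(n,10)} | 4·10⁻⁴ |
| λ_out(n) (min⁻¹ per attached cell) | 0.005 | 0.02 |
| Γ_frag(n) (per frame) | 0 at n = 0; 10⁻⁴·e^{0.55·min(n,12)} | 0 |

No measured per-cell rate values exist to copy, so these were chosen
once for realism and fixed: mean dwell times of hours on an
antigen-bearing target versus minutes on a control, a first attachment
within the first hour or two for a typical load, and an overall
successful-killing fraction of roughly a third of OVA-like droplets at
14 h (the control never fragments).  Default duration is 24 h with the
14 h success cutoff.

What the generator does *not* emulate — and hence what green tests do
not certify about real data: detection noise and occupancy
mis-counting, spatial clustering of kills on the spheroid surface,
spheroid growth or shrinkage, time-varying rates (e.g. CTL exhaustion),
and any coupling between walker positions and attachment (occupancy
dynamics are decoupled from tracks by default; a spatial mode derives
contact labels geometrically for testing the labelling stage only).

## Numerical choices and scales

Tolerances: master-equation integration at rtol 10⁻¹⁰ with probability
conservation checked to 10⁻⁸; the independent-model fit by golden-
section search at tol 10⁻¹²; the exponential fit by Nelder–Mead from
three starts (c₀ = 0, 0.3, 0.8) on (log γ₀, c).  Ties and degenerate
inputs: zero-exposure rows are missing, not zero; stationary tracks
refuse an MSD-exponent fit; all-censored cohorts return ρ = 0 flagged
as a boundary.  Test and verification scales — 150–200 droplets for
recovery properties, 300 trajectories for motility exponents, 50
cohorts per arm for model-selection calibration, 10³ replicates for
Monte-Carlo/master-equation agreement — were chosen so each check's
sampling error sits well inside its assertion band.

A known limitation worth restating: per-level Γ̂(n) carries at most one
death per droplet, so cohort-scale data constrain the *shape* of
Γ_frag(n) (through the pooled model fits) far better than its
level-by-level values; per-level relative errors of tens of percent at
sparsely visited occupancies are expected and are not an estimator
defect.

## The fitted-model interface

`ctl_fit()` wraps the full inference (transition counting, rate
bootstrap, fragmentation ML, model comparison) into a classed object
with `print()`, `summary()`, `coef()`, `plot()`, `simulate()` (fate
replicates from the fitted profiles) and `predict()` (killing
probability versus CTL load through the sweep).  The module-level
functions remain exported for stage-by-stage use; the package is a
library, so no command-line wrapper is shipped.
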
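# ctlswarm

Probabilistic inference of cooperative T-cell accumulation and
tumor-spheroid killing from droplet time-lapse data.

## The problem

In droplet-microfluidic killing assays, hundreds of single tumor
spheroids are each challenged by a small, variable number *N* of
cytotoxic T lymphocytes (CTLs) and followed by time-lapse imaging (one
frame every Δt = 2 min, up to ~24 h).  Each droplet yields CTL
migration tracks, an occupancy series n_t (CTLs in contact with the
spheroid per frame) and the time of the first *fragmentation* event —
the operational killing readout — or a censoring time.  The scientific
questions: do CTLs accumulate on the target by independent random
encounters or through a positive feedback loop, and do they kill
independently or cooperatively?

ctlswarm answers them with four model layers, each exposed as plain
functions and bundled behind one fitting interface:

* **Motility** — time-and-ensemble-averaged MSD with power-law exponent
  α (MSD ∝ τ^α; α ≈ 1.6 in the gel, ≈ 1.1 on the spheroid), exact
  2D-projection corrections (projected MSD = 2/3 × 3D MSD), frame-rate
  dependence of measured speeds, and a Monte-Carlo first-passage null
  for first CTL–spheroid contact times.
* **Accumulation** — Markov-chain ML estimation of per-cell attachment
  and detachment rates from pooled transition counts,
  λ_in(n) = −log(1 − p̂(n→n+1)) / ((N−n) Δt), with droplet bootstrap
  uncertainty and a master-equation cross-check.  A rising affinity
  ratio λ_in(n)/λ_out(n) is the signature of cooperative recruitment.
* **Killing** — ML fragmentation rate per frame,
  Γ̂(n) = K_death(n)/(K_death(n) + K(n)), and binomial-likelihood
  comparison of the independent-killer curve Γ(n) = 1 − (1−ρ)^n
  (concave; robust to per-cell efficacy heterogeneity, which provably
  collapses onto ⟨ρ⟩) against a cooperative exponential γ₀e^{cn}
  (convex), selected by a likelihood-ratio rule.
* **Fate** — a discrete-time branching process (fragment → detach →
  attach per frame) that maps a droplet's CTL count to its killing
  probability and first-fragmentation time, closing the loop from
  estimated parameters back to cohort-level outcomes.

A synthetic-cohort generator (fractional-Brownian walkers,
occupancy-dependent rates, per-droplet RNG sub-streams) supplies ground
truth for every estimator; all tests run against it.

## Worked example

Generate a cohort of 84 droplets under the cooperative (OVA-like)
preset, fit the full model, and predict killing probability versus CTL
load:

```r
library(ctlswarm)
cfg    <- sim_config("ova", duration = 840)     # 14 h at 2 min/frame
cohort <- generate_cohort(cfg, 84, seed = 7)
fit    <- ctl_fit(cohort, reps = 50, fraction = 0.7, seed = 1)
fit
#> CTL accumulation / killing fit: 84 droplets, delta_t = 2 min
#>   killing success (< 840 min): 31.0% (26/84)
#>   occupancy levels observed: 0..11; total deaths: 26
#>   killing models: logLik(exponential) - logLik(independent) = 12.00
```

31% of spheroids were killed before 14 h, and the likelihood-ratio
statistic (2 × 12.0 = 24.0 ≫ 3.84) selects the cooperative killing
model.  The estimated rate profile shows the accumulation feedback —
λ_in rises with the number of attached CTLs while λ_out stays flat, so
the affinity ratio climbs:

```r
round(as.data.frame(fit$rates)[1:6, c("n", "lambda_in", "lambda_out", "affinity")], 4)
#>   n lambda_in lambda_out affinity
#> 1 0    0.0019         NA       NA
#> 2 1    0.0026     0.0044   0.5857
#> 3 2    0.0033     0.0048   0.6869
#> 4 3    0.0050     0.0049   1.0173
#> 5 4    0.0054     0.0050   1.0871
#> 6 5    0.0075     0.0057   1.3207

fit$models$exponential
#> <frag_fit> exponential: gamma0 = 8.5459e-05, c = 0.6259, logLik = -178.060

predict(fit, newdata = c(2, 5, 10, 15), reps_per_N = 50,
        duration = 840, seed = 2)[, c("N", "p_frag", "p_lo", "p_hi")]
#>    N p_frag  p_lo  p_hi
#> 1  2   0.08 0.022 0.192
#> 2  5   0.08 0.022 0.192
#> 3 10   0.62 0.472 0.753
#> 4 15   0.82 0.686 0.914
```

Killing probability rises steeply with the droplet CTL count — the
combined effect of faster accumulation and cooperative killing.
`plot(fit)` draws the rate profiles and the fitted Γ(n) curves;
`simulate(fit, ...)` returns occupancy-series replicates from the
fitted profiles.

The methods vignette (`vignettes/methods.Rmd`) documents the models,
their assumptions, the generator presets and the numerical choices.

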
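#' Built-in attachment / detachment / fragmentation rate presets
#'
#' Two generative regimes bracket the biology:
#'
#' * `"ova"` — antigen-bearing target: the per-cell attachment rate
#'   `lambda_in(n)` rises exponentially with the number `n` of CTLs already
#'   on the spheroid (the positive-feedback hallmark), the detachment rate
#'   `lambda_out` is constant, and the per-frame fragmentation probability
#'   `gamma(n)` grows exponentially in `n` (cooperative killing), with
#'   `gamma(0) = 0` (an untouched spheroid never fragments).
#' * `"wt"` — antigen-free control: low constant attachment, fast
#'   detachment, and no fragmentation at any occupancy.
#'
#' Rates are per minute per cell; `gamma` is a probability per frame.
#' Profiles are vectors indexed by occupancy `n = 0..n_cap`.
#'
#' @param condition `"ova"` or `"wt"`.
#' @param n_cap highest occupancy with an explicit entry (clamped beyond).
#' @return list with numeric vectors `lambda_in`, `lambda_out`, `gamma`,
#'   each of length `n_cap + 1`.
#' @export
rate_preset <- function(condition = c("ova", "wt"), n_cap = 25) {
  condition <- match.arg(condition)
  n <- 0:n_cap
  if (condition == "ova") {
    list(lambda_in  = 0.002 * exp(0.25 * pmin(n, 10)),
         lambda_out = rep(0.005, n_cap + 1),
         gamma      = c(0, pmin(1e-4 * exp(0.55 * pmin(n[-1], 12)), 0.5)))
  } else {
    list(lambda_in  = rep(4e-4, n_cap + 1),
         lambda_out = rep(0.02, n_cap + 1),
         gamma      = rep(0, n_cap + 1))
  }
}

#' Motility presets for the fractional-Brownian walker
#'
#' `"gel"` reproduces super-diffusive exploration of the matrix
#' (Hurst `H = 0.8`, MSD exponent `2H = 1.6`); `"spheroid"` reproduces the
#' near-diffusive crawling observed once a CTL reaches the target
#' (`H = 0.55`, exponent `1.1`).  The step scale `sigma` (um per min^H per
#' axis) is calibrated so that the power-law regime spans the 2–60 min MSD
#' fit window within the default droplet geometry: confinement by the
#' droplet walls is then negligible over that window and the fitted
#' exponent recovers `2H`.
#'
#' @param preset `"gel"` or `"spheroid"`.
#' @return list with `hurst` and `sigma`.
#' @export
motility_preset <- function(preset = c("gel", "spheroid")) {
  preset <- match.arg(preset)
  switch(preset,
         gel      = list(hurst = 0.80, sigma = 0.5),
         spheroid = list(hurst = 0.55, sigma = 0.8))
}

#' Full generative specification of a synthetic droplet cohort
#'
#' Geometry is a cylindrical droplet (reflecting walls) holding a single
#' spherical spheroid at its centre.  CTL counts per droplet are Poisson
#' with mean `ctl_mean`, truncated at `ctl_max` (a broad distribution, as
#' droplet loading produces).  Occupancy dynamics follow the state-
#' dependent rate profiles; killing is a per-frame Bernoulli event with
#' probability `gamma(n)`.
#'
#' @param condition `"ova"` or `"wt"`; selects the default rate profiles.
#' @param droplet_radius,droplet_height cylinder radius and height (um).
#'   Defaults 400 and 100 um match a 50 nl droplet in a 100 um chamber.
#' @param spheroid_radius spheroid radius (um), default 40 (observed radii
#'   mostly span 35–45 um).
#' @param contact_margin distance margin for on-spheroid labelling (um),
#'   default 10 (about one T-cell radius).
#' @param lambda_in,lambda_out,gamma rate profiles indexed by occupancy
#'   `n = 0, 1, ...`; default from [rate_preset()].
#' @param ctl_mean,ctl_max Poisson mean (7) and truncation (20) for the
#'   per-droplet CTL count.
#' @param delta_t frame interval, min (default 2).
#' @param duration observation duration, min (default 1440 = 24 h).
#' @param success_cutoff killing-success cutoff, min (default 840 = 14 h).
#' @param bootstrap_reps,bootstrap_fraction defaults for rate
#'   bootstrapping (50 repetitions on 70% subsamples).
#' @param seed master seed for cohort generation.
#' @param motility named list of motility presets (`gel`, `spheroid`).
#' @return a `sim_config` object.
#' @export
sim_config <- function(condition = c("ova", "wt"),
                       droplet_radius = 400, droplet_height = 100,
                       spheroid_radius = 40, contact_margin = 10,
                       lambda_in = NULL, lambda_out = NULL, gamma = NULL,
                       ctl_mean = 7, ctl_max = 20,
                       delta_t = 2, duration = 1440, success_cutoff = 840,
                       bootstrap_reps = 50, bootstrap_fraction = 0.7,
                       seed = 1,
                       motility = list(gel = motility_preset("gel"),
                                       spheroid = motility_preset("spheroid"))) {
  condition <- match.arg(condition)
  preset <- rate_preset(condition)
  if (is.null(lambda_in)) lambda_in <- preset$lambda_in
  if (is.null(lambda_out)) lambda_out <- preset$lambda_out
  if (is.null(gamma)) gamma <- preset$gamma
  if (any(lambda_in < 0) || any(lambda_out < 0))
    stop("rates must be non-negative")
  if (any(gamma < 0 | gamma > 1))
    stop("'gamma' entries must be probabilities in [0, 1]")
  if (spheroid_radius >= droplet_radius)
    stop("'spheroid_radius' must be smaller than 'droplet_radius'")
  for (m in motility)
    if (m$hurst <= 0 || m$hurst >= 1)
      stop("Hurst index must lie strictly in (0, 1)")
  if (delta_t <= 0 || duration <= 0 || success_cutoff <= 0)
    stop("all durations must be positive")
  if (bootstrap_fraction <= 0 || bootstrap_fraction > 1)
    stop("'bootstrap_fraction' must lie in (0, 1]")
  structure(list(condition = condition,
                 droplet_radius = droplet_radius,
                 droplet_height = droplet_height,
                 spheroid_radius = spheroid_radius,
                 contact_margin = contact_margin,
                 lambda_in = lambda_in, lambda_out = lambda_out,
                 gamma = gamma,
                 ctl_mean = ctl_mean, ctl_max = ctl_max,
                 delta_t = delta_t, duration = duration,
                 success_cutoff = success_cutoff,
                 bootstrap_reps = bootstrap_reps,
                 bootstrap_fraction = bootstrap_fraction,
                 seed = seed, motility = motility),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0("<sim_config> condition = %s, droplet r = %g um x h = %g um,",
                     " spheroid r = %g um\n  delta_t = %g min, duration = %g min,",
                     " CTLs ~ Poisson(%g) capped at %d, seed = %d\n"),
              x$condition, x$droplet_radius, x$droplet_height,
              x$spheroid_radius, x$delta_t, x$duration,
              x$ctl_mean, x$ctl_max, x$seed))
  invisible(x)
}

# clamp a rate profile to occupancy n (0-based), extending beyond its range
profile_at <- function(profile, n) {
  profile[pmin(n, length(profile) - 1L) + 1L]
}
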
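# shared fixture builders: everything is generated in code, nothing on disk

# shorthand occupancy series
occ <- function(n_t, t_frag = NA_real_, delta_t = 2, N = max(n_t, 1),
                id = "d1", ...) {
  occupancy_series(droplet_id = id, n_t = n_t, delta_t = delta_t, N = N,
                   t_frag = t_frag, ...)
}

# isotropic Brownian 3D tracks with diffusion coefficient D (um^2/min):
# per-axis increments N(0, sqrt(2 D dt))
brownian_tracks <- function(n_tracks, steps, D = 1, dt = 1) {
  s <- sqrt(2 * D * dt)
  df <- do.call(rbind, lapply(seq_len(n_tracks), function(i) {
    data.frame(droplet_id = "d1", cell_id = sprintf("c%04d", i),
               t_min = (0:steps) * dt,
               x_um = cumsum(c(0, stats::rnorm(steps, 0, s))),
               y_um = cumsum(c(0, stats::rnorm(steps, 0, s))),
               z_um = cumsum(c(0, stats::rnorm(steps, 0, s))))
  }))
  ctl_tracks(df)
}

# straight-line 3D tracks at speed v um/min along a random direction
ballistic_tracks <- function(n_tracks, steps, v = 2, dt = 1) {
  df <- do.call(rbind, lapply(seq_len(n_tracks), function(i) {
    u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
    t <- (0:steps) * dt
    data.frame(droplet_id = "d1", cell_id = sprintf("c%04d", i),
               t_min = t, x_um = v * t * u[1], y_um = v * t * u[2],
               z_um = v * t * u[3])
  }))
  ctl_tracks(df)
}

# free (unconfined) fractional-Brownian tracks, per-axis scale sigma
fbm_tracks <- function(n_tracks, steps, hurst, sigma = 1, dt = 2) {
  df <- do.call(rbind, lapply(seq_len(n_tracks), function(i) {
    data.frame(droplet_id = "d1", cell_id = sprintf("c%04d", i),
               t_min = (0:steps) * dt,
               x_um = cumsum(c(0, rfgn(steps, hurst, sd = sigma * dt^hurst))),
               y_um = cumsum(c(0, rfgn(steps, hurst, sd = sigma * dt^hurst))),
               z_um = cumsum(c(0, rfgn(steps, hurst, sd = sigma * dt^hurst))))
  }))
  ctl_tracks(df)
}

# binomially sampled fragmentation counts from a known gamma(n) curve
frag_counts_from_curve <- function(gamma_at, levels, trials) {
  k_death <- k_exp <- integer(max(levels) + 1)
  for (i in seq_along(levels)) {
    n <- levels[i]
    d <- stats::rbinom(1, trials[i], gamma_at(n))
    k_death[n + 1] <- d
    k_exp[n + 1] <- trials[i] - d
  }
  structure(list(k_death = k_death, k_exposure = k_exp,
                 n_max = max(levels), delta_t = 2),
            class = "frag_counts")
}
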
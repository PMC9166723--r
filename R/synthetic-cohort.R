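#' Simulate 3D CTL migration tracks inside a droplet
#'
#' Each cell performs an isotropic fractional-Brownian walk: per-axis
#' increments are fractional Gaussian noise with the preset Hurst index,
#' scaled by `sigma * delta_t^H`, so the free-space ensemble MSD grows as
#' `3 * sigma^2 * tau^{2H}` and a log-log fit over lags well inside the
#' droplet recovers the exponent `2H`.  Cells start uniformly in the
#' droplet volume outside the spheroid and are reflected at the cylinder
#' walls.
#'
#' @param config a [sim_config()].
#' @param n_cells number of cells (>= 0).
#' @param preset `"gel"` or `"spheroid"` motility preset name.
#' @param duration track duration, min (default `config$duration`).
#' @param droplet_id identifier stamped on the tracks.
#' @param label if `TRUE`, attach per-frame `on_spheroid` labels computed
#'   from the spheroid geometry (spatial contact ground truth).
#' @return a 3D [ctl_tracks()] table.
#' @export
simulate_tracks <- function(config, n_cells, preset = "gel",
                            duration = config$duration, droplet_id = "d1",
                            label = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  if (n_cells < 0) stop("'n_cells' must be non-negative")
  mot <- config$motility[[match.arg(preset, names(config$motility))]]
  if (mot$hurst <= 0 || mot$hurst >= 1) stop("Hurst index outside (0, 1)")
  dt <- config$delta_t
  steps <- floor(duration / dt)
  t_min <- (0:steps) * dt
  if (n_cells == 0) {
    empty <- data.frame(droplet_id = character(), cell_id = character(),
                        t_min = numeric(), x_um = numeric(),
                        y_um = numeric(), z_um = numeric())
    if (label) empty$on_spheroid <- logical(0)
    return(ctl_tracks(empty, delta_t = dt))
  }

  R <- config$droplet_radius; H <- config$droplet_height
  rs <- config$spheroid_radius
  ctr <- c(0, 0, H / 2)                       # spheroid centre

  start <- matrix(NA_real_, n_cells, 3)
  got <- 0L
  while (got < n_cells) {                     # uniform in cylinder \ spheroid
    need <- n_cells - got
    u <- sqrt(stats::runif(2 * need)) * R
    th <- stats::runif(2 * need, 0, 2 * pi)
    cand <- cbind(u * cos(th), u * sin(th), stats::runif(2 * need, 0, H))
    d2 <- (cand[, 1] - ctr[1])^2 + (cand[, 2] - ctr[2])^2 + (cand[, 3] - ctr[3])^2
    cand <- cand[d2 > rs^2, , drop = FALSE]
    take <- min(nrow(cand), need)
    if (take > 0) {
      start[(got + 1):(got + take), ] <- cand[seq_len(take), , drop = FALSE]
      got <- got + take
    }
  }

  scl <- mot$sigma * dt^mot$hurst
  inc <- array(0, dim = c(steps, n_cells, 3))
  if (scl > 0 && steps > 0)
    for (ax in 1:3)
      inc[, , ax] <- vapply(seq_len(n_cells),
                            function(i) rfgn(steps, mot$hurst, sd = scl),
                            numeric(steps))

  pos <- array(NA_real_, dim = c(steps + 1, n_cells, 3))
  pos[1, , ] <- start
  cur <- start
  for (s in seq_len(steps)) {
    cur <- cur + inc[s, , , drop = TRUE]
    if (n_cells == 1) cur <- matrix(cur, 1, 3)
    # reflect z into [0, H] (triangle fold handles large excursions)
    z <- cur[, 3] %% (2 * H)
    cur[, 3] <- H - abs(z - H)
    # reflect radially at the cylinder wall
    r <- sqrt(cur[, 1]^2 + cur[, 2]^2)
    out <- which(r > R)
    if (length(out)) {
      f <- (2 * R - r[out]) / r[out]
      f[f < 0] <- 0                            # pathological overshoot: clamp
      cur[out, 1] <- cur[out, 1] * f
      cur[out, 2] <- cur[out, 2] * f
    }
    pos[s + 1, , ] <- cur
  }

  df <- data.frame(
    droplet_id = droplet_id,
    cell_id = rep(sprintf("c%03d", seq_len(n_cells)), each = steps + 1),
    t_min = rep(t_min, times = n_cells),
    x_um = as.vector(pos[, , 1]),
    y_um = as.vector(pos[, , 2]),
    z_um = as.vector(pos[, , 3]),
    stringsAsFactors = FALSE)
  if (label) {
    d <- sqrt((df$x_um - ctr[1])^2 + (df$y_um - ctr[2])^2 + (df$z_um - ctr[3])^2)
    df$on_spheroid <- d <= rs + config$contact_margin
  }
  ctl_tracks(df, delta_t = dt)
}

#' Project 3D tracks onto the imaging plane
#'
#' Drops the axial coordinate, mimicking single-plane imaging of cells
#' moving in 3D.  The result is flagged as 2D-projected; 3D-only
#' statistics refuse it and [correct_projection()] converts its summary
#' statistics back to 3D estimates under isotropy.
#'
#' @param tracks a 3D `ctl_tracks` table.
#' @return a 2D-projected `ctl_tracks` table.
#' @export
project_tracks_2d <- function(tracks) {
  stopifnot(inherits(tracks, "ctl_tracks"))
  if (is_projected(tracks))
    stop("tracks are already 2D-projected; refusing to project twice")
  df <- as.data.frame(tracks)
  df$z_um <- NULL
  ctl_tracks(df, delta_t = attr(tracks, "delta_t"))
}

# shared discrete-time engine: one step = (fragmentation check on the
# starting occupancy) -> (aggregated detach draw) -> (aggregated attach
# draw); at most one occupancy event per step, matching the one-event-per-
# frame observation model.
sim_chain <- function(lambda_in, lambda_out, gamma, N, steps, delta_t,
                      n0 = 0L) {
  n_t <- integer(steps + 1)
  n <- as.integer(n0)
  frag_frame <- NA_integer_
  for (s in 0:steps) {
    n_t[s + 1] <- n
    g <- profile_at(gamma, n)
    if (g > 1) stop("fragmentation probability per frame exceeds 1; ",
                    "time step too coarse")
    if (g > 0 && stats::runif(1) < g) { frag_frame <- s; break }
    if (s == steps) break
    p_out <- 1 - exp(-n * profile_at(lambda_out, n) * delta_t)
    if (n > 0 && stats::runif(1) < p_out) {
      n <- n - 1L
    } else {
      p_in <- 1 - exp(-(N - n) * profile_at(lambda_in, n) * delta_t)
      if (n < N && stats::runif(1) < p_in) n <- n + 1L
    }
  }
  last <- if (is.na(frag_frame)) steps else frag_frame
  list(n_t = n_t[seq_len(last + 1)], frag_frame = frag_frame)
}

#' Simulate one spheroid occupancy series
#'
#' Runs the discrete-time occupancy chain at interval `delta_t`: per step,
#' a fragmentation Bernoulli with probability `gamma(n)` (per frame, using
#' the step's starting occupancy), then an aggregated detach draw with
#' probability `1 - exp(-n lambda_out(n) dt)`, else an aggregated attach
#' draw with probability `1 - exp(-(N - n) lambda_in(n) dt)`.  The series
#' is censored at `duration` if no fragmentation occurred.
#'
#' @param config a [sim_config()] providing the rate profiles.
#' @param N total CTLs in the droplet (>= 0).
#' @param droplet_id identifier.
#' @param n0 starting occupancy.
#' @return an [occupancy_series()].
#' @export
simulate_occupancy <- function(config, N, droplet_id = "d1", n0 = 0L) {
  stopifnot(inherits(config, "sim_config"))
  if (N < 0) stop("'N' must be non-negative")
  steps <- floor(config$duration / config$delta_t)
  run <- sim_chain(config$lambda_in, config$lambda_out, config$gamma,
                   as.integer(N), steps, config$delta_t, n0 = n0)
  occupancy_series(droplet_id = droplet_id, n_t = run$n_t,
                   delta_t = config$delta_t, N = N,
                   t_frag = if (is.na(run$frag_frame)) NA_real_
                            else run$frag_frame * config$delta_t,
                   duration = config$duration,
                   condition = config$condition)
}

#' Generate a full synthetic cohort
#'
#' Draws a CTL count `N` per droplet from the truncated-Poisson loading
#' law and simulates each droplet's occupancy series independently, with
#' per-droplet RNG sub-streams derived from the master seed (so the cohort
#' is reproducible and droplets are independent replicates).  In spatial
#' mode, 3D migration tracks are simulated as well and the occupancy
#' series is derived from their geometric contact labels (no fragmentation
#' dynamics), which exercises the contact-labelling stage against a known
#' truth.
#'
#' @param config a [sim_config()].
#' @param n_droplets number of droplets (>= 1).
#' @param spatial if `TRUE`, generate labelled tracks and derive occupancy
#'   geometrically.
#' @param seed master seed (default `config$seed`).
#' @return a [ctl_cohort()] with the generative `config` attached as truth.
#' @export
generate_cohort <- function(config, n_droplets, spatial = FALSE,
                            seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  if (n_droplets < 1) stop("'n_droplets' must be >= 1")
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, n_droplets)
  Ns <- draw_ctl_counts(n_droplets, config$ctl_mean, config$ctl_max)
  ids <- sprintf("d%04d", seq_len(n_droplets))
  series <- vector("list", n_droplets)
  all_tracks <- if (spatial) vector("list", n_droplets) else NULL
  for (i in seq_len(n_droplets)) {
    set.seed(sub_seeds[i])
    if (spatial) {
      tr <- simulate_tracks(config, Ns[i], preset = "gel",
                            droplet_id = ids[i], label = TRUE)
      series[[i]] <- occupancy_from_labels(tr, ids[i], config, Ns[i])
      all_tracks[[i]] <- as.data.frame(tr)
    } else {
      series[[i]] <- simulate_occupancy(config, Ns[i], droplet_id = ids[i])
    }
  }
  tracks <- if (spatial)
    ctl_tracks(do.call(rbind, all_tracks), delta_t = config$delta_t)
  else NULL
  ctl_cohort(series, tracks = tracks, truth = config)
}

draw_ctl_counts <- function(n, mean, cap) {
  x <- stats::rpois(n, mean)
  while (any(x > cap)) x[x > cap] <- stats::rpois(sum(x > cap), mean)
  x
}

occupancy_from_labels <- function(tracks, droplet_id, config, N) {
  df <- as.data.frame(tracks)
  if (N == 0 || nrow(df) == 0) {
    n_t <- rep(0L, floor(config$duration / config$delta_t) + 1)
  } else {
    n_t <- tapply(df$on_spheroid, df$t_min, sum)
    n_t <- as.integer(n_t[order(as.numeric(names(n_t)))])
  }
  occupancy_series(droplet_id = droplet_id, n_t = n_t,
                   delta_t = config$delta_t, N = N, t_frag = NA_real_,
                   duration = (length(n_t) - 1) * config$delta_t,
                   condition = config$condition)
}
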
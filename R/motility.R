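#' Time-and-ensemble-averaged mean-squared displacement
#'
#' For each track the MSD at lag `tau` is averaged over all overlapping
#' windows; the curve is then the ensemble mean across tracks, with the
#' SEM across tracks attached per lag.  Tracks of mixed dimensionality
#' (2D-projected vs 3D) are never pooled: the table's projection flag
#' decides which coordinates enter.
#'
#' @param tracks a `ctl_tracks` table.
#' @param max_lag largest lag, min (truncated with a warning beyond half
#'   the shortest track).
#' @return an `msd_curve` object: lags (min), msd (um^2), sem, number of
#'   tracks, dimensionality.
#' @export
compute_msd <- function(tracks, max_lag = 60) {
  stopifnot(inherits(tracks, "ctl_tracks"))
  if (nrow(tracks) == 0) stop("empty track table")
  dt <- attr(tracks, "delta_t")
  dim3 <- !is_projected(tracks)
  cols <- if (dim3) c("x_um", "y_um", "z_um") else c("x_um", "y_um")
  df <- as.data.frame(tracks)
  key <- interaction(df$droplet_id, df$cell_id, drop = TRUE)
  paths <- split(df[cols], key)
  paths <- paths[vapply(paths, nrow, integer(1)) >= 2]
  if (!length(paths)) stop("no track has at least two frames")
  shortest <- min(vapply(paths, nrow, integer(1))) - 1L
  max_frames <- floor(max_lag / dt)
  if (max_frames > shortest %/% 2) {
    max_frames <- max(1L, shortest %/% 2)
    warning("max_lag exceeds half the shortest track; truncated to ",
            max_frames * dt, " min")
  }
  lags <- seq_len(max_frames)
  per_track <- vapply(paths, function(p) {
    m <- as.matrix(p)
    vapply(lags, function(L) {
      d <- m[-seq_len(L), , drop = FALSE] - m[seq_len(nrow(m) - L), , drop = FALSE]
      mean(rowSums(d^2))
    }, numeric(1))
  }, numeric(length(lags)))
  per_track <- matrix(per_track, nrow = length(lags))
  msd <- rowMeans(per_track)
  sem <- apply(per_track, 1, stats::sd) / sqrt(ncol(per_track))
  structure(list(lags = lags * dt, msd = msd, sem = sem,
                 n_tracks = ncol(per_track), dim = if (dim3) 3L else 2L,
                 delta_t = dt),
            class = "msd_curve")
}

#' @export
print.msd_curve <- function(x, ...) {
  cat(sprintf("<msd_curve> %dD, %d tracks, lags %g-%g min%s\n",
              x$dim, x$n_tracks, min(x$lags), max(x$lags),
              if (is.null(x$alpha)) ""
              else sprintf(", alpha = %.3f (se %.3f)", x$alpha, x$alpha_se)))
  invisible(x)
}

#' @export
plot.msd_curve <- function(x, ...) {
  graphics::plot(x$lags, x$msd, log = "xy", xlab = "lag (min)",
                 ylab = expression(MSD ~ (mu * m^2)), pch = 16, ...)
  if (!is.null(x$alpha)) {
    sel <- x$lags >= x$fit_range[1] & x$lags <= x$fit_range[2]
    graphics::lines(x$lags[sel],
                    exp(x$fit_intercept + x$alpha * log(x$lags[sel])),
                    col = 2, lwd = 2)
  }
  invisible(x)
}

#' Fit the MSD power-law exponent
#'
#' Least-squares slope of `log(msd)` against `log(tau)` over the fit
#' range.  An exponent above 1 indicates super-diffusive migration.
#'
#' @param curve an `msd_curve`.
#' @param fit_range lag window (min), default 2–60.
#' @return the `msd_curve` with `alpha`, `alpha_se`, `fit_range` filled in.
#' @export
fit_msd_exponent <- function(curve, fit_range = c(2, 60)) {
  stopifnot(inherits(curve, "msd_curve"))
  sel <- curve$lags >= fit_range[1] & curve$lags <= fit_range[2] &
    is.finite(curve$msd) & curve$msd > 0
  if (sum(sel) < 4)
    stop("need at least 4 lags with positive MSD in the fit range")
  fit <- stats::lm(log(curve$msd[sel]) ~ log(curve$lags[sel]))
  curve$alpha <- unname(stats::coef(fit)[2])
  # exact power-law input yields a perfect fit; the SE is then 0
  curve$alpha_se <- suppressWarnings(summary(fit)$coefficients[2, 2])
  curve$fit_intercept <- unname(stats::coef(fit)[1])
  curve$fit_range <- fit_range
  # diffusion coefficient under the 3D convention MSD = 6 D tau; for
  # 2D-projected tracks of 3D motion this yields the apparent D_p = 2/3 D
  slope <- sum(curve$msd[sel] * curve$lags[sel]) / sum(curve$lags[sel]^2)
  curve$diffusion_coeff <- slope / 6
  curve
}

#' Empirical distribution of single-step displacement magnitudes
#'
#' @param tracks a `ctl_tracks` table.
#' @param lag lag time, min; must be a multiple of the frame interval.
#' @param breaks histogram breaks (passed to [graphics::hist()]).
#' @return list with the pooled displacement magnitudes `dr` (um), the
#'   histogram, and the sample count.
#' @export
displacement_distribution <- function(tracks, lag, breaks = "FD") {
  stopifnot(inherits(tracks, "ctl_tracks"))
  dt <- attr(tracks, "delta_t")
  k <- lag / dt
  if (abs(k - round(k)) > 1e-9)
    stop("'lag' must be a multiple of the frame interval (", dt, " min)")
  k <- as.integer(round(k))
  dr <- displacement_magnitudes(tracks, k)
  h <- graphics::hist(dr, breaks = breaks, plot = FALSE)
  list(dr = dr, histogram = h, n = length(dr), lag = lag)
}

displacement_magnitudes <- function(tracks, k) {
  cols <- if (is_projected(tracks)) c("x_um", "y_um") else c("x_um", "y_um", "z_um")
  df <- as.data.frame(tracks)
  key <- interaction(df$droplet_id, df$cell_id, drop = TRUE)
  unlist(lapply(split(df[cols], key), function(p) {
    m <- as.matrix(p)
    if (nrow(m) <= k) return(numeric(0))
    d <- m[-seq_len(k), , drop = FALSE] - m[seq_len(nrow(m) - k), , drop = FALSE]
    sqrt(rowSums(d^2))
  }), use.names = FALSE)
}

#' Scaling of the distance travelled with lag time
#'
#' Fits a power law to the mean displacement magnitude versus lag,
#' `<|dr(tau)|> ~ tau^b`.  For random (non-ballistic) motion `b < 1`, so
#' the apparent mean velocity `<|dr|>/tau ~ tau^{b-1}` decreases with the
#' sampling interval — the reason measured cell speeds depend on the
#' imaging frame rate.
#'
#' @param tracks a `ctl_tracks` table.
#' @param lags lag times (min), at least 4, multiples of the frame
#'   interval.
#' @return list with `displacement_exponent`, its standard error, the
#'   implied `velocity_exponent` (`displacement_exponent - 1`), and the
#'   mean displacement per lag.
#' @export
velocity_lag_scaling <- function(tracks, lags) {
  if (length(lags) < 4) stop("need at least 4 lags")
  dt <- attr(tracks, "delta_t")
  mean_dr <- vapply(lags, function(L) {
    k <- L / dt
    if (abs(k - round(k)) > 1e-9)
      stop("every lag must be a multiple of the frame interval")
    mean(displacement_magnitudes(tracks, as.integer(round(k))))
  }, numeric(1))
  ok <- is.finite(mean_dr) & mean_dr > 0
  if (sum(ok) < 4) stop("need at least 4 lags with positive mean displacement")
  fit <- stats::lm(log(mean_dr[ok]) ~ log(lags[ok]))
  b <- unname(stats::coef(fit)[2])
  list(displacement_exponent = b,
       se = suppressWarnings(summary(fit)$coefficients[2, 2]),
       velocity_exponent = b - 1,
       lags = lags, mean_dr = mean_dr)
}

#' Convert a planar measurement of isotropic 3D motion to a 3D estimate
#'
#' Under isotropy the in-plane projection of a 3D displacement carries
#' 2/3 of the squared magnitude, so projected MSD and diffusion
#' coefficients are scaled by 3/2 and mean displacements / speeds by
#' sqrt(3/2).
#'
#' @param stat_2d scalar statistic measured on 2D-projected tracks, or an
#'   `msd_curve` computed from them.
#' @param kind one of `"mean_speed"`, `"msd"`, `"diffusion"` (ignored for
#'   `msd_curve` input).
#' @return corrected 3D-scale statistic (same shape as the input).
#' @export
correct_projection <- function(stat_2d,
                               kind = c("mean_speed", "msd", "diffusion")) {
  if (inherits(stat_2d, "msd_curve")) {
    if (stat_2d$dim == 3)
      stop("curve was computed from 3D tracks; no correction needed")
    stat_2d$msd <- stat_2d$msd * 3 / 2
    stat_2d$sem <- stat_2d$sem * 3 / 2
    if (!is.null(stat_2d$diffusion_coeff))
      stat_2d$diffusion_coeff <- stat_2d$diffusion_coeff * 3 / 2
    stat_2d$dim <- 3L
    return(stat_2d)
  }
  kind <- match.arg(kind)
  factor <- switch(kind, mean_speed = sqrt(3 / 2), msd = 3 / 2,
                   diffusion = 3 / 2)
  stat_2d * factor
}

#' Monte-Carlo null distribution of first CTL–spheroid contact times
#'
#' Simulates independent walkers with the gel motility preset, seeded
#' uniformly in the droplet outside the spheroid, and records the first
#' time each comes within the contact radius of the spheroid surface
#' (absorbing).  This is the no-attraction null: observed first-contact
#' times compatible with it indicate that initial contact is a pure
#' random-search event.
#'
#' @param config a [sim_config()].
#' @param n_walkers number of walkers (>= 1).
#' @param max_duration simulation cap, min.
#' @return list with `times` (absorbed walkers, min), `n_censored`, and
#'   the cap.  Errors if no walker reaches the spheroid before the cap.
#' @export
first_contact_null <- function(config, n_walkers,
                               max_duration = config$duration) {
  stopifnot(inherits(config, "sim_config"))
  tr <- simulate_tracks(config, n_walkers, preset = "gel",
                        duration = max_duration, label = TRUE)
  df <- as.data.frame(tr)
  key <- interaction(df$droplet_id, df$cell_id, drop = TRUE)
  hit <- tapply(seq_len(nrow(df)), key, function(ix) {
    w <- which(df$on_spheroid[ix])
    if (length(w)) df$t_min[ix[w[1]]] else NA_real_
  })
  times <- unname(hit[!is.na(hit)])
  if (!length(times))
    stop("no walker reached the spheroid within ", max_duration, " min")
  list(times = times, n_censored = sum(is.na(hit)),
       max_duration = max_duration)
}

#' Goodness of fit of observed first-contact times to the random-search null
#'
#' Two-sample Kolmogorov–Smirnov test of the observed first-contact times
#' against Monte-Carlo samples from [first_contact_null()].
#'
#' @param observed observed first-contact times (min).
#' @param null_samples Monte-Carlo null samples (>= 1000 recommended).
#' @return `htest` object from [stats::ks.test()].
#' @export
first_contact_test <- function(observed, null_samples) {
  if (is.list(null_samples)) null_samples <- null_samples$times
  stats::ks.test(observed, null_samples)
}
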
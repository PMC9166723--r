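#' Extract a clamped rate vector from an estimated profile
#'
#' Simulators need a rate for every occupancy `0..n_cap`.  Estimated
#' profiles have missing rows (levels never observed) and stop at the
#' largest observed occupancy; consumed by a simulator they are completed
#' by carrying the last defined value forward (and the first defined
#' value backward), with the clamped range recorded in the `clamped`
#' attribute.
#'
#' @param profile a `rate_profile` or `frag_profile` (or a bare numeric
#'   vector, returned extended as-is).
#' @param what column to extract (`"lambda_in"`, `"lambda_out"` or
#'   `"gamma"`).
#' @param n_cap highest occupancy needed.
#' @return numeric vector of length `n_cap + 1` with a `clamped`
#'   attribute listing filled-in occupancy levels.
#' @export
profile_vector <- function(profile, what, n_cap) {
  if (is.numeric(profile)) {
    v <- profile_at(profile, 0:n_cap)
    attr(v, "clamped") <- if (n_cap + 1 > length(profile))
      length(profile):n_cap else integer(0)
    return(v)
  }
  stopifnot(is.data.frame(profile), what %in% names(profile))
  v <- rep(NA_real_, n_cap + 1)
  v[profile$n + 1] <- profile[[what]]
  v[is.infinite(v)] <- NA_real_              # censored-infinite rows
  filled <- which(is.na(v))
  ok <- which(!is.na(v))
  if (!length(ok)) stop("profile '", what, "' has no defined rows")
  for (i in seq_along(v)) {
    if (is.na(v[i])) {
      prev <- ok[ok < i]
      v[i] <- if (length(prev)) v[max(prev)] else v[min(ok)]
    }
  }
  attr(v, "clamped") <- filled - 1L
  v
}

#' Simulate one spheroid-fate replicate
#'
#' Runs the two-step branching process: at every frame the spheroid
#' fragments with probability `gamma(n)` (start-of-step occupancy), else
#' one CTL may detach (probability `1 - exp(-n lambda_out(n) dt)`) or
#' attach (probability `1 - exp(-(N - n) lambda_in(n) dt)`), iterated
#' until fragmentation or the end of the experiment.
#'
#' @param rate_profile a `rate_profile` (or list with numeric `lambda_in`
#'   and `lambda_out` vectors).
#' @param frag_profile a `frag_profile` (or numeric `gamma` vector, per
#'   frame).
#' @param N total CTLs in the droplet.
#' @param duration experiment duration, min.
#' @param delta_t frame interval, min.
#' @param n0 starting occupancy.
#' @param droplet_id identifier for the returned series.
#' @return an [occupancy_series()] (censored `t_frag` if the spheroid
#'   survived).
#' @export
simulate_fate <- function(rate_profile, frag_profile, N, duration,
                          delta_t = 2, n0 = 0L, droplet_id = "sim") {
  if (N < 0) stop("'N' must be non-negative")
  lam_in <- as_lambda(rate_profile, "lambda_in", N)
  lam_out <- as_lambda(rate_profile, "lambda_out", N)
  gam <- as_gamma(frag_profile, N)
  steps <- floor(duration / delta_t)
  run <- sim_chain(lam_in, lam_out, gam, as.integer(N), steps, delta_t,
                   n0 = n0)
  occupancy_series(droplet_id = droplet_id, n_t = run$n_t,
                   delta_t = delta_t, N = N,
                   t_frag = if (is.na(run$frag_frame)) NA_real_
                            else run$frag_frame * delta_t,
                   duration = duration, condition = "simulated")
}

as_lambda <- function(profile, what, N) {
  if (is.list(profile) && !is.data.frame(profile) && !is.null(profile[[what]]))
    profile_vector(profile[[what]], what, N)
  else profile_vector(profile, what, N)
}

as_gamma <- function(profile, N) {
  g <- if (is.numeric(profile)) profile_vector(profile, "gamma", N)
  else profile_vector(profile, "gamma", N)
  if (any(g < 0 | g > 1, na.rm = TRUE))
    stop("fragmentation probabilities must lie in [0, 1]")
  g
}

#' Sweep spheroid fate across droplet CTL numbers
#'
#' Repeats [simulate_fate()] `reps_per_N` times for every CTL count in
#' `N_range` and summarizes the fragmentation probability (with 95%
#' binomial confidence intervals) and the first-fragmentation time (mean
#' and 95% interval over fragmented replicates) as functions of `N`.
#'
#' @param rate_profile,frag_profile profiles as in [simulate_fate()].
#' @param N_range CTL counts to sweep (default 0:20).
#' @param reps_per_N replicates per count (default 50).
#' @param duration,delta_t experiment duration and frame interval (min).
#' @param cutoff success cutoff for the probability summaries (min,
#'   default `duration`).
#' @param seed RNG seed.
#' @return a `fate_sweep` object: the summary data.frame and all
#'   replicate outcomes.
#' @export
sweep_cohort <- function(rate_profile, frag_profile, N_range = 0:20,
                         reps_per_N = 50, duration = 840, delta_t = 2,
                         cutoff = duration, seed = 1) {
  if (reps_per_N < 2) warning("fewer than 2 replicates per N: no intervals")
  set.seed(seed)
  out <- vector("list", length(N_range))
  reps <- list()
  for (i in seq_along(N_range)) {
    N <- N_range[i]
    tf <- vapply(seq_len(reps_per_N), function(r) {
      s <- simulate_fate(rate_profile, frag_profile, N, duration, delta_t,
                         droplet_id = sprintf("N%02d_r%03d", N, r))
      reps[[length(reps) + 1L]] <<- s
      if (is.na(s$t_frag)) NA_real_ else s$t_frag
    }, numeric(1))
    k <- sum(!is.na(tf) & tf < cutoff)
    ci <- if (reps_per_N >= 2)
      stats::binom.test(k, reps_per_N)$conf.int else c(NA_real_, NA_real_)
    frag_times <- tf[!is.na(tf)]
    out[[i]] <- data.frame(
      N = N, reps = reps_per_N, p_frag = k / reps_per_N,
      p_lo = ci[1], p_hi = ci[2],
      n_frag = length(frag_times),
      t_frag_mean = if (length(frag_times)) mean(frag_times) else NA_real_,
      t_frag_lo = if (length(frag_times) >= 2)
        unname(stats::quantile(frag_times, 0.025)) else NA_real_,
      t_frag_hi = if (length(frag_times) >= 2)
        unname(stats::quantile(frag_times, 0.975)) else NA_real_)
  }
  structure(list(summary = do.call(rbind, out), replicates = reps,
                 duration = duration, delta_t = delta_t, cutoff = cutoff,
                 seed = seed),
            class = "fate_sweep")
}

#' @export
print.fate_sweep <- function(x, ...) {
  cat(sprintf("<fate_sweep> N = %d..%d, %d reps each, duration %g min (cutoff %g)\n",
              min(x$summary$N), max(x$summary$N), x$summary$reps[1],
              x$duration, x$cutoff))
  print.data.frame(x$summary[, c("N", "p_frag", "p_lo", "p_hi",
                                 "t_frag_mean")],
                   row.names = FALSE, digits = 3)
  invisible(x)
}

#' @export
plot.fate_sweep <- function(x, ...) {
  s <- x$summary
  graphics::plot(s$N, s$p_frag, type = "b", pch = 16, ylim = c(0, 1),
                 xlab = "CTLs in droplet (N)",
                 ylab = "fragmentation probability", ...)
  graphics::polygon(c(s$N, rev(s$N)), c(s$p_lo, rev(s$p_hi)),
                    col = grDevices::adjustcolor("steelblue", 0.3),
                    border = NA)
  invisible(x)
}

#' Fraction of spheroids killed before a cutoff
#'
#' "Successful killing" is a first fragmentation event before the cutoff
#' (default 840 min = 14 h).  Censored droplets count as failures.
#'
#' @param cohort a `ctl_cohort` or list of `occupancy_series`.
#' @param cutoff minutes (must not exceed the shortest observation).
#' @return list with `rate`, binomial `sem`, and counts.
#' @export
success_rate <- function(cohort, cutoff = 840) {
  series <- if (inherits(cohort, "ctl_cohort")) cohort$occupancy else cohort
  if (!length(series)) stop("empty occupancy pool")
  durations <- vapply(series, function(s) s$duration, numeric(1))
  if (cutoff > min(durations))
    stop("cutoff exceeds the shortest observation duration (",
         min(durations), " min)")
  hit <- vapply(series, function(s) !is.na(s$t_frag) && s$t_frag < cutoff,
                logical(1))
  p <- mean(hit)
  list(rate = p, sem = sqrt(p * (1 - p) / length(hit)),
       n_success = sum(hit), n = length(hit), cutoff = cutoff)
}

#' Empirical fragmentation probability versus droplet CTL count
#'
#' Groups a cohort by its per-droplet CTL count `N` and reports the
#' fraction killed before the cutoff with 95% binomial confidence
#' intervals — the empirical curve that a fate sweep run with the
#' cohort's estimated profiles should reproduce.
#'
#' @param cohort a `ctl_cohort` or list of `occupancy_series`.
#' @param cutoff success cutoff, min.
#' @return data.frame: `N`, droplet count, `p_frag`, binomial `p_lo`,
#'   `p_hi`.
#' @export
fragmentation_by_count <- function(cohort, cutoff = 840) {
  series <- if (inherits(cohort, "ctl_cohort")) cohort$occupancy else cohort
  N <- vapply(series, function(s) s$N, integer(1))
  hit <- vapply(series, function(s) !is.na(s$t_frag) && s$t_frag < cutoff,
                logical(1))
  rows <- lapply(sort(unique(N)), function(Ni) {
    k <- sum(hit[N == Ni]); m <- sum(N == Ni)
    ci <- stats::binom.test(k, m)$conf.int
    data.frame(N = Ni, droplets = m, p_frag = k / m,
               p_lo = ci[1], p_hi = ci[2])
  })
  do.call(rbind, rows)
}
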
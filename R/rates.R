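#' Label track frames as on or off the spheroid
#'
#' A CTL is "on" the spheroid when its distance to the spheroid centre is
#' at most `spheroid_radius + margin`.  The margin (default 10 um, about
#' one T-cell radius) stands in for the image-mask contact definition of
#' segmentation pipelines.
#'
#' @param tracks a `ctl_tracks` table (2D or 3D).
#' @param spheroid_radius spheroid radius (um).
#' @param margin contact margin (um).
#' @param center spheroid centre coordinates; length 3 for 3D tracks,
#'   length 2 (or the first two entries) for projected tracks.
#' @return the tracks with an `on_spheroid` column.
#' @export
label_contacts <- function(tracks, spheroid_radius, margin = 10,
                           center = c(0, 0, 0)) {
  stopifnot(inherits(tracks, "ctl_tracks"))
  if (missing(spheroid_radius) || is.null(spheroid_radius) ||
      !is.finite(spheroid_radius))
    stop("spheroid geometry (radius) is required")
  df <- as.data.frame(tracks)
  if (is_projected(tracks)) {
    d <- sqrt((df$x_um - center[1])^2 + (df$y_um - center[2])^2)
  } else {
    if (length(center) < 3) stop("3D tracks need a length-3 centre")
    d <- sqrt((df$x_um - center[1])^2 + (df$y_um - center[2])^2 +
                (df$z_um - center[3])^2)
  }
  df$on_spheroid <- d <= spheroid_radius + margin
  ctl_tracks(df, delta_t = attr(tracks, "delta_t"))
}

#' Build occupancy series from contact-labelled tracks
#'
#' Counts labelled cells per frame and droplet.  Frames where the count
#' jumps by more than one violate the single-event observation model;
#' they are reported, and droplets whose fraction of such frames exceeds
#' `max_multi_event` are excluded (the offending frame pairs are later
#' dropped from transition counting, never split).
#'
#' @param tracks a `ctl_tracks` table with `on_spheroid` labels, or a
#'   `ctl_cohort` (returned unchanged).
#' @param max_multi_event exclusion threshold on the fraction of
#'   multi-event frame pairs per droplet.
#' @param condition label stamped on the series.
#' @return a [ctl_cohort()]; its `validation` attribute holds the
#'   per-droplet report.
#' @export
build_occupancy <- function(tracks, max_multi_event = 0.05,
                            condition = "ova") {
  if (inherits(tracks, "ctl_cohort")) return(tracks)
  stopifnot(inherits(tracks, "ctl_tracks"))
  df <- as.data.frame(tracks)
  if (is.null(df$on_spheroid)) stop("tracks carry no 'on_spheroid' labels")
  dt <- attr(tracks, "delta_t")
  series <- lapply(split(df, df$droplet_id), function(d) {
    N <- length(unique(d$cell_id))
    n_t <- tapply(d$on_spheroid, d$t_min, sum)
    n_t <- as.integer(n_t[order(as.numeric(names(n_t)))])
    occupancy_series(droplet_id = d$droplet_id[1], n_t = n_t, delta_t = dt,
                     N = N, duration = (length(n_t) - 1) * dt,
                     condition = condition)
  })
  report <- validate_cohort(unname(series))
  report$excluded <- report$multi_event / pmax(report$frames - 1, 1) >
    max_multi_event
  keep <- unname(series)[!report$excluded]
  out <- ctl_cohort(keep)
  attr(out, "validation") <- report
  out
}

#' Count occupancy transitions pooled across droplets
#'
#' Tallies `a[k, l]`, the number of observed frame-to-frame transitions
#' from `k` to `l` CTLs on the spheroid.  Frame pairs violating the
#' single-event assumption (`|l - k| > 1`) are dropped and counted in the
#' report; frames after the first fragmentation are excluded when
#' `pre_frag_only` (the killing process is modelled as independent of
#' attachment/detachment).  Per-droplet exposure (frames at each
#' occupancy, with that droplet's total CTL count) is retained for the
#' per-cell rate normalization.
#'
#' @param cohort a `ctl_cohort` or list of `occupancy_series`.
#' @param pre_frag_only exclude frames after the first fragmentation
#'   (default `TRUE`).
#' @return a `transition_counts` object.
#' @export
count_transitions <- function(cohort, pre_frag_only = TRUE) {
  series <- if (inherits(cohort, "ctl_cohort")) cohort$occupancy else cohort
  if (!length(series)) stop("empty occupancy pool")
  n_max <- max(vapply(series, function(s) max(s$n_t, 0L, na.rm = TRUE),
                      integer(1)))
  K <- n_max + 1L
  a <- matrix(0L, K, K, dimnames = list(0:n_max, 0:n_max))
  per <- list()
  dropped_multi <- 0L
  dt <- series[[1]]$delta_t
  for (s in series) {
    n_t <- s$n_t
    if (pre_frag_only && !is.na(s$t_frag)) {
      last <- floor(s$t_frag / s$delta_t) + 1L
      n_t <- n_t[seq_len(min(last, length(n_t)))]
    }
    if (length(n_t) < 2) next
    from <- n_t[-length(n_t)]
    to <- n_t[-1]
    ok <- !is.na(from) & !is.na(to)
    multi <- ok & abs(to - from) > 1
    dropped_multi <- dropped_multi + sum(multi)
    ok <- ok & !multi
    from <- from[ok]; to <- to[ok]
    if (length(from)) {
      lin <- from + to * K + 1L            # column-major cell index
      a[] <- a + tabulate(lin, nbins = K * K)
    }
    frames <- tabulate(from + 1L, nbins = K)
    att <- tabulate(from[to == from + 1L] + 1L, nbins = K)
    det <- tabulate(from[to == from - 1L] + 1L, nbins = K)
    per[[length(per) + 1L]] <- data.frame(
      droplet_id = s$droplet_id, n = 0:n_max, frames = frames,
      att = att, det = det, N = s$N, stringsAsFactors = FALSE)
  }
  structure(list(a = a, frames_at = rowSums(a),
                 per_droplet = do.call(rbind, per),
                 dropped_multi_event = dropped_multi,
                 delta_t = dt, n_max = n_max),
            class = "transition_counts")
}

#' @export
print.transition_counts <- function(x, ...) {
  cat(sprintf("<transition_counts> occupancy 0-%d, %d transitions (%d multi-event pairs dropped)\n",
              x$n_max, sum(x$a), x$dropped_multi_event))
  invisible(x)
}

#' Maximum-likelihood transition probabilities of the occupancy chain
#'
#' The ML estimate of the per-frame transition matrix is the observed
#' fraction `p[k, l] = a[k, l] / sum_j a[k, j]`.  Rows with no exposure
#' are `NA` ("missing", never zero).  The per-minute rate matrix
#' `q = p / delta_t` is attached.
#'
#' @param counts a `transition_counts` object.
#' @return a `transition_estimate` with matrices `p` and `q`.
#' @export
estimate_transition_probabilities <- function(counts) {
  stopifnot(inherits(counts, "transition_counts"))
  tot <- rowSums(counts$a)
  p <- counts$a / ifelse(tot > 0, tot, NA_real_)
  q <- p / counts$delta_t
  diag(q) <- NA_real_
  structure(list(p = p, q = q, exposure = tot, delta_t = counts$delta_t),
            class = "transition_estimate")
}

#' Per-cell attachment and detachment rates versus occupancy
#'
#' Converts pooled transition statistics into per-cell rates.  With
#' `method = "exposure"` (default) each droplet contributes exposure
#' `frames_at(n) * (N_droplet - n)` cell-frames to the attachment
#' denominator (and `frames_at(n) * n` to detachment), and the rate is
#' events per cell-frame divided by `delta_t` — the small-probability
#' limit of the per-cell waiting-time model, valid for heterogeneous
#' droplet loads.  With `method = "stratified"` the exact
#' `lambda_in(n) = -log(1 - p[n, n+1]) / ((N - n) delta_t)` is applied
#' within each stratum of equal `N` and strata are combined by exposure
#' weight; a stratum with `p[n, n+1] = 1` yields an infinite rate, which
#' is reported as censored-infinite rather than clamped.
#'
#' @param counts a `transition_counts` object.
#' @param method `"exposure"` or `"stratified"`.
#' @param conditioning `"sequential"` (default) or `"none"`.  Under the
#'   one-event-per-frame observation model an attachment can only be
#'   recorded on a frame without a detachment, so the raw attachment
#'   fraction estimates `(1 - p_out) p_in`, not `p_in`; the sequential
#'   conditioning divides attachment counts by the frames free of
#'   detachments (the exact conditional ML of the single-event chain).
#'   `"none"` uses the raw fractions, which is adequate when all
#'   per-frame probabilities are small.
#' @return a `rate_profile` data.frame: occupancy `n`, `lambda_in`,
#'   `lambda_out` (per min per cell), `affinity` (`NaN` where
#'   `lambda_out = 0`), per-frame `p_in`/`p_out`, exposures and event
#'   counts, and normalized rates (`lambda_in(n)/lambda_in(0)`,
#'   `lambda_out(n)/lambda_out(1)`).
#' @export
per_cell_rates <- function(counts, method = c("exposure", "stratified"),
                           conditioning = c("sequential", "none")) {
  stopifnot(inherits(counts, "transition_counts"))
  method <- match.arg(method)
  conditioning <- match.arg(conditioning)
  pd <- counts$per_droplet
  dt <- counts$delta_t
  ns <- 0:counts$n_max
  lam_in <- lam_out <- exp_in <- exp_out <- att <- det <- rep(NA_real_, length(ns))
  for (i in seq_along(ns)) {
    n <- ns[i]
    rows <- pd[pd$n == n & pd$frames > 0, , drop = FALSE]
    if (!nrow(rows)) next
    att[i] <- sum(rows$att); det[i] <- sum(rows$det)
    free <- if (conditioning == "sequential") rows$frames - rows$det
            else rows$frames
    exp_in[i] <- sum(free * pmax(rows$N - n, 0))
    exp_out[i] <- sum(rows$frames * n)
    if (method == "exposure") {
      lam_in[i] <- if (exp_in[i] > 0) att[i] / (exp_in[i] * dt) else NA_real_
      lam_out[i] <- if (exp_out[i] > 0) det[i] / (exp_out[i] * dt) else NA_real_
    } else {
      lam_in[i] <- stratified_rate(rows, n, dt, "att", conditioning)
      lam_out[i] <- stratified_rate(rows, n, dt, "det", conditioning)
    }
  }
  affinity <- ifelse(!is.na(lam_out) & lam_out == 0, NaN, lam_in / lam_out)
  out <- data.frame(
    n = ns, lambda_in = lam_in, lambda_out = lam_out, affinity = affinity,
    p_in = 1 - exp(-lam_in * dt), p_out = 1 - exp(-lam_out * dt),
    exposure_in = exp_in, exposure_out = exp_out, att = att, det = det)
  out$normalized_in <- out$lambda_in / out$lambda_in[out$n == 0]
  out$normalized_out <- out$lambda_out / out$lambda_out[out$n == 1][1]
  structure(out, class = c("rate_profile", "data.frame"),
            delta_t = dt, method = method)
}

stratified_rate <- function(rows, n, dt, what, conditioning = "sequential") {
  per_N <- split(rows, rows$N)
  vals <- w <- numeric(0)
  for (g in per_N) {
    N <- g$N[1]
    cells <- if (what == "att") N - n else n
    if (cells <= 0) next
    frames <- if (what == "att" && conditioning == "sequential")
      sum(g$frames) - sum(g$det) else sum(g$frames)
    if (frames <= 0) next
    p <- sum(g[[what]]) / frames
    vals <- c(vals, -log1p(-p) / (cells * dt))   # Inf when p == 1
    w <- c(w, frames * cells)
  }
  if (!length(vals)) return(NA_real_)
  if (any(is.infinite(vals))) return(Inf)        # censored-infinite row
  sum(vals * w) / sum(w)
}

#' @export
print.rate_profile <- function(x, ...) {
  cat(sprintf("<rate_profile> method = %s, delta_t = %g min\n",
              attr(x, "method"), attr(x, "delta_t")))
  cols <- intersect(c("n", "lambda_in", "lambda_out", "affinity",
                      "exposure_in"), names(x))
  print.data.frame(x[, cols, drop = FALSE], row.names = FALSE, digits = 4)
  invisible(x)
}

#' Bootstrap uncertainty for the per-cell rate profile
#'
#' Re-estimates the rate profile on repeated droplet subsamples (without
#' replacement) and summarizes the per-occupancy distributions by
#' quartiles and SEM.  Defaults follow the estimation protocol of 50
#' repetitions on 70% of the droplets.
#'
#' @param cohort a `ctl_cohort` or list of `occupancy_series` (>= 3
#'   droplets).
#' @param reps bootstrap repetitions.
#' @param fraction droplet subsample fraction in (0, 1].
#' @param seed RNG seed (required for reproducibility).
#' @param method rate pooling method, see [per_cell_rates()].
#' @return the point-estimate `rate_profile` with a `bootstrap` attribute:
#'   per-quantity matrices (reps x occupancy) and a per-n summary table.
#' @export
bootstrap_rates <- function(cohort, reps = 50, fraction = 0.7, seed,
                            method = "exposure") {
  series <- if (inherits(cohort, "ctl_cohort")) cohort$occupancy else cohort
  D <- length(series)
  if (D < 3) stop("bootstrap needs at least 3 droplets")
  m <- max(1L, round(fraction * D))
  if (m < 2 && reps > 1) stop("subsample smaller than 2 droplets")
  if (missing(seed)) stop("a seed is required")
  point <- per_cell_rates(count_transitions(series), method = method)
  n_levels <- nrow(point)
  set.seed(seed)
  draws <- list(lambda_in = matrix(NA_real_, reps, n_levels),
                lambda_out = matrix(NA_real_, reps, n_levels),
                affinity = matrix(NA_real_, reps, n_levels))
  for (r in seq_len(reps)) {
    sub <- series[sample.int(D, m)]
    rp <- per_cell_rates(count_transitions(sub), method = method)
    idx <- match(point$n, rp$n)
    draws$lambda_in[r, ] <- rp$lambda_in[idx]
    draws$lambda_out[r, ] <- rp$lambda_out[idx]
    draws$affinity[r, ] <- rp$affinity[idx]
  }
  qs <- function(mat) t(apply(mat, 2, function(col) {
    col <- col[is.finite(col)]
    if (!length(col)) return(c(q25 = NA, median = NA, q75 = NA,
                               mean = NA, sem = NA))
    c(q25 = unname(stats::quantile(col, 0.25)),
      median = unname(stats::median(col)),
      q75 = unname(stats::quantile(col, 0.75)),
      mean = mean(col), sem = stats::sd(col) / sqrt(length(col)))
  }))
  summary <- list(lambda_in = qs(draws$lambda_in),
                  lambda_out = qs(draws$lambda_out),
                  affinity = qs(draws$affinity))
  attr(point, "bootstrap") <- list(draws = draws, summary = summary,
                                   reps = reps, fraction = fraction,
                                   seed = seed)
  point
}

#' Forward solution of the occupancy master equation
#'
#' Integrates the birth–death master equation for the number of CTLs on
#' the spheroid,
#' `dP(n,t)/dt = (N-n+1) lambda_in(n-1) P(n-1,t) + (n+1) lambda_out(n+1) P(n+1,t)
#'   - ((N-n) lambda_in(n) + n lambda_out(n)) P(n,t)`,
#' which describes the same Markov process as the discrete-time chain.
#' Rate profiles shorter than `N + 1` are clamped to their last value
#' (flagged in the result).
#'
#' @param lambda_in,lambda_out rate profiles (per min per cell), vectors
#'   indexed from `n = 0`.
#' @param N total CTLs in the droplet.
#' @param times output times (min).
#' @param init initial occupancy distribution over `0..N`, or a single
#'   starting occupancy.
#' @return matrix of `P(n, t)` (rows = `times`, columns = `n = 0..N`)
#'   with attributes `times` and `clamped`.
#' @export
master_equation_forward <- function(lambda_in, lambda_out, N, times,
                                    init = 0L) {
  if (any(lambda_in < 0, na.rm = TRUE) || any(lambda_out < 0, na.rm = TRUE))
    stop("negative rates")
  clamped <- length(lambda_in) < N + 1 || length(lambda_out) < N + 1
  up <- (N - 0:N) * profile_at(lambda_in, 0:N)
  down <- (0:N) * profile_at(lambda_out, 0:N)
  if (length(init) == 1) {
    p0 <- rep(0, N + 1); p0[init + 1] <- 1
  } else {
    if (length(init) != N + 1 || abs(sum(init) - 1) > 1e-8)
      stop("'init' must be a distribution over 0..N")
    p0 <- init
  }
  deriv <- function(t, P, parms) {
    flow_up <- up * P                 # n -> n+1
    flow_down <- down * P             # n -> n-1
    dP <- -(flow_up + flow_down)
    dP[-1] <- dP[-1] + flow_up[-(N + 1)]
    dP[-(N + 1)] <- dP[-(N + 1)] + flow_down[-1]
    list(dP)
  }
  sol <- deSolve::ode(y = p0, times = times, func = deriv, parms = NULL,
                      rtol = 1e-10, atol = 1e-12)
  if (attr(sol, "istate")[1] < 0)
    stop("master-equation integration failed; see deSolve diagnostics")
  P <- unname(sol[, -1, drop = FALSE])
  if (any(abs(rowSums(P) - 1) > 1e-8))
    stop("probability not conserved to 1e-8; integration step failure")
  structure(P, times = times, clamped = clamped,
            dimnames = list(NULL, 0:N))
}
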
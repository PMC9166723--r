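#' Fit the full accumulation-and-killing model to an occupancy cohort
#'
#' The central estimator of the package.  From a cohort of per-droplet
#' occupancy time series it
#'
#' 1. counts frame-to-frame occupancy transitions and estimates per-cell
#'    attachment and detachment rates `lambda_in(n)`, `lambda_out(n)` and
#'    the affinity ratio as functions of the number of CTLs on the
#'    spheroid, with bootstrap uncertainty ([per_cell_rates()],
#'    [bootstrap_rates()]);
#' 2. tallies fragmentation events against pre-fragmentation exposure and
#'    estimates the per-frame fragmentation rate `Gamma(n)` by maximum
#'    likelihood ([estimate_gamma()]);
#' 3. fits and compares the independent-killer and exponential
#'    (cooperative) fragmentation models by binomial likelihood
#'    ([fit_independent()], [fit_exponential()]).
#'
#' The fitted object simulates: [simulate.ctl_fit()] draws spheroid-fate
#' replicates from the estimated profiles, and [predict.ctl_fit()] maps
#' droplet CTL numbers to killing probabilities through the branching-
#' process sweep.
#'
#' @param cohort a [ctl_cohort()] or list of [occupancy_series()].
#' @param bootstrap run the droplet bootstrap (default `TRUE`).
#' @param reps,fraction bootstrap repetitions and droplet subsample
#'   fraction (defaults 50 and 0.7).
#' @param seed RNG seed for the bootstrap.
#' @param method rate pooling method, see [per_cell_rates()].
#' @param frag_models fit the killing-model comparison (needs >= 3
#'   occupancy levels with data; skipped with a note otherwise).
#' @param success_cutoff cutoff for the success-rate summary, min.
#' @return a `ctl_fit` object.
#' @seealso [summary.ctl_fit()], [coef.ctl_fit()], [plot.ctl_fit()]
#' @examples
#' cfg <- sim_config("ova", duration = 600)
#' cohort <- generate_cohort(cfg, 40, seed = 7)
#' fit <- ctl_fit(cohort, bootstrap = FALSE)
#' fit
#' coef(fit)$exponential
#' @export
ctl_fit <- function(cohort, bootstrap = TRUE, reps = 50, fraction = 0.7,
                    seed = 1, method = "exposure", frag_models = TRUE,
                    success_cutoff = 840) {
  series <- if (inherits(cohort, "ctl_cohort")) cohort$occupancy else cohort
  if (!length(series)) stop("empty cohort")
  counts <- count_transitions(series)
  rates <- if (bootstrap && length(series) >= 3)
    bootstrap_rates(series, reps = reps, fraction = fraction, seed = seed,
                    method = method)
  else per_cell_rates(counts, method = method)
  frag_counts <- count_frag_exposure(series)
  gamma <- estimate_gamma(frag_counts)
  models <- NULL
  n_levels <- sum(gamma$n >= 1 & (gamma$deaths + gamma$exposure) > 0)
  if (frag_models && n_levels >= 3 && sum(gamma$deaths) > 0)
    models <- tryCatch(compare_frag_models(frag_counts),
                       error = function(e) NULL)
  sr <- tryCatch(success_rate(series, cutoff = success_cutoff),
                 error = function(e) NULL)
  structure(list(rates = rates, gamma = gamma, models = models,
                 counts = counts, frag_counts = frag_counts,
                 success = sr, n_droplets = length(series),
                 delta_t = counts$delta_t, method = method,
                 success_cutoff = success_cutoff,
                 call = match.call()),
            class = "ctl_fit")
}

#' @export
print.ctl_fit <- function(x, ...) {
  cat(sprintf("CTL accumulation / killing fit: %d droplets, delta_t = %g min\n",
              x$n_droplets, x$delta_t))
  if (!is.null(x$success))
    cat(sprintf("  killing success (< %g min): %.1f%% (%d/%d)\n",
                x$success$cutoff, 100 * x$success$rate,
                x$success$n_success, x$success$n))
  obs <- x$rates[is.finite(x$rates$lambda_in) | is.finite(x$rates$lambda_out), ]
  cat(sprintf("  occupancy levels observed: 0..%d; total deaths: %d\n",
              max(obs$n), sum(x$gamma$deaths)))
  if (!is.null(x$models))
    cat(sprintf("  killing models: logLik(exponential) - logLik(independent) = %.2f\n",
                x$models$delta_logLik))
  invisible(x)
}

#' @rdname ctl_fit
#' @param object,x a `ctl_fit`.
#' @param ... unused.
#' @export
summary.ctl_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.ctl_fit")
}

#' @export
print.summary.ctl_fit <- function(x, ...) {
  f <- x$fit
  print(f)
  cat("\nPer-cell rates (per min per cell):\n")
  print.data.frame(f$rates[, c("n", "lambda_in", "lambda_out", "affinity",
                               "normalized_in", "normalized_out")],
                   row.names = FALSE, digits = 3)
  cat("\nPer-frame fragmentation rate:\n")
  print.data.frame(as.data.frame(f$gamma), row.names = FALSE, digits = 3)
  if (!is.null(f$models)) {
    cat("\nKilling-model comparison (same occupancy levels):\n")
    print(f$models$independent)
    print(f$models$exponential)
  }
  invisible(x)
}

#' Extract fitted parameters
#'
#' @param object a `ctl_fit`.
#' @param ... unused.
#' @return list with the rate vectors (`lambda_in`, `lambda_out`,
#'   `affinity` indexed by occupancy), the `gamma` vector, and — when the
#'   model comparison ran — `rho` (independent model) and `exponential`
#'   (`gamma0`, `c`).
#' @export
coef.ctl_fit <- function(object, ...) {
  out <- list(
    lambda_in = stats::setNames(object$rates$lambda_in, object$rates$n),
    lambda_out = stats::setNames(object$rates$lambda_out, object$rates$n),
    affinity = stats::setNames(object$rates$affinity, object$rates$n),
    gamma = stats::setNames(object$gamma$gamma, object$gamma$n))
  if (!is.null(object$models)) {
    out$rho <- object$models$independent$rho
    out$exponential <- c(gamma0 = object$models$exponential$gamma0,
                         c = object$models$exponential$c)
  }
  out
}

#' Simulate spheroid-fate replicates from a fitted model
#'
#' @param object a `ctl_fit`.
#' @param nsim number of replicates.
#' @param seed RNG seed.
#' @param N droplet CTL count per replicate (recycled).
#' @param duration experiment duration, min.
#' @param ... unused.
#' @return list of [occupancy_series()].
#' @export
simulate.ctl_fit <- function(object, nsim = 1, seed = NULL, N = 7,
                             duration = 840, ...) {
  if (!is.null(seed)) set.seed(seed)
  N <- rep_len(N, nsim)
  lapply(seq_len(nsim), function(i)
    simulate_fate(object$rates, object$gamma, N[i], duration,
                  delta_t = object$delta_t,
                  droplet_id = sprintf("sim%03d", i)))
}

#' Predict killing probability versus droplet CTL count
#'
#' Runs the branching-process sweep with the fitted profiles and returns
#' the fragmentation probability (with 95% binomial intervals) for each
#' requested CTL count.
#'
#' @param object a `ctl_fit`.
#' @param newdata data.frame with a column `N`, or a numeric vector of
#'   CTL counts (default 0:20).
#' @param reps_per_N replicates per count.
#' @param duration experiment duration, min.
#' @param cutoff success cutoff, min.
#' @param seed RNG seed.
#' @param ... unused.
#' @return the [sweep_cohort()] summary data.frame.
#' @export
predict.ctl_fit <- function(object, newdata = 0:20, reps_per_N = 50,
                            duration = 840, cutoff = duration, seed = 1,
                            ...) {
  N_range <- if (is.data.frame(newdata)) newdata$N else newdata
  sw <- sweep_cohort(object$rates, object$gamma, N_range = N_range,
                     reps_per_N = reps_per_N, duration = duration,
                     delta_t = object$delta_t, cutoff = cutoff, seed = seed)
  sw$summary
}

#' Plot a fitted accumulation / killing model
#'
#' Two panels: per-cell attachment and detachment rates (with bootstrap
#' interquartile boxes when available) versus occupancy, and the
#' estimated per-frame fragmentation rate with the fitted independent and
#' exponential curves.
#'
#' @param x a `ctl_fit`.
#' @param ... passed to the base plotting calls.
#' @export
plot.ctl_fit <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  r <- x$rates
  ok <- is.finite(r$lambda_in) | is.finite(r$lambda_out)
  graphics::matplot(r$n[ok], cbind(r$lambda_in[ok], r$lambda_out[ok]),
                    type = "b", pch = c(16, 1), lty = 1,
                    col = c("firebrick", "steelblue"),
                    xlab = "CTLs on spheroid (n)",
                    ylab = "rate (per min per cell)", ...)
  bs <- attr(r, "bootstrap")
  if (!is.null(bs)) {
    lo <- bs$summary$lambda_in[, "q25"]
    hi <- bs$summary$lambda_in[, "q75"]
    show <- ok & is.finite(lo) & is.finite(hi) & hi > lo
    if (any(show))
      graphics::arrows(r$n[show], lo[show], r$n[show], hi[show],
                       angle = 90, code = 3, length = 0.03,
                       col = "firebrick")
  }
  graphics::legend("topleft", c(expression(lambda["in"]),
                                expression(lambda["out"])),
                   pch = c(16, 1), col = c("firebrick", "steelblue"),
                   bty = "n")
  g <- x$gamma
  gok <- !is.na(g$gamma)
  graphics::plot(g$n[gok], g$gamma[gok], pch = 16,
                 xlab = "CTLs on spheroid (n)",
                 ylab = "fragmentation rate (per frame)", ...)
  if (!is.null(x$models)) {
    nn <- seq(0, max(g$n), by = 0.1)
    graphics::lines(nn, independent_model(x$models$independent$rho, nn),
                    col = "steelblue", lty = 2)
    graphics::lines(nn, pmin(x$models$exponential$gamma0 *
                               exp(x$models$exponential$c * nn), 1),
                    col = "firebrick", lty = 2)
    graphics::legend("topleft", c("independent", "exponential"),
                     lty = 2, col = c("steelblue", "firebrick"), bty = "n")
  }
  invisible(x)
}
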
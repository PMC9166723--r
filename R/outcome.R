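#' Per-droplet outcome features
#'
#' Reduces each occupancy series to the droplet-level predictors used for
#' outcome modelling: the first times `t1..t4` at which the occupancy
#' reaches 1 to 4 CTLs (missing when never reached), the maximum recorded
#' occupancy `n_max`, the droplet CTL count `N`, the spheroid projected
#' area, and the success label (first fragmentation before the cutoff).
#'
#' @param cohort a `ctl_cohort` or list of `occupancy_series`.
#' @param cutoff success cutoff, min (default 840 = 14 h).
#' @return a `droplet_features` data.frame.
#' @export
extract_features <- function(cohort, cutoff = 840) {
  series <- if (inherits(cohort, "ctl_cohort")) cohort$occupancy else cohort
  rows <- lapply(series, function(s) {
    t_of <- function(k) {
      w <- which(!is.na(s$n_t) & s$n_t >= k)
      if (length(w)) (w[1] - 1) * s$delta_t else NA_real_
    }
    data.frame(droplet_id = s$droplet_id, N = s$N,
               n_max = max(s$n_t, 0L, na.rm = TRUE),
               area_um2 = s$spheroid_area,
               t1 = t_of(1), t2 = t_of(2), t3 = t_of(3), t4 = t_of(4),
               success = !is.na(s$t_frag) && s$t_frag < cutoff,
               stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows),
            class = c("droplet_features", "data.frame"), cutoff = cutoff)
}

#' Logistic regression of killing success on droplet features
#'
#' Binomial GLM (logit link) of the success label on the maximum
#' occupancy `n_max`, the droplet CTL count `N`, the spheroid area, and
#' the contact times `t1..t4`.  Complete-case: droplets missing any
#' retained covariate are dropped and counted.  Covariates that are
#' entirely missing or constant are excluded automatically (and listed),
#' so cohorts without area measurements still fit.  Quasi-complete
#' separation is flagged; a ridge-penalized refit is available for that
#' case.
#'
#' @param features a `droplet_features` data.frame.
#' @param covariates character vector of covariate names to use.
#' @param standardize centre/scale covariates before fitting (off by
#'   default; coefficients are then per original unit).
#' @param penalized logical; add a small L2 penalty (IRLS ridge) instead
#'   of plain ML — use when separation is flagged.  No p-values are
#'   reported in that case.
#' @param ridge penalty strength when `penalized = TRUE`.
#' @return an `outcome_glm` object: coefficient table (estimate, SE, z,
#'   two-sided p, 95% interval), sample sizes, dropped covariates and
#'   cases, separation flag, and the underlying [stats::glm()] fit.
#' @export
fit_outcome_glm <- function(features,
                            covariates = c("n_max", "N", "area_um2",
                                           "t1", "t2", "t3", "t4"),
                            standardize = FALSE, penalized = FALSE,
                            ridge = 1e-2) {
  df <- as.data.frame(features)
  if (!"success" %in% names(df)) stop("'features' must carry a success column")
  present <- intersect(covariates, names(df))
  usable <- character(0); dropped <- character(0)
  for (v in present) {
    x <- df[[v]]
    if (all(is.na(x)) || length(unique(x[!is.na(x)])) < 2)
      dropped <- c(dropped, v)
    else usable <- c(usable, v)
  }
  cc <- stats::complete.cases(df[usable])
  d <- df[cc, , drop = FALSE]
  if (nrow(d) < 20)
    stop("fewer than 20 complete-case droplets (", nrow(d), ")")
  if (length(unique(d$success)) < 2)
    stop("outcome is constant; nothing to fit")
  if (standardize)
    for (v in usable) d[[v]] <- as.numeric(scale(d[[v]]))
  form <- stats::as.formula(paste("success ~", paste(usable, collapse = " + ")))
  fit <- stats::glm(form, family = stats::binomial(), data = d)
  mu <- stats::fitted(fit)
  separated <- any(mu > 1 - 1e-8) || any(mu < 1e-8) ||
    any(abs(stats::coef(fit)[-1]) > 15)
  if (penalized) {
    X <- stats::model.matrix(form, d)
    beta <- ridge_logistic(X, as.numeric(d$success), ridge)
    tab <- data.frame(term = colnames(X), estimate = beta,
                      std_error = NA_real_, z = NA_real_, p = NA_real_,
                      ci_lo = NA_real_, ci_hi = NA_real_)
  } else {
    s <- summary(fit)$coefficients
    ci <- suppressMessages(stats::confint.default(fit))
    tab <- data.frame(term = rownames(s), estimate = s[, 1],
                      std_error = s[, 2], z = s[, 3], p = s[, 4],
                      ci_lo = ci[, 1], ci_hi = ci[, 2])
  }
  rownames(tab) <- NULL
  structure(list(table = tab, n_samples = nrow(d),
                 n_dropped_cases = sum(!cc), dropped_covariates = dropped,
                 separation = separated, penalized = penalized,
                 standardized = standardize, fit = fit),
            class = "outcome_glm")
}

# IRLS with an L2 penalty on all but the intercept
ridge_logistic <- function(X, y, lambda, maxit = 100, tol = 1e-10) {
  beta <- rep(0, ncol(X))
  pen <- diag(c(0, rep(lambda, ncol(X) - 1)), ncol(X))
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    new <- solve(crossprod(X, w * X) + pen, crossprod(X, w * z))
    if (max(abs(new - beta)) < tol) { beta <- drop(new); break }
    beta <- drop(new)
  }
  stats::setNames(beta, colnames(X))
}

#' @export
print.outcome_glm <- function(x, ...) {
  cat(sprintf("<outcome_glm> logistic model of killing success, n = %d (%d dropped)%s%s\n",
              x$n_samples, x$n_dropped_cases,
              if (length(x$dropped_covariates))
                paste0("; excluded: ",
                       paste(x$dropped_covariates, collapse = ", ")) else "",
              if (x$separation) "; WARNING: separation flagged" else ""))
  print(x$table, digits = 3)
  invisible(x)
}

#' Mann–Whitney–Wilcoxon group comparisons with Bonferroni correction
#'
#' All pairwise two-sided rank-sum tests among the supplied groups, with
#' Bonferroni multiplication (capped at 1) and the conventional
#' significance-band annotation: `ns` for p > 0.05 down to `****` for
#' p <= 1e-4.
#'
#' @param ... named numeric vectors, or a single named list of them.
#' @return data.frame: group pair, U statistic, raw and corrected p,
#'   annotation band.
#' @export
compare_groups <- function(...) {
  groups <- list(...)
  if (length(groups) == 1 && is.list(groups[[1]]) &&
      !is.numeric(groups[[1]]))
    groups <- groups[[1]]
  if (length(groups) < 2) stop("need at least two groups")
  if (is.null(names(groups)) || any(names(groups) == ""))
    names(groups) <- paste0("g", seq_along(groups))
  for (nm in names(groups))
    if (!length(groups[[nm]])) stop("empty group: ", nm)
  pairs <- utils::combn(names(groups), 2, simplify = FALSE)
  m <- length(pairs)
  rows <- lapply(pairs, function(pr) {
    ht <- suppressWarnings(stats::wilcox.test(groups[[pr[1]]],
                                              groups[[pr[2]]],
                                              alternative = "two.sided"))
    p_adj <- min(ht$p.value * m, 1)
    data.frame(group_a = pr[1], group_b = pr[2],
               U = unname(ht$statistic), p_raw = ht$p.value,
               p_corrected = p_adj, band = p_value_band(p_adj),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Significance annotation band for a corrected p-value
#'
#' `ns`: 0.05 < p <= 1; `*`: 0.01 < p <= 0.05; `**`: 0.001 < p <= 0.01;
#' `***`: 1e-4 < p <= 1e-3; `****`: p <= 1e-4.
#'
#' @param p corrected p-value(s) in \[0, 1\].
#' @return character vector of bands.
#' @export
p_value_band <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  cut(p, breaks = c(-Inf, 1e-4, 1e-3, 1e-2, 5e-2, Inf),
      labels = c("****", "***", "**", "*", "ns")) |> as.character()
}
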
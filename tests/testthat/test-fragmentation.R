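test_that("death and exposure counts follow the trial bookkeeping", {
  s <- occ(c(0, 1, 2, 2), t_frag = 6, N = 3)     # death on the last frame
  fc <- count_frag_exposure(list(s))
  expect_equal(fc$k_death, c(0L, 0L, 1L))
  expect_equal(fc$k_exposure, c(1L, 1L, 1L))

  censored <- occ(c(0, 1, 1, 2), N = 3)
  fc2 <- count_frag_exposure(list(censored))
  expect_equal(sum(fc2$k_death), 0)
  expect_equal(fc2$k_exposure, c(1L, 2L, 1L))

  pooled <- count_frag_exposure(list(s, censored))
  expect_equal(pooled$k_death, fc$k_death + fc2$k_death)
  expect_equal(pooled$k_exposure, fc$k_exposure + fc2$k_exposure)
})

test_that("the ML fragmentation rate is the event fraction, with exact bounds", {
  fc <- structure(list(k_death = c(0L, 0L, 3L), k_exposure = c(50L, 40L, 27L),
                       n_max = 2L, delta_t = 2),
                  class = "frag_counts")
  g <- estimate_gamma(fc)
  expect_equal(g$gamma[g$n == 2], 0.1)
  # no deaths at a level -> exactly zero; instant deaths -> exactly one
  expect_identical(g$gamma[g$n == 1], 0)
  fc1 <- structure(list(k_death = c(0L, 5L), k_exposure = c(10L, 0L),
                        n_max = 1L, delta_t = 2),
                   class = "frag_counts")
  expect_identical(estimate_gamma(fc1)$gamma[2], 1)
  # unobserved level -> missing, not zero
  fc2 <- structure(list(k_death = c(0L, 0L, 1L), k_exposure = c(5L, 0L, 3L),
                        n_max = 2L, delta_t = 2),
                   class = "frag_counts")
  expect_true(is.na(estimate_gamma(fc2)$gamma[2]))
})

test_that("the event-fraction estimator maximizes the Bernoulli likelihood", {
  # independent grid-search oracle over the per-level likelihood
  d <- 7L; e <- 93L
  grid <- seq(1e-4, 0.9999, by = 1e-4)
  ll <- d * log(grid) + e * log(1 - grid)
  expect_equal(grid[which.max(ll)], d / (d + e), tolerance = 1e-4)
  fc <- structure(list(k_death = c(0L, d), k_exposure = c(10L, e),
                       n_max = 1L, delta_t = 2),
                  class = "frag_counts")
  expect_equal(estimate_gamma(fc)$gamma[2], d / (d + e), tolerance = 1e-12)
})

test_that("independent-killer curve evaluates exactly", {
  expect_equal(independent_model(0.3, 0), 0)
  expect_equal(independent_model(0.1, 2), 0.19)
  expect_equal(independent_model(1, 5), 1)
  expect_error(independent_model(1.2, 1), "rho")
  expect_error(independent_model(0.5, -1), "non-negative")
  # concave, below n * rho, anchored at zero
  n <- 0:10
  g <- independent_model(0.07, n)
  expect_true(all(diff(g, differences = 2) < 0))
  expect_true(all(g <= n * 0.07 + 1e-12))
})

test_that("independent fit recovers rho and handles edge cases", {
  set.seed(81)
  fc <- frag_counts_from_curve(function(n) independent_model(0.05, n),
                               levels = 1:6,
                               trials = rep(2000, 6))
  fit <- fit_independent(fc)
  expect_equal(fit$rho, 0.05, tolerance = 0.01)
  # saturated single-level case: rho equals the raw estimate
  fc1 <- structure(list(k_death = c(0L, 12L), k_exposure = c(0L, 88L),
                        n_max = 1L, delta_t = 2),
                   class = "frag_counts")
  expect_equal(fit_independent(fc1)$rho, 0.12, tolerance = 1e-6)
  # all-censored data: boundary at zero, flagged
  fc0 <- structure(list(k_death = c(0L, 0L), k_exposure = c(10L, 90L),
                        n_max = 1L, delta_t = 2),
                   class = "frag_counts")
  f0 <- fit_independent(fc0)
  expect_equal(f0$rho, 0)
  expect_true(f0$boundary)
})

test_that("independent ML equals a grid-search likelihood maximizer", {
  fc <- structure(list(k_death = c(0L, 3L, 8L, 9L),
                       k_exposure = c(40L, 120L, 80L, 30L),
                       n_max = 3L, delta_t = 2),
                  class = "frag_counts")
  fit <- fit_independent(fc)
  grid <- seq(1e-5, 0.5, by = 1e-5)
  n <- 1:3; d <- fc$k_death[2:4]; e <- fc$k_exposure[2:4]
  ll <- vapply(grid, function(r)
    sum(d * log(1 - (1 - r)^n) + e * n * log(1 - r)), numeric(1))
  expect_equal(fit$rho, grid[which.max(ll)], tolerance = 1e-3)
})

test_that("killer heterogeneity collapses onto the mean-rho curve", {
  set.seed(91)
  het <- heterogeneous_equivalence(list(name = "beta", shape1 = 2,
                                        shape2 = 8),
                                   n_range = 0:5, n_mc = 2e4)
  expect_equal(het$mean_rho, 0.2)
  expect_equal(het$table$closed[het$table$n == 3], 1 - 0.8^3)
  expect_lt(het$max_deviation, 3 * max(het$table$mc_se))

  point <- heterogeneous_equivalence(list(name = "point", value = 0.1),
                                     n_range = 0:4, n_mc = 100)
  expect_equal(point$max_deviation, 0, tolerance = 1e-12)
  expect_equal(point$table$mc, independent_model(0.1, 0:4))

  unif <- heterogeneous_equivalence(list(name = "uniform", min = 0,
                                         max = 0.3),
                                    n_range = 0:4, n_mc = 2e4)
  expect_lt(unif$max_deviation, 3 * max(unif$table$mc_se))
  expect_error(heterogeneous_equivalence(list(name = "cauchy")),
               "unsupported")
})

test_that("exponential fit recovers its parameters and the flat limit", {
  set.seed(83)
  fc <- frag_counts_from_curve(function(n) min(0.001 * exp(0.8 * n), 1),
                               levels = 1:6,
                               trials = c(4000, 3000, 2000, 1500, 800, 400))
  fit <- fit_exponential(fc)
  expect_equal(fit$gamma0, 0.001, tolerance = 0.2)
  expect_equal(fit$c, 0.8, tolerance = 0.2)
  # constant-gamma data: c ~ 0
  set.seed(84)
  flat <- frag_counts_from_curve(function(n) 0.02, levels = 1:5,
                                 trials = rep(4000, 5))
  expect_equal(fit_exponential(flat)$c, 0, tolerance = 0.05)
  expect_error(fit_exponential(frag_counts_from_curve(function(n) 0.1,
                                                      1:2, c(10, 10))),
               "at least 3")
})

test_that("fitted curves carry the shape signature of each model", {
  set.seed(85)
  fc <- frag_counts_from_curve(function(n) min(5e-4 * exp(0.9 * n), 1),
                               levels = 1:7, trials = rep(3000, 7))
  cmp <- compare_frag_models(fc)
  # cooperative data: exponential wins the likelihood-ratio comparison
  expect_gt(cmp$delta_logLik, 0)
  expect_equal(cmp$preferred, "exponential")
  # exponential fit is convex for c > 0, independent fit concave
  ge <- cmp$exponential$fitted$gamma
  gi <- cmp$independent$fitted$gamma
  expect_true(all(diff(ge, differences = 2) > -1e-12))
  expect_true(all(diff(gi, differences = 2) < 1e-12))
})

test_that("for small rates the two models coincide at first order", {
  set.seed(86)
  fc <- frag_counts_from_curve(function(n) independent_model(0.002, n),
                               levels = 1:5, trials = rep(5000, 5))
  cmp <- compare_frag_models(fc)
  # both reduce to ~ n * rho: likelihoods nearly indistinguishable
  expect_lt(abs(cmp$delta_logLik), qchisq(0.95, 1) / 2)
  expect_equal(cmp$preferred, "independent")
})
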
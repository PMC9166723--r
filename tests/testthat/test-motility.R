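test_that("MSD closed forms: ballistic and Brownian", {
  set.seed(31)
  bal <- ballistic_tracks(20, 40, v = 2, dt = 1)
  mb <- compute_msd(bal, max_lag = 10)
  expect_equal(mb$msd, 4 * mb$lags^2, tolerance = 1e-9)
  fit <- fit_msd_exponent(mb, fit_range = c(1, 10))
  expect_equal(fit$alpha, 2, tolerance = 1e-9)

  bro <- brownian_tracks(400, 300, D = 1, dt = 1)
  m3 <- compute_msd(bro, max_lag = 20)
  expect_equal(m3$msd / (6 * m3$lags), rep(1, length(m3$lags)),
               tolerance = 0.05)
  m2 <- compute_msd(project_tracks_2d(bro), max_lag = 20)
  expect_equal(m2$msd / (4 * m2$lags), rep(1, length(m2$lags)),
               tolerance = 0.05)
})

test_that("stationary tracks yield zero MSD and refuse an exponent fit", {
  still <- ballistic_tracks(5, 30, v = 0, dt = 1)
  m <- compute_msd(still, max_lag = 10)
  expect_true(all(m$msd == 0))
  expect_error(fit_msd_exponent(m, c(1, 10)), "positive MSD")
})

test_that("an exact power law is recovered to numerical precision", {
  lags <- seq(2, 60, by = 2)
  curve <- structure(list(lags = lags, msd = 3.7 * lags^1.3,
                          sem = rep(0, length(lags)), n_tracks = 1,
                          dim = 3L, delta_t = 2),
                     class = "msd_curve")
  fit <- fit_msd_exponent(curve, c(2, 60))
  expect_equal(fit$alpha, 1.3, tolerance = 1e-9)
})

test_that("empty or too-short input is rejected and long lags truncated", {
  expect_error(compute_msd(ctl_tracks(data.frame(
    droplet_id = character(), cell_id = character(), t_min = numeric(),
    x_um = numeric(), y_um = numeric()))), "empty")
  set.seed(1)
  short <- brownian_tracks(3, 10, dt = 1)
  expect_warning(compute_msd(short, max_lag = 50), "truncated")
})

test_that("displacement distributions degenerate correctly", {
  still <- ballistic_tracks(4, 20, v = 0, dt = 1)
  d0 <- displacement_distribution(still, lag = 2)
  expect_true(all(d0$dr == 0))
  set.seed(2)
  bal <- ballistic_tracks(10, 20, v = 3, dt = 1)
  d1 <- displacement_distribution(bal, lag = 4)
  expect_equal(d1$dr, rep(12, d1$n), tolerance = 1e-9)
  expect_error(displacement_distribution(bal, lag = 1.5), "multiple")
})

test_that("two cohorts from one motility law are KS-compatible", {
  set.seed(33)
  a <- fbm_tracks(40, 100, hurst = 0.8, sigma = 1)
  b <- fbm_tracks(40, 100, hurst = 0.8, sigma = 1)
  ks <- suppressWarnings(stats::ks.test(
    displacement_distribution(a, lag = 2)$dr,
    displacement_distribution(b, lag = 2)$dr))
  expect_gt(ks$p.value, 0.01)
})

test_that("distance-travelled scaling exposes the sampling-rate effect", {
  set.seed(41)
  bal <- ballistic_tracks(10, 60, v = 2, dt = 1)
  vb <- velocity_lag_scaling(bal, lags = c(2, 4, 8, 16))
  expect_equal(vb$displacement_exponent, 1, tolerance = 1e-6)
  expect_equal(vb$velocity_exponent, 0, tolerance = 1e-6)

  bro <- brownian_tracks(300, 200, D = 1, dt = 1)
  vr <- velocity_lag_scaling(bro, lags = c(2, 4, 8, 16, 32))
  expect_equal(vr$displacement_exponent, 0.5, tolerance = 0.05)

  gel <- fbm_tracks(200, 200, hurst = 0.8, sigma = 1)
  vg <- velocity_lag_scaling(gel, lags = c(4, 8, 16, 32, 64))
  expect_equal(vg$displacement_exponent, 0.8, tolerance = 0.05)
  expect_lt(vg$displacement_exponent, 1)  # sub-linear: frame-rate dependent speed
})

test_that("projection corrections scale by the isotropy factors", {
  expect_equal(correct_projection(5.14, "mean_speed"), sqrt(3 / 2) * 5.14)
  expect_equal(correct_projection(5.14, "mean_speed"), 6.3, tolerance = 0.01)
  expect_equal(correct_projection(2, "diffusion"), 3)
  expect_equal(correct_projection(8, "msd"), 12)
  expect_equal(correct_projection(0, "msd"), 0)
  expect_error(correct_projection(1, "banana"))
  set.seed(3)
  tr3 <- brownian_tracks(5, 20)
  m3 <- compute_msd(tr3, 5)
  expect_error(correct_projection(m3), "3D tracks")
  # correct_projection after projection recovers the 3D diffusion estimate
  big <- brownian_tracks(300, 200, D = 1, dt = 1)
  d3 <- fit_msd_exponent(compute_msd(big, 20), c(1, 20))$diffusion_coeff
  d2 <- fit_msd_exponent(compute_msd(project_tracks_2d(big), 20),
                         c(1, 20))$diffusion_coeff
  expect_equal(correct_projection(d2, "diffusion") / d3, 1, tolerance = 0.03)
})

test_that("first-contact null responds to geometry and mobility", {
  fast <- function(sigma, spheroid = 40)
    sim_config("ova", droplet_radius = 150, droplet_height = 150,
               spheroid_radius = spheroid, duration = 400,
               motility = list(gel = list(hurst = 0.8, sigma = sigma),
                               spheroid = motility_preset("spheroid")))
  set.seed(51)
  near_fill <- first_contact_null(fast(5, spheroid = 130), 200)
  expect_lt(stats::median(near_fill$times), 20)
  set.seed(52)
  quick <- first_contact_null(fast(6), 300)
  set.seed(53)
  slow <- first_contact_null(fast(3), 300)
  expect_lt(stats::median(quick$times), stats::median(slow$times))
  # zero mobility: nobody arrives -> error after the cap
  cfg0 <- fast(0)
  expect_error(first_contact_null(cfg0, 20), "no walker")
})

test_that("observed times from the null model pass the KS check", {
  fast <- sim_config("ova", droplet_radius = 150, droplet_height = 150,
                     duration = 600,
                     motility = list(gel = list(hurst = 0.8, sigma = 10),
                                     spheroid = motility_preset("spheroid")))
  set.seed(61)
  null <- first_contact_null(fast, 1000)
  expect_gte(length(null$times), 500)
  accept <- replicate(10, {
    obs <- first_contact_null(fast, 80)$times
    suppressWarnings(first_contact_test(obs, null))$p.value > 0.05
  })
  expect_gte(sum(accept), 9)
})
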
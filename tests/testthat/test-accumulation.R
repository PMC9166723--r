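test_that("transition counts match a hand tally and pool additively", {
  s <- occ(c(0, 0, 1, 1, 0, 1, 2, 2), N = 3)
  tc <- count_transitions(list(s))
  expect_equal(tc$a["0", "0"], 1)
  expect_equal(tc$a["0", "1"], 2)
  expect_equal(tc$a["1", "1"], 1)
  expect_equal(tc$a["1", "0"], 1)
  expect_equal(tc$a["1", "2"], 1)
  expect_equal(tc$a["2", "2"], 1)
  expect_equal(sum(tc$a), 7)

  const <- occ(c(3, 3, 3, 3), N = 5)
  tc2 <- count_transitions(list(const))
  expect_equal(tc2$a["3", "3"], 3)
  expect_equal(sum(tc2$a), 3)

  pooled <- count_transitions(list(s, const))
  expect_equal(sum(pooled$a), sum(tc$a) + sum(tc2$a))
  expect_equal(pooled$a["3", "3"], 3)
})

test_that("frames after the first fragmentation are excluded by default", {
  s <- occ(c(0, 1, 1, 1, 1, 1), t_frag = 4, N = 2)  # death on frame 3
  tc <- count_transitions(list(s))
  expect_equal(sum(tc$a), 2)                        # pairs 0-1, 1-1 only
  tc_all <- count_transitions(list(s), pre_frag_only = FALSE)
  expect_equal(sum(tc_all$a), 5)
})

test_that("multi-event frame pairs are dropped, not split", {
  s <- occ(c(0, 2, 2), N = 3)                       # one 0 -> 2 jump
  tc <- count_transitions(list(s))
  expect_equal(tc$dropped_multi_event, 1)
  expect_equal(sum(tc$a), 1)                        # only the 2 -> 2 pair
  expect_equal(tc$a["2", "2"], 1)
  expect_equal(sum(tc$a["0", ]), 0)
})

test_that("transition probabilities follow the observed-fraction rule", {
  s <- occ(c(0, 0, 1, 1, 0, 1, 2, 2), N = 3)
  est <- estimate_transition_probabilities(count_transitions(list(s)))
  expect_equal(est$p["0", "1"], 2 / 3)
  expect_equal(est$p["1", "0"], 1 / 3)
  expect_equal(est$p["1", "1"], 1 / 3)
  expect_equal(est$p["1", "2"], 1 / 3)
  # rows are stochastic where observed, missing where not
  expect_equal(unname(rowSums(est$p)[1:3]), rep(1, 3))
  lone <- occ(c(4, 4), N = 5)
  est2 <- estimate_transition_probabilities(count_transitions(list(lone)))
  expect_equal(est2$p["4", "4"], 1)
  expect_true(all(is.na(est2$p["0", ])))
})

test_that("per-cell attachment rate reproduces the waiting-time formula", {
  # ten transitions out of n = 0, one of them an attachment: p01 = 0.1
  s <- occ(c(rep(0L, 10), 1L), N = 5)
  rp <- per_cell_rates(count_transitions(list(s)), method = "stratified")
  expect_equal(rp$lambda_in[rp$n == 0], -log(1 - 0.1) / (5 * 2),
               tolerance = 1e-12)
  expect_equal(rp$lambda_in[rp$n == 0], 0.01054, tolerance = 1e-3)
  # small-probability pooling gives p / ((N - n) dt)
  rp2 <- per_cell_rates(count_transitions(list(s)), method = "exposure")
  expect_equal(rp2$lambda_in[rp2$n == 0], 0.1 / (5 * 2), tolerance = 1e-12)
  # no attachments -> rate exactly zero
  flat <- occ(rep(0L, 20), N = 5)
  rp3 <- per_cell_rates(count_transitions(list(flat)))
  expect_equal(rp3$lambda_in[rp3$n == 0], 0)
  # certain attachment -> censored-infinite, flagged not clamped
  jump <- occ(c(0L, 1L, 1L), N = 2)
  rp4 <- per_cell_rates(count_transitions(list(jump)), method = "stratified")
  expect_true(is.infinite(rp4$lambda_in[rp4$n == 0]))
})

test_that("affinity is flagged undefined where lambda_out is zero", {
  s <- occ(c(0, 1, 1, 1), N = 2)    # no detachments observed
  rp <- per_cell_rates(count_transitions(list(s)))
  expect_true(is.nan(rp$affinity[rp$n == 1]))
})

test_that("contact labelling is a deterministic distance threshold", {
  df <- data.frame(droplet_id = "d", cell_id = "c", t_min = c(0, 2, 4),
                   x_um = c(0, 45, 51), y_um = 0, z_um = 0)
  tr <- ctl_tracks(df)
  lab <- label_contacts(tr, spheroid_radius = 40, margin = 10)
  expect_identical(as.data.frame(lab)$on_spheroid, c(TRUE, TRUE, FALSE))
  expect_error(label_contacts(tr, spheroid_radius = NULL), "geometry")
})

test_that("occupancy built from labels gives the unit-step series", {
  df <- data.frame(droplet_id = "d", cell_id = "c1",
                   t_min = seq(0, 8, by = 2),
                   x_um = c(200, 100, 10, 5, 0), y_um = 0, z_um = 0)
  tr <- label_contacts(ctl_tracks(df), spheroid_radius = 40, margin = 10)
  co <- build_occupancy(tr)
  expect_identical(co$occupancy[[1]]$n_t, c(0L, 0L, 1L, 1L, 1L))
})

test_that("rate estimates recover generative truth within sampling error", {
  # constant-rate cohort in the small-probability regime; every
  # qualified level must sit within max(10% of truth, 3 binomial SE) of
  # the generating rate, and the heavily observed levels within 10%
  cfg <- sim_config("ova", duration = 840, delta_t = 1, ctl_mean = 5,
                    lambda_in = rep(0.01, 26), lambda_out = rep(0.02, 26),
                    gamma = rep(0, 26))
  co <- generate_cohort(cfg, 150, seed = 71)
  tc <- count_transitions(co)
  rp <- per_cell_rates(tc, method = "stratified")
  frames <- vapply(rp$n, function(n)
    sum(tc$per_droplet$frames[tc$per_droplet$n == n]), numeric(1))
  for (i in which(frames >= 200)) {
    if (!is.na(rp$lambda_in[i]) && rp$att[i] > 0) {
      se <- rp$lambda_in[i] / sqrt(rp$att[i])
      expect_lt(abs(rp$lambda_in[i] - 0.01), max(0.1 * 0.01, 3 * se))
    }
    if (rp$n[i] >= 1 && !is.na(rp$lambda_out[i]) && rp$det[i] > 0) {
      se <- rp$lambda_out[i] / sqrt(rp$det[i])
      expect_lt(abs(rp$lambda_out[i] - 0.02), max(0.1 * 0.02, 3 * se))
    }
  }
  # well-populated levels (>= 900 events) meet the 10% band outright
  strong <- which(!is.na(rp$att) & rp$att >= 900)
  expect_gte(length(strong), 2)
  for (i in strong)
    expect_lt(abs(rp$lambda_in[i] / 0.01 - 1), 0.1)
})

test_that("sequential conditioning removes the detach-first bias", {
  # with detachments drawn before attachments, the raw attachment
  # fraction estimates (1 - p_out) p_in; the conditioned estimator must
  # beat the raw one where detachments are frequent
  cfg <- sim_config("ova", duration = 840, delta_t = 1, ctl_mean = 5,
                    lambda_in = rep(0.01, 26), lambda_out = rep(0.02, 26),
                    gamma = rep(0, 26))
  co <- generate_cohort(cfg, 150, seed = 77)
  tc <- count_transitions(co)
  seq_fit <- per_cell_rates(tc, method = "stratified")
  raw_fit <- per_cell_rates(tc, method = "stratified",
                            conditioning = "none")
  lv <- which(seq_fit$n %in% 2:4)
  err_seq <- mean(abs(seq_fit$lambda_in[lv] / 0.01 - 1))
  err_raw <- mean(abs(raw_fit$lambda_in[lv] / 0.01 - 1))
  expect_lt(err_seq, err_raw)
  # the predicted suppression factor: raw/seq ~ 1 - p_out(n)
  p_out <- 1 - exp(-seq_fit$n[lv] * 0.02)
  expect_equal(raw_fit$lambda_in[lv] / seq_fit$lambda_in[lv],
               1 - p_out, tolerance = 0.02)
})

test_that("bootstrap spread is sane for an unbiased estimator", {
  # 70% no-replacement subsamples spread ~0.65 sigma around the full
  # estimate, so the IQR box should cover truth in roughly a third of
  # rows -- far from never and far from always
  cfg <- sim_config("ova", duration = 840, delta_t = 1, ctl_mean = 5,
                    lambda_in = rep(0.01, 26), lambda_out = rep(0.02, 26),
                    gamma = rep(0, 26))
  co <- generate_cohort(cfg, 150, seed = 79)
  rp <- bootstrap_rates(co, reps = 50, fraction = 0.7, seed = 80,
                        method = "stratified")
  tc <- count_transitions(co)
  frames <- vapply(rp$n, function(n)
    sum(tc$per_droplet$frames[tc$per_droplet$n == n]), numeric(1))
  qual <- which(frames >= 500)
  bs <- attr(rp, "bootstrap")$summary
  covered <- c(
    vapply(qual, function(i) isTRUE(bs$lambda_in[i, "q25"] <= 0.01 &&
                                      0.01 <= bs$lambda_in[i, "q75"]),
           logical(1)),
    vapply(qual[rp$n[qual] >= 1], function(i)
      isTRUE(bs$lambda_out[i, "q25"] <= 0.02 &&
               0.02 <= bs$lambda_out[i, "q75"]), logical(1)))
  expect_gte(mean(covered), 0.15)
  expect_lte(mean(covered), 0.95)
})

test_that("cooperative truth shows an increasing affinity ratio", {
  cfg <- sim_config("ova", duration = 840, gamma = rep(0, 26))
  co <- generate_cohort(cfg, 150, seed = 73)
  rp <- per_cell_rates(count_transitions(co))
  # restrict to the range where the generative lambda_in still grows
  # (the preset saturates at n = 10) and exposure is substantial
  ok <- !is.na(rp$affinity) & is.finite(rp$affinity) &
    rp$exposure_out >= 2000 & rp$n <= 10
  aff <- rp$affinity[ok]
  expect_gte(length(aff), 4)
  expect_true(all(diff(aff) > 0))
  # detachment stays flat: normalized lambda_out within noise of 1
  nout <- rp$normalized_out[ok]
  expect_true(all(abs(nout - 1) < 0.25))
})

test_that("bootstrap is reproducible and degenerates to the point estimate", {
  cfg <- sim_config("ova", duration = 400)
  co <- generate_cohort(cfg, 12, seed = 5)
  b1 <- bootstrap_rates(co, reps = 10, fraction = 0.7, seed = 99)
  b2 <- bootstrap_rates(co, reps = 10, fraction = 0.7, seed = 99)
  expect_identical(attr(b1, "bootstrap")$draws, attr(b2, "bootstrap")$draws)
  full <- bootstrap_rates(co, reps = 1, fraction = 1, seed = 1)
  point <- per_cell_rates(count_transitions(co))
  expect_equal(attr(full, "bootstrap")$draws$lambda_in[1, ],
               point$lambda_in)
  expect_error(bootstrap_rates(co$occupancy[1:2], reps = 5, fraction = 0.7,
                               seed = 1), "at least 3")
})

test_that("master equation reproduces the telegraph closed form", {
  lam <- rep(0.05, 2)
  t <- seq(0, 60, by = 5)
  P <- master_equation_forward(lam, lam, N = 1, times = t, init = 0L)
  expect_equal(P[, 2], 0.5 * (1 - exp(-0.1 * t)), tolerance = 1e-6)
  expect_equal(rowSums(P), rep(1, length(t)), tolerance = 1e-8)
  # absorbing empty state when attachment is impossible
  P0 <- master_equation_forward(rep(0, 8), rep(0.05, 8), N = 7,
                                times = c(0, 50), init = 0L)
  expect_equal(P0[, 1], c(1, 1), tolerance = 1e-10)
  expect_error(master_equation_forward(rep(-1, 3), rep(0, 3), 2, 0:2),
               "negative")
})
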
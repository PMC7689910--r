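# Decay fitting, hetNOE, reduced spectral density mapping and grouping.

test_that("delay schedules match the experimental design", {
  d1 <- t1_delay_schedule()
  d2 <- t2_delay_schedule()
  expect_equal(length(unique(d1)), 10L)
  expect_equal(range(d1), c(0.01, 2))
  expect_equal(length(unique(d2)), 11L)
  expect_equal(range(d2), c(0.03, 1.36))
  # one delay recorded twice for reproducibility checking
  expect_equal(sum(duplicated(d1)), 1L)
  expect_equal(sum(duplicated(d2)), 1L)
})

test_that("noiseless exponential decays are fitted exactly", {
  d <- t2_delay_schedule()
  ser <- decay_series(rep(1L, length(d)), d, exp(-2.0 * d), "T2")
  fit <- fit_exponential_decay(ser)
  expect_equal(fit$rate, 2.0, tolerance = 1e-6)
  expect_equal(fit$flag, "ok")
})

test_that("rate fits are unbiased under noise and flag bad series", {
  set.seed(3)
  d <- t1_delay_schedule()
  est <- replicate(100, {
    ser <- decay_series(rep(1L, length(d)), d,
                        10 * exp(-0.5 * d) + rnorm(length(d), 0, 0.1), "T1")
    fit_exponential_decay(ser)$rate
  })
  expect_lt(abs(mean(est) - 0.5), 0.02)
  # increasing intensities are unfittable
  ser_up <- decay_series(rep(1L, 11), seq(0.03, 1.36, length.out = 11),
                         seq(1, 2, length.out = 11), "T2")
  expect_equal(fit_exponential_decay(ser_up)$flag, "unfittable")
  # discrepant duplicate delay flags irreproducibility
  d2 <- t2_delay_schedule()
  dup <- d2[duplicated(d2)]
  i <- exp(-2 * d2) + rnorm(length(d2), 0, 0.001)
  i[which(d2 == dup)[2]] <- i[which(d2 == dup)[1]] + 0.5
  ser_bad <- decay_series(rep(1L, length(d2)), d2, i, "T2")
  expect_equal(fit_exponential_decay(ser_bad)$flag, "irreproducible")
})

test_that("rate fitting is scale invariant and time-rescaling equivariant", {
  set.seed(4)
  d <- t2_delay_schedule()
  i <- 7 * exp(-1.3 * d) + rnorm(length(d), 0, 0.01)
  r1 <- fit_exponential_decay(decay_series(rep(1L, length(d)), d, i))$rate
  r_scaled <- fit_exponential_decay(
    decay_series(rep(1L, length(d)), d, 100 * i))$rate
  expect_equal(r_scaled, r1, tolerance = 1e-8)
  k <- 2.5
  r_time <- fit_exponential_decay(
    decay_series(rep(1L, length(d)), k * d, i))$rate
  expect_equal(r_time, r1 / k, tolerance = 1e-8)
})

test_that("hetNOE is the saturated/unsaturated intensity ratio", {
  sat <- data.frame(residue_index = 1:3, intensity = c(1.0, 0.5, -0.2))
  unsat <- data.frame(residue_index = 1:3, intensity = c(1.0, 1.0, 1.0))
  out <- het_noe(sat, unsat)
  expect_equal(out$noe, c(1.0, 0.5, -0.2))
  # unsaturated intensity at the noise floor -> undefined
  unsat$intensity[2] <- 0.001
  expect_message(out2 <- het_noe(sat, unsat, noise = 0.01), "undefined")
  expect_true(is.na(out2$noe[2]))
})

test_that("highly mobile residues give negative NOEs at high field", {
  r <- modelfree_rates(0.2, 1e-9, 50e-12, 0, spectrometer_context(700.17))
  expect_lt(r$noe, 0)
})

test_that("reduced mapping inverts the forward model across the IDP regime", {
  ctx <- spectrometer_context(700.17)
  omega <- c(0, ctx$omega_N, 0.87 * ctx$omega_H)
  for (S2 in c(0.2, 0.5, 0.8, 0.95)) {
    for (tau_c in c(2e-9, 5e-9, 10e-9)) {
      rec <- exact_relaxation_record(S2, tau_c, ctx = ctx)
      jm <- reduced_spectral_density(rec, n_mc = 0)
      truth <- modelfree_J(omega, S2, tau_c, 50e-12)
      expect_equal(c(jm$J0, jm$JwN, jm$JwH087), truth,
                   tolerance = 0.05, ignore_attr = TRUE)
    }
  }
})

test_that("hetNOE of exactly 1 forces J(0.87wH) = 0", {
  ctx <- spectrometer_context()
  rec <- exact_relaxation_record(0.9, 5e-9, ctx = ctx)
  rec$noe <- 1
  jm <- reduced_spectral_density(rec, n_mc = 0)
  expect_identical(jm$JwH087, 0)
})

test_that("exchange only inflates J(0)", {
  ctx <- spectrometer_context()
  jm0 <- reduced_spectral_density(exact_relaxation_record(0.8, 4e-9, ctx = ctx),
                                  n_mc = 0)
  jm5 <- reduced_spectral_density(
    exact_relaxation_record(0.8, 4e-9, Rex = 5, ctx = ctx), n_mc = 0)
  expect_gt(jm5$J0, jm0$J0)
  expect_equal(jm5$JwN, jm0$JwN, tolerance = 1e-12)
  expect_equal(jm5$JwH087, jm0$JwH087, tolerance = 1e-12)
})

test_that("hetNOE above 1 clamps J(0.87wH) to zero with a warning", {
  ctx <- spectrometer_context()
  rec <- exact_relaxation_record(0.9, 5e-9, ctx = ctx)
  rec$noe <- 1.2
  expect_warning(jm <- reduced_spectral_density(rec, n_mc = 0), "clamped")
  expect_identical(jm$JwH087, 0)
  expect_true(jm$clamped)
})

test_that("the single-motion curve has the closed-form shape", {
  ctx <- spectrometer_context()
  tau_star <- 1 / ctx$omega_N
  sm <- single_motion_curve(ctx, tau = tau_star)
  expect_equal(sm$JwN, sm$J0 / 2)
  grid <- single_motion_curve(ctx, tau = 10^seq(-12, -7, length.out = 2000))
  expect_false(is.unsorted(grid$J0))  # monotone in J(0)
  # J(wN) attains its maximum at tau = 1/wN
  expect_equal(grid$tau[which.max(grid$JwN)], tau_star, tolerance = 0.01)
  expect_lte(max(grid$JwN), 0.2 / ctx$omega_N + 1e-15)
  tiny <- single_motion_curve(ctx, tau = 1e-15)
  expect_lt(tiny$J0, 1e-15)
  expect_lt(tiny$JwN, 1e-15)
})

test_that("rigid-limit residues sit on the single-motion curve", {
  ctx <- spectrometer_context()
  for (tau_c in c(3e-9, 6e-9, 9e-9)) {
    jm <- reduced_spectral_density(
      exact_relaxation_record(1, tau_c, ctx = ctx), n_mc = 0)
    curve_JwN <- single_motion_curve(ctx, tau = jm$J0 / 0.4)$JwN
    expect_equal(jm$JwN, curve_JwN, tolerance = 0.02)
  }
})

test_that("mobility grouping recovers well-separated levels and matches a partition oracle", {
  ctx <- spectrometer_context()
  set.seed(9)
  J0 <- rep(c(0.3, 0.8, 2, 4) * 1e-9, each = 10) *
    (1 + rnorm(40, 0, 0.02))
  jm <- data.frame(residue_index = 1:40, J0 = J0, JwN = 0.2e-9,
                   JwH087 = 5e-12, clamped = FALSE)
  attr(jm, "context") <- ctx
  class(jm) <- c("spectral_density_map", "data.frame")
  out <- group_residues(jm)
  expect_equal(as.integer(out$group), rep(1:4, each = 10))
  expect_equal(as.integer(out$group), oracle_partition4(J0))
})

test_that("degenerate grouping falls back to a single group with a warning", {
  ctx <- spectrometer_context()
  jm <- data.frame(residue_index = 1:6, J0 = rep(2e-9, 6), JwN = 0.2e-9,
                   JwH087 = 5e-12, clamped = FALSE)
  attr(jm, "context") <- ctx
  class(jm) <- c("spectral_density_map", "data.frame")
  expect_warning(out <- group_residues(jm), "single-group")
  expect_true(all(out$group == "I"))
})

test_that("J(0) far above the single-motion locus flags exchange", {
  ctx <- spectrometer_context()
  sm <- single_motion_curve(ctx, tau = c(1e-9, 2e-9, 4e-9, 8e-9))
  jm <- data.frame(residue_index = 1:4, J0 = sm$J0, JwN = sm$JwN,
                   JwH087 = 0, clamped = FALSE)
  jm$J0[4] <- 3 * jm$J0[4]  # constructed exchange case
  attr(jm, "context") <- ctx
  class(jm) <- c("spectral_density_map", "data.frame")
  out <- group_residues(jm, boundaries = c(1e-10, 5e-10, 2e-9))
  expect_equal(out$exchange_suspect, c(FALSE, FALSE, FALSE, TRUE))
})
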
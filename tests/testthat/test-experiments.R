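test_that("bias slope recovers -(1 - alpha) exactly on the closed form", {
  mus <- seq(12, 28, length.out = 30)
  for (alpha in c(0, 0.25, 0.6, 1)) {
    b <- compute_bias(synthetic_alpha_result(alpha, mus), drop_frac = 0)
    expect_equal(b$slope, -(1 - alpha), tolerance = 1e-10)
  }
  # output pinned at the global mean: full contraction, slope -1
  full <- synthetic_alpha_result(0, mus)
  expect_equal(compute_bias(full, drop_frac = 0)$slope, -1, tolerance = 1e-10)
  # degenerate design: identical trial means
  expect_error(compute_bias(synthetic_alpha_result(0.5, rep(15, 10)),
                            drop_frac = 0), "identical")
})

test_that("simulated bias is positive below and negative above the mean", {
  net <- test_network("MFN1")
  proto <- protocol_preset("fig5A_high", seed = 31)
  proto$n_trials <- 100L
  b <- compute_bias(run_simulation(net, proto))
  expect_lt(b$slope, 0)
  lo <- b$trials$bias[b$trials$mu < quantile(b$trials$mu, 0.3)]
  hi <- b$trials$bias[b$trials$mu > quantile(b$trials$mu, 0.7)]
  expect_gt(mean(lo), 0)
  expect_lt(mean(hi), 0)
})

test_that("bias grows with stimulus variance and shrinks with trial variance", {
  net <- test_network("MFN1")
  shrink <- function(nm, n = 100, seed = 31) {
    p <- protocol_preset(nm, seed = seed)
    p$n_trials <- as.integer(n)
    p
  }
  sw <- bias_factor_sweeps(net, list(
    sigma_low = shrink("fig5A_low"), sigma_high = shrink("fig5A_high")),
    seed = 5)
  expect_true(all(is.na(sw$error)))
  expect_gt(sw$abs_slope[sw$design == "sigma_high"],
            sw$abs_slope[sw$design == "sigma_low"])
  tv <- bias_factor_sweeps(net, list(
    trial_low = stimulus_protocol(100, 10, 500, uniform_from_moments(20, 2), 9),
    trial_high = stimulus_protocol(100, 10, 500, uniform_from_moments(20, 25), 9)),
    seed = 6)
  expect_gt(tv$abs_slope[tv$design == "trial_low"],
            tv$abs_slope[tv$design == "trial_high"])
})

test_that("bias is insensitive to the crossed variance when the other is zero", {
  net <- test_network("MFN1")
  resize <- function(nm) {
    p <- protocol_preset(nm, seed = 31)
    p$n_trials <- 150L
    p
  }
  # zero stimulus variance: trial-to-trial spread does not change the slope
  c5 <- bias_factor_sweeps(net, list(narrow = resize("fig5C_narrow"),
                                     wide = resize("fig5C_wide")), seed = 7)
  expect_lt(abs(c5$abs_slope[1] - c5$abs_slope[2]) / max(c5$abs_slope), 0.3)
  # zero trial variance: stimulus noise level does not change the slope much
  d5 <- bias_factor_sweeps(net, list(lo = resize("fig5D_low"),
                                     hi = resize("fig5D_high")), seed = 8)
  expect_lt(abs(d5$abs_slope[1] - d5$abs_slope[2]) / max(d5$abs_slope), 0.5)
})

test_that("longer trials reduce the contraction bias", {
  net <- test_network("MFN1")
  mk <- function(n_steps) {
    p <- protocol_preset("fig5E_trial", seed = 31)
    p$n_trials <- 100L
    p$n_steps <- as.integer(n_steps)
    p
  }
  sw <- bias_factor_sweeps(net, list(d5s = mk(500), d10s = mk(1000)), seed = 9)
  expect_gt(sw$abs_slope[sw$design == "d5s"],
            sw$abs_slope[sw$design == "d10s"])
})

test_that("sensory weight dips after trial onset and recovers within the trial", {
  net <- test_network("MFN1")
  for (nm in c("fig3F_5s", "fig3F_1s")) {
    ta <- time_resolved_alpha(run_simulation(net, protocol_preset(nm,
                                                                  seed = 21)))
    n <- nrow(ta)
    end <- mean(tail(ta$alpha_mean, max(1, n %/% 20)))
    expect_gt(end - min(ta$alpha_mean), 0.01)
    expect_lt(which.min(ta$alpha_mean), 0.7 * n)   # dip early in the trial
    expect_true(all(ta$alpha_sem >= 0))
  }
  # stationary control (no trial-to-trial change): flat time course
  ctrl <- run_simulation(net, stimulus_protocol(60, 10, 500, c(5, 5), 5,
                                                seed = 22))
  tc <- time_resolved_alpha(ctrl)
  expect_lt(max(tc$alpha_mean) - min(tc$alpha_mean), 0.05)
})

test_that("steady-state alpha is monotone across the variance grid", {
  net <- test_network("MFN1")
  grid <- sweep_variance_grid(net, sigma2_in_grid = c(0, 5, 15),
                              sigma2_trial_grid = c(0, 5, 15),
                              n_trials = 100, seed = 13)
  expect_true(all(is.na(grid$error)))
  a <- matrix(grid$alpha, 3, 3)   # rows: sigma2_in, cols: sigma2_trial
  # alpha decreases with stimulus noise at fixed trial variance
  for (j in 1:3) expect_true(all(diff(a[, j]) < 0.02))
  # increasing in trial variance at fixed stimulus noise; the noiseless
  # corner (both variances zero) is the degenerate perfect-representation
  # limit (alpha = 1) and sits above the rest of its row, so the row check
  # starts beyond it
  for (i in 1:3) {
    row <- if (i == 1) a[1, 2:3] else a[i, ]
    expect_true(all(diff(row) > -0.02))
  }
  # corner cases: noiseless input is represented faithfully,
  # equal nonzero variances weight both streams comparably
  expect_gt(a[1, 1], 0.95)
  expect_gt(a[1, 3], 0.7)
  expect_lt(a[3, 1], 0.3)
  expect_lt(abs(a[2, 2] - 0.5), 0.15)
})

test_that("perturbation experiment reports baseline and perturbed windows", {
  net <- test_network("MFN1")
  pe <- perturbation_experiment(net, "sensory", targets = list("PV"),
                                strengths = c(0, 0.5), n_trials = 60,
                                seed = 17)
  expect_equal(nrow(pe), 2)
  expect_equal(pe$delta_alpha, pe$alpha_pert - pe$alpha_base)
  # zero-strength modulation leaves the weighting unchanged (drifts only)
  expect_lt(abs(pe$delta_alpha[pe$strength == 0]), 0.1)
  expect_lt(pe$delta_alpha[pe$strength == 0.5], -0.1)
  expect_error(perturbation_experiment(net, "sensory",
                                       targets = list("nope")), "unknown")
})
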
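test_that("sensory weight follows the variance ratio with its limit cases", {
  expect_equal(sensory_weight(1, 1), 0.5)
  expect_equal(sensory_weight(0, 3), 1)
  expect_equal(sensory_weight(3, 1), 0.25)
  expect_equal(sensory_weight(0, 0), 1)       # perfect representation
  expect_equal(sensory_weight(2, 0), 0)       # perfectly reliable prediction
  a <- sensory_weight(c(1, 0, 3, 0), c(1, 3, 1, 0))
  expect_equal(a, c(0.5, 1, 0.25, 1))
  expect_true(all(a >= 0 & a <= 1))
  expect_error(sensory_weight(-1, 1), "nonnegative")
})

test_that("weighted output is the convex combination of input and prediction", {
  expect_equal(weighted_output(3, 8, 1), 3)
  expect_equal(weighted_output(3, 8, 0), 8)
  expect_equal(weighted_output(4, 8, 0.25), 7)
  s <- runif(20, 0, 10)
  m <- runif(20, 0, 10)
  a <- runif(20)
  ro <- weighted_output(s, m, a)
  expect_true(all(ro >= pmin(s, m) - 1e-12 & ro <= pmax(s, m) + 1e-12))
  expect_error(weighted_output(1, 2, 1.2), "0, 1")
})

test_that("network building normalizes memory and variance weights by gain", {
  net <- test_network("MFN1")
  expect_equal(unname(net$w_V_high["nPE"] * net$g_nPE), 1)
  expect_equal(unname(net$w_V_low["pPE"] * net$g_dyn_pPE), 1)
  expect_equal(unname(net$w_M_low["nPE"]),
               net$lambda_low / (net$g_nominal * net$g_dyn_nPE))
  expect_equal(effective_tau_M(net, "low"),
               net$tau_E_M * net$g_nominal / net$lambda_low)
  # higher-level memory is slower than the lower-level one
  expect_gt(effective_tau_M(net, "high"), effective_tau_M(net, "low"))
})

test_that("R network stepper matches the compiled hierarchy integrator", {
  net <- test_network("MFN1")
  proto <- stimulus_protocol(1, 1, 40, 6, 0, seed = 5)   # constant 40-ms drive
  sim <- run_simulation(net, proto, record_every = 0)
  st <- network_state(net)
  for (i in 1:40) st <- step_network(st, net, 6, dt = 1)
  sc <- sim$scalars
  expect_equal(st$r_M_low, sc$rM_low[40], tolerance = 1e-12)
  expect_equal(st$r_V_low, sc$rV_low[40], tolerance = 1e-12)
  expect_equal(st$r_M_high, sc$rM_high[40], tolerance = 1e-12)
  expect_equal(st$r_V_high, sc$rV_high[40], tolerance = 1e-12)
})

test_that("constant input drives the hierarchy to its noiseless fixed point", {
  net <- test_network("MFN1")
  proto <- stimulus_protocol(1, 1, 30000, 5, 0, seed = 1)
  sim <- run_simulation(net, proto)
  last <- tail(sim$scalars, 1)
  expect_equal(last$rM_low, 5, tolerance = 0.01)
  expect_lt(last$rV_low, 0.01)
  # lower PE rates back at baseline
  expect_lt(max(tail(sim$rates_low, 1)[, 1:2]), 1e-3)
  # zero-input run stays at the calibrated fixed point throughout
  z <- run_simulation(net, stimulus_protocol(1, 1, 2000, 0, 0))
  expect_lt(max(abs(z$scalars$rM_low)), 1e-6)
  expect_lt(max(abs(sweep(tail(z$rates_low, 1), 2,
                          c(0, 0, 0, 0, 4, 4, 4, 4)))), 0.02)
})

test_that("circuit memory follows the closed-form EMA oracle", {
  # 10 piecewise-constant segments; compare segment-end values against the
  # exact exponential-moving-average solution warm-started after the initial
  # zero-state transient
  net <- test_network("MFN1")
  set.seed(31)
  vals <- runif(10, 2.5, 7.5)
  low <- net$lower
  out <- pecircuit:::sim_hier_cpp(
    low$W, low$w_ff, low$w_fb, low$I_bg,
    low$W, low$w_ff, low$w_fb, low$I_bg, low$tau,
    net$w_M_low["nPE"], net$w_M_low["pPE"],
    net$w_M_high["nPE"], net$w_M_high["pPE"],
    net$w_V_low["nPE"], net$w_V_low["pPE"],
    net$w_V_high["nPE"], net$w_V_high["pPE"],
    net$tau_E_M, net$tau_V, rep(vals, each = 500),
    rep(0, 8), rep(0, 8), 0L, 1, 0L, 1L)
  ends <- out$rM_low[seq(500, 5000, by = 500)]
  oracle <- ema_closed_form(vals[4:10], rep(500, 7),
                            effective_tau_M(net, "low"), r_M0 = ends[3])
  # PE neurons lag value onsets by tens of ms, so segment ends agree to
  # within a few percent of the segment-to-segment swing
  expect_lt(max(abs(ends[4:10] - oracle)), 0.15)
})

test_that("common scaling of both memory scales matters less than asymmetric", {
  circ <- test_circuit("MFN1")
  proto <- protocol_preset("fig3E", seed = 61)
  proto$n_trials <- 60L
  base <- build_network("MFN1", circuit = circ)
  common <- build_network("MFN1", lambda_low = 9e-2, lambda_high = 1.4e-3,
                          circuit = circ)
  asym <- build_network("MFN1", lambda_low = 9e-2, circuit = circ)
  a0 <- steady_alpha(run_simulation(base, proto))
  d_common <- abs(steady_alpha(run_simulation(common, proto)) - a0)
  d_asym <- abs(steady_alpha(run_simulation(asym, proto)) - a0)
  expect_lt(d_common, d_asym)
})

test_that("equal PE baseline offsets inflate variance but barely move the mean", {
  circ <- test_circuit("MFN1")
  net <- build_network("MFN1", lambda_low = 3e-3, circuit = circ)
  offset <- circ
  offset$I_bg[1:2] <- offset$I_bg[1:2] + 0.5   # both somas +0.5 at baseline
  net_off <- net
  net_off$lower <- offset
  proto <- protocol_preset("fig2DE", seed = 41)
  r0 <- run_simulation(net, proto, levels = 1)
  r1 <- run_simulation(net_off, proto, levels = 1)
  tail_mean <- function(r, col) mean(tail(r$scalars[[col]], 10000))
  expect_lt(abs(tail_mean(r1, "rM_low") - tail_mean(r0, "rM_low")), 0.3)
  expect_gt(tail_mean(r1, "rV_low"), tail_mean(r0, "rV_low") + 2)
})
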
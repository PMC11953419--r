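test_that("all three variants build into validated PE circuits", {
  for (v in mfn_variants()) {
    circ <- test_circuit(v)
    rep <- verify_pe_responses(circ)
    expect_true(rep$pass, info = v)
    expect_gt(rep$gain_nPE, 0)
    expect_gt(rep$gain_pPE, 0)
    # Dale's sign pattern: excitatory columns nonnegative, inhibitory
    # columns nonpositive
    expect_true(all(circ$W[, 1:4] >= 0), info = v)
    expect_true(all(circ$W[, 5:8] <= 0), info = v)
    # compartment targeting: PV inhibits only somas, SOM the only
    # inhibitor of dendrites
    expect_true(all(circ$W[3:4, 5:6] == 0), info = v)
    expect_true(all(circ$W[3:4, 8] == 0), info = v)
    expect_true(all(circ$W[3:4, 7] < 0), info = v)
    expect_true(circ$W[7, 8] < 0 && circ$W[8, 7] < 0, info = v)
    # input routing complementarity
    expect_equal(circ$w_ff, 1 - circ$w_fb)
    expect_equal(circ$w_ff[c(1, 2, 5)], c(1, 1, 1))  # somas + PV1 feedforward
    expect_equal(circ$w_fb[c(3, 4, 6)], c(1, 1, 1))  # dendrites + PV2 feedback
  }
  expect_error(build_mfn("MFN4"))
})

test_that("input routing distinguishes the three variants", {
  expect_equal(test_circuit("MFN1")$w_ff[7:8], c(1, 0))  # SOM ff, VIP fb
  expect_equal(test_circuit("MFN2")$w_ff[7:8], c(0, 1))  # swapped
  expect_equal(test_circuit("MFN3")$w_ff[7:8], c(1, 1))  # both ff
})

test_that("background calibration reaches the prescribed baseline", {
  circ <- test_circuit("MFN1")
  ss <- circuit_steady_state(circ, ff = 0, fb = 0, h0 = rep(0, 8))
  expect_true(ss$converged)
  expect_lt(max(abs(ss$r - c(0, 0, 0, 0, 4, 4, 4, 4))), 0.01)
  # idempotence: recalibrating the calibrated circuit returns the same I_bg
  expect_equal(calibrate_background(circ), circ$I_bg, tolerance = 1e-10)
  # with no internal connections the fixed point is the input itself
  dec <- decoupled_circuit()
  expect_equal(calibrate_background(dec, target_baselines = rep(2, 8)),
               rep(2, 8))
})

test_that("a decoupled excitatory unit relaxes with the 60-ms time constant", {
  dec <- decoupled_circuit()
  tr <- pecircuit:::sim_circuit_cpp(dec$W, dec$w_ff, dec$w_fb, dec$I_bg, dec$tau,
                        ff = rep(1, 300), fb = rep(0, 300), rep(0, 8),
                        rep(0, 8), 1)
  t <- 1:300
  expect_equal(tr$rates[, 1], 1 - exp(-t / 60), tolerance = 1e-4)
  # interneuron entries relax with tau_I = 2 ms
  expect_equal(tr$rates[, 5], 1 - exp(-t / 2), tolerance = 1e-2)
})

test_that("PE somas stay balanced under common input shifts (E/I balance)", {
  for (v in mfn_variants()) {
    circ <- test_circuit(v)
    for (c0 in c(2, 5, 8)) {
      r <- circuit_steady_state(circ, ff = c0, fb = c0)$r
      expect_lt(max(abs(r[1:2])), 1e-3)
      expect_true(all(r[5:8] > 0))   # interneurons stay active
    }
  }
})

test_that("R reference stepper agrees with the compiled trajectory", {
  circ <- test_circuit("MFN2")
  n <- 60
  ff <- 5 + sin(seq_len(n) / 5)
  fb <- rep(4.5, n)
  cpp <- pecircuit:::sim_circuit_cpp(circ$W, circ$w_ff, circ$w_fb, circ$I_bg, circ$tau,
                         ff, fb, rep(0, 8), circ$baseline, 1)
  st <- list(h = circ$baseline)
  for (i in seq_len(n)) st <- step_circuit(st, circ, ff[i], fb[i], dt = 1)
  expect_equal(st$h, cpp$h, tolerance = 1e-12)
})

test_that("RK2 trajectories self-converge with 2nd-order error scaling", {
  circ <- test_circuit("MFN1")
  run <- function(dt) {
    st <- list(h = circ$baseline)
    for (i in seq_len(100 / dt)) st <- step_circuit(st, circ, 6, 5, dt = dt)
    st$h
  }
  ref <- run(0.01)
  e1 <- max(abs(run(1) - ref))
  e2 <- max(abs(run(0.5) - ref))
  expect_gt(e1 / e2, 3)
  expect_lt(e1 / e2, 6)
  expect_lt(e1, 0.05)
})

test_that("PE responses are one-sided with slopes matching the linear fit", {
  circ <- test_circuit("MFN1")
  rep <- verify_pe_responses(circ)
  fits <- fit_baseline_gain(circ)
  expect_equal(fits$slope[fits$neuron == "nPE"], rep$gain_nPE,
               tolerance = 0.05)
  expect_equal(fits$slope[fits$neuron == "pPE"], rep$gain_pPE,
               tolerance = 0.05)
  expect_lt(max(abs(fits$intercept)), 0.02)   # baseline at zero
})

test_that("PV activation decreases both baseline and gain of the PE neurons", {
  for (v in mfn_variants()) {
    circ <- test_circuit(v)
    f0 <- fit_baseline_gain(circ)
    # moderate drive: strong enough to shift the balance, weak enough that
    # responses are not fully silenced over the probe range
    f1 <- fit_baseline_gain(circ, pert = perturbation_spec("PV", 0.2))
    expect_true(all(f1$intercept < f0$intercept - 0.01), info = v)
    expect_true(all(f1$slope < f0$slope - 0.01), info = v)
  }
})

test_that("perturbation specs validate their targets and map to inputs", {
  pv <- perturbation_spec("PV", 0.3)
  expect_equal(pecircuit:::pert_vector(pv), c(0, 0, 0, 0, 0.3, 0.3, 0, 0))
  both <- perturbation_spec(c("SOM", "VIP"), 0.5)
  expect_equal(pecircuit:::pert_vector(both), c(0, 0, 0, 0, 0, 0, 0.5, 0.5))
  expect_error(perturbation_spec("PYR"), "subset")
  expect_error(perturbation_spec("PV", -1), "nonnegative")
})

test_that("circuits serialize to JSON and back without behavioral change", {
  circ <- test_circuit("MFN3")
  path <- tempfile(fileext = ".json")
  write_circuit_json(circ, path)
  back <- read_circuit_json(path)
  expect_equal(back$W, circ$W, ignore_attr = TRUE)
  expect_equal(back$I_bg, circ$I_bg)
  expect_equal(back$w_ff, circ$w_ff)
  r1 <- circuit_steady_state(circ, 6, 5)$r
  r2 <- circuit_steady_state(back, 6, 5)$r
  expect_equal(r1, r2, tolerance = 1e-12)
})
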
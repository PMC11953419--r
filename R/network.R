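# Two-level hierarchy: a lower PE circuit driven by the sensory stimulus and
# a higher PE circuit driven by the lower memory neuron's activity. Each
# level has a memory neuron (perfect integrator: tau_E dr_M/dt =
# w_M<-pPE r_pPE - w_M<-nPE r_nPE) and a variance neuron (leaky integrator
# with quadratic activation, tau_V = 5 s). Weights onto M and V neurons are
# gain-normalized: w_M<-PE = lambda / g and w_V<-PE = 1 / g, with g the
# measured mismatch gain of the respective PE neuron.

#' Build the two-level hierarchy network
#'
#' Both subnetworks use the same validated microcircuit; they differ only in
#' the non-normalized memory weight `lambda`, which sets the effective
#' timescale `tau_E / lambda` at which each memory neuron integrates new
#' evidence (`lambda_high < lambda_low`, so the higher-level prediction is
#' slower). PE gains are measured from steady-state probes of the built
#' circuit and divide the memory and variance weights, making the memory
#' neuron an exponential moving average of its feedforward drive and the
#' variance neuron an estimator of that drive's variance.
#'
#' @param variant circuit variant, see [mfn_variants()].
#' @param lambda_low lower-level memory weight scale. The default 4.5e-2
#'   matches the trial-based experiments; use 3e-3 for the slow
#'   single-stream mean/variance estimation runs.
#' @param lambda_high higher-level memory weight scale (default 7e-4).
#' @param g_nominal nominal gain factor of the memory normalization. The
#'   memory weights are `lambda / (g_nominal * g)` with `g` the measured PE
#'   gain, which makes the effective memory timescale
#'   `tau_E * g_nominal / lambda` for every variant. The default 0.5 is the
#'   calibration at which the hierarchy weights sensory input and prediction
#'   equally when the within-trial and trial-to-trial variances match.
#' @param value_ms stimulus-value presentation duration (ms) at which the
#'   lower-level variance weights are calibrated via
#'   [measure_dynamic_gain()]; the higher level, whose feedforward drive
#'   varies slowly, uses the steady-state gains. Default 500 ms, the
#'   standard protocol value.
#' @param tau_V variance-neuron time constant in ms (default 5000).
#' @param circuit optionally pass a pre-built/validated `pe_circuit` to use
#'   for both levels.
#' @return An object of class `pe_network`.
#' @examples
#' net <- build_network("MFN1")
#' effective_tau_M(net, "low") # tau_E * g_nominal / lambda_low, in ms
#' @export
build_network <- function(variant = "MFN1", lambda_low = 4.5e-2,
                          lambda_high = 7e-4, g_nominal = 0.5,
                          value_ms = 500, tau_V = 5000, circuit = NULL) {
  stopifnot(lambda_low > 0, lambda_high > 0, g_nominal > 0, tau_V > 0)
  if (is.null(circuit)) circuit <- build_mfn(variant)
  ver <- verify_pe_responses(circuit)
  if (!ver$pass) stop("circuit failed PE-response validation")
  g_ss <- c(nPE = ver$gain_nPE, pPE = ver$gain_pPE)
  g_dyn <- measure_dynamic_gain(circuit, value_ms = value_ms)
  structure(list(
    lower = circuit, higher = circuit,
    lambda_low = lambda_low, lambda_high = lambda_high,
    g_nominal = g_nominal,
    g_nPE = unname(g_ss["nPE"]), g_pPE = unname(g_ss["pPE"]),
    g_dyn_nPE = unname(g_dyn["nPE"]), g_dyn_pPE = unname(g_dyn["pPE"]),
    w_M_low = lambda_low / (g_nominal * g_dyn),
    w_M_high = lambda_high / (g_nominal * g_ss),
    w_V_low = 1 / g_dyn,
    w_V_high = 1 / g_ss,
    tau_E_M = 60, tau_V = tau_V,
    variant = circuit$variant
  ), class = "pe_network")
}

#' @export
print.pe_network <- function(x, ...) {
  cat(sprintf("<pe_network> %s; lambda low %.3g / high %.3g\n", x$variant,
              x$lambda_low, x$lambda_high))
  cat(sprintf(" measured PE gains: nPE %.3f, pPE %.3f\n", x$g_nPE, x$g_pPE))
  cat(sprintf(" effective memory timescales: low %.3g s, high %.3g s\n",
              effective_tau_M(x, "low") / 1000,
              effective_tau_M(x, "high") / 1000))
  invisible(x)
}

#' Effective memory-neuron time constant
#'
#' With memory weights `lambda / (g_nominal * g)` and PE mismatch gain `g`,
#' the memory neuron obeys `tau_E dr_M/dt = (lambda / g_nominal) (s - r_M)`
#' in the one-sided PE regime, i.e. an exponential moving average with time
#' constant `tau_E * g_nominal / lambda`.
#'
#' @param net a `pe_network`.
#' @param level `"low"` or `"high"`.
#' @return Time constant in ms.
#' @export
effective_tau_M <- function(net, level = c("low", "high")) {
  level <- match.arg(level)
  net$tau_E_M * net$g_nominal /
    switch(level, low = net$lambda_low, high = net$lambda_high)
}

#' Sensory weight from the two variance read-outs
#'
#' `alpha = (1 + r_V_low / r_V_high)^-1 = r_V_high / (r_V_low + r_V_high)`.
#' Degenerate cases follow the zero-variance limits: both variances zero
#' means the sensory input is perfectly reliable (`alpha = 1`); a zero
#' prediction variance with nonzero sensory variance gives `alpha = 0`.
#'
#' @param r_V_low lower-level (sensory) variance rate, >= 0.
#' @param r_V_high higher-level (prediction) variance rate, >= 0.
#' @return Sensory weight in `[0, 1]` (vectorized).
#' @export
sensory_weight <- function(r_V_low, r_V_high) {
  if (any(r_V_low < 0) || any(r_V_high < 0))
    stop("variance rates must be nonnegative")
  out <- r_V_high / (r_V_low + r_V_high)
  out[r_V_low == 0 & r_V_high == 0] <- 1
  out
}

#' Uncertainty-weighted output
#'
#' Convex combination `r_out = alpha s + (1 - alpha) r_M_low`, computed
#' arithmetically (it is not fed back into the dynamics).
#'
#' @param s sensory stimulus.
#' @param r_M_low lower-level memory (prediction) rate.
#' @param alpha sensory weight in `[0, 1]`.
#' @return The weighted output (vectorized).
#' @export
weighted_output <- function(s, r_M_low, alpha) {
  if (any(alpha < 0 | alpha > 1)) stop("alpha must lie in [0, 1]")
  alpha * s + (1 - alpha) * r_M_low
}

#' Zero-initialized network state
#'
#' All rates start at 0, matching the simulation convention.
#'
#' @param net a `pe_network` (unused fields tolerated).
#' @return List with `h_low`, `h_high` (length 8), `r_M_low`, `r_V_low`,
#'   `r_M_high`, `r_V_high`.
#' @export
network_state <- function(net = NULL) {
  list(h_low = rep(0, 8), h_high = rep(0, 8),
       r_M_low = 0, r_V_low = 0, r_M_high = 0, r_V_high = 0)
}

# full coupled RHS used by the R reference stepper
network_rhs <- function(state, net, s, pv_low, pv_high) {
  rl <- pmax(state$h_low, 0)
  low <- net$lower
  dhl <- as.numeric(-state$h_low + low$W %*% rl + low$w_fb * state$r_M_low +
                      low$w_ff * s + low$I_bg + pv_low) / low$tau
  dMl <- (net$w_M_low["pPE"] * rl[2] - net$w_M_low["nPE"] * rl[1]) / net$tau_E_M
  ul <- net$w_V_low["pPE"] * rl[2] + net$w_V_low["nPE"] * rl[1]
  dVl <- (-state$r_V_low + ul^2) / net$tau_V
  rh <- pmax(state$h_high, 0)
  high <- net$higher
  dhh <- as.numeric(-state$h_high + high$W %*% rh +
                      high$w_fb * state$r_M_high +
                      high$w_ff * state$r_M_low + high$I_bg + pv_high) /
    high$tau
  dMh <- (net$w_M_high["pPE"] * rh[2] - net$w_M_high["nPE"] * rh[1]) /
    net$tau_E_M
  uh <- net$w_V_high["pPE"] * rh[2] + net$w_V_high["nPE"] * rh[1]
  dVh <- (-state$r_V_high + uh^2) / net$tau_V
  list(h_low = dhl, h_high = dhh, r_M_low = unname(dMl),
       r_V_low = unname(dVl), r_M_high = unname(dMh), r_V_high = unname(dVh))
}

#' One RK2 step of the full hierarchy
#'
#' Reference R implementation of one explicit midpoint step of the coupled
#' system: the lower circuit sees `(ff = s, fb = r_M_low)`, the higher sees
#' `(ff = r_M_low, fb = r_M_high)`; memory neurons integrate without leak and
#' variance neurons as leaky integrators with quadratic activation. Variance
#' and memory rates are clipped at 0 after the step (numerical guard only).
#'
#' @param state a [network_state()].
#' @param net a `pe_network`.
#' @param s stimulus value over this step.
#' @param pert optional [perturbation_spec()]; its scope selects the level(s).
#' @param dt step size (ms).
#' @return The advanced state.
#' @export
step_network <- function(state, net, s, pert = NULL, dt = 1) {
  if (dt <= 0) stop("dt must be positive")
  pv <- scoped_pert_vectors(pert)
  k1 <- network_rhs(state, net, s, pv$low, pv$high)
  mid <- Map(function(x, d) x + dt / 2 * d, state, k1[names(state)])
  k2 <- network_rhs(mid, net, s, pv$low, pv$high)
  out <- Map(function(x, d) x + dt * d, state, k2[names(state)])
  if (any(!is.finite(unlist(out)))) stop("network state diverged (NaN/Inf)")
  out$r_V_low <- max(out$r_V_low, 0)
  out$r_V_high <- max(out$r_V_high, 0)
  out$r_M_low <- max(out$r_M_low, 0)
  out$r_M_high <- max(out$r_M_high, 0)
  out
}

# split a perturbation into per-level input vectors according to its scope
scoped_pert_vectors <- function(pert) {
  if (is.null(pert)) return(list(low = rep(0, 8), high = rep(0, 8)))
  v <- pert_vector(pert)
  scope <- if (inherits(pert, "perturbation_spec")) pert$scope else "both"
  list(low = if (scope %in% c("both", "lower")) v else rep(0, 8),
       high = if (scope %in% c("both", "higher")) v else rep(0, 8))
}
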
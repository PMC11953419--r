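#' Idealized prediction-error rates
#'
#' The defining rectified responses of idealized nPE and pPE neurons given
#' the current prediction `r_M` and stimulus `S`:
#' `r_nE = [r_M - S]_+` and `r_pE = [S - r_M]_+`. At most one of the two is
#' nonzero; both vanish when the input is fully predicted.
#'
#' @param r_M activity of the memory neuron (the prediction).
#' @param S feedforward stimulus value.
#' @return A list with numeric components `r_nE` and `r_pE` (vectorized over
#'   the inputs).
#' @examples
#' idealized_pe_rates(5, 3) # nPE = 2, pPE = 0
#' @export
idealized_pe_rates <- function(r_M, S) {
  list(r_nE = pmax(r_M - S, 0), r_pE = pmax(S - r_M, 0))
}

#' Parameters of the idealized mean/variance tracker
#'
#' `tau_M` is the effective time constant of the memory neuron. In the full
#' circuit the memory neuron is a perfect integrator driven by gain-normalized
#' PE weights `lambda / g`, which makes its effective constant
#' `tau_M = tau_E / lambda`; exposing it here keeps the idealized model and
#' the circuit mode directly comparable (see [effective_tau_M()]).
#'
#' @param tau_M memory time constant (ms), > 0.
#' @param tau_V variance-neuron time constant (ms), > 0. Default 5000 ms.
#' @return An object of class `idealized_params`.
#' @export
idealized_params <- function(tau_M, tau_V = 5000) {
  stopifnot(is.numeric(tau_M), tau_M > 0, is.numeric(tau_V), tau_V > 0)
  structure(list(tau_M = tau_M, tau_V = tau_V), class = "idealized_params")
}

#' State of the idealized model
#'
#' @param r_M memory (mean estimate) rate; finite.
#' @param r_V variance estimate (stimulus units squared); nonnegative.
#' @param t time (ms).
#' @return An object of class `idealized_state`.
#' @export
idealized_state <- function(r_M = 0, r_V = 0, t = 0) {
  stopifnot(is.finite(r_M), r_V >= 0)
  structure(list(r_M = r_M, r_V = r_V, t = t), class = "idealized_state")
}

# shared RHS: the variance drive goes through the PE rates so that the same
# code path serves regimes with perturbed (non-complementary) PE activity
idealized_rhs <- function(r_M, r_V, S, params) {
  pe <- idealized_pe_rates(r_M, S)
  c((pe$r_pE - pe$r_nE) / params$tau_M,
    (-r_V + (pe$r_pE + pe$r_nE)^2) / params$tau_V)
}

#' One RK2 step of the idealized model
#'
#' Advances the memory and variance dynamics
#' `tau_M dr_M/dt = r_pE - r_nE` and
#' `tau_V dr_V/dt = -r_V + (r_pE + r_nE)^2`
#' by one explicit midpoint (2nd-order Runge-Kutta) step with the stimulus
#' held constant over the step.
#'
#' @param state an [idealized_state()].
#' @param S stimulus value over this step.
#' @param dt step size (ms); must be positive and small against the time
#'   constants.
#' @param params an [idealized_params()].
#' @return The advanced `idealized_state`.
#' @export
step_idealized <- function(state, S, dt, params) {
  if (!is.numeric(dt) || length(dt) != 1 || dt <= 0)
    stop("dt must be a positive scalar")
  k1 <- idealized_rhs(state$r_M, state$r_V, S, params)
  mid <- c(state$r_M, state$r_V) + dt / 2 * k1
  k2 <- idealized_rhs(mid[1], mid[2], S, params)
  out <- c(state$r_M, state$r_V) + dt * k2
  idealized_state(r_M = out[1], r_V = max(out[2], 0), t = state$t + dt)
}

#' Simulate the idealized model over a stimulus series
#'
#' Convenience RK2 loop over a per-step stimulus vector (one value per `dt`).
#'
#' @param stim numeric vector, stimulus value per step.
#' @param params an [idealized_params()].
#' @param dt step size in ms (default 1).
#' @param r_M0,r_V0 initial rates.
#' @return A data.frame with columns `t`, `S`, `r_M`, `r_V`.
#' @export
simulate_idealized <- function(stim, params, dt = 1, r_M0 = 0, r_V0 = 0) {
  if (!is.numeric(dt) || dt <= 0) stop("dt must be a positive scalar")
  n <- length(stim)
  rM <- numeric(n)
  rV <- numeric(n)
  m <- r_M0
  v <- r_V0
  tM <- params$tau_M
  tV <- params$tau_V
  for (i in seq_len(n)) {
    s <- stim[i]
    # inline midpoint step (scalar form of step_idealized) for speed
    d1m <- (max(s - m, 0) - max(m - s, 0)) / tM
    d1v <- (-v + (m - s)^2) / tV
    mm <- m + dt / 2 * d1m
    vv <- v + dt / 2 * d1v
    m <- m + dt * (max(s - mm, 0) - max(mm - s, 0)) / tM
    v <- max(v + dt * (-vv + (mm - s)^2) / tV, 0)
    rM[i] <- m
    rV[i] <- v
  }
  data.frame(t = seq_len(n) * dt, S = stim, r_M = rM, r_V = rV)
}

#' Closed-form exponential-moving-average trajectory
#'
#' Exact piecewise-exponential solution of `tau_M dr_M/dt = S - r_M` for a
#' piecewise-constant input: within a segment of value `c` and duration `T`,
#' `r_M(T) = c + (r_M(0) - c) exp(-T / tau_M)`. Serves as the analytic oracle
#' for [step_idealized()] and for the circuit-mode memory neuron.
#'
#' @param values segment stimulus values.
#' @param durations segment durations (ms), all positive.
#' @param tau_M memory time constant (ms).
#' @param r_M0 initial value (default 0).
#' @return Numeric vector of `r_M` at the end of each segment.
#' @export
ema_closed_form <- function(values, durations, tau_M, r_M0 = 0) {
  if (length(values) == 0) stop("empty segment sequence")
  if (length(durations) != length(values))
    stop("values and durations must have equal length")
  if (any(durations <= 0)) stop("durations must be positive")
  out <- numeric(length(values))
  m <- r_M0
  for (i in seq_along(values)) {
    m <- values[i] + (m - values[i]) * exp(-durations[i] / tau_M)
    out[i] <- m
  }
  out
}
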
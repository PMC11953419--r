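# The 8-unit mean-field PE microcircuit.
#
# Unit order: nE, pE (somas of the nPE/pPE neurons), nD, pD (their dendritic
# compartments), PV1, PV2, SOM, VIP. Somas, PV1 and (depending on the
# variant) SOM/VIP receive the feedforward input; dendrites, PV2 and the
# remaining interneurons receive the feedback prediction (w_ff = 1 - w_fb).
# PV neurons inhibit only the somas, the SOM neuron only the dendrites among
# the compartments; SOM and VIP inhibit each other and both inhibit PV.

tau_default <- function() c(rep(60, 4), rep(2, 4))

new_pe_circuit <- function(W, w_ff, w_fb, I_bg, tau, variant,
                           dendrite_mode = NA_character_, solve_info = NULL) {
  dimnames(W) <- list(UNITS, UNITS)
  structure(list(
    W = W, w_ff = as.numeric(w_ff), w_fb = as.numeric(w_fb),
    I_bg = as.numeric(I_bg), tau = as.numeric(tau), variant = variant,
    baseline = c(rep(0, 4), rep(4, 4)),
    dendrite_mode = dendrite_mode, solve_info = solve_info
  ), class = "pe_circuit")
}

#' @export
print.pe_circuit <- function(x, ...) {
  cat(sprintf("<pe_circuit> variant %s (%s dendrites)\n", x$variant,
              x$dendrite_mode))
  cat(" feedforward targets:", paste(UNITS[x$w_ff == 1], collapse = ", "), "\n")
  cat(" feedback targets:   ", paste(UNITS[x$w_fb == 1], collapse = ", "), "\n")
  if (!is.null(x$solve_info))
    cat(sprintf(" analytic PE gains: nPE %.3f, pPE %.3f\n",
                x$solve_info$gain_nPE, x$solve_info$gain_pPE))
  invisible(x)
}

#' Available mean-field network variants
#'
#' The three wirings differ only in whether the SOM and VIP interneurons
#' receive the feedforward input or the prediction: MFN1 SOM ff / VIP fb,
#' MFN2 SOM fb / VIP ff, MFN3 both ff.
#' @return Character vector of variant labels.
#' @export
mfn_variants <- function() c("MFN1", "MFN2", "MFN3")

# Solve the multi-pathway E/I-balance constraints for one variant.
#
# The connection template (sign pattern, input routing, SOM/VIP mutual
# inhibition and SOM/VIP -> PV surround) is fixed per variant; the free
# magnitudes -- the SOM -> dendrite weight, the dendrite -> soma couplings
# and the four PV -> soma weights -- are solved so that:
#   (i)  a fully predicted input leaves both PE somas exactly at baseline
#        for any common input level (multi-pathway E/I balance),
#   (ii) each soma is silenced with margin `margin` on its null side, which
#        makes the one-sided mismatch gains positive by construction, and
#   (iii) equal extra drive onto SOM and VIP cancels in the PE somas
#        (neuromodulatory co-activation invariance), which simultaneously
#        makes single SOM and VIP perturbations equal and opposite there.
# Interneuron responses are linear at the balanced point (PE somas silent),
# so the constraints reduce to a 4x4 linear solve for the interneuron
# response matrix plus one 3x3 linear solve per soma. The dendrites operate
# at an interior (tonically active) point -- required for (iii), since a
# dendrite pinned at its rectification boundary cannot transmit extra SOM
# inhibition -- with the exactly balanced boundary dendrite as fallback.
solve_mfn_weights <- function(variant, margin = 0.5, e_to_i = 0.1,
                              som_vip_mutual = 0.5,
                              pv_from_som = NULL, pv_from_vip = NULL,
                              dend_f = NULL) {
  # per-variant interneuron-surround magnitudes c(strong, weak) and
  # dendritic operating factor, each from the interior of the region where
  # the constraint solve has a nonnegative (Dale-consistent) solution
  hyper <- switch(variant,
    MFN1 = list(ws = c(0.15, 0.075), wv = c(0.15, 0.075), f = 1.0),
    MFN2 = list(ws = c(0.25, 0.125), wv = c(0.20, 0.10), f = 0.8),
    MFN3 = list(ws = c(0.25, 0.125), wv = c(0.45, 0.225), f = 0.6),
    stop(sprintf("unknown variant '%s'", variant)))
  if (is.null(pv_from_som)) pv_from_som <- hyper$ws
  if (is.null(pv_from_vip)) pv_from_vip <- hyper$wv
  if (is.null(dend_f)) dend_f <- hyper$f

  W <- matrix(0, 8, 8)
  W[7, 8] <- -som_vip_mutual; W[8, 7] <- -som_vip_mutual
  w_fb <- c(0, 0, 1, 1, 0, 1, switch(variant,
    MFN1 = c(0, 1), MFN2 = c(1, 0), MFN3 = c(0, 0)))
  w_ff <- 1 - w_fb
  # SOM/VIP -> PV: each PV neuron is inhibited more strongly by the
  # interneuron carrying the opposite input stream (PV1 is feedforward-
  # routed, PV2 feedback-routed), giving it an opposing inhibitory surround
  pv_w <- function(w, carrier_ff) {
    if (carrier_ff) c(w[2], w[1]) else c(w[1], w[2])
  }
  ws <- pv_w(pv_from_som, w_ff[7] == 1)
  wv <- pv_w(pv_from_vip, w_ff[8] == 1)
  W[5, 7] <- -ws[1]; W[6, 7] <- -ws[2]
  W[5, 8] <- -wv[1]; W[6, 8] <- -wv[2]
  W[5:8, 1] <- e_to_i; W[5:8, 2] <- e_to_i      # local soma -> interneuron

  ii <- 5:8
  A <- solve(diag(4) - W[ii, ii], cbind(w_ff[ii], w_fb[ii]))
  AS <- A[3, ]     # SOM steady-state response to (s, p)
  AP <- A[1:2, ]   # PV1, PV2 rows
  c_tot <- c(ws[1] + wv[1], ws[2] + wv[2])   # (c_S + c_V) per PV neuron
  com <- AP[, 1] + AP[, 2]

  # Interior dendrite: per soma, solve for (w_PV1, w_PV2, w_dend) from the
  # common-input balance, the null-side silencing margin, and the SOM/VIP
  # co-activation cancellation w_dend * w_dS = sum_k w_PVk (c_Sk + c_Vk).
  interior_solve <- function(w_dS) {
    Ad <- c(-w_dS * AS[1], 1 - w_dS * AS[2])  # linear dendrite channel
    Mn <- rbind(c(com[1], com[2], -sum(Ad)),
                c(AP[1, 1], AP[2, 1], -Ad[1]),
                c(c_tot[1], c_tot[2], -w_dS))
    sn <- tryCatch(solve(Mn, c(1, 1 + margin, 0)), error = function(e) NULL)
    Mp <- rbind(c(com[1], com[2], -sum(Ad)),
                c(AP[1, 2], AP[2, 2], -Ad[2]),
                c(c_tot[1], c_tot[2], -w_dS))
    sp <- tryCatch(solve(Mp, c(1, margin, 0)), error = function(e) NULL)
    if (is.null(sn) || is.null(sp)) return(NULL)
    if (any(c(sn, sp) < -1e-9) || any(c(sn, sp) > 8)) return(NULL)
    list(wn = sn[1:2], wp = sp[1:2], w_En = sn[3], w_Ep = sp[3],
         gain_n = margin, gain_p = margin)
  }
  # Boundary dendrite (no cancellation constraint): two 2x2 solves.
  balanced_solve <- function(w_dS) {
    d_over <- max(0, 1 - w_dS * AS[2])
    d_under <- max(0, -w_dS * AS[1])
    sn <- tryCatch(solve(rbind(com, AP[, 1]), c(1, 1 + d_under + margin)),
                   error = function(e) NULL)
    sp <- tryCatch(solve(rbind(com, AP[, 2]), c(1, d_over + margin)),
                   error = function(e) NULL)
    if (is.null(sn) || is.null(sp) || any(c(sn, sp) < -1e-9)) return(NULL)
    list(wn = sn, wp = sp, w_En = 1, w_Ep = 1,
         gain_n = margin + d_over + d_under,
         gain_p = margin + d_over + d_under)
  }

  sol <- NULL
  for (f in unique(c(dend_f, 1, 0.8, 0.6))) {
    w_dS <- f / max(abs(AS))
    if (!is.finite(w_dS) || w_dS <= 0) next
    if (1 - w_dS * sum(AS) < 0.05) next  # dendrite must stay tonically active
    sol <- interior_solve(w_dS)
    if (!is.null(sol)) { mode <- "interior"; break }
  }
  if (is.null(sol)) {
    w_dS <- 1 / sum(AS)
    if (is.finite(w_dS) && w_dS > 0) sol <- balanced_solve(w_dS)
    mode <- "balanced"
  }
  if (is.null(sol))
    stop(sprintf("E/I-balance solve failed for %s: no nonnegative weight set",
                 variant))
  W[1, 3] <- sol$w_En; W[2, 4] <- sol$w_Ep      # dendrite -> own soma
  W[3, 7] <- -w_dS; W[4, 7] <- -w_dS
  W[1, 5] <- -sol$wn[1]; W[1, 6] <- -sol$wn[2]
  W[2, 5] <- -sol$wp[1]; W[2, 6] <- -sol$wp[2]
  list(W = W, w_ff = w_ff, w_fb = w_fb, mode = mode,
       info = list(gain_nPE = sol$gain_n, gain_pPE = sol$gain_p,
                   margin = margin, w_dS = w_dS))
}

#' Build one validated mean-field PE microcircuit
#'
#' Constructs the 8-unit circuit for the requested variant. The connection
#' template (which units receive the feedforward input vs the prediction, the
#' compartment targeting of PV and SOM, the SOM/VIP mutual inhibition) is
#' fixed; the free weight magnitudes are obtained by solving the
#' multi-pathway excitation/inhibition-balance constraints so that fully
#' predicted inputs leave both PE somas at baseline while mismatches evoke
#' one-sided responses with positive gain. Background inputs are then
#' calibrated with [calibrate_background()] and the resulting circuit is
#' gated behind [verify_pe_responses()].
#'
#' @param variant one of [mfn_variants()].
#' @param margin silencing margin of the null-side soma response (rate units
#'   per unit mismatch); sets the analytic PE gain together with the
#'   dendritic channel.
#' @param validate run [verify_pe_responses()] and fail on a non-passing
#'   circuit (default TRUE).
#' @return A `pe_circuit` object: weight matrix `W` (8 x 8, entry (i, j) is
#'   the weight from unit j onto unit i), input routing vectors `w_ff` and
#'   `w_fb`, calibrated background `I_bg`, time constants `tau` (60 ms for
#'   excitatory compartments, 2 ms for interneurons) and bookkeeping fields.
#' @examples
#' circ <- build_mfn("MFN1")
#' verify_pe_responses(circ)$pass
#' @export
build_mfn <- function(variant = mfn_variants(), margin = 0.5,
                      validate = TRUE) {
  variant <- match.arg(variant)
  sol <- solve_mfn_weights(variant, margin = margin)
  circ <- new_pe_circuit(sol$W, sol$w_ff, sol$w_fb, I_bg = rep(0, 8),
                         tau = tau_default(), variant = variant,
                         dendrite_mode = sol$mode, solve_info = sol$info)
  circ$I_bg <- calibrate_background(circ)
  if (validate) {
    rep <- verify_pe_responses(circ)
    if (!rep$pass)
      stop(sprintf("constraint solve produced a non-validated %s circuit",
                   variant))
  }
  circ
}

#' Calibrate the background inputs of a circuit
#'
#' Solves the steady-state equations `h = W r + I_bg` at the target baseline
#' rates (excitatory compartments at 0, interneurons at 4 s^-1 by default):
#' with the silent units exactly at their rectification boundary (h = 0) the
#' fixed point is linear in `I_bg`, giving `I_bg = r* - W r*`. The calibrated
#' circuit is then simulated with zero sensory input and zero prediction and
#' an error is raised if the prescribed steady state is not reached within
#' 0.01 s^-1 on every unit.
#'
#' @param params a `pe_circuit`.
#' @param target_baselines length-8 vector of target rates.
#' @param tol acceptance tolerance on the simulated baseline (s^-1).
#' @return The calibrated background-input vector (length 8).
#' @export
calibrate_background <- function(params,
                                 target_baselines = c(rep(0, 4), rep(4, 4)),
                                 tol = 0.01) {
  stopifnot(length(target_baselines) == 8, all(target_baselines >= 0))
  I_bg <- as.numeric(target_baselines - params$W %*% target_baselines)
  check <- params
  check$I_bg <- I_bg
  check$baseline <- target_baselines
  ss <- circuit_steady_state(check, ff = 0, fb = 0, h0 = rep(0, 8))
  if (!ss$converged || max(abs(ss$r - target_baselines)) > tol)
    stop("no steady state with the prescribed rectification pattern exists")
  I_bg
}

#' Steady state of a circuit under clamped inputs
#'
#' Integrates the circuit with fixed feedforward drive `ff` and clamped
#' prediction `fb` until the largest rate change falls below `tol` per ms.
#'
#' @param params a `pe_circuit`.
#' @param ff feedforward input value.
#' @param fb clamped prediction value.
#' @param pert optional length-8 extra input (or a [perturbation_spec()]).
#' @param dt integration step (ms); 0.1 by default for probe accuracy.
#' @param tol steady-state detection threshold (rate change per ms).
#' @param max_ms bailout horizon.
#' @param h0 initial condition (defaults to the calibrated baseline).
#' @return List with `h`, `r`, `converged`, `ms`.
#' @export
circuit_steady_state <- function(params, ff, fb, pert = NULL, dt = 0.1,
                                 tol = 1e-6, max_ms = 20000, h0 = NULL) {
  pv <- pert_vector(pert)
  if (is.null(h0)) h0 <- params$baseline
  steady_circuit_cpp(params$W, params$w_ff, params$w_fb, params$I_bg,
                     params$tau, ff, fb, pv, h0, dt, tol, max_ms)
}

#' One RK2 step of the circuit
#'
#' Reference R implementation of a single explicit midpoint step of
#' `T_c dh/dt = -h + W [h]_+ + w_fb r_M + w_ff s + I_bg`; rectification is
#' applied when forming rates at every evaluation. The compiled simulators
#' take the same step, which the test suite cross-checks.
#'
#' @param state list with component `h` (length 8).
#' @param params a `pe_circuit`.
#' @param ff feedforward input over this step.
#' @param fb feedback (prediction) input over this step.
#' @param pert optional length-8 extra input or [perturbation_spec()].
#' @param dt step size (ms), positive.
#' @return Updated state: list with `h` and rectified rates `r`.
#' @export
step_circuit <- function(state, params, ff, fb, pert = NULL, dt = 1) {
  if (dt <= 0) stop("dt must be positive")
  pv <- pert_vector(pert)
  rhs <- function(h) {
    r <- pmax(h, 0)
    as.numeric(-h + params$W %*% r + params$w_fb * fb + params$w_ff * ff +
                 params$I_bg + pv) / params$tau
  }
  k1 <- rhs(state$h)
  k2 <- rhs(state$h + dt / 2 * k1)
  h <- state$h + dt * k2
  if (any(!is.finite(h))) stop("circuit state diverged (NaN/Inf)")
  list(h = h, r = pmax(h, 0))
}

#' Verify the PE response pattern of a circuit
#'
#' Probes the calibrated circuit at steady state against a clamped prediction
#' over a grid of mismatches. A passing circuit keeps both PE somas at
#' baseline (within `tol`) for fully predicted input, responds with the pPE
#' soma only when the input exceeds the prediction and with the nPE soma only
#' when it falls short. Measured response slopes (gains) are returned.
#'
#' @param params a `pe_circuit`.
#' @param probe_prediction clamped prediction used for the probes.
#' @param mismatch_grid stimulus offsets around the prediction.
#' @param tol silence threshold on the PE rates (s^-1).
#' @return An object of class `pe_verify`: list with `pass`, a response
#'   `table` (mismatch, r_nE, r_pE), measured `gain_nPE` / `gain_pPE`, the
#'   common-input balance error, and the failure messages (if any).
#' @export
verify_pe_responses <- function(params, probe_prediction = 5,
                                mismatch_grid = seq(-2.5, 2.5, by = 0.5),
                                tol = 1e-3) {
  grid <- sort(unique(c(0, mismatch_grid)))
  probe <- function(s, p) circuit_steady_state(params, ff = s, fb = p)$r
  rates <- t(vapply(grid, function(d)
    probe(probe_prediction + d, probe_prediction), numeric(8)))
  tab <- data.frame(mismatch = grid, r_nE = rates[, 1], r_pE = rates[, 2])
  fails <- character(0)
  at0 <- tab[tab$mismatch == 0, ]
  if (abs(at0$r_nE) > tol || abs(at0$r_pE) > tol)
    fails <- c(fails, "PE somas leave baseline under fully predicted input")
  pos <- tab[tab$mismatch > 0, ]
  neg <- tab[tab$mismatch < 0, ]
  if (!all(pos$r_pE > tol) || any(pos$r_nE > tol))
    fails <- c(fails, "response to under-predicted input is not pPE-only")
  if (!all(neg$r_nE > tol) || any(neg$r_pE > tol))
    fails <- c(fails, "response to over-predicted input is not nPE-only")
  # common-input invariance: shifting s and p together must not move the somas
  shift <- probe(probe_prediction + 2, probe_prediction + 2)
  balance_err <- max(abs(shift[1:2]))
  if (balance_err > tol)
    fails <- c(fails, "E/I balance broken for common input shifts")
  gain_n <- if (nrow(neg)) coef(lm(r_nE ~ I(-mismatch), data = neg))[2] else NA
  gain_p <- if (nrow(pos)) coef(lm(r_pE ~ mismatch, data = pos))[2] else NA
  structure(list(pass = length(fails) == 0, table = tab,
                 gain_nPE = unname(gain_n), gain_pPE = unname(gain_p),
                 balance_error = balance_err, failures = fails,
                 probe_prediction = probe_prediction),
            class = "pe_verify")
}

#' @export
print.pe_verify <- function(x, ...) {
  cat(sprintf("<pe_verify> %s; gains nPE %.3f / pPE %.3f; balance err %.2g\n",
              if (x$pass) "PASS" else "FAIL", x$gain_nPE, x$gain_pPE,
              x$balance_error))
  for (f in x$failures) cat("  -", f, "\n")
  invisible(x)
}

#' Fit baseline and gain of the PE neurons
#'
#' Probes the steady-state PE-soma rate as a function of mismatch magnitude
#' over `input_range` (nPE with over-predicted, pPE with under-predicted
#' inputs) and fits a least-squares line per neuron: the intercept is the
#' (possibly negative, i.e. thresholded) baseline and the slope the gain.
#' Interneuron perturbations shift both.
#'
#' @param params a `pe_circuit`.
#' @param pert optional [perturbation_spec()] or length-8 input vector.
#' @param input_range mismatch-magnitude range of the probes.
#' @param n_probe number of probe points.
#' @param probe_prediction clamped prediction.
#' @return Data frame with one row per PE neuron: `neuron`, `intercept`
#'   (baseline), `slope` (gain).
#' @export
fit_baseline_gain <- function(params, pert = NULL, input_range = c(0, 2.5),
                              n_probe = 11, probe_prediction = 5) {
  mags <- seq(input_range[1], input_range[2], length.out = n_probe)
  pv <- pert_vector(pert)
  probe <- function(s) {
    ss <- circuit_steady_state(params, ff = s, fb = probe_prediction,
                               pert = pv)
    if (!ss$converged) stop("probe simulation failed to converge")
    ss$r
  }
  r_n <- vapply(mags, function(d) probe(probe_prediction - d)[1], 0)
  r_p <- vapply(mags, function(d) probe(probe_prediction + d)[2], 0)
  fit <- function(y) coef(lm(y ~ mags))
  cn <- fit(r_n)
  cp <- fit(r_p)
  data.frame(neuron = c("nPE", "pPE"),
             intercept = unname(c(cn[1], cp[1])),
             slope = unname(c(cn[2], cp[2])))
}

#' Measure the dynamic (finite-presentation) PE gain
#'
#' The steady-state mismatch gain overstates the effective response to
#' stimulus values of finite duration: the PE somas and dendrites ramp with
#' the 60-ms excitatory time constant, so part of each presentation is spent
#' below the asymptotic response. This probe drives the circuit with a
#' deterministic sequence of mismatch magnitudes, each held for `value_ms`,
#' and returns the root-mean-square response gain per PE neuron --- the gain
#' at which a variance read-out of such piecewise-constant input is unbiased.
#' For long presentations it converges to the steady-state slope.
#'
#' @param params a `pe_circuit`.
#' @param value_ms presentation duration of each probe value (ms).
#' @param probe_prediction clamped prediction.
#' @return Named vector `c(nPE = ..., pPE = ...)`.
#' @export
measure_dynamic_gain <- function(params, value_ms = 500,
                                 probe_prediction = 5) {
  # fixed mixed-sign sequence: sign runs of length 1 and 2 in equal measure,
  # as for symmetric noise around the prediction, so each PE neuron sees the
  # realistic silence/ramp alternation
  signs <- c(1, -1, 1, 1, -1, -1, 1, -1, 1, 1, -1, 1, -1, -1, 1, -1)
  mags <- rep(c(1.5, 0.5, 2.5, 1.0, 2.0, 0.75, 1.75, 1.25), 2)
  d <- signs * mags
  s <- rep(probe_prediction + d, each = value_ms)
  fb <- rep(probe_prediction, length(s))
  tr <- sim_circuit_cpp(params$W, params$w_ff, params$w_fb, params$I_bg,
                        params$tau, s, fb, rep(0, 8), params$baseline, 1)
  keep <- seq.int(2 * value_ms + 1, length(s))  # discard onset segments
  dm <- s[keep] - probe_prediction
  c(nPE = sqrt(sum(tr$rates[keep, 1]^2) / sum(pmax(-dm, 0)^2)),
    pPE = sqrt(sum(tr$rates[keep, 2]^2) / sum(pmax(dm, 0)^2)))
}

#' Specify a neuromodulatory interneuron perturbation
#'
#' Models a neuromodulator as a constant extra excitatory input to one or
#' more interneuron classes ("PV" drives both PV neurons), switched on at a
#' given trial.
#'
#' @param targets character subset of `c("PV", "SOM", "VIP")`.
#' @param magnitude nonnegative input per target (recycled).
#' @param scope which subnetwork is modulated: `"both"` (global
#'   neuromodulation, the default), `"lower"` or `"higher"`.
#' @param onset_trial first perturbed trial (1 = from the start).
#' @return An object of class `perturbation_spec`.
#' @export
perturbation_spec <- function(targets, magnitude = 0.5,
                              scope = c("both", "lower", "higher"),
                              onset_trial = 1L) {
  scope <- match.arg(scope)
  if (!all(targets %in% c("PV", "SOM", "VIP")))
    stop("targets must be a subset of PV, SOM, VIP")
  magnitude <- rep_len(magnitude, length(targets))
  if (any(magnitude < 0))
    stop("perturbation magnitudes must be nonnegative (excitatory modulation)")
  structure(list(targets = targets, magnitude = magnitude, scope = scope,
                 onset_trial = as.integer(onset_trial)),
            class = "perturbation_spec")
}

# map a perturbation (spec, 8-vector or NULL) to the per-unit input vector
pert_vector <- function(pert) {
  if (is.null(pert)) return(rep(0, 8))
  if (is.numeric(pert)) {
    stopifnot(length(pert) == 8)
    return(as.numeric(pert))
  }
  stopifnot(inherits(pert, "perturbation_spec"))
  v <- rep(0, 8)
  for (i in seq_along(pert$targets)) {
    idx <- switch(pert$targets[i], PV = c(5, 6), SOM = 7, VIP = 8)
    v[idx] <- v[idx] + pert$magnitude[i]
  }
  v
}

#' Serialize a circuit to JSON
#'
#' Round-trippable plain-text representation, so externally derived weight
#' matrices can be loaded verbatim with [read_circuit_json()].
#'
#' @param params a `pe_circuit`.
#' @param path output file.
#' @return The path, invisibly.
#' @export
write_circuit_json <- function(params, path) {
  obj <- list(variant = params$variant, units = UNITS,
              W = params$W, w_ff = params$w_ff, w_fb = params$w_fb,
              I_bg = params$I_bg, tau = params$tau,
              baseline = params$baseline,
              dendrite_mode = params$dendrite_mode)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_circuit_json
#' @export
read_circuit_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  W <- matrix(as.numeric(obj$W), 8, 8)
  circ <- new_pe_circuit(W, obj$w_ff, obj$w_fb, obj$I_bg, obj$tau,
                         obj$variant, obj$dendrite_mode)
  circ$baseline <- as.numeric(obj$baseline)
  circ
}
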
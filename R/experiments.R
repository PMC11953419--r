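# Experiment drivers: full simulations, variance-grid sweeps, time-resolved
# sensory weight, interneuron perturbation experiments and contraction-bias
# analysis.

#' Run one full network simulation
#'
#' Renders the protocol, integrates the hierarchy with the compiled RK2
#' stepper (1-ms steps, all rates initialized at 0) and assembles the
#' recorded trajectories. The sensory weight is computed instantaneously at
#' every step from the two variance rates and the weighted output follows
#' from it arithmetically.
#'
#' @param network a `pe_network` from [build_network()].
#' @param protocol a [stimulus_protocol()] (its seed fixes the stimulus).
#' @param pert optional [perturbation_spec()]; switched on at its
#'   `onset_trial` in the level(s) selected by its scope.
#' @param levels 2 for the full hierarchy (default) or 1 for the single
#'   lower subnetwork (mean/variance estimation runs; no sensory weight).
#' @param record_every stride (ms) for recording the 16 circuit rates; the
#'   memory/variance rates, sensory weight and weighted output are always
#'   kept at full 1-ms resolution.
#' @return An object of class `pe_sim`: list with `scalars` (data.frame:
#'   `t`, `s`, `trial`, `rM_low`, `rV_low`, `rM_high`, `rV_high`, `alpha`,
#'   `r_out`), strided `rates_low` / `rates_high` matrices with `rate_times`,
#'   `trial_means`, the originating `protocol` and `pert`, network metadata
#'   and the clip counters of the nonnegativity guards.
#' @export
run_simulation <- function(network, protocol, pert = NULL, levels = 2,
                           record_every = 10) {
  stopifnot(inherits(network, "pe_network"), levels %in% c(1, 2))
  series <- render_protocol(protocol)
  stim <- series$values
  trial_len <- protocol$n_values * protocol$n_steps
  pv <- scoped_pert_vectors(pert)
  onset <- if (is.null(pert)) 0L
           else (pert$onset_trial - 1L) * trial_len + 1L
  low <- network$lower
  high <- network$higher
  out <- sim_hier_cpp(low$W, low$w_ff, low$w_fb, low$I_bg,
                      high$W, high$w_ff, high$w_fb, high$I_bg, low$tau,
                      network$w_M_low["nPE"], network$w_M_low["pPE"],
                      network$w_M_high["nPE"], network$w_M_high["pPE"],
                      network$w_V_low["nPE"], network$w_V_low["pPE"],
                      network$w_V_high["nPE"], network$w_V_high["pPE"],
                      network$tau_E_M, network$tau_V, stim,
                      pv$low, pv$high, onset, 1, as.integer(record_every),
                      as.integer(levels))
  n <- length(stim)
  sc <- data.frame(t = seq_len(n), s = stim, trial = series$trial_index,
                   rM_low = out$rM_low, rV_low = out$rV_low,
                   rM_high = if (levels == 2) out$rM_high else NA_real_,
                   rV_high = if (levels == 2) out$rV_high else NA_real_)
  if (levels == 2) {
    sc$alpha <- sensory_weight(sc$rV_low, sc$rV_high)
    sc$r_out <- weighted_output(sc$s, sc$rM_low, sc$alpha)
  } else {
    sc$alpha <- NA_real_
    sc$r_out <- NA_real_
  }
  rl <- out$rates_low
  rh <- out$rates_high
  colnames(rl) <- UNITS
  colnames(rh) <- UNITS
  structure(list(
    scalars = sc, rates_low = rl,
    rates_high = if (levels == 2) rh else NULL,
    rate_times = out$rate_times,
    trial_means = series$trial_means, protocol = protocol, pert = pert,
    levels = levels,
    network_meta = list(variant = network$variant,
                        lambda_low = network$lambda_low,
                        lambda_high = network$lambda_high,
                        g_nPE = network$g_nPE, g_pPE = network$g_pPE),
    n_clip_M = out$n_clip_M, n_clip_V = out$n_clip_V
  ), class = "pe_sim")
}

#' @export
print.pe_sim <- function(x, ...) {
  cat(sprintf("<pe_sim> %s, %d level(s), %d trial(s), %.1f s simulated\n",
              x$network_meta$variant, x$levels, x$protocol$n_trials,
              nrow(x$scalars) / 1000))
  if (x$levels == 2)
    cat(sprintf(" steady-state sensory weight: %.3f\n", steady_alpha(x)))
  invisible(x)
}

#' Steady-state sensory weight of a run
#'
#' Time-average of the instantaneous sensory weight over the last `frac`
#' fraction of trials (default: last 50 percent, the post-convergence
#' window).
#'
#' @param result a `pe_sim`.
#' @param frac trailing fraction of trials to average over.
#' @param trials optional explicit trial indices (overrides `frac`).
#' @return Scalar mean sensory weight.
#' @export
steady_alpha <- function(result, frac = 0.5, trials = NULL) {
  sc <- result$scalars
  if (is.null(trials)) {
    nt <- result$protocol$n_trials
    trials <- seq_len(nt)[seq_len(nt) > nt * (1 - frac)]
  }
  mean(sc$alpha[sc$trial %in% trials])
}

#' Sensory weight across a grid of input statistics
#'
#' Runs one seeded simulation per (within-trial variance, trial-to-trial
#' variance) cell and records the steady-state sensory weight. Cells that
#' fail propagate their error message but do not stop the sweep.
#'
#' @param network a `pe_network`.
#' @param sigma2_in_grid within-trial variances.
#' @param sigma2_trial_grid trial-to-trial variances (uniform trial-mean
#'   bounds via [uniform_from_moments()]).
#' @param mu_trial common mean of the trial-mean distribution (default 5).
#' @param n_trials,n_values,n_steps protocol shape (defaults: 100 trials of
#'   10 values held 500 ms).
#' @param seed base seed; each cell derives an independent stream.
#' @return Data frame with `sigma2_in`, `sigma2_trial`, `alpha`, `error`.
#' @export
sweep_variance_grid <- function(network, sigma2_in_grid, sigma2_trial_grid,
                                mu_trial = 5, n_trials = 100, n_values = 10,
                                n_steps = 500, seed = 1L) {
  grid <- expand.grid(sigma2_in = sigma2_in_grid,
                      sigma2_trial = sigma2_trial_grid)
  grid$alpha <- NA_real_
  grid$error <- NA_character_
  for (i in seq_len(nrow(grid))) {
    res <- tryCatch({
      proto <- stimulus_protocol(
        n_trials, n_values, n_steps,
        uniform_from_moments(mu_trial, grid$sigma2_trial[i]),
        grid$sigma2_in[i], seed = sub_seed(seed, "sweep_cell", i))
      steady_alpha(run_simulation(network, proto))
    }, error = function(e) e)
    if (inherits(res, "error")) grid$error[i] <- conditionMessage(res)
    else grid$alpha[i] <- res
  }
  grid
}

#' Trial-aligned time course of the sensory weight
#'
#' Averages the instantaneous sensory weight across trials as a function of
#' time since trial onset, after discarding the initial (transient) trials.
#'
#' @param result a `pe_sim` with at least 10 analyzed trials.
#' @param drop_frac fraction of initial trials to discard (default 0.5).
#' @return Data frame with `time_ms` (since trial onset), `alpha_mean`,
#'   `alpha_sem`.
#' @export
time_resolved_alpha <- function(result, drop_frac = 0.5) {
  sc <- result$scalars
  if (all(is.na(sc$alpha))) stop("single-level run has no sensory weight")
  nt <- result$protocol$n_trials
  keep <- sc$trial > nt * drop_frac
  if (length(unique(sc$trial[keep])) < 10)
    stop("need at least 10 trials after excluding transients")
  trial_len <- result$protocol$n_values * result$protocol$n_steps
  a <- matrix(sc$alpha[keep], nrow = trial_len)
  data.frame(time_ms = seq_len(trial_len),
             alpha_mean = rowMeans(a),
             alpha_sem = apply(a, 1, sd) / sqrt(ncol(a)))
}

#' Interneuron perturbation experiment
#'
#' For each target set and modulation strength, runs the chosen input regime
#' with the perturbation switched on at `onset_trial` and reports the change
#' in steady-state sensory weight relative to the pre-perturbation baseline
#' window of the same run: the baseline is averaged over the second half of
#' the unperturbed trials (post-convergence) and the perturbed value over
#' the trailing half of the perturbed trials.
#'
#' @param network a `pe_network`.
#' @param regime `"sensory"` (low stimulus noise, variable environment) or
#'   `"prediction"` (noisy stimulus, stable environment); presets
#'   `fig4_sensory` / `fig4_prediction` resized to `n_trials`.
#' @param targets list of character vectors, e.g.
#'   `list("PV", "VIP", c("SOM", "VIP"))`; pairs are co-activated at equal
#'   strength.
#' @param strengths perturbation magnitudes (input units).
#' @param n_trials total trials per run (perturbation in the second half).
#' @param scope perturbation scope (`"both"`, `"lower"`, `"higher"`).
#' @param seed base seed (one stimulus realization per regime).
#' @return Data frame with `regime`, `target`, `strength`, `alpha_base`,
#'   `alpha_pert`, `delta_alpha`.
#' @export
perturbation_experiment <- function(network,
                                    regime = c("sensory", "prediction"),
                                    targets = list("PV", "SOM", "VIP",
                                                   c("SOM", "VIP")),
                                    strengths = c(0.5),
                                    n_trials = 200, scope = "both",
                                    seed = 1L) {
  regime <- match.arg(regime)
  preset <- if (regime == "sensory") "fig4_sensory" else "fig4_prediction"
  proto <- protocol_preset(preset, seed = sub_seed(seed, paste0("pert_", regime)))
  proto$n_trials <- as.integer(n_trials)
  onset <- n_trials %/% 2 + 1L
  base_win <- seq.int(onset %/% 2 + 1L, onset - 1L)
  pert_win <- seq.int(n_trials - (n_trials - onset + 1L) %/% 2 + 1L, n_trials)
  rows <- list()
  for (tg in targets) {
    if (!all(tg %in% c("PV", "SOM", "VIP"))) stop("unknown perturbation target")
    for (st in strengths) {
      spec <- perturbation_spec(tg, magnitude = st, scope = scope,
                                onset_trial = onset)
      sim <- run_simulation(network, proto, pert = spec)
      rows[[length(rows) + 1]] <- data.frame(
        regime = regime, target = paste(tg, collapse = "+"), strength = st,
        alpha_base = steady_alpha(sim, trials = base_win),
        alpha_pert = steady_alpha(sim, trials = pert_win))
    }
  }
  out <- do.call(rbind, rows)
  out$delta_alpha <- out$alpha_pert - out$alpha_base
  out
}

#' Contraction bias of a run
#'
#' The bias of a trial is the trial-averaged weighted output minus the
#' trial's mean stimulus (the realized mean of the values presented in that
#' trial); the contraction bias is quantified by the slope of the
#' least-squares line of bias against trial stimulus mean (`|m|` is the bias
#' magnitude; a slope of -1 means full contraction to the global mean). The
#' realized mean is used rather than the nominal drawn mean so that designs
#' with a fixed trial mean but noisy stimulus values remain analyzable.
#'
#' @param result a `pe_sim` with trial structure.
#' @param drop_frac fraction of initial (transient) trials excluded from the
#'   fit (default 0.2).
#' @param tail_frac optionally average `r_out` only over the trailing
#'   fraction of each trial (steady state within trial); `NULL` (default)
#'   averages the whole trial.
#' @return An object of class `pe_bias`: data frame `trials` (`trial`, `mu`,
#'   `bias`), fitted `slope` and `intercept`.
#' @export
compute_bias <- function(result, drop_frac = 0.2, tail_frac = NULL) {
  sc <- result$scalars
  if (all(is.na(sc$r_out))) stop("run has no weighted output")
  nt <- result$protocol$n_trials
  keep_trials <- seq_len(nt)[seq_len(nt) > nt * drop_frac]
  trial_len <- result$protocol$n_values * result$protocol$n_steps
  tail_idx <- if (is.null(tail_frac)) seq_len(trial_len)
              else seq.int(floor(trial_len * (1 - tail_frac)) + 1, trial_len)
  per_trial <- vapply(keep_trials, function(tr) {
    ro <- sc$r_out[sc$trial == tr][tail_idx]
    mu <- mean(sc$s[sc$trial == tr])
    c(mu, mean(ro) - mu)
  }, numeric(2))
  mus <- per_trial[1, ]
  bias <- per_trial[2, ]
  if (length(unique(mus)) < 2)
    stop("bias slope undefined: all trial means identical")
  fit <- lm(bias ~ mus)
  structure(list(trials = data.frame(trial = keep_trials, mu = mus,
                                     bias = bias),
                 slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1])),
            class = "pe_bias")
}

#' @export
print.pe_bias <- function(x, ...) {
  cat(sprintf("<pe_bias> slope m = %.4f (|m| = %.4f) over %d trials\n",
              x$slope, abs(x$slope), nrow(x$trials)))
  invisible(x)
}

#' Contraction-bias slope across designs
#'
#' Runs [compute_bias()] for a named list of protocols and collects the
#' fitted slopes, e.g. to compare stimulus variance, trial-to-trial variance
#' or trial-duration conditions.
#'
#' @param network a `pe_network`.
#' @param designs named list of [stimulus_protocol()]s.
#' @param seed base seed; each design derives its own stream.
#' @param drop_frac passed to [compute_bias()].
#' @return Data frame with `design`, `slope`, `abs_slope`, `error`.
#' @export
bias_factor_sweeps <- function(network, designs, seed = 1L, drop_frac = 0.2) {
  stopifnot(is.list(designs), !is.null(names(designs)))
  out <- data.frame(design = names(designs), slope = NA_real_,
                    abs_slope = NA_real_, error = NA_character_)
  for (i in seq_along(designs)) {
    res <- tryCatch({
      proto <- designs[[i]]
      proto$seed <- sub_seed(seed, "bias_design", i)
      compute_bias(run_simulation(network, proto), drop_frac = drop_frac)
    }, error = function(e) e)
    if (inherits(res, "error")) out$error[i] <- conditionMessage(res)
    else {
      out$slope[i] <- res$slope
      out$abs_slope[i] <- abs(res$slope)
    }
  }
  out
}
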
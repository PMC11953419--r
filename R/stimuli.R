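#' Define a piecewise-constant stimulation protocol
#'
#' A protocol has `n_trials` trials; each trial presents `n_values` constant
#' stimulus values, each held for `n_steps` time steps of 1 ms, so the trial
#' duration is `n_values * n_steps` ms. Within a trial, values are drawn
#' i.i.d. from a normal (default) or moment-matched uniform distribution with
#' mean `mu_in` and variance `sigma2_in`; across trials, `mu_in` is re-drawn
#' from a uniform distribution `U(a, b)` (mean `(a+b)/2`, standard deviation
#' `(b-a)/sqrt(12)`), emulating changes in the environment.
#'
#' @param n_trials number of trials (>= 1).
#' @param n_values number of constant values per trial (N_in, >= 1).
#' @param n_steps number of 1-ms steps each value is held for (N_step, >= 1).
#' @param trial_mean either a single number (fixed mean, every trial uses it)
#'   or a length-2 vector `c(a, b)` of uniform bounds from which the trial
#'   mean is drawn (use `c(m, m)` for a degenerate uniform).
#' @param sigma2_in within-trial variance of the stimulus values (>= 0).
#' @param family within-trial distribution, `"normal"` or `"uniform"`
#'   (uniform uses [uniform_from_moments()]).
#' @param scalar_k optional scalar-variability slope: when set, the
#'   within-trial standard deviation is `k * mu_in` (overriding `sigma2_in`),
#'   so stimulus noise grows linearly with the trial mean.
#' @param seed integer seed; rendering is fully reproducible given the
#'   protocol.
#' @return An object of class `stim_protocol`.
#' @seealso [render_protocol()], [protocol_preset()]
#' @export
stimulus_protocol <- function(n_trials, n_values, n_steps, trial_mean,
                              sigma2_in, family = c("normal", "uniform"),
                              scalar_k = NULL, seed = 1L) {
  family <- match.arg(family)
  stopifnot(n_trials >= 1, n_values >= 1, n_steps >= 1)
  if (!is.numeric(sigma2_in) || sigma2_in < 0)
    stop("sigma2_in must be nonnegative")
  if (!is.null(scalar_k) && scalar_k < 0) stop("scalar_k must be nonnegative")
  if (length(trial_mean) == 1) {
    bounds <- c(trial_mean, trial_mean)
    spec <- "fixed"
  } else if (length(trial_mean) == 2) {
    if (trial_mean[1] > trial_mean[2]) stop("trial_mean bounds must have a <= b")
    bounds <- as.numeric(trial_mean)
    spec <- "uniform"
  } else stop("trial_mean must have length 1 (fixed) or 2 (uniform bounds)")
  structure(list(
    n_trials = as.integer(n_trials), n_values = as.integer(n_values),
    n_steps = as.integer(n_steps), trial_bounds = bounds,
    mean_spec = spec, sigma2_in = sigma2_in, family = family,
    scalar_k = scalar_k, seed = as.integer(seed)
  ), class = "stim_protocol")
}

#' @export
print.stim_protocol <- function(x, ...) {
  mu <- if (x$mean_spec == "fixed") sprintf("fixed %.3g", x$trial_bounds[1])
        else sprintf("U(%.3g, %.3g)", x$trial_bounds[1], x$trial_bounds[2])
  cat(sprintf(
    "<stim_protocol> %d trial(s) x %d values x %d ms; mean %s; sigma2_in %.3g (%s)%s; seed %d\n",
    x$n_trials, x$n_values, x$n_steps, mu, x$sigma2_in, x$family,
    if (!is.null(x$scalar_k)) sprintf("; scalar k %.3g", x$scalar_k) else "",
    x$seed))
  invisible(x)
}

#' Trial-to-trial moments of a protocol
#'
#' Mean `(a+b)/2` and variance `(b-a)^2/12` of the uniform distribution the
#' per-trial means are drawn from.
#'
#' @param protocol a [stimulus_protocol()].
#' @return Named numeric vector `c(mu_trial, sigma2_trial)`.
#' @export
trial_moments <- function(protocol) {
  a <- protocol$trial_bounds[1]
  b <- protocol$trial_bounds[2]
  c(mu_trial = (a + b) / 2, sigma2_trial = (b - a)^2 / 12)
}

#' Uniform bounds from target moments
#'
#' Inverts mean `(a+b)/2` and standard deviation `(b-a)/sqrt(12)`:
#' `a = mu - sqrt(3 sigma2)`, `b = mu + sqrt(3 sigma2)`.
#'
#' @param mu target mean.
#' @param sigma2 target variance (>= 0).
#' @return Numeric vector `c(a, b)`.
#' @export
uniform_from_moments <- function(mu, sigma2) {
  if (sigma2 < 0) stop("sigma2 must be nonnegative")
  h <- sqrt(3 * sigma2)
  c(mu - h, mu + h)
}

#' Draw the per-trial stimulus means
#'
#' @param protocol a [stimulus_protocol()] with a uniform trial-mean spec.
#' @param seed optional override of the protocol seed.
#' @return Numeric vector of `n_trials` means.
#' @export
draw_trial_means <- function(protocol, seed = protocol$seed) {
  if (protocol$mean_spec != "uniform")
    stop("protocol has a fixed trial mean; no distribution to draw from")
  a <- protocol$trial_bounds[1]
  b <- protocol$trial_bounds[2]
  with_seed(sub_seed(seed, "trial_means"), {
    if (a == b) rep(a, protocol$n_trials)
    else runif(protocol$n_trials, a, b)
  })
}

#' Draw the within-trial stimulus values
#'
#' @param mean trial mean `mu_in`.
#' @param sigma2 within-trial variance.
#' @param n_values number of values.
#' @param family `"normal"` or `"uniform"` (moment matched).
#' @param k optional scalar-variability slope (`sd = k * mean`, overrides
#'   `sigma2`).
#' @return Numeric vector of `n_values` draws.
#' @export
draw_stimulus_values <- function(mean, sigma2, n_values,
                                 family = c("normal", "uniform"), k = NULL) {
  family <- match.arg(family)
  if (sigma2 < 0) stop("sigma2 must be nonnegative")
  if (!is.null(k)) sigma2 <- (k * mean)^2
  if (sigma2 == 0) return(rep(mean, n_values))
  if (family == "normal") rnorm(n_values, mean, sqrt(sigma2))
  else {
    ab <- uniform_from_moments(mean, sigma2)
    runif(n_values, ab[1], ab[2])
  }
}

#' Render a protocol to a stimulus series
#'
#' Produces the full piecewise-constant time series (one value per 1-ms step)
#' together with the per-trial means and a per-step trial label. The global
#' seed spawns independent streams for the trial means and for each trial's
#' within-trial values, so changing `n_trials` does not reshuffle the noise of
#' earlier trials. Negative values from the normal family are kept as drawn;
#' their count is recorded in the `n_negative` attribute.
#'
#' @param protocol a [stimulus_protocol()].
#' @return An object of class `stim_series`: list with `values` (length
#'   `n_trials * n_values * n_steps`), `trial_means`, `trial_index`, `dt`
#'   (1 ms) and the originating `protocol`.
#' @export
render_protocol <- function(protocol) {
  p <- protocol
  if (p$n_trials * p$n_values * p$n_steps == 0) stop("zero-length protocol")
  means <- if (p$mean_spec == "uniform") draw_trial_means(p)
           else rep(p$trial_bounds[1], p$n_trials)
  vals <- matrix(0, nrow = p$n_values, ncol = p$n_trials)
  for (tr in seq_len(p$n_trials)) {
    vals[, tr] <- with_seed(sub_seed(p$seed, "stim_values", tr),
      draw_stimulus_values(means[tr], p$sigma2_in, p$n_values, p$family,
                           p$scalar_k))
  }
  series <- rep(as.numeric(vals), each = p$n_steps)
  structure(list(
    values = series,
    trial_means = means,
    trial_index = rep(seq_len(p$n_trials), each = p$n_values * p$n_steps),
    dt = 1,
    protocol = p
  ), class = "stim_series", n_negative = sum(vals < 0))
}

#' @export
print.stim_series <- function(x, ...) {
  cat(sprintf("<stim_series> %d steps (%.1f s), %d trial(s)\n",
              length(x$values), length(x$values) / 1000,
              x$protocol$n_trials))
  invisible(x)
}

#' Write a stimulus series as two-column tabular text
#'
#' @param series a `stim_series`.
#' @param path output file.
#' @return The path, invisibly.
#' @export
write_series <- function(series, path) {
  df <- data.frame(time_ms = seq_along(series$values) * series$dt,
                   value = series$values)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# The published stimulation-protocol table, one row per experiment panel.
# Sweep entries keep the concrete example/default value; the swept ranges are
# handled by the experiment drivers.
preset_table <- function() {
  list(
    # single 100-s probe of the circuit against a clamped prediction
    fig1B = stimulus_protocol(1, 1, 1e5, 5, 0),
    # mean/variance estimation runs: 200 values x 500 ms, uniform family
    fig2BC = stimulus_protocol(1, 200, 500, 4.5, 4.5, family = "uniform"),
    fig2DE = stimulus_protocol(1, 200, 500, 5, 4, family = "uniform"),
    # hierarchy limit cases and grid
    fig3C = stimulus_protocol(100, 10, 500, c(1, 9), 0),
    fig3D = stimulus_protocol(100, 10, 500, c(5, 5), 5),
    fig3E = stimulus_protocol(100, 10, 500, uniform_from_moments(5, 5), 5),
    fig3F_5s = stimulus_protocol(100, 10, 500, uniform_from_moments(5, 9), 0),
    fig3F_1s = stimulus_protocol(100, 10, 100, uniform_from_moments(5, 9), 0),
    # perturbation regimes: sensory-driven and prediction-driven
    fig4_sensory = stimulus_protocol(200, 10, 500, uniform_from_moments(5, 1), 0),
    fig4_prediction = stimulus_protocol(200, 10, 500, c(5, 5), 1),
    fig4D = stimulus_protocol(200, 10, 500, c(5, 5), 5),
    # contraction bias
    fig5A_low = stimulus_protocol(200, 10, 500, c(15, 25), 1),
    fig5A_high = stimulus_protocol(200, 10, 500, c(15, 25), 49),
    fig5B = stimulus_protocol(200, 10, 500, c(15, 25), 25),
    fig5C_narrow = stimulus_protocol(200, 10, 500, c(15, 25), 0),
    fig5C_wide = stimulus_protocol(200, 10, 500, c(10, 30), 0),
    fig5D_low = stimulus_protocol(200, 10, 500, c(15, 15), 4),
    fig5D_high = stimulus_protocol(200, 10, 500, c(15, 15), 25),
    fig5E_trial = stimulus_protocol(200, 10, 500, c(15, 25), 0),
    fig5E_stim = stimulus_protocol(200, 10, 500, c(15, 15), 25)
  )
}

#' Named stimulation-protocol presets
#'
#' Returns the protocol for one of the published experiment panels (e.g.
#' `"fig2DE"`, `"fig3C"`, `"fig4_sensory"`, `"fig5C_narrow"`). Panels defined
#' by a swept parameter store the example value; the sweeps are run by
#' [sweep_variance_grid()], [perturbation_experiment()] and
#' [bias_factor_sweeps()].
#'
#' @param name preset name; see `list_presets()`.
#' @param seed optional seed override.
#' @return A [stimulus_protocol()].
#' @export
protocol_preset <- function(name, seed = NULL) {
  tab <- preset_table()
  if (!name %in% names(tab))
    stop(sprintf("unknown preset '%s'; see list_presets()", name))
  p <- tab[[name]]
  if (!is.null(seed)) p$seed <- as.integer(seed)
  p
}

#' @rdname protocol_preset
#' @export
list_presets <- function() names(preset_table())
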
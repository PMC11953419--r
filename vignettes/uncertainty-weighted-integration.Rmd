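---
title: "Uncertainty-weighted integration with prediction-error circuits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Uncertainty-weighted integration with prediction-error circuits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pecircuit)
```

## The model

Cortical circuits must combine noisy bottom-up sensory evidence with
top-down predictions. A normative answer is reliability weighting: the
output is a convex combination

$$ r_\mathrm{out} = \alpha\, s + (1 - \alpha)\, r_M, \qquad
   \alpha = \left(1 + \frac{r_V^\mathrm{low}}{r_V^\mathrm{high}}\right)^{-1}, $$

where $s$ is the stimulus, $r_M$ the prediction, and
$r_V^\mathrm{low}$, $r_V^\mathrm{high}$ the estimated variances of the
sensory input and of the prediction. This package implements a rate-based
circuit that computes all of these quantities with biologically grounded
components.

The core is an 8-unit mean-field microcircuit: the somas (nE, pE) and
dendrites (nD, pD) of a negative and a positive prediction-error (PE)
neuron, two PV interneurons, one SOM and one VIP interneuron. PV cells
inhibit the somas; the SOM cell is the only inhibitor of the dendrites; SOM
and VIP inhibit each other and both inhibit PV. Unit $i$ obeys

$$ T_i \dot h_i = -h_i + \sum_j W_{ij} [h_j]_+ + w^{fb}_i r_M
   + w^{ff}_i s + I_i, \qquad r_i = [h_i]_+, $$

with $\tau_E = 60$ ms for excitatory compartments and $\tau_I = 2$ ms for
interneurons, and $w^{ff} = 1 - w^{fb}$ elementwise. When the
excitatory and inhibitory pathways onto the PE somas are balanced for fully
predicted input, the nPE soma fires above baseline only for over-predicted
input ($s < r_M$) and the pPE soma only for under-predicted input
($s > r_M$) — the defining one-sided response pattern.

Each level also has a **memory neuron**, a perfect integrator driven by
pPE excitation and nPE inhibition
($\tau_E \dot r_M = w_{M\leftarrow pPE} r_{pPE} - w_{M\leftarrow nPE}
r_{nPE}$), whose steady state is the exponential moving average of its
feedforward drive, and a **variance neuron**, a leaky integrator with a
quadratic activation on the summed weighted PE rates ($\tau_V = 5$ s),
whose steady state is the variance of that drive. Two such subnetworks are
stacked: the lower one receives the stimulus, the higher one receives the
lower memory rate as its feedforward input, so its variance neuron tracks
the uncertainty of the prediction.

## How the connectivity is obtained

The published model fixes the architecture (routing, compartment targeting,
the three MFN variants that differ in whether SOM and VIP receive the
stimulus or the prediction) but the weight magnitudes live in companion
material that is not part of this package. `build_mfn()` therefore derives
them by a constrained solve, which we regard as part of the model
definition rather than a fit:

1. The interneuron block is linear while the PE somas are silent, so its
   steady-state response to $(s, r_M)$ is one $4\times4$ linear solve.
2. Per PE soma, three linear constraints determine the two PV weights and
   the dendrite-to-soma coupling: (i) exact balance for common input
   ($s = r_M$ at any level), (ii) silencing of the null side with a margin
   (0.5 rate units per unit mismatch, which is also the analytic mismatch
   gain), and (iii) cancellation of equal extra drive onto SOM and VIP at
   the soma.
3. Background inputs follow from the target baseline rates
   (0 s⁻¹ for excitatory compartments, 4 s⁻¹ for interneurons) by
   $I = r^* - W r^*$.

Constraint (iii) reflects the reported co-activation invariance of
neuromodulation: because SOM and VIP mutually inhibit, equal excitation of
both raises each by the same amount; the solve places the dendritic
(SOM-mediated) and perisomatic (PV-mediated) consequences in exact
opposition. This is only possible when the dendrites are tonically active
— an inhibited dendrite pinned at its rectification boundary cannot
transmit additional SOM inhibition — so the circuits operate with
"interior" dendrites whose tonic rate grows with the common input level.
A boundary-balanced dendrite mode exists as a fallback. The remaining
template magnitudes (SOM/VIP→PV surround, dendritic operating point) are
per-variant constants chosen from the interior of the region where the
solve has a Dale-consistent (sign-correct, nonnegative) solution.
`verify_pe_responses()` gates every built circuit: baseline at the
calibrated rates, one-sided responses over a ±2.5 mismatch grid around a
prediction of 5, and common-input balance.

## Calibration of the unprinted gain constants

Two constants of the published parameterization are not printed and are
calibrated against printed claims:

* **Memory weights.** The model uses gain-normalized weights
  $w_{M\leftarrow PE} = \lambda / (g_\mathrm{nom}\, g)$, with $g$ the
  measured mismatch gain of the PE neuron and $g_\mathrm{nom}$ a nominal
  gain factor, yielding the effective integration timescale
  $\tau_M = \tau_E\, g_\mathrm{nom} / \lambda$ for every variant. With
  $g_\mathrm{nom} = 0.5$ and the published $\lambda$ values
  ($\lambda^\mathrm{low} = 4.5\times10^{-2}$ for trial-based protocols,
  $3\times10^{-3}$ for the slow estimation runs,
  $\lambda^\mathrm{high} = 7\times10^{-4}$), the lower memory integrates
  with $\tau_M \approx 0.67$ s and the higher with $\approx 43$ s (a ratio
  of 64; the slow estimation setting gives a ratio of 4.3). This value of
  $g_\mathrm{nom}$ is the calibration at which equal within-trial and
  trial-to-trial variances yield a sensory weight of 0.5; with
  $g_\mathrm{nom} = 1$ the same equations give $\alpha \approx 0.35$, for
  purely kinematic reasons (the slower memory both inflates the lower
  variance through change-point transients and carries less of the
  trial-to-trial variance into the higher circuit).
* **Variance weights.** $w_{V\leftarrow PE} = 1/g$, with $g$ measured at
  the timescale of the level's input. The lower level uses the RMS
  response gain to 500-ms value presentations
  (`measure_dynamic_gain()`): PE somas and dendrites ramp with the 60-ms
  membrane time constant and repeatedly reset when the mismatch changes
  sign, so the effective response to piecewise-constant noise is ~10%
  below the asymptotic slope; normalizing by the RMS gain makes the
  variance neuron an unbiased estimator for such input. The higher level's
  drive varies slowly, so it uses the steady-state slope.

## Stimulation protocols

`stimulus_protocol()` renders seeded, piecewise-constant series: each trial
presents `n_values` values held `n_steps` ms (1-ms resolution), drawn from
a normal (default) or moment-matched uniform distribution with mean
$\mu_\mathrm{in}$ and variance $\sigma^2_\mathrm{in}$; per trial,
$\mu_\mathrm{in}$ is drawn from $U(a, b)$ with variance
$\sigma^2_\mathrm{trial} = (b-a)^2/12$. The global seed spawns one stream
for the trial means and one per trial for the values, so extending a
protocol never reshuffles earlier trials. Negative values from the normal
family are kept as drawn (rare under the published parameter ranges; the
count is recorded). `protocol_preset()` names every published protocol row;
rows defined by swept parameters store the example value and the sweeps are
run by the experiment drivers. The slow estimation preset (`fig2DE`) uses
the uniform family, matching the text describing that experiment; the
trial-based presets use the normal family.

What the generator emulates is stationary piecewise-constant stimulation
with independent trial re-draws — it does not model sensory adaptation,
temporal correlations within a trial, or continuously varying signals, so
passing tests bound the model's behavior only under those statistics.

## Numerical scheme

All dynamics are integrated with an explicit midpoint (2nd-order
Runge–Kutta) fixed-step scheme, dt = 1 ms for full simulations (0.1 ms for
steady-state probes), rectification applied at every right-hand-side
evaluation, all rates initialized at 0. With $\tau_I = 2$ ms the fastest
mode gives $dt/\tau = 0.5$, inside the RK2 stability region; the test suite
checks 2nd-order self-convergence and agreement between the R reference
stepper and the compiled integrator. Variance and memory rates are clipped
at zero after each step as a numerical guard (the clip counters are
reported in every result); steady-state probes stop when the largest rate
change falls below $10^{-6}$ per ms; PE neurons count as silent below
$10^{-3}$ s⁻¹.

## Experiment conventions

* The sensory weight is computed instantaneously at every step from the
  two variance rates; condition summaries average it over the last half of
  the trials (`steady_alpha()`).
* Perturbation experiments run 200 trials with the modulation switched on
  at trial 101; the baseline window is trials 51–100 and the perturbed
  window the last 50 trials. Perturbations are excitatory, applied to both
  levels by default (global neuromodulation), with `lower`/`higher` scopes
  available.
* Contraction bias is the trial-averaged weighted output minus the trial's
  realized mean stimulus, fitted against that mean
  (`compute_bias()`); the realized mean (rather than the nominal drawn
  mean) keeps designs with a fixed nominal mean but noisy values
  analyzable. The first 20% of trials are excluded as transient.
* The within-trial dip of the sensory weight develops a few hundred
  milliseconds after trial onset because the variance neurons integrate
  with $\tau_V = 5$ s; analyses therefore compare the within-trial minimum
  to the trial-end value.
* Test and example problem sizes (50–200 trials, 3–5 seeds, 3×3 variance
  grids) are chosen so that one full suite completes in minutes on a
  single core while Monte-Carlo error stays well inside the asserted
  tolerances; the published protocol sizes are the presets' defaults.

## Known limitations

* The equal-baseline-offset invariance of the mean estimate holds exactly
  only when the nPE and pPE effective gains match; with the per-neuron
  normalization used here they differ by ~15%, so a +0.5 rate offset on
  both PE neurons shifts the mean estimate by about −0.2 (while inflating
  the variance estimate severalfold, the contrast of interest).
* The sensory weight depends mainly on the lower memory timescale, so
  scaling both memory-weight scales together is only mildly less
  consequential than scaling the lower one alone; the near-invariance
  under common scaling reported for the published model is weaker here.
* SOM-only modulation is variant- and strength-dependent (as reported);
  only the PV, VIP, and SOM+VIP effects are stable across variants.
* The heterogeneous multi-cell population network and spatial replicate
  network are out of scope; this package implements the mean-field model
  only.

## A minimal session

```{r example, eval = FALSE}
net <- build_network("MFN1")
sim <- run_simulation(net, protocol_preset("fig3C", seed = 1))
steady_alpha(sim)          # sensory-dominated: well above 0.5
b <- compute_bias(run_simulation(net, protocol_preset("fig5A_high",
                                                      seed = 1)))
abs(b$slope)               # contraction-bias magnitude
```
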
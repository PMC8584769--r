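---
title: "A population model of nonlinear visuoauditory integration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A population model of nonlinear visuoauditory integration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(scmsi)
library(dplyr)
```

## The scientific problem

Neurons in the deep superior colliculus (SC) respond to both visual and
auditory stimuli, and some of them integrate the two nonlinearly: a
combined stimulus can evoke more (multisensory enhancement) or less
(multisensory suppression) than the sum of the unimodal responses.
Characterizing this with raw significance tests is hopeless on a rich
stimulus set — a factorial design of 5 visual contrasts x 5 sound levels
x 3 visual x 3 auditory locations yields 168 non-redundant stimulus
patterns per neuron, and testing each one invites a crushing
multiple-comparisons correction. `scmsi` instead fits a compact
population model and reads the integration properties off its
parameters.

## The model

For a stimulus with visual azimuth $\phi_V$, visual contrast $I_V$,
auditory azimuth $\phi_A$ and sound level $I_A$, the late-window firing
rate of neuron $i$ is modeled as

$$
R_i = \alpha_i^{\,\delta(\phi, I)}
\left( F_{V,i}(\phi_V)\, S(I_V; I_{V50,i}, n_{V,i}) +
       F_{A,i}(\phi_A)\, S(I_A; I_{A50,i}, n_{A,i}) + b_i \right)
$$

where $S(I; I_{50}, n) = I^n / (I_{50}^n + I^n)$ is a saturating
intensity sigmoid, $F_{V,i}$ and $F_{A,i}$ are maximal evoked rates (one
per stimulus location, no spatial interpolation), and $b_i$ is the
measured baseline rate (fixed, not fitted). The nonlinearity is the
exponentiated modulation coefficient $\alpha_i^{\delta}$: $\alpha_i \ge
1$ is a per-neuron modulation weight, and

$$
\delta(\phi, I) = A_{Exc}\, G(\phi_{e\!f\!f} - \phi; \sigma_{Exc})\,
S(I; I_{Exc50}, n_{Exc}) - A_{Inh}\, G(\phi_{e\!f\!f} - \phi;
\sigma_{Inh})\, S(I; I_{Inh50}, n_{Inh})
$$

is a modulation field shared by *every neuron in a dataset* ($G$ is a
unit-height Gaussian; $\phi_{e\!f\!f}$ is the neuron's effective
receptive-field azimuth). Three variants are compared: the
audition-modulated model (AM, $\delta$ driven by $\phi_A, I_A$), the
vision-modulated model (VM, driven by $\phi_V, I_V$), and the linear
model (L, $\alpha = 1$, no modulation, 10 free parameters per neuron
instead of 12 plus 8 shared).

A center-surround $\delta$ — narrow low-threshold excitation minus broad
high-threshold inhibition — compactly expresses the two classical
principles of multisensory integration: *spatial matching* (enhancement
only near the aligned azimuth) and *inverse effectiveness* (enhancement
fades, and turns into suppression, as the sound gets louder).

## The likelihood

Trial-averaged rates are overdispersed counts, so the fit minimizes a
quasi-Poisson deviance. Per (neuron, pattern):

$$
D_{ij} = \frac{2 R_{obs}}{\theta}\left( \frac{R_{model}}{R_{obs}} - 1 -
\log\frac{R_{model}}{R_{obs}} \right), \qquad
\theta = \frac{\sigma_{obs}^2}{R_{obs}},
$$

with $\sigma_{obs}$ the SEM of the trial rates; for $R_{obs} = 0$ the
continuous limit $2 R_{model}/\theta$ is used, and $\theta$ falls back
to 1 (Poisson) when undefined. $\theta$ is a plug-in value from the
observed table, never re-estimated during fitting. A response table may
instead carry a known per-pattern `theta` column (the simulator writes
one under `sem = "true"`); calibration studies use it because the
plug-in ratio is noisy at 30 trials and biases the deviance per degree
of freedom upward by roughly 15% at collicular firing rates — a property
of the statistic, not of the optimizer.

Deviance sums over the 168 non-redundant late-window patterns and over
neurons. The all-blank pattern is enumerated by `stimulus_grid()` but
excluded from the likelihood: with it the pattern count would be 169,
which is incompatible with the degrees-of-freedom bookkeeping
`df = 168N - (12N + 8)` (modulated) and `158N` (linear). It exists only
to measure $b$. `D/df` near 1 indicates a good fit by Wilks' asymptotic
equivalence; `D/df - 1` is the *outlier deviance*, the share of the data
the model fails to describe.

## Fitting procedure

Hundreds of parameters (12 per neuron + 8 shared) are fit jointly, so
the optimization is broken into blocks:

1. **Initialization.** Each neuron's sigmoids and maximal rates are fit
   on its unimodal patterns alone; $\alpha$ starts at the narrow-phase
   lower bound (1.01) and $\phi_{e\!f\!f}$ at a location-derived value
   supplied with the data (`phi_eff_init`). Modulation parameters start
   at random positions inside their narrow-phase boxes with amplitudes
   at 0.1 to keep the first refits stable.
2. **Alternation.** Per-neuron refits (shared field frozen) alternate
   with refits of the 8 shared parameters (neurons frozen), followed
   each cycle by a joint refit of the modulation block (shared
   parameters plus every neuron's $\alpha$, and in Phase 2
   $\phi_{e\!f\!f}$) — with the tuning parameters frozen the linear sums
   are constant, so this joint step is cheap and cuts through the
   valley that plain alternation zigzags along. The loop stops when the
   negative log-likelihood (NLL $= D/2$) improves by less than the
   tolerance 0.1 per cycle.
3. **Refinement.** A joint bounded quasi-Newton polish over all free
   parameters, then a profile-likelihood sweep of each shared parameter
   (5 points across $\pm 2\sigma$ from the Hessian diagonal, the other
   shared parameters re-optimized at each point). Any gain above the
   tolerance restarts the alternation; otherwise the phase ends. The
   refinement is profiled over the shared parameters only: the
   per-neuron blocks are refit in full immediately afterwards, so
   sweeping them too would add cost quadratic in the population size
   without adding escape routes — the coupled local minima this step
   exists to escape live in the shared field.
4. **Two phases.** Phase 1 uses narrow parameter boxes and pins
   $\phi_{e\!f\!f}$; Phase 2 relaxes the boxes (maximal rates may go
   negative, exponents and half-maxima widen, $\alpha$ down to 1) and
   frees $\phi_{e\!f\!f}$. Fitting everything at once from the start is
   unstable — simultaneous movement of the effective azimuths and the
   modulation shape creates a minefield of local minima.
5. **Restarts.** The whole two-phase procedure repeats with fresh random
   modulation starts (both phases re-run per restart); the restart with
   the lowest NLL wins, ties (within 1e-6) going to the lowest index for
   determinism. The linear variant has no random initialization and no
   shared block, so one pass of independent neuron fits suffices.

All block optimizers are bounded quasi-Newton (`L-BFGS-B`) with analytic
gradients (implemented in C++ together with the deviance kernel) and
box-width parameter scaling; any step that would increase the NLL is
rejected, so the accepted trace is monotone.

### Identifiability

The model has an exact flat direction: scaling both modulation
amplitudes by $c$ while replacing every $\alpha_i$ by $\alpha_i^{1/c}$
leaves all predictions unchanged. Consequences the package makes
explicit rather than hiding:

* Marginal Hessian errors (`estimate_errors()`) along that direction are
  infinite. Parameters with appreciable loading on a flat (or
  non-positive-definite) eigendirection are flagged and given infinite
  errors; this is expected for $\alpha$ and the amplitudes, not a
  defect. Wald intervals for $\alpha$ are therefore honest but often
  unbounded.
* The modulation *coefficient* $\alpha^{\delta}$ **is** identified, and
  its delta-method test uses the pseudo-inverse covariance restricted to
  the identified subspace.
* The per-neuron question "is this neuron nonlinear, given the
  population-level modulation field" is also identified;
  `test_modulation_significance()` answers it with a one-sided Wald test
  of $\alpha > 1$ whose error is conditional on the shared parameters
  (the neuron-block Hessian). A weight sitting on its lower bound is
  never called significant.

### Classification

A neuron is *superlinear* when its maximal $\alpha^{\delta}$ over the
144 bimodal grid points is significantly above 1 (p < 0.01, two-sided on
the log scale), *sublinear* when the extreme coefficient is
significantly below 1; a neuron qualifying for both (possible because
$\delta$ changes sign over the grid) is labeled by the larger absolute
log coefficient, keeping the categories mutually exclusive. In
`run_pipeline()` the label is only awarded when the modulation weight
itself is significant, which keeps false nonlinearity calls on purely
linear populations near zero.

## Upstream characterization

* `split_windows()` separates the early (0–20 ms after auditory onset,
  boundary spike counted as late) and late (20–100 ms; 100 ms is the
  stimulus duration) response epochs. Only audition drives the early
  window.
* `responsiveness_test()` compares a window's total evoked count with
  the baseline expectation under an overdispersed Poisson null with
  variance $\theta \cdot$ mean, realized as a Poisson ($\theta \le 1$)
  or moment-matched negative binomial ($\theta > 1$); p < 0.001 flags a
  responsive neuron. `run_pipeline()` applies it to the strongest
  unimodal late response with a Bonferroni correction over the unimodal
  patterns tested.
* `classify_monotonicity()` runs an omnibus one-way ANOVA over intensity
  levels followed by one-sided pooled-variance contrasts of each non-max
  level against the max level; any contrast below p < 0.001
  (uncorrected, applied per neuron) marks the tuning non-monotonic. The
  construction (omnibus-then-contrast rather than direct pairwise
  testing) is this package's choice; alternatives exist and are not
  claimed equivalent.
* `fit_visual_rf()` fits baseline + amplitude x 2D isotropic Gaussian to
  flashed-spot counts (16 x 7 grid, 10 degree spacing) by Poisson
  maximum likelihood; `fit_auditory_rf()` fits the symmetric
  (ovalness-free) special case of the Kent distribution on the
  virtual-speaker sphere (5 elevations x 17 azimuths, 85 directions),
  reporting the angular radius at which the density falls to
  $e^{-1/2}$ of the peak — the grid is too coarse to constrain
  eccentricity reliably, hence the symmetric restriction. Elevation is
  fit but only azimuth propagates to the overlap and topography
  analyses, which are azimuthal.
* `fit_topography()` regresses RF azimuth on anteroposterior position
  with inverse-variance weights; because the measurement errors are
  known, the slope and offset standard errors come from the weighted
  normal equations without residual rescaling.
* `rf_overlap()` declares visual and auditory RFs overlapping when
  their 1-sigma azimuthal intervals intersect.

## The synthetic-data generator

No recordings ship with the package, so `make_population()` and
`simulate_trials()` generate populations with known ground truth under
the factorial design: maximal evoked rates lognormal around 5–40 Hz,
half-maxima inside the narrow-phase boxes, baselines 1–10 Hz, trial
dispersion $\theta$ uniform on 1–3 (typical collicular overdispersion;
not reported for the original recordings, so declared here, not
inferred), 30 trials per pattern, and a default center-surround
modulation field (excitatory $\sigma = 25°$, $I_{50} = 25$ dB, $n = 2$,
$A = 2$; inhibitory $\sigma = 60°$, $I_{50} = 45$ dB, $n = 4$, $A = 3$).
Counts are gamma-mixed Poisson (negative binomial) with variance
$\theta \mu$ — the analysis only assumes the variance relation, so any
matched-moment law would do. Late-window rates use the 80 ms window,
early rates the 20 ms window with a separate monotone auditory sigmoid
per neuron. The `mixed` scenario reproduces the qualitative composition
reported for the mouse SC: 17% superlinear-dominant, 13%
sublinear-dominant (effective azimuth displaced off the excitatory
center so suppression dominates), 70% linear.

What the generator does *not* emulate: spike timing within windows,
adaptation and running-state covariates, correlated noise across
neurons, and non-monotonic early responses. Passing recovery tests on
these simulations therefore validates the estimator under the model's
own assumptions; it does not certify behavior on real recordings, where
the true modulation need not factor into Gaussian-by-sigmoid halves.

```{r example, eval = FALSE}
gt <- make_population(20, scenario = "AM", seed = 1)
responses <- simulate_trials(gt, n_trials = 30, seed = 2)
fit <- fit_msi(responses, "AM", n_restarts = 5, seed = 3)
glance(fit)
test_modulation_significance(fit, stimulus_grid())
autoplot(fit)   # heat map of the recovered modulation field
```

## Numerical choices

* Predicted rates are floored at $10^{-3}$ Hz before the log-likelihood;
  the relaxed Phase-2 boxes allow negative maximal rates, and the floor
  is the smallest intrusion that keeps $\log R_{model}$ defined while
  preserving gradients elsewhere.
* Dispersion floor 1 (Poisson) where $\theta$ is undefined —
  conservative for silent cells.
* Per-neuron `D/df` uses 168 − 12 (modulated) or 168 − 10 (linear)
  degrees of freedom, ignoring the fractional per-neuron share of the 8
  shared parameters.
* Convergence tolerance 0.1 NLL per cycle in both phases; restarts
  tie-break to the lowest index; all randomness flows from explicit
  seeds, so every fit is reproducible bit-for-bit.
* Absent modalities contribute nothing to the linear sum and zero the
  modulation exponent; their azimuth entries are `NA` by construction
  and never consulted.

## Simulation sizes

The validation suite and `scripts/acceptance.R` use sizes chosen to
exercise the asymptotics the diagnostics rely on while remaining
routine desk-scale computations: calibration and recovery studies use
20 neurons x 168 patterns x 30 trials (recovery with 5 restarts); model
selection uses 20 replicate populations of 6 neurons; the
false-positive study uses 60 linear neurons; classifier null
calibrations use 4,000–10,000 replicates; receptive-field and
topography recovery use 100 and 200 replicates. The headline fractions
and deviance values reported for the original recordings depend on that
unreleased dataset and are mirrored only qualitatively here.

## Known limitations

* The modulation scale degeneracy makes individual $\alpha$ values
  comparable only within a fit, not across datasets; compare
  $\alpha^{\delta}$ instead.
* Wald tests near the $\alpha = 1$ boundary are conservative; a
  likelihood-ratio alternative would have more power but a non-standard
  null distribution at the bound.
* The block-coordinate optimizer guarantees monotone NLL, not a global
  optimum; multi-restart is the defense, and the restart NLL spread in
  `restart_nlls` is worth inspecting.
* The quasi-Poisson deviance is only asymptotically chi-squared; at low
  firing rates its null expectation sits a few percent above 1 even
  with exact dispersions.
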
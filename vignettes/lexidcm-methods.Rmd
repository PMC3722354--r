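---
title: "Models and methods behind lexidcm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind lexidcm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the generative models, the estimation machinery
and the design choices in `lexidcm`, in the spirit of a methods appendix.
Nothing here asserts an empirical result beyond what the package's test
suite and acceptance script themselves compute.

## The source model

Each cortical source is a three-population neural mass of the Jansen–Rit
family: spiny stellate cells (granular layer), pyramidal cells
(infragranular/supragranular output population) and inhibitory
interneurons.  Every synaptic projection is a second-order linear kernel

$$\ddot v = H\kappa\,u(t) - 2\kappa\,\dot v - \kappa^2 v,$$

where $u$ is presynaptic firing input, $H$ the maximum postsynaptic
potential and $\kappa = 1/\tau$ the inverse synaptic time constant.
Membrane potential converts to population firing through the sigmoid
$s(v) = 2e_0/(1 + e^{-r(v - v_0)})$.  Inside the coupled dynamics the
sigmoid is centred, $s(v) - s(0)$, so the all-zero resting state is an
exact fixed point; `sigmoid_rate()` exposes the uncentred convention
(bounded in $(0, 2e_0)$ with $s(v_0) = e_0$).

Defaults are the published values for this model family and are exposed
as arguments of `dcm_params()`:

| parameter | default | units | role |
|---|---|---|---|
| $H_e$, $H_i$ | 3.25, 22 | mV | excitatory / inhibitory synaptic gain |
| $\tau_e$, $\tau_i$ | 10, 20 | ms | synaptic time constants |
| $e_0$, $v_0$, $r$ | 2.5 s⁻¹, 6 mV, 0.56 mV⁻¹ | — | firing sigmoid |
| $\gamma_{1..4}$ | 135, 108, 33.75, 33.75 | — | intrinsic coupling |
| delay | 16 | ms | uniform inter-source conduction delay |
| input onset / width | 60 / 16 | ms | Gaussian exogenous bump |

Sources are coupled by laminar-typed extrinsic connections: forward
afferents target the stellate population, backward afferents the
pyramidal and inhibitory populations, and lateral afferents all three.
Extrinsic inputs are the delayed, sigmoid-transformed pyramidal outputs
of the sending source; intra-source coupling is undelayed.  Default
extrinsic strengths are laminar-typed (forward 32, backward 16,
lateral 4), in keeping with the convention that ascending connections
are strong and driving while lateral ones are weak.

The exogenous input is a Gaussian bump delivered to the level-1
(occipital) nodes, peaking at 60 ms peristimulus.  Only the onset is a
study condition; the waveform shape and width, the conduction delay and
the synaptic defaults are this package's own modelling choices since no
single canonical values exist for them, and all are config-overridable.

A condition (e.g. trained vs untrained words) acts multiplicatively:
connection strength $A$ becomes $A \cdot B$ in the modulated condition on
connections whose switch group is on.  $B = 1$ means no condition
difference.  Self-connections carry their gain on the intrinsic
pyramidal-to-stellate loop ($\gamma_1$).

**Integration.** Fixed-step RK4 at $dt = 1/480$ s (the recording rate),
with the inter-source delay implemented by linear interpolation in the
output history.  The step is validated against a $dt/4$ oracle in the
test suite (waveform change under 1% of signal range).  Divergence
(any state beyond 1000 mV) raises an explicit instability error rather
than returning garbage.  Stochastic innovations are not modelled: the
simulator produces the deterministic generative mean, and noise is added
at the sensors.

## Model space

In a six-source network there are 30 directed connections and $2^{30}$
unrestricted modulation models.  Three rules make the space tractable:

1. connections may be forward, backward or lateral, but not *diagonal*
   (cross-hemisphere between different levels);
2. every forward/backward connection is switched together with its
   opposite-hemisphere mirror;
3. every lateral connection is switched together with its reciprocal.

This leaves 9 independent groups — six mirrored forward/backward pairs
(including the level-skipping OCC↔IFG pairs, which are within-hemisphere
and therefore *not* diagonal) and three bidirectional lateral bundles —
and $2^9 = 512$ models.  Only this reading reproduces the count of nine;
treating level-skipping connections as inadmissible would leave seven
groups.  Self-connections are not among the nine: their condition
modulation is treated as present in every model, so their gains are
estimated but never switched.  Patterns are enumerated in little-endian
binary counting order over the documented group order, making model
indices reproducible.

For small test networks, `independent_groups(include_self = "pooled")`
optionally adds the self-connections as one extra switch group.  The
desk-scale recovery harness uses this on a 2-source network to obtain an
8-model space (forward, backward, pooled-self switches); with selves
unswitched a 2-source network would give only 4 models.

## Forward model and dipole fitting

The magnetic forward model is the analytic Sarvas solution for a current
dipole in a homogeneous conducting sphere, with the sensor array
approximated as radially oriented magnetometers outside the sphere.
This is a deliberate simplification of realistic single-shell head
models: it is closed-form, dependency-free, and exact for the synthetic
studies the package performs.  Its two structural properties — radial
dipoles are silent, and the radial field component equals that of the
free-space primary dipole — serve as independent oracles in the tests.
MNI source coordinates are shrunk by a factor 0.8 to sit inside the
90 mm model sphere; interface units are mm, SI internally.

`fit_ecd()` is a maximum-a-posteriori simplification of variational
Bayesian dipole fitting: moments are solved linearly at each candidate
location, locations are optimized by Nelder–Mead under a Gaussian prior
penalty, and the procedure restarts from prior locations jittered with
6 mm SD (100 restarts by default), keeping the best penalized fit.  Full
model-evidence scoring of dipole counts is out of scope; a warning is
issued when fitted dipoles approach within 2 cm of each other.

## Inversion

`invert()` implements variational Laplace for the two-condition evoked
pair over the 1–200 ms fit window.  All estimated parameters are
log-scaling factors (extrinsic strengths, modulatory gains, input
amplitude) with independent $\mathcal N(0, 1/16)$ priors, so positivity
is structural and a prior SD of 0.25 log-units keeps gains in a
physiologically plausible range.  The noise model is i.i.d. Gaussian at
the sensors with one log-precision per condition, point-estimated each
iteration (capped at $\pm 16$ on unit-scaled data; an uncapped precision
from a zero-residual fit destroys the curvature conditioning).

Numerics: Gauss–Newton steps with Levenberg–Marquardt damping; a step is
accepted only if the free energy increases, otherwise it is rolled back
and the damping increased (so the accepted-F trajectory is
non-decreasing by construction); convergence is declared after three
consecutive iterations with $\Delta F < 0.01$, with a cap of 64
iterations; singular curvature is ridge-regularized; forward-difference
Jacobians with step $10^{-3}$; data and predictions are jointly rescaled
to unit SD before fitting.  Non-convergence returns the last iterate
with `converged = FALSE` rather than an error.  The free energy is the
standard accuracy-minus-complexity bound with a closed-form Gaussian KL
complexity term; the noise precision enters as a point estimate, not a
random variable, so F carries no hyperparameter complexity term.

Both conditions are fitted jointly in one model (baseline strengths plus
modulation), the standard design for condition-difference studies.  No
sensor-mode reduction is applied by default because the synthetic arrays
are small.

## Group inference

`rfx_bms()` is the variational Dirichlet scheme for random-effects model
selection: subject-wise posterior model assignments are re-weighted by
the group Dirichlet expectation in a fixed-point loop, and model
exceedance probabilities are Monte-Carlo estimates over the fitted
Dirichlet.  `bma_gains()` composes with it: per pooled draw, each
subject contributes a model sampled from its posterior assignment
probabilities and a parameter vector sampled from that model's Gaussian
posterior; connections unmodulated in the sampled model contribute gain
exactly 1 (the generative meaning of an absent modulation).  No Occam's
window is applied — all models contribute.  The proportion test then
draws 10 000 Gaussian samples per connection from the pooled mean and SD
and flags a connection when at least 90% of draws fall on one side of 1;
the exceedance probability converts to a Bayes factor as $P/(1-P)$.  All
sampling is seeded and seeds are recorded in the outputs.

## Sensor preprocessing

Filters are 5th-order Butterworth applied forward-backward (zero phase);
the filter family is this package's choice.  Epochs span −100…1000 ms at
480 Hz with the prestimulus mean subtracted per trial and sensor.
Robust averaging uses bisquare weights computed per time sample across
trials, independently per sensor, with tuning constant 4.685 × MAD, at
most 8 iterations and tolerance $10^{-6}$ on the weight change —
conventional robust-GLM settings, stated here because no canonical
constants exist.  With ~95% Gaussian efficiency, the robust mean of 50
clean trials deviates from the arithmetic mean by about 0.03 noise-SD
per cell; tests bound the maximum over all cells accordingly.  The 30 Hz
low-pass can be repeated after averaging (`lowpass_hz = 30`) to remove
high-frequency noise introduced by the weighting; the recovery harness
skips it because its model predictions are unfiltered.  Global field
power is the literal sum of squared sensor amplitudes (not RMS), and the
group comparison is an uncorrected pointwise t-test on untransformed GFP.

## Behavioural measures

Reaction-time trimming is single-pass: mean and SD are computed once per
length bin and responses beyond 2 SD are excluded; trimming is per
length bin, not on the grand mean, and is not iterated.  The word-length
effect is the OLS slope of per-length mean RTs on letter length — for
equally spaced lengths this coincides with the average successive
difference, so both readings of "average increase per letter" agree.
Accuracy scores correct = 1, error/omission = 0, self-correction = 0.5,
with voice-key failures excluded from the denominator.  n-gram frequency
indices use token counting (every occurrence in every reference word),
divided by the word's n-gram count; within-list indices exclude the
word's own entry.  The training-task ladder saturates at its endpoints
(easy floors, hard ceilings) — only the interior transitions are
prescribed, saturation is this package's choice.  Word-pair difficulty
statistics use multiset letter intersection, provided as a utility
(`shared_letters()`) since only averages, not a counting rule, are
conventional.

## The synthetic-data generator

The generator defines the study conditions under which the pipeline is
validated, and its defaults are fixed accordingly:

* **Behaviour** — 9 subjects, four timepoints, 128 trials per timepoint
  balanced over lengths 3–6 and trained/untrained lists; lognormal RTs
  (right-skewed, which is what makes 2-SD trimming meaningful) around a
  per-subject base (median 1300 ms, between-subject log-SD 0.25) with a
  100 ms/letter slope; a multiplicative trained-list reduction of 11.5%
  at t3 with a per-letter interaction (0.02/letter, centred on the mean
  length so the configured effect equals the length-collapsed average);
  50% of the effect retained at t4 (no quantitative retention figure
  exists; this is a package choice).
* **Word lists** — two disjoint lists of consonant–vowel pseudowords with
  identical length histograms; `overlap = "none"` uses disjoint alphabets
  so the between-list bigram index is exactly 0, the degenerate case that
  makes whole-word and sub-lexical learning indistinguishable.
* **MEG** — per-subject lognormal jitter (SD 0.1) on extrinsic strengths
  with shared condition gains, matching the random-effects target of the
  group analysis; 50 trials per condition; sensor noise at
  `rms(signal)/SNR`; catch trials generated but labelled for exclusion.

What the generator does *not* emulate: real head geometry and
coregistration error, correlated sensor noise, eye and muscle artifacts,
linguistic structure of real words (frequency, imageability), and
between-subject variability in source locations.  Passing recovery tests
therefore demonstrates the internal consistency and statistical
calibration of the pipeline, not robustness to those real-data
complications.

## Problem sizes

The desk preset used by the tests and the acceptance script runs the
complete chain at reduced scale — 2 sources, 8 models, 8 subjects, 16
sensors, 50 trials/condition, −100…250 ms epochs — so one replicate
inverts 64 models and the 10-replicate recovery study completes in a few
minutes on one CPU.  The full-scale layout (6 sources, 512 models, 275
sensors, −100…1000 ms) is supported by the same code paths via
`default_config("full")` and is correspondingly expensive (hours, not
minutes).

## Known limitations

* The spherical forward model and fixed tangential source orientations
  are simplifications; localization and gain estimates on real data
  would inherit their bias.
* The noise precision is point-estimated, so free energies omit its
  uncertainty; model comparisons are insensitive to this at the SNRs
  studied but the absolute F values are not full evidence bounds.
* `fit_ecd()` ranks restarts by penalized residual, not model evidence,
  and does not select the number of dipoles.
* Robust-averaging weights are computed independently per sensor;
  spatially coherent artifacts are down-weighted less effectively than
  by multivariate schemes.
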
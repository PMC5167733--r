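---
title: "Serial vs parallel somatosensory routing: models, inversion and group inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Serial vs parallel somatosensory routing: models, inversion and group inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcmerp)
```

## The question

Tactile input reaches the cortex through the thalamus. Two routings are
anatomically possible: *serial* — the thalamus drives the primary
somatosensory cortex (SI), which relays preprocessed information to the
secondary somatosensory cortex (SII) — and *parallel* — the thalamus also
drives SII directly. `dcmerp` implements a dynamic-causal-modeling (DCM)
analysis that turns this into a Bayesian model comparison on evoked MEG
responses, and asks a sharper question on top: does the dominant route
*change over peri-stimulus time*, from parallel at stimulus onset to serial
once a stimulus persists?

The package provides every stage as a tested function: a biophysical
forward model of a three-node cortical network, a linear sensor model with
spatial-mode reduction, MEG-style preprocessing, variational-Laplace model
inversion yielding a free-energy approximation to the log model evidence,
random-effects Bayesian model selection (RFX BMS) with exceedance
probabilities across peri-stimulus windows, Bayesian model averaging (BMA)
of thalamic input strengths, and a synthetic multi-subject generator with
known ground truth so that the whole chain is verifiable end to end.

## The neural mass network

Each node (contralateral SI, contralateral SII, ipsilateral SII) is a
standard evoked-response neural mass: three subpopulations — spiny
stellate cells in the granular layer, pyramidal cells, and inhibitory
interneurons — coupled through second-order synaptic kernels

$$\ddot v = \frac{H}{\tau}\, s(t) - \frac{2}{\tau}\dot v - \frac{v}{\tau^2},$$

whose impulse response $h(t) = (H/\tau)\,t\,e^{-t/\tau}$ peaks at $t=\tau$
with height $H/e$. Presynaptic firing is a centred sigmoid
$S(v) = 1/(1+e^{-r v}) - 1/2$ of the membrane potential, so the quiescent
state is an exact fixed point: zero input produces exactly zero output.
Rate constants follow the conventional seconds-based normalization of this
model family (DC synaptic gain $H\tau/1000$ with $\tau$ in ms), which keeps
the standard coupling constants in their stable regime.

Defaults (all re-estimated during inversion as log-scaling coefficients):

| parameter | default | unit | role |
|---|---|---|---|
| $H_e$, $H_i$ | 3.25, 29.4 | mV | excitatory / inhibitory synaptic gain |
| $\tau_e$, $\tau_i$ | 10, 16 | ms | synaptic time constants |
| $\gamma_{1..4}$ | 50, 40, 12, 12 | — | intrinsic coupling |
| $r$ | 0.56 | 1/mV | sigmoid slope |
| extrinsic / intrinsic delay | 16, 2 | ms | conduction delays |
| forward / backward strength | 128, 64 | — | extrinsic coupling at the prior mean |

The extrinsic baseline strengths are our own choice (no published value
fixes them): 128/64 makes the serial relay transmit a non-trivial fraction
of the SI response to SII (about half, at one synaptic stage) while keeping
the extrinsic loop gain well below unity. Forward connections enter the
stellate population, backward connections the pyramidal and inhibitory
populations; only the edge pairs SIc↔SIIc and SIIc↔SIIi exist, each node
has a self-connection (a log gain multiplying its intrinsic couplings), and
the node output is the pyramidal depolarization.

Thalamic drive is split into two Gaussian components: a *phasic* component
(mean 30 ms, SD 16 ms) encoding stimulus onset and a *sustained* component
(mean 170 ms, SD 70 ms) modeling ongoing stimulation. The four competing
architectures differ only in which nodes these components reach:

* **A** — permanent serial: both components to SIc only;
* **B** — serial then parallel: phasic to SIc; sustained to SIc and SIIc;
* **C** — parallel then serial: phasic to SIc and SIIc; sustained to SIc;
* **D** — permanent parallel: both components to SIc and SIIc.

Each (component, target) pair carries its own amplitude parameter: whether
the two components share per-target strengths is not constrained by the
hypotheses, so we expose the superset (independent amplitudes) and let the
priors regularize it. The ipsilateral SII never receives direct input under
any hypothesis. The single-input `"serial"` / `"parallel"` models used in
the initiation analysis keep only the phasic component.

```{r architectures}
build_model("C")
```

### Numerical integration

Fixed-step RK4 at 0.5 ms internal steps (halving the step changes
trajectories by under 0.05% RMS), with conduction delays handled by linear
interpolation of the stored firing-rate history — both delays exceed the
step, so delayed look-ups never leave the recorded history, and the
pre-onset past is exactly quiescent. The integrator is deterministic given
the model and grid; a non-finite state aborts with an error naming the
parameter regime. In the decoupled linear regime the integrator matches
the closed-form kernel convolution to well under 2% — one of the package's
standing oracle tests.

## Observation model and dimension reduction

Cortical-patch lead fields require individual anatomy, which a synthetic
study cannot and need not reproduce. `synthetic_gain()` instead builds a
smooth topography per node on a quasi-uniform unit-sphere sensor layout
(102 channels by default, 306 optional): a Gaussian pattern in great-circle
distance (width 0.5 rad) centred on the sensor nearest the node's direction,
with the node directions taken from fixed group-level MNI activation maxima
(`source_locations()`), plus a small seeded per-channel gain jitter. This
preserves exactly what the inversion must cope with — strongly overlapping
spatial mixtures of three sources — without a head model.

Sensor data are reduced to their leading spatial modes (left singular
vectors) before inversion; seven modes capture >99% of the variance of
three-source data. Modes are computed per subject and per analysis window
(the windowed data are what the model must explain; computing modes per
window keeps the reduction faithful for short segments).

## Preprocessing

The pipeline mirrors standard MEG practice: zero-phase 4th-order
Butterworth filtering (0.5–100 Hz band), anti-alias filtering and
decimation to 500 Hz, epoching over the closed interval [−50, 300] ms
around stimulus onset — 176 samples per epoch — and per-trial baseline
correction over the half-open window [−50, 0) ms. The closed/half-open
endpoint conventions are fixed here once so that sample counts are
unambiguous. Stimulus markers are assumed to already carry the stimulus
device's onset correction (the 40 ms pneumatic delay convention); the
synthetic generator emits corrected, epoch-grid-aligned onsets.

Cardiac and ocular artifacts are removed by signal-space projection:
segments around detected artifact events are averaged event-locked (which
cancels brain activity not phase-locked to the artifact), the leading
principal component of the averaged segment gives the artifact's sensor
topography $u$, and all data are projected with $I - uu^\top$ — a rank-1
reduction per artifact class. Visual inspection of noisy segments is
replaced in this implementation by the projector plus the generator's
clean-by-construction records.

## Variational Laplace inversion

`invert()` fits one network model to one subject's reduced ERF by
maximizing the free energy

$$F = \langle \log p(y \mid \theta) \rangle_q - \mathrm{KL}\!\left(q \,\|\, p\right),$$

over a Gaussian $q(\theta)$: a Gauss–Newton outer loop on the posterior
mean with Levenberg–Marquardt damping (damping shrinks after every accepted
step, grows eightfold on rejection; a step is accepted only if the fully
re-evaluated $F$ increases, so $F$ is monotone over accepted iterations by
construction), the posterior covariance from the damped-free curvature, and
a 1-D Newton update of the log noise precision of each spatial mode
(IID-in-time noise, one precision per mode, Gaussian hyperprior, MAP point
estimate; the update is reverted in the rare case it lowers $F$).
Convergence is declared when the $F$ increment falls below 0.01 nats
(default; at most 128 iterations — non-convergence returns the best state
flagged). $F$ splits exactly as accuracy − complexity. On a linear-Gaussian
model with fixed noise this scheme reproduces the conjugate posterior and
the exact log evidence — the package's second standing oracle.

Parameters are log-scaling coefficients on the extrinsic connections
(prior SD 0.25), self-connections (0.125) and input amplitudes (0.5), an
additive shift of each input's onset mean (prior SD half the component's
own width: 8 ms phasic, 35 ms sustained — the stated 16/70 ms values are
the widths of the input functions themselves, so the timing *priors* are
tighter), and a log-scaling of each width (SD 0.25). The amplitude and
connection prior SDs are package defaults, config-exposed, not published
values. Jacobians are forward differences with steps of $10^{-3}$ prior SD.

### Windowed comparison

`window_data()` restricts an ERF to the closed interval
$[\mathrm{start}, \mathrm{start}+\mathrm{length}]$ — at 500 Hz a
(1, 40) ms window keeps exactly 20 samples — then reduces to modes. Two
window schemes reproduce the two complementary analyses:
`incremental_windows()` (18 windows, lengths evenly spaced 40→260 ms
snapped to the 2 ms grid, all starting at 1 ms; the exact 18 lengths are
not published, so even spacing is adopted and overridable) and
`fixed_windows()` (60 ms sliding windows, default step 30 ms — start times
are likewise not published).

For fixed windows that start late, the single-input initiation models need
an input that can explain a mid-response segment. With `onset_prior =
"window"` the onset prior is re-centred at the window start: the synaptic
cascade then places the modeled SI response ~25 ms into the window and its
serially relayed SII counterpart ~20 ms later, so both fall inside a 60 ms
segment and the serial/parallel distinction stays identifiable. Anchoring
the input at the stimulus instead would push the serial model's predicted
SII response outside short late windows and bias the comparison toward
parallel for purely geometric reasons.

## Group inference

`rfx_bms()` implements the variational Dirichlet scheme over model
frequencies: iterate $u_{nk} \propto \exp(F_{nk} + \psi(\alpha_k) -
\psi(\Sigma\alpha))$, normalize per subject, accumulate
$\alpha = \alpha_0 + \Sigma_n g_{nk}$, to convergence ($10^{-6}$ in
$\alpha$), with $\alpha_0 = 1$ (uniform prior; config-exposed). Per-subject
evidences are shifted by their row maximum before exponentiation — the
posterior is provably invariant to such shifts, and the package asserts it.
Exceedance probabilities $P(r_k = \max)$ use the exact Beta closed form for
two models and a seeded Monte-Carlo estimate (default $10^6$ draws;
argmax partition, so the vector sums to one exactly) otherwise; the
Monte-Carlo route is itself validated against the Beta closed form.

`bma_inputs()` averages per-target log input strengths across models —
restricted to the winning model by default (one-hot weights), with
softmax-of-evidence weights as an option — and contrasts SI vs SII input
strength with a paired two-sided t-test across subjects
($df = n-1$). With a single subject, note, RFX exceedance saturates at
$1-\mathrm{BetaCDF}(\tfrac12; 2, 1) = 0.75$ under the uniform prior: a
mathematical ceiling of the random-effects scheme, not a bug.

## The synthetic generator

`ground_truth()` → `sample_subject()` → `synthesize_recording()` /
`synthesize_epochs()` generate groups that emulate the target study's
conditions: 17 subjects, 154 trials each, inter-stimulus intervals uniform
on 2–3.8 s, 2 kHz continuous records (102 channels), and a single-trial
SNR — defined as clean-ERF RMS over single-trial noise RMS, verified to
within 10% by a standing test — defaulting to 5, a free simulation
parameter reported with every acceptance run (the original recordings'
SNR is unpublished). Between-subject variability is log-normal on
connection gains and input amplitudes (SD 0.2 — a typical effective-
connectivity spread; no published value exists). Sensor noise is AR(1) in
time (coefficient 0.95 at 2 kHz — a crude 1/f-like spectrum), IID across
channels. Optional cardiac (~1 s quasi-period) and blink (0.2 Hz Poisson)
artifacts are fixed random topographies with scheduled waveforms.

Two generation paths exist by design. The continuous-recording path
exercises the full preprocessing chain (filtering, decimation, epoching,
SSP). The epoch-level fast path generates the equivalent baseline-corrected
500 Hz epochs directly (AR coefficient mapped as $0.95^4$; a standing test
confirms the two paths agree on the evoked signal) and is what the large
recovery studies use — a 17-subject group generates in seconds. Stimulus
onsets are aligned to the 500 Hz analysis grid, so trial averaging is free
of sub-sample jitter.

What the generator does **not** emulate: realistic head geometry and lead
fields, environmental interference and its hardware filtering,
sensor-array unit mixing (magnetometers vs gradiometers), head movement,
habituation or latency drift across trials, and trial rejection (all
trials are kept). Passing recovery tests therefore demonstrates the
*inferential machinery* — that the pipeline identifies the generating
routing architecture, its switch over time, and input-strength asymmetries
at realistic SNR and group size — not performance against the
idiosyncrasies of real MEG recordings.

## What the recovery studies show

Run end to end (see `scripts/acceptance.R` and the test suite), the
pipeline recovers, on synthetic groups of 17 subjects at SNR 5:

* the generating architecture among {A, C, D} with exceedance probability
  above 0.9 from the full-window four-model RFX BMS;
* the parallel→serial switch: on data generated under architecture C, the
  single-input initiation comparison favors the parallel model in early
  incremental windows (≤100 ms) and the serial model in late fixed windows
  (≥200 ms), with mixed evidence in the 120–160 ms transition zone where
  the decaying direct drive and the rising relayed drive overlap;
* a 2:1 SI:SII input-strength asymmetry, via winner-model BMA and a paired
  t-test, at p < 0.01.

Problem sizes in the shipped tests are chosen for desk-scale runtimes:
recovery uses the full-window evidence (a strict subset of the 18-window
sweep), three seeded replicates per architecture, and eight windows for the
initiation analysis; all other conditions are the study conditions above.

## Known limitations

* The inversion estimates fixed network parameters per window; it does not
  model within-window nonstationarity.
* The noise hyperparameter is a MAP point estimate (no posterior over
  precisions), adequate here because mode-space residuals are
  high-dimensional.
* BMA is over the model set actually fitted; protected exceedance
  probabilities and family inference are out of scope.
* The synthetic gain stands in for anatomy; absolute source amplitudes are
  therefore only defined up to the gain scale, and only *relative*
  (SI vs SII) input strengths are interpreted.
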
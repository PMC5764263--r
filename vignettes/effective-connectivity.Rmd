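---
title: "Motor execution vs. imagery effective connectivity: models, assumptions, and numerical choices"
author: "eegdcm authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motor execution vs. imagery effective connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(eegdcm)
```

## The scientific question

During both overt finger tapping (motor execution, ME) and its mental
rehearsal (motor imagery, MI), a network of motor and cognitive areas is
active: primary motor cortex (M1), supplementary motor area (SMA), dorsal
premotor cortex (PMC) and dorsolateral prefrontal cortex (DLPFC). The
question this package addresses is *directed*: through which region does
task input enter the network, and which inter-regional couplings are
modulated by performing a trial? `eegdcm` implements the full analysis
chain — task simulation, EEG preprocessing, time-frequency
desynchronization analysis, ROI extraction, dynamic causal modeling (DCM),
family-level Bayesian model selection (BMS) and group statistics — as a
desk-scale, fully simulation-testable pipeline.

## The generative model

Neural dynamics over the four ROIs follow the bilinear state-space model

$$\dot x = \bigl(A + u_{\mathrm{mod}}(t)\,B\bigr)\,x + C\,u_{\mathrm{drive}}(t),
\qquad x(0)=0,$$

with $A$ the intrinsic couplings (1/s; fixed self-decay of $-1$/s on the
diagonal), $B$ unitless modulatory gains active while a dot trial is
performed (dot onset to onset + 0.8 s), and $C$ a driving gain that is
nonzero at exactly one region — PMC or SMA — defining the two model
*families*. DLPFC–M1 connections are structurally absent in both
directions. The observation model multiplies each ROI state by a free gain
(prior $\mathcal N(1, 1/16)$) and adds white Gaussian noise; the gains
absorb the arbitrary sign and scale of minimum-norm ROI series.

This bilinear form is a declared simplification: the source study names
only the A/B/C structure of its DCM, not its equations, and the bilinear
model is the canonical minimal member of that family that remains
invertible on a single CPU.

### Priors

Shrinkage priors are used throughout: free $A$ entries
$\mathcal N(0, 1/16)$, $B$ entries $\mathcal N(0, 1/16)$, the single $C$
entry $\mathcal N(0, 1)$, observation gains $\mathcal N(1, 1/16)$, and a
$\mathrm{Gamma}(2, 1)$ prior on the noise precision. Inversion is
variational Laplace: damped Gauss–Newton updates of the posterior mode, a
closed-form Gaussian covariance at the expansion point, a conjugate
fixed-point update of the noise precision, and the variational free energy
$F = \mathbb E_q[\log p(y\mid\theta)] - \mathrm{KL}(q\,\|\,p)$ as the
model-evidence surrogate. For linear models with known noise this $F$
equals the exact log marginal likelihood, which the test suite exploits as
an oracle.

### The 16-model space

Eight modulatory structures per input family. Every structure modulates
the six core couplings among PMC, SMA and M1; three binary toggles add
(i) modulation of DLPFC→PMC, (ii) modulation of DLPFC→SMA, and (iii) the
identity of a single return edge to DLPFC — from the family's input region
or from the other secondary motor area. The published figure defining the
original 16 structures is not machine-readable, so this enumeration is a
documented default chosen to match the published coupling tables
(structures 2 and 3 carry both DLPFC→ modulations and differ only in the
return edge); `build_model_space(structures = ...)` accepts explicit mask
lists for users who know the exact structures.

## The synthetic world

The generator's defaults are fixed once and state what they emulate:

* **Paradigm** — 20 blocks per session; 4.0 s cue; 3–5 dot trials per
  block at 1.3 s intervals (dot 0.8 s, fixation 0.5 s); end-of-block
  button probe with Bernoulli accuracy 0.904 (ME) / 0.845 (MI), the
  observed group rates.
* **Couplings** — intrinsic couplings 0.3/s on all allowed edges (the
  magnitude scale of published cortico-cortical DCM estimates; at 0.1/s
  the DLPFC receives too little signal for any structural inference),
  modulatory gains +0.3 on forward edges and −0.2 on feedback edges
  (the scale of the published coupling table), driving gain 1 at the
  input region. Stability of $A$ and $A+B$ is verified for every
  structure.
* **Oscillations** — band-limited mu (and optionally beta) activity at
  M1 whose amplitude is multiplied by a suppression factor $s<1$ during
  trial performance: the generative counterpart of event-related
  desynchronization (ERD). A per-trial suppression vector deepens ERD
  across successive trials.
* **Forward model** — 32-channel 10–20 montage on a spherical head;
  Gaussian spatial-spread lead field with a 25 mm scale (intermediate
  between a focal cortical patch and broad volume-conducted smearing;
  wide enough for realistic channel correlation, narrow enough that left
  M1 projects clearly more to C3 than C4), 20 pink-noise distractor
  sources, pink plus white channel noise in microvolts.
* **Artifacts** — a fixed 400 ms biphasic blink template, frontally
  weighted, injected at Poisson times; optional square amplitude spikes.
  Determinism: identical seeds give bit-identical recordings.
* **Cohorts** — between-subject variability is parameter jitter with
  sd 0.05 around the ground-truth vector (neither the study nor the
  build contract states a value; 0.05 keeps subjects individually
  identifiable while making fixed-effects pooling non-trivial).

What the generator does **not** emulate: anatomical head geometry and
tissue conductivities, neural mass dynamics, EMG/line noise, keyboard
latencies, or non-stationary background rhythms. A green end-to-end test
therefore establishes internal consistency of the pipeline under its own
stated world, not validity on empirical EEG.

## Numerical choices

* **Integration** — a single compiled RK4 integrator (inputs held
  constant within each step) is shared between the generator and DCM
  inversion, so estimator and simulator cannot drift apart numerically.
  RK4 matches constant-input closed forms to ~1e-10; an explicit Euler
  mode is retained because the order-1 dt-halving property is a useful
  convergence diagnostic. Plain Euler at dt = 1e-3 has global error
  ~2e-4 and cannot meet a 1e-6 closed-form tolerance; RK4 can.
* **Filtering** — Butterworth sections designed by bilinear transform
  with prewarping, applied forward–backward (zero phase) with
  odd-reflection padding. A 4th-order band-pass at 0.1–50 Hz attenuates
  60 Hz by ~15 dB after both passes (the closed-form two-pass magnitude
  response, which the tests assert); 20 dB at 60 Hz requires order 8.
* **Resampling** — Fourier-method (spectral truncation), exact for
  band-limited signals; output length `round(n * fs_out / fs_in)`.
* **Epoching** — half-open windows `[tmin, tmax)`, 0-based sample
  arithmetic; −1000..4000 ms at 512 Hz is exactly 2560 samples.
* **Rejection** — block-level only, inclusive at ±100 µV (the study
  states the range, not the boundary semantics; a sample at exactly
  100 µV is retained). The ambiguous "lowest amplitude threshold
  0.2 µV" is implemented as a flat-channel detector (peak-to-peak below
  0.2 µV in any epoch marks the channel for neighbor interpolation);
  both readings are exposed in configuration.
* **Blink handling** — ICA is replaced by deterministic template
  regression at matched-filter-detected instants: reproducible, exactly
  testable (noise-free injected blinks cancel to machine precision), and
  honest about its assumption that blinks are stereotyped.
* **ERSP** — 7-cycle Morlet wavelets on a 4–30 Hz grid, divisive
  pre-stimulus baseline, `10 log10` scaling. Per-bin ERSP values on 100
  noise epochs fluctuate by ±1.5 dB (and more at the convolution edges),
  so the "flat map on noise" property is asserted on time-averaged and
  band/window-averaged values, which sit well inside ±0.5 dB.
* **Inversion controls** — convergence when the free-energy change
  drops below `tol` (default 1e-2 nats; pipeline default 0.1 for
  throughput), divergence guard after 8 consecutive decreases, jittered
  Cholesky for covariance factorizations, deterministic initialization
  at the prior mean.
* **Selection tie-breaks** — within-family argmax ties resolve to the
  lowest model index. Degenerate statistics have documented conventions:
  all-identical ANOVA groups give p = 1; a zero-variance nonzero paired
  difference gives the smallest representable p.

## Identifiability: what model selection can and cannot recover

Two facts about this model space, established numerically in the test
suite and worth stating plainly:

1. **The input family is strongly identified.** Data generated with SMA
   input are assigned to the SMA family with posterior > 0.95 by
   fixed-effects BMS over 20 subjects at 10 dB SNR (and symmetrically for
   PMC); summed evidence differences between families are on the order of
   thousands of nats.
2. **Within a family, the DLPFC-modulation toggles are not identified.**
   Because the modulatory boxcar covers nearly all periods in which the
   sources are active, a structure lacking the DLPFC→PMC/DLPFC→SMA
   modulations can reproduce data generated with them to a relative
   residual of ~4e-4 by adjusting its free intrinsic couplings: the
   models are likelihood-equivalent at this design's resolution. Only the
   return-edge toggle (which source feeds DLPFC) separates structures, by
   roughly 7 nats per 20 subjects. Consequently the best-model choice
   within a family is reliable only up to this equivalence class, and the
   acceptance test that demands exact generating-model recovery documents
   this limitation rather than hiding it. Single-condition, stereotyped
   trial designs simply do not dissociate "coupling" from "modulated
   coupling"; designs that fit multiple conditions jointly (as
   full-scale DCM studies do) are the remedy, and are out of scope here.

## Known limitations

* The source model is a Tikhonov minimum-norm inverse on a synthetic
  lead field; no anatomical forward model, so localization claims are
  limited to the simulated geometry.
* ROI center defaults are literature-style coordinates supplied as
  configuration, not data; override `default_roiset(centers = ...)` to
  match a specific atlas.
* Fixed-effects pooling assumes every subject expresses the same model;
  random-effects BMS is deliberately out of scope.
* The ANOVA groups couplings by edge with subjects as observations — one
  documented reading of an ambiguous published description.
* Paired t-tests assume the same subjects contribute to both compared
  streams, matching the within-subject session design.
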
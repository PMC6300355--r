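---
title: "Position-heading tuning fields, model comparison and population decoding"
author: "navfield"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Position-heading tuning fields, model comparison and population decoding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(navfield)
```

## The problem

During visually guided navigation in a virtual T-maze, a mouse's behavior at
every imaging frame is summarized by two spatial variables: its position
along the corridor, `z` (0–110 cm), and its heading angle, `theta` (bounded
in [-90, +90] degrees). Neurons in posterior parietal cortex appear
choice-selective — they form left- and right-choice activation sequences —
but that selectivity may be a by-product of spatial tuning: cells that prefer
particular combinations of `(z, theta)` will fire on the trials whose
trajectories pass through their preferred region, and trajectories diverge by
choice. This package implements the full analysis chain needed to test that
idea: per-neuron position–heading tuning-field estimation, nested comparison
of response models with and without an explicit decision variable, Bayesian
decoding of the trajectory from population activity, and psychometric /
neurometric choice analyses — together with a synthetic-session generator
that makes every stage testable without recordings.

## The tuning-field estimator

For each neuron, frames are binned on a `(z, theta)` grid into an occupancy
map `M_occ` and an accumulated-signal map `M_sig`. Both maps are filtered
with the same two-dimensional Gaussian kernel (SDs `sigma_z` in cm,
`sigma_theta` in degrees), and the field is the regularized ratio

    F(z, theta) = (M_sig_filt + lambda * F_mean) / (M_occ_filt + lambda)

where `F_mean` is the neuron's mean response and `lambda` (default 1
occupancy count) keeps the ratio finite and pulls it toward `F_mean` where
data are scarce. The estimate is exactly the local average response where
occupancy is high and degrades gracefully to the mean elsewhere.

Bandwidths are chosen per neuron by 10-fold cross-validation: trials (never
frames — consecutive frames are strongly autocorrelated) are split into
choice-balanced folds; for every candidate `(sigma_z, sigma_theta)` the field
is fit on 90% of trials and scored on the held-out 10% with the normalized
error

    eps = <(Fhat(z(t), theta(t)) - F(t))^2>_t / <(F(t) - F_mean_train)^2>_t

averaged over folds; the arg-min candidate wins. `eps = 1` means the model
predicts no better than the training mean, `eps = 0` is perfect prediction.

Numerical choices worth knowing:

* **Grid.** Default 2 cm x 3 degree bins (55 x 60). The grid is deliberately
  finer than any plausible bandwidth, so smoothing — not binning — sets the
  effective resolution.
* **Boundary handling.** The smoothing kernel uses mirror (half-sample
  reflection) boundaries. The folded kernel matrix is doubly stochastic, so
  smoothing conserves each map's total mass exactly *and* leaves constant
  maps unchanged — both properties matter because the field is a ratio of
  the two smoothed maps, and any edge attenuation would bias it at the
  corridor ends. `theta` is bounded, not circular, so no wrap-around is
  applied.
* **Candidate set.** Log-spaced, `sigma_z` in {2, 4, 8, 16, 32} cm x
  `sigma_theta` in {3, 6, 12, 24, 45} degrees, overridable. Exact ties are
  broken toward larger bandwidths (smoother fields generalize better at
  equal measured error).
* **Lookup.** Fields are evaluated along trajectories by bilinear
  interpolation between bin centers (clamped at edges); nearest-bin lookup
  is available for strict parity with the binned formula.
* **A caveat on flat optima.** The cross-validated error surface is often
  nearly flat across small bandwidths; the arg-min then lands on a small
  `sigma_theta` even for broadly tuned neurons, whose flat peaks make the
  field's arg-max jitter by a few degrees. This affects arg-max-based
  summaries, not prediction quality.

```{r fields, eval = FALSE}
sess <- simulateSession(simulationConfig(nTrials = 200, seed = 1))
sess <- generateResponses(sess, generatePopulation(50, seed = 2), seed = 3)
fit <- selectBandwidths(sess, responses(sess)[1, ], defaultGrid())
fit$bandwidths
cvError(fit$field)
```

## Models with an explicit decision variable

Three nested response models are compared:

* `f(z, theta)` — the position–heading field above;
* `f(z, d)` — position and decision: one position profile per choice class,
  flat in `theta`. Implemented with the same regularized-ratio machinery on
  a grid whose `theta` axis is smoothed uniformly, so only `sigma_z` is
  cross-validated per class;
* `f(z, theta, d)` — one full position–heading field per choice class
  ("two sub-models", each with its own cross-validated bandwidths).

Quality of fit is the Pearson correlation, across trials, between
trial-averaged measured and cross-validated predicted activity (for each
choice-balanced group of trials, activity is predicted from models
re-estimated on the other 90%). Before averaging, frames are dropped at
positions where heading and choice are practically interchangeable as
predictors: per position bin, the rank-sum auROC between left- and
right-choice heading samples is computed, rectified to `max(A, 1 - A)`, and
bins exceeding 0.95 are excluded. The mask is computed once per session from
behavior alone. Neurons whose trial-mean vector has zero variance are
reported as missing and excluded from medians.

A known limitation at simulation scale: with a few hundred trials, each
choice-conditioned sub-model sees only its own class's trajectories, so in
the retained mid-corridor zone (where heading and choice remain correlated,
auROC 0.85–0.93) the extended model pays a small coverage penalty relative to
`f(z, theta)`. The comparison's *direction* is unaffected — adding the
decision to the position–heading model never helps when the underlying
tuning is purely spatial — but the per-neuron correlation difference sits a
few percent below zero rather than at zero.

## Choice-conditioned activation sequences

To reconstruct the sequence plots, each neuron's activity is trial-averaged
separately over left- and right-choice trials on a normalized-time axis
(50 bins by default; per-trial activity is linearly interpolated to bin
centers). Neurons are assigned to the choice class with the larger peak,
ordered by peak time, and peak-normalized. The ordering derived from measured
activity can be reused for model predictions, so the correspondence between
measured and predicted sequences is quantified by the rank correlation of
peak times under a common ordering.

## Bayesian population decoding

Assuming each neuron's response at a location is Gaussian around its field
value, `R_i(z, theta) ~ N(mu_i(z, theta), sigma_i)`, with `sigma_i^2` the
neuron's overall response variance across the session (population 1/n
convention, floored at 1e-6 of the trace range), the log posterior over the
grid at one frame is, up to a constant,

    log Post(z, theta) = -sum_i (mu_i(z, theta) - r_i(t))^2 / (2 sigma_i^2)
                         + log Pr(z, theta)

with the prior `Pr(z, theta)` a smoothed, normalized occupancy map of the
training trials (zero-occupancy bins get 1e-8 mass before normalization so
the log prior stays finite; prior smoothing defaults to 4 cm x 6 degrees).
Decoding is leave-one-trial-out: fields and prior are re-estimated without
the decoded trial. Bandwidths are selected once per neuron on the full
session and reused across refits — re-selecting per held-out trial would be
quadratic in session length while changing the selected values only at the
fold-noise level. Each frame is decoded independently (no temporal
smoothing); the MAP is the arg-max bin, ties broken toward the first bin in
z-outer (theta-fastest) order.

The decoded heading feeds the *neurometric* analysis: at each position
checkpoint, the decoded `theta` at the trial's first crossing is passed to
the identical cross-validated threshold classifier used for the behavioral
heading analysis, yielding neurometric predictability-versus-position curves
and per-contrast neurometric functions directly comparable to their
behavioral counterparts.

## Behavioral analyses

The psychometric curve is the fraction of rightward choices per signed
contrast with Clopper–Pearson 95% intervals, fitted by maximum likelihood
with the standard two-alternative forced-choice form

    P(R | c) = lapse + (1 - 2 lapse) * Phi(slope * (c - bias))

Baited repeat trials are excluded from psychometric fits by default (they
bias contrast-conditional choice frequencies) but participate in field
estimation. Choice predictability from heading uses a deliberately weak
decision rule — a single threshold on `theta`, with orientation and cut
chosen on training folds and scored on held-out folds — shared verbatim with
the neurometric analysis so the two curves are comparable by construction.

## The synthetic-session generator

The generator produces sessions with the statistical structure the analyses
assume, not a mechanistic mouse:

* **Choices** are drawn first, from the lapse-equipped cumulative-Gaussian
  psychometric function of signed contrast (defaults: slope 8 per unit
  contrast, bias 0, lapse 0.05, contrasts ±{0.5, 0.25, 0.125} and 0). Drawing
  the choice before the trajectory decouples choice statistics from
  trajectory noise and makes the psychometric parameters exactly
  recoverable.
* **Trajectories**: `z` advances at 20 cm/s (SD 2 cm/s per frame, floored to
  stay monotone), giving ~5.5 s trials at the 7.5 Hz default frame rate
  (within the 6–10 Hz effective sampling of the imaging setup). Heading
  follows an Ornstein–Uhlenbeck-style drift toward a target angle of ±65
  degrees on the chosen side whose magnitude ramps linearly with corridor
  progress — emulating gradual commitment, so trajectories toward the two
  choices overlap early and diverge along the corridor. The relaxation rate
  is `1.6 * (0.25 + |contrast|)` per second, so easier trials diverge
  sooner; diffusion noise is 25 deg s^-1 Hz^-1/2, and heading reflects at
  ±90 degrees. At zero contrast either side is rewarded with probability
  0.5 (the task's zero-contrast reward rule is a free choice).
* **Baiting** (off by default): an error trial is repeated with the same
  stimulus, flagged `isRepeat`, until answered correctly.
* **Neurons** are unimodal Gaussian bumps over `(z, theta)` with centers
  tiling the reachable region (the heading envelope widens with `z`), widths
  8–25 cm x 10–30 degrees, amplitudes 0.5–2 with baselines up to 0.2
  (response units), and additive Gaussian observation noise with SD 0.3 x
  amplitude by default — exactly the decoder's generative assumption. A
  `choiceGain < 1` makes the truth decision-dependent by scaling the field
  on non-preferred-choice trials. An optional exponential calcium-kernel
  convolution exists for robustness experiments and is off by default,
  because every model in the chain is defined on instantaneous responses.

What the generator does *not* emulate: slow calcium indicator dynamics (by
default), neuropil contamination, non-Gaussian and signal-dependent imaging
noise, slow drifts in tuning or behavior state, timeout/aborted trials, and
any visual- or motor-specific response component. Passing tests therefore
demonstrate that the estimators and decoder are correct and well-calibrated
under their own assumptions — not that those assumptions hold in recorded
data.

## Problem sizes and reproducibility

The packaged analyses and tests run on sessions of 200 trials (~8,000
frames) with populations of 50 neurons for field recovery and model
comparison and 100 neurons for decoding — sizes chosen to match a typical
recording session while keeping every analysis comfortably interactive on a
single CPU. Every stochastic step (simulation, population sampling, noise,
fold assignment, classifier folds) is seeded; `runPipeline()` derives all
stage seeds from one master seed, and two runs from the same configuration
produce byte-identical reports (wall-clock entries in the manifest aside).

```{r pipeline, eval = FALSE}
cfg <- runConfig(simulation = simulationConfig(nTrials = 200),
                 nNeurons = 25, masterSeed = 1)
runPipeline(cfg, "navfield-run")
```
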
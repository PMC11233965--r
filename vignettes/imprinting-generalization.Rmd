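---
title: "Predispositions, imprinting dynamics and color generalization: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predispositions, imprinting dynamics and color generalization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imprintr)
library(dplyr)
```

This vignette documents the models implemented in `imprintr`, the
assumptions behind them, the numerical choices made where the problem left
them open, and what the synthetic-data generators do and do not emulate.

## The stimulus continuum

All models live on an ordered one-dimensional color continuum (for example
the 8-stimulus red→yellow series). Only the *order* of the stimuli is
empirically grounded; their perceptual spacing is not measured. We therefore
normalize the axis to [0, 1] and space stimuli equally by default —
`build_continuum()` accepts explicit positions for users who have a
discriminability-scaled axis, but no receptor-noise scaling is attempted.
Perceptual distance is `|x_i − x_j|`: symmetric, zero only on the diagonal,
and additive along the line.

A single **ratio choice rule** is used everywhere a model must turn two
preference values into a binary choice:
$P(\text{choose } i \text{ over } j) = \mathrm{pref}_i / (\mathrm{pref}_i + \mathrm{pref}_j)$.
Using one rule across the unbiased and the biased model isolates every
difference between their predictions to the preference structure itself.

## The unbiased null model

Under Shepard's universal law, the probability of responding to a test
stimulus as to the trained one decays with their perceptual distance. The
null model assigns the familiar stimulus a value of 1 and a test stimulus
at distance $d$ a value of $s(d)$, where $s$ is `exp(−d/λ)` (default; the
classical exponential form) or a Gaussian `exp(−d²/2τ²)`. Through the ratio
rule the raw familiar preference is $100/(1+s(d))$ percent. Because $s$
depends on distance only, the null prediction is *symmetric* around the
imprinted stimulus and *monotone* in distance under any kernel and scale —
which is what makes it falsifiable by asymmetric gradients or
novelty preferences.

How a similarity value becomes a choice prediction is a genuine design
choice: we adopted value-1-vs-$s(d)$ plus the shared ratio rule, rather
than, say, treating $s$ directly as a choice probability, precisely so the
null and biased models differ only in their preference structure. Since the
kernel scale for the null curve is not empirically fixed, only the
qualitative properties (symmetry, monotonicity, bounds) are asserted;
`fit_unbiased_scale()` offers a 1-D grid search for users who want a
best-fitting scale.

## The predisposition + update model

The biased model holds a strictly positive preference per stimulus and
treats imprinting as a multiplicative, Gaussian-weighted update:
$\mathrm{pref}_{i,t+1} = \mathrm{pref}_{i,t}\,(1 + \alpha\, w_i)$ with
$w_i = \exp(−(x_i − x_{\text{imprint}})²/2σ²)$, followed by renormalization
of the curve to its maximum. Defaults are α = 0.01 (learning speed),
σ = 0.2 (update width), 400 steps, with read-outs at t = 100 (short, about
one day of analysed imprinting exposure) and t = 300 (long, about five
days). Three interpretive choices deserve note:

* **σ is on the normalized axis.** The width is stated without units; on a
  [0, 1] axis with 8 equally spaced stimuli, σ = 0.2 spans roughly 1.4
  inter-stimulus steps, a "narrow" bump relative to the full range. It is a
  plain argument for users with a different axis convention.
* **The weight's peak height is fixed at 1.** Any other height is
  indistinguishable from rescaling α, so it is not a free parameter.
* **Normalization to the maximum** is implemented exactly as stated, though
  preference *ratios* — and hence every choice probability — are invariant
  to whether one normalizes to the maximum, the sum, or not at all. This
  invariance yields the closed form
  $\mathrm{pref}_{i,T}/\mathrm{pref}_{j,T} =
  (\mathrm{pref}_{i,0}/\mathrm{pref}_{j,0})\,
  \left(\frac{1+\alpha w_i}{1+\alpha w_j}\right)^{T}$,
  which the test suite asserts against the iterated simulation at
  tolerance 1e−9 — an independent oracle for the whole dynamics.

**Initialization from predisposition tests.** First-exposure double-choice
proportions are inverted through the ratio rule
($\mathrm{pref}_a/\mathrm{pref}_b = c/(1−c)$ for a measured proportion $c$),
chained from an anchor stimulus fixed at 1, and unmeasured stimuli are
filled by linear interpolation of preference along position (constant
beyond the measured ends). Linear-in-position fill is the simplest
order-preserving rule consistent with the three measured anchors
(Red1 ≈ Orange at hatching, Red1 about twice Yellow1); any monotone fill
between the same anchors produces qualitatively identical dynamics.
Proportions of exactly 0 or 1 are rejected (the ratio is undefined), as are
pair graphs that do not connect every measured stimulus to the anchor.

**Read-out and scaling.** The model's raw prediction for test stimulus $j$
at step $t$ is $100\,\mathrm{pref}_{\text{imprint},t} /
(\mathrm{pref}_{\text{imprint},t} + \mathrm{pref}_{j,t})$ percent. Raw
predictions are rescaled affinely about the 50% chance anchor so that the
curve's largest deviation from chance maps to the maximum observed
preference — by default the rehearsal-trial maximum, a config choice since
either the rehearsal or the test maximum is defensible. The scaling is
sign-preserving: a raw prediction below 50% (novelty preference) stays
below 50% after scaling. One consequence worth knowing: the scaled curve
always spans exactly [50, max_observed], so comparisons of *how fast* a
preference forms (the predisposed Red1 forms its curve faster than the
non-predisposed Yellow1) must be read from the raw predictions, where the
curve range at t = 100 differs several-fold between the two imprinting
stimuli.

`fit_readout()` scans a grid of steps for the best R² against an observed
curve, breaking ties toward the earliest step (the more conservative claim
about how much imprinting has accrued).

## The Bayesian ideal observer

A chick that must decide whether a colored object is its imprinting target
can be modelled as computing
$P(t\mid c) = P(c\mid t)P(t) / (P(c\mid t)P(t) + P(c\mid \neg t)(1−P(t)))$.
$P(t)$ is a user-supplied constant (default 0.5). The two likelihoods come
from color-frequency tables: the target's color distribution and the
environment's. The default binning of continuous loci is categorical —
each locus is labelled by its dominant cone class, or "achromatic" when no
relative catch reaches 0.35 — because color prevalence in natural-spectra
libraries is most robustly summarized categorically; a Cartesian grid
binning (`bin_tetra_grid()`) is available when finer resolution is wanted.
The threshold 0.35 sits between the achromatic value 0.25 and clear
single-cone dominance; it is exposed as an argument. The package ships no
empirical hen or environment tables — those depend on external reflectance
databases — but the synthetic library generator reproduces the directional
structure (red rare in the environment, enriched on the target) that makes
red a high-likelihood-ratio color.

## Avian color space

Quantum catches are $QC_i = \int_{300}^{700} R(\lambda) S_i(\lambda)
I(\lambda)\, d\lambda$, computed by the trapezoidal rule on a 1-nm grid
spanning the integral's stated limits; the illuminant defaults to a
constant 1. Spectra are linearly interpolated onto the grid, with values
outside a spectrum's measured range set to zero. Trapezoidal accuracy is
ample for smooth reflectances: refining to 0.25 nm moves catches by about
1e−5 relative with ~35-nm-wide cone sensitivities (the error scales with
the integrand's curvature), which is orders of magnitude below any
biological effect of interest.

The four catches are normalized to sum to 1 and projected by
$x = \frac{1-2s-m-u}{2}\sqrt{3/2}$, $y = \frac{-1+3m+u}{2\sqrt 2}$,
$z = u - \frac14$: a regular tetrahedron with each pure-cone vertex at
distance 0.75 from the achromatic origin (both properties are asserted in
the tests).

The cone sensitivities shipped by `synthetic_receptor_set()` are smooth
unimodal curves peaking near 370/445/508/565 nm. They are **synthetic
stand-ins** with the qualitative shape of average UV-sensitive avian cone
sensitivities, intended for tests and examples; analyses of real
reflectance data should load measured sensitivity functions through
`load_spectra()` (delimited text, `wavelength_nm` first column, one column
per sample — exports from FReD- or USGS-style libraries should be converted
to this layout).

## The behavior pipeline

Frames from markerless tracking are filtered at likelihood ≥ 0.9 (the
boundary value is kept). Zones are the regions within 20 cm of each monitor
in the 90 × 60 cm arena; a coordinate exactly on the 20-cm line belongs to
the monitor zone, a boundary policy we had to fix since "within 20 cm"
leaves it open. Each retained frame credits one frame interval of dwell
time to its zone; gaps from discarded frames are *not* interpolated — the
simplest unbiased estimator, since discarded frames are (in the generator,
and plausibly in real data) unrelated to position. The preference index is
$100\, t_{\text{fam}}/(t_{\text{fam}}+t_{\text{unfam}})$; a trial with no
choice-zone time at all yields `NA` and is excluded. Rehearsal trials
(familiar stimulus alone) run through the same index against the
blank-monitor zone, giving the baseline attachment strength.

Statistics are deliberately standard and delegated: one-sample t-tests
against 50% (`stats::t.test`, two-sided, α = 0.05), Holm step-down
correction (`stats::p.adjust`), and degree-0/1/2 least-squares gradient
fits (`stats::lm`) selected by AICc — corrected AIC is the right default at
n = 8 points; AIC and adjusted R² are available as alternatives, and exact
fits are handled by clamping the residual sum of squares so that ties
resolve toward the simpler polynomial. Mixed-model ANOVA machinery is out
of scope; users who need it should take the per-trial tibbles into `lme4`
or `ez` directly.

## What the synthetic data emulate — and what they do not

The generators reproduce the *designs* exactly: 8 sessions × 10 trials of
10-min imprinting exposure per imprinting day (1 or 5 days), test days of
8 sessions × (2 rehearsal + 8 test) trials with every test stimulus once
per session in randomized order, and 6 × 20-min predisposition trials with
sides counterbalanced 3/3. Behavior is generated top-down: the familiar
side's share of choice-zone time is drawn from a Beta distribution whose
mean is the ratio-rule choice probability and whose concentration (default
10) reproduces between-trial SEMs of a few percentage points at realistic
sample sizes; center time is a fixed fraction (default 0.1, since real
chicks spend >90% of their time near the monitors); frames are a reflected
Gaussian random walk confined to zone bouts that match the trial's zone
times to within one frame interval, at a default 10 fps with 2% of frames
given sub-threshold tracking likelihood.

This emulates the *statistical* structure the pipeline consumes, not real
chick behavior: there is no locomotor autocorrelation beyond the walk, no
within-trial drift of preference, no sleep, no first-approach dynamics, and
tracking errors are independent of position, whereas real pose-estimation
failures cluster (occlusion near walls and feeders). Passing the recovery
tests therefore shows the pipeline and models are *internally consistent*
and unbiased under known ground truth — it does not validate the behavioral
model against real chicks. Synthetic reflectance libraries are smooth
low-order spectra (Gaussian bumps at 330–520 nm for the green/brown/grey
bulk; sigmoidal long-pass curves rising near 590–620 nm, phaeomelanin-like,
for the red minority); real libraries contain multimodal and glossy spectra
these do not mimic.

Problem sizes used by the test suite — 48 chicks per simulated experiment
(matching the power-analysis-driven group sizes of the original designs),
1e5-frame pipeline-consistency runs, 200–500-spectrum libraries — keep the
whole suite under a minute while leaving Monte-Carlo error well inside the
asserted tolerances (the 48-chick predisposition recovery has a standard
error of about 0.009 against a ±0.03 assertion).

## Known limitations

* The stimulus axis is ordinal-equal-spaced unless the user supplies
  positions; no discriminability scaling is computed.
* α and σ are fixed constants, not fitted to data; the package provides no
  stochastic trial-by-trial learning rule.
* The Bayes module ships machinery plus synthetic tables only; empirical
  conclusions about natural color statistics require external reflectance
  databases.
* Receptor-noise discriminability (ΔS/JND) and double-cone luminance
  channels are deliberately absent from the color module.
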
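---
title: "An ideal-observer model of sound localization with unknown source spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An ideal-observer model of sound localization with unknown source spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(soundloc)
```

## The problem and the model

A listener receives left- and right-ear signals that are the source
spectrum filtered by the direction-dependent acoustics of head and ears
(the HRTF). Decoding the direction is an inverse problem, and it is
ill-posed whenever the source spectrum is unknown: a spectral notch in the
ear signal may come from the pinna (and carry direction information) or
from the source itself (and carry none). `soundloc` implements a Bayesian
ideal observer that resolves this ambiguity with a *prior on source
spectra* learned from an ensemble of real-world sounds.

The acoustic input is the stacked vector of an ITD coordinate and the two
ears' log-magnitude spectra sampled at ERB-spaced centre frequencies,

$$\mathbf{X} = [X_\mathrm{ITD},\ \mathbf{X}^l,\ \mathbf{X}^r],$$

and the posterior over direction $\theta$ on a discrete grid is

$$P(\theta \mid \mathbf{X}) \propto P(\mathbf{X}\mid\theta)\,P(\theta),
\qquad P(\mathbf{X}\mid\theta) \sim
\mathcal N\!\big(\mathbf{T}(\theta), \Sigma\big),$$

with a uniform spatial prior $P(\theta)$. The template
$\mathbf{T}(\theta)$ combines the HRTF filtering for $\theta$ with the
most likely source spectrum (the prior mean); the covariance $\Sigma$ is
independent of direction and input, and splits into a measurement-noise
part and a source-uncertainty part:

$$\Sigma = A\,\Sigma_\mathrm{noise}\,A^\top + (AB)\,\Sigma_S\,(AB)^\top,$$

where $A$ is the (linear) feature map applied to the stacked input and
$B$ stacks one source spectrum identically onto both ears. Inputs are
expressed in units in which discrimination noise is input-independent:
log-magnitude in dB, and the ITD through a compressive
just-noticeable-difference (jnd) transform. The decision rule is maximum
a posteriori over the grid.

Five feature representations are built in (`build_feature_map()`):

* `LOGMAG` — the raw stacked input;
* `ISD` — ITD plus the channelwise interaural spectral difference
  $\mathbf{X}^l - \mathbf{X}^r$, which cancels the source spectrum
  exactly and therefore needs no source prior;
* `BIN_SG` — ITD, broadband ILD
  $\tfrac1N\sum_i (X^l_i - X^r_i)$, and both ears' spectral gradients
  $dX_i = X_{i+1} - X_i$;
* `POS_SG` — `BIN_SG` with the gradients rectified (only positive
  slopes relayed), a hypothesized physiological code;
* `IPSI_SG` — `BIN_SG` restricted to the gradient of the ear on the
  side the measured ITD points to.

Because all maps are linear (up to the final rectification/selection),
Gaussian priors propagate exactly through $A\Sigma A^\top$, and the
`BIN_SG` set is provably information-equivalent to `LOGMAG` whenever the
overall level carries no directional information
(`spectral_contrast_map()` is full-rank).

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| filterbank span | 300–12000 | Hz | audible band with reliable spectral cues; 30 channels at 1-ERB spacing |
| channel spacing | 1 | ERB | approximately independent auditory channels |
| `sigma_itd_jnd` | 1 | jnd | by construction of the jnd coordinate |
| `sigma_channel_db` | 1 | dB | order of spectral discrimination thresholds; scalar or per channel |
| ITD jnd curve | 20→60 | µs/jnd | compressive: thresholds widen from 20 µs near zero to 60 µs at 600 µs; any tabulated (ITD, jnd) curve can be substituted |
| elevation cut | −45 | deg | lower cone unmeasured in HRTF rigs; retains (1+sin 45°)/2 ≈ 85.4% of a uniform grid |
| region mask | 30 / ±60 | deg | benchmark response region near the midsagittal plane, front and rear |
| ripple `f_ref_hz` | 1000 | Hz | phase reference of the log-frequency cosine |
| SH resampling | order 15, λ = 1e−4 | — | enough degrees for smooth HRTF fields; small ridge for stability |

## The synthetic-data generators

Real HRTF databases and audio corpora are external inputs; the package
ships generators that emulate their statistical structure so that every
result is reproducible from code alone.

**`synth_corpus()`** draws log-magnitude frames from a Gaussian with (i)
a mean spectrum falling ~30 dB from 300 Hz to 12 kHz, (ii) a 12-dB-sd
common-level term (sounds differ wildly in overall level — the dominant
background covariance of real corpora), and (iii) channel fluctuations of
8.6 dB sd with a 1.5-ERB correlation length. The induced
gradient-domain prior has a std of
$\sqrt{2\sigma^2(1 - e^{-1/L})} \approx 8.5$ dB/ERB, the value reported
for environmental-sound ensembles, and the first-difference map
annihilates the level term exactly ($D\mathbf{1}=0$), reproducing the
tridiagonal, negative-off-diagonal structure of measured gradient
covariances.

**`synth_hrtf()`** emulates human directional filtering: a Woodworth
spherical-head ITD (8.75 cm radius, ~660 µs maximum), an ILD growing
with lateral angle and frequency (to ~20 dB), and per-ear spectra with
two pinna notches sweeping in opposite senses with the polar angle
(28 dB deep near 6.5 kHz, 15 dB near 10 kHz, 0.8 ERB wide) plus a
~10 dB concha peak near 4 kHz whose gain varies front-to-back. Together
the features make every grid direction spectrally distinct. Small
per-ear jitters (0.25 ERB notch position, 1.5 dB depth) reproduce the
left/right asymmetries of real ears. The jitter magnitude was fixed by
one calibration: an observer using only interaural differences (`ISD`)
should show the ~0.2 polar confusion level that such observers reach on
measured human HRTF sets — interaural asymmetry is precisely what gives
the ISD its residual polar information near the midline, and it is not
directly measurable from published summaries. With the defaults the
generator reproduces, without further adjustment, the benchmark
phenomenology: a gradient-observer confusion peak near 1 ripple/octave,
near-linear growth of errors with ripple depth, and density-independent
ISD errors.

What the generators do *not* emulate: measurement noise in HRTF data,
frequency fine structure beyond a scalar notch/peak parameterization,
torso reflections, non-Gaussian corpus statistics (heavy tails,
harmonicity), and inter-channel dependencies beyond second order.
Passing tests on these fixtures therefore demonstrate correctness of the
machinery and of the qualitative mechanisms, not quantitative agreement
with any individual's HRTF or any specific corpus; for that, point
`load_sofa()` at measured SOFA files and `chop_corpus()` at a real corpus
(see the README).

## The benchmark experiments

`run_ripple_experiment()` reproduces the classic rippled-spectrum
paradigm: stimuli whose log-magnitude is a cosine in log-frequency with
depth $A$ (dB, peak-to-trough), density $\rho$ (ripples/octave) and
phase $\phi$. Per trial, the observation is the true direction's HRTF
filtering of the *actual* stimulus plus measurement noise only — the
source-uncertainty part of $\Sigma$ parameterizes the decoder's beliefs,
not the world, so it is never sampled. Performance is the polar error
rate: the proportion of responses whose wrapped polar-angle error
exceeds 45°; a variant excluding trials with large lateral errors is
available (`exclude_lateral_deg`), matching the stricter benchmark
convention. Rates are pooled over subjects and directions into one value
per condition. `run_flat_experiment()` maps the mean great-circle error
per direction for a flat-spectrum source under different decoder
variants, and `response_distribution()` exposes response "attractors" —
directions that accumulate erroneous responses because their gradient
templates resemble the stimulus gradient.

The mechanism that makes intermediate ripple densities hard is visible
in `sg_std()`: the stimulus' gradient std rises with density, peaks
around 1–2 ripples/octave above the ~8.5 dB/ERB the prior expects, and
falls again as the cochlear sampling low-passes dense ripples. Stimuli
in that range do not fit the prior and are misattributed to directional
filtering.

## Numerical choices

* **Covariance assembly and factorization.** $\Sigma$ is assembled once
  per (representation, prior, noise) and Cholesky-factored once;
  likelihood evaluation over the grid whitens templates once and never
  refactors per trial. If the factorization fails, a jitter of
  $10^{-10}\,\mathrm{tr}(\Sigma)$ is added to the diagonal.
* **Estimated priors** use the unbiased ($n-1$) covariance; eigenvalues
  below $-10^{-8}\,\mathrm{tr}$ raise an error, and mildly negative ones
  are clipped to zero with a warning.
* **Rectified gradients (`POS_SG`).** Rectification destroys
  Gaussianity; observation and template are both rectified and the
  `BIN_SG` covariance is retained. This is one consistent reading of a
  likelihood "derived from" the linear case; it is an approximation, and
  it preserves the zero-noise fixed point (rectified template matches
  rectified observation exactly).
* **Ipsilateral selection (`IPSI_SG`)** conditions on the sign of the
  measured ITD (left at exactly zero, a measure-zero tie under
  continuous noise) and evaluates a reduced Gaussian with the
  contralateral gradient rows/columns dropped; the ITD/ILD cross-terms
  are retained.
* **Posterior** normalization uses log-sum-exp; MAP ties break to the
  lowest index.
* **Log floor.** Channel values are clamped at −120 dB so silent frames
  stay finite; corpus frames quieter than −60 dBFS RMS are discarded.
* **Windowing.** Corpus frames use a Hann window and band-integrated
  power; impulse responses use a rectangular window and band-averaged
  squared magnitude (a transfer-function estimate), since an HRIR is a
  deterministic response, not a stationary signal.
* **Seeds.** One master seed; sub-seeds for subjects, conditions and
  runs are derived with a modular counter (kept below $2^{31}$), so any
  block can be re-run independently of execution order. Noise is drawn
  per (subject × condition × replicate) block in a single vectorized
  call; trials within a block follow the fixed direction order, so runs
  are reproducible and block-order independent.

## Design choices made where the design was open

* **Elevation cut sign.** The retained fraction of a uniform grid pins
  the cut at −45° (85.4% ≈ (1+sin 45°)/2 of 2000 ≈ 1708 directions);
  a +45° cut would keep only 15%. We therefore use −45°.
* **Region band.** The response region is implemented in polar angle
  (front band [−60°, 60°], rear band [120°, 240°]); on the reference
  grid this reproduces the canonical 599-direction count. An
  elevation-band variant is available via `region_mask(mode =
  "elevation")`.
* **Band integration.** Channel magnitudes integrate a rectangular
  1-ERB band of the periodogram. Gammatone-weighted integration would
  smooth channel edges but changes none of the structural results.
* **Frame levels are not normalized** before pooling corpus statistics:
  the large common-level variance is part of what the listener must be
  robust to, and it is exactly the component the gradient
  representation discards.
* **ITD extraction from HRIRs** defaults to a 10%-of-peak onset
  difference (on 8× upsampled responses); a cross-correlation method
  (`itd_method = "xcorr"`) is more accurate for smooth synthetic
  responses. The jnd curve is tabulated and fully replaceable.

## Problem sizes used in the shipped analyses

The packaged tests and the acceptance analysis run at the reference
configuration: a 2000-direction uniform grid (1707 after the elevation
cut, 599 in the response region), a 20-subject synthetic cohort for the
precision analysis (11,980 trials per run, 20 runs), a 6-subject cohort
for the ripple-curve analyses, and 20,000-frame synthetic corpora for
prior estimation (50,000 where recovery accuracy itself is under test).

## Known limitations

* No dynamic cues (head or source movement), no reverberation or noise
  floor, no non-uniform spatial prior, and no model of pointing error —
  the decoder's error is decision error only.
* The `POS_SG` covariance treatment is approximate (see above).
* The supplementary-grade jnd calibration of the ITD transform and any
  frequency dependence of the spectral noise are represented by
  configurable defaults, not measured values.
* SOFA I/O requires a Python interpreter with `h5py` on the PATH (SOFA
  is a netCDF-4/HDF5 container).
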
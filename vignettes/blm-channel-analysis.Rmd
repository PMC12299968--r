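---
title: "Methods: simulation, idealization and classification of BLM single-channel recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulation, idealization and classification of BLM single-channel recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(blmchannel)
```

This vignette documents the model behind the package, the parameter choices
and their defaults, the numerical decisions that matter for correctness, and
the known limitations.

## 1. The measurement model

A black lipid membrane recording is a current trace $I(t)$ (pA) at fixed
holding potential $V$ (default 100 mV), sampled at $f_s$ (default 5 kHz) and
low-pass filtered at a bandwidth $f_c = f_s/20$ (250 Hz) by a 4-pole Bessel
filter, the standard anti-alias/noise filter of patch/BLM amplifiers.
Conductance is Ohmic throughout: $G\,[\mathrm{pS}] = 1000\, I\,[\mathrm{pA}]
/ V\,[\mathrm{mV}]$, so at 100 mV a 14.40 pS channel is a 1.440 pA
deflection.

Membrane-inserted channels produce upward current excursions from a flat
baseline. Four signature classes are modelled, with literature-derived
defaults (`abeta_config()`):

| class | waveform | mean G (pS) | lifetime law (ms) | rate /s |
|---|---|---|---|---|
| spike | exponential decay | 13.38 ± 10.28 | log-normal, median 9.04 | 0.10 |
| bump | raised cosine | 8.79 ± 3.34 | log-normal, median 321.30 | 0.12 |
| step | rectangle | 14.40 ± 7.64 | log-normal, median 277.20 | 0.50 |
| erratic | reflected random walk | peak > 20 pA | log-normal, median 277.20 | 0.01 |

`gramicidin_config()` instead produces a single step class at
11.73 ± 3.13 pS with **exponential** lifetimes whose 75th percentile is
165 ms (median $165\ln 2/\ln 4 = 82.5$ ms, mean $165/\ln 4 \approx 119$ ms).

## 2. Generator design and calibration

**Arrivals.** Events arrive as independent Poisson processes per class;
placement avoids overlap by rejection-redraw (an event failing 10⁴ placement
attempts raises an error rather than silently overlapping).

**Conductances** are drawn from a normal truncated at zero (a conductance
cannot be negative). Naive truncation biases the post-truncation mean upward
— by ~2 pS for the spike class, whose SD is large relative to its mean — so
the location parameter is *calibrated*: `uniroot()` solves
$\mu + \sigma\,\varphi(\mu/\sigma)/\Phi(\mu/\sigma) = m$ so that the
post-truncation mean equals the published class mean $m$ exactly. Without
this, large-sample mean-recovery tests would fail honestly.

**Lifetimes.** The published lifetime SDs exceed the means (e.g. step:
277.20 ± 371.14 ms), which a normal law cannot produce; a log-normal with
median equal to the printed central value and $\sigma$ solved from
$\mathrm{SD} = m\, e^{\sigma^2/2}\sqrt{e^{\sigma^2}-1}$ reproduces both
numbers. Gramicidin lifetimes are exponential, the classical dimer
dissociation law, anchored at the 165 ms 75th percentile.

**Waveforms.** The rectangle's plateau equals the drawn mean conductance.
The bump is $\bar I\,(1-\cos 2\pi (i-\tfrac12)/n)$, whose discrete midpoint
mean is exactly $\bar I$. The spike is $P e^{-2t/L}$ with $P$ chosen so the
time average equals the drawn mean (peak/mean ≈ 2.3, matching the published
spike peak-to-mean ratio). Erratic events are reflected Gaussian random
walks rescaled to a peak of $20 + \mathrm{Exp}(10)$ pA.

**Noise and filtering.** The Bessel filter is designed from the analog
4-pole Bessel prototype (−3 dB magnitude normalization) by prewarped
bilinear transform, normalized to exactly unit DC gain, and applied causally
with a first-sample offset so a trace that starts on its baseline has no
startup transient. `noise_sd_pA` (default 0.15) is the **post-filter**
noise SD — the number one would quote from a quiet stretch of a real
recording — so the generator scales the white noise up by the inverse of the
filter's white-noise gain ($\sqrt{\sum h_k^2} \approx 0.32$ at
$f_c/f_s = 1/20$) before filtering.

Everything is driven by one integer seed; identical seeds give bit-identical
traces and truth tables.

## 3. Idealization

**Baseline.** Level = sample median; noise scale = Gaussian-consistent MAD
with one exclusion pass (samples above median + 3·MAD₀ are dropped and the
MAD recomputed). At the default event rates, events occupy ~25% of the trace
and inflate the plain MAD by ~30%, which would raise the detection threshold;
the single trimming pass removes that bias while staying fully robust.

**Detection** is hysteresis thresholding: an event opens above
baseline + $k_{on}\sigma$ ($k_{on}=4$), closes below baseline +
$k_{off}\sigma$ ($k_{off}=1$), and its boundaries are extended outward to
the nearest baseline crossings — operationalizing "from the beginning of the
current increase to the current drop". Events closer than `merge_gap_ms`
(5 ms) are merged and events shorter than `min_duration_ms` (2 ms, about
half the 250 Hz filter rise time) are dropped. Both are noise heuristics:
on noiseless traces, tests disable merging and recover boundaries within
±1 sample and mean conductances to 10⁻⁶ relative.

## 4. Classification

Shape features are computed on a boxcar-smoothed copy of the event segment
(window $f_s/2f_c$ samples ≈ half the filter rise time, capped at a quarter
of the event) so they describe the waveform, not the residual noise;
`peak_current_pA` comes from the raw segment. Three numerical choices
matter:

- **Robust peak.** The rise/symmetry reference is the 95th percentile of the
  smoothed segment, not the maximum: the maximum of a long noisy plateau
  grows with window length and would place the "90% of peak" crossing at an
  arbitrary noise excursion.
- **Conditional rise cap.** For plateau-like events (smoothed median >
  0.75 × robust peak) the rise threshold is capped at the median, so a low
  plateau buried in noise still reads as a fast rise; the cap must not apply
  to graded shapes or a bump's slow rise would be misread. The exact
  90%-of-peak crossing of the raised cosine is at $t \approx 0.40$ of the
  lifetime.
- **Noise-consistent plateau stability.** A fixed plateau-CV cutoff is
  amplitude-dependent: a ~5 pS step in 0.15 pA noise has plateau CV ≈ 0.3
  while its plateau SD equals the pure-noise floor (measured 0.11–0.13 pA vs
  0.12 pA). A plateau therefore also counts as stable when its SD is at or
  below `noise_consistency` (default 1) × the baseline noise SD.

The decision cascade (first match wins): **erratic** if peak > 20 pA *and*
not step-like (irregular plateau or slow rise — a large clean step is never
attributed to membrane damage); **spike** if lifetime < 50 ms; **step** if
fast rise and stable plateau; **bump** if gradual and roughly symmetric;
otherwise unclassified. Apart from the erratic rule, all decisions are
invariant under uniform current rescaling. Every cutoff is exposed in
`classifier_rules()` because the source taxonomy is qualitative.

Against ground truth (window overlap ≥ 50% of the shorter event), the
seeded 280 s default-noise fixture gives per-class recall ≈ 0.92 (step),
0.97 (bump), 0.88 (spike), 1.0 (erratic).

## 5. Pore geometry

`conductance_cylindrical()` implements $G = \sigma\pi d^2/(4l)$ with fixed
units (σ in S/m, d and l in Å, G in pS: $G = 100\,\sigma\pi d^2/(4l)$).
The absolute model is knowingly poor at sub-nanometre scale — gramicidin
geometry in a 1.7 S/m electrolyte predicts ≈ 82 pS against the measured
≈ 12 pS, reflecting access resistance, single-file water and ion–wall
interactions — which is exactly why diameters are estimated by **reference
calibration** (`diameter_by_reference()`): the ratio of two channels in the
same electrolyte cancels σ and the model's absolute scale. Uncertainty is
propagated to first order from the SEs of both conductance means
(`diameter_ci_by_reference()`).

## 6. AFM heights

`synth_height_map()` plants non-overlapping spherical caps (lateral
geometry converted to nm, so cap curvature is physical) on a rough
background; defaults follow the oligomer population (3.28 ± 0.49 nm apex
height, 4 nm pixels). `detect_particles()` subtracts the median background,
thresholds, labels by **8-connectivity** (a small in-package BFS; the
commonly available labeler is 4-connectivity and splits diagonally-touching
regions), and reports each region's maximum height above background — the
AFM z-height convention.

## 7. Problem sizes and verification

Test oracles use: 280 s (1.4 M samples, ~200 events) for detection and
classification regression; generator-level draws of 5×10⁴–10⁵ events for
statistical recovery of the published means and the 165 ms lifetime
quantile; 200-particle, 400² topographs for AFM recovery; 20–30 s pipeline
runs (twice) for byte-identical determinism. The full suite runs in well
under a minute on one CPU.

## 8. Limitations

- Classes are independent Poisson processes; real recordings show membrane
  state progression (bump/spike early, step/erratic late) and inter-event
  correlation. The generator models the stationary mixture only.
- Overlapping events are excluded by construction; the idealizer therefore
  never faces genuinely superimposed channels.
- A true step shorter than 50 ms is labelled spike — the taxonomy itself is
  ambiguous there, and the published spike/step lifetime laws overlap.
- Sub-threshold events (≲ 4σ of noise, ~3 pS at defaults) are undetectable
  by design; recovery claims are stated for events ≥ 5 pS.
- The cylindrical model is used only in ratio form for inference; absolute
  conductance predictions from it should not be trusted at this scale.
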
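---
title: "Texture-based colony detection: models, parameters and design choices"
author: "ColonyQuant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Texture-based colony detection: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ColonyQuant)
```

## The problem

Human embryonic stem cells (hESCs) grow as compact colonies of small,
tightly packed cells on top of a feeder layer of inactivated mouse
embryonic fibroblasts (iMEFs). In label-free phase-contrast images the
two populations differ mostly in *texture*, not in intensity: colony
interiors are finely granular and isotropic, while the fibroblast
background is sparse and dominated by elongated cell bodies. ColonyQuant
segments colonies from that texture difference and reports the culture
statistics a process-development lab monitors daily: colony count, total
and mean colony area, and confluency (the fraction of the imaged field
covered by colony pixels).

The package also implements the analytical fluid-physics arithmetic for
the parallel-plate perfusion chamber this kind of culture is run in:
wall shear stress, shear at a height above the culture plane, residence
time and media-exchange rate.

## The detection model

Detection is a per-pixel classification with four stages.

**1. Calibrated greyscale.** RGB frames are reduced to luminance with
fixed channel weights 0.290, 0.570 and 0.140 (red, green, blue). The
weights are used exactly as stated — they already sum to 1 — and the
result stays in double precision. Spatial calibration is attached from a
named profile; a 4x objective at 1280x960 resolves 2.86 um^2 per pixel.
Since all downstream scores are homogeneous of degree one in intensity,
the absolute intensity scale (0–1 versus 0–255) is irrelevant; an
additive offset, by contrast, shifts the flatness score, so inputs
should not be re-centred.

**2. Basic image features (BIFs).** At each analysis scale sigma, the
image is convolved with Gaussian-derivative filters up to second order,
and each response is multiplied by sigma to the derivative order
(scale normalisation). Writing lambda for the Laplacian c20 + c02 and
gamma for sqrt((c20 - c02)^2 + 4 c11^2), each pixel receives the class
with the largest of seven scores:

| class | score |
|---|---|
| 1 flat | epsilon * c00 |
| 2 slope | 2 sqrt(c10^2 + c01^2) |
| 3 dark blob | +lambda |
| 4 light blob | -lambda |
| 5 dark line | (gamma + lambda) / sqrt(2) |
| 6 light line | (gamma - lambda) / sqrt(2) |
| 7 saddle | gamma |

The sign convention makes a positive Laplacian — a local intensity
minimum — read "dark". The class names are an internal vocabulary:
training and prediction share the convention, so results do not depend
on it. Ties in the argmax (a measure-zero event on real images) break
toward the lowest class index for determinism.

Defaults: scales 0.7 * (1, 2, 4, 8) and epsilon = 0.11. Epsilon is the
only tuning knob of this stage: it decides how much local structure is
absorbed into "flat". The flatness score uses the raw smoothed image
c00, not a mean-subtracted version; this is recorded in the
configuration so that models and features can never silently disagree
about it.

**3. Local histogram features.** For each scale, a 25 x 25 uniformly
weighted window around each pixel is summarised as a 7-bin count
histogram of the BIF classes, and the four per-scale histograms are
concatenated in scale order into a 28-element feature vector. The
histograms are raw counts (no normalisation): each scale's bins sum to
625 everywhere, because border windows are completed by reflective
padding rather than truncated.

**4. Random forest.** A 20-tree forest with 5 variables sampled per
split maps feature vectors to colony/background. Training pixels are
sampled per image with a 1:1 class balance; a frame whose colony class
is present but smaller than its quota (a single small colony) is
bootstrapped — resampled with replacement — up to the quota, with a
warning, so the balance is preserved without discarding the frame. A
frame missing a class entirely is rejected. The prediction is the
majority vote (threshold 0.5); a vote-fraction map is available for
inspection. Every model stores a fingerprint of the feature
configuration (scales, epsilon, window) and refuses to predict on
features computed differently — the 28-element contract is enforced, not
assumed.

**Cleanup and metrics.** The raw binary map is cleaned in the order the
two filters are defined: connected objects smaller than 4000 pixels are
removed as detection noise, then enclosed holes smaller than 6000 pixels
are filled. Both thresholds are strict (`< 4000`, `< 6000`). Objects use
8-connectivity and holes 4-connectivity, the complementary pair that
avoids foreground and background claiming the same diagonal; a hole is a
background component that does not touch the image border, measured
after object removal. Surviving components are labelled, and metrics
follow directly: total area is positive pixels times the calibration
factor, confluency is positives over all pixels, mean area is total over
count (flagged undefined when nothing was detected). Merged colonies are
reported as one object — no watershed splitting is attempted, matching
how counts naturally drop as neighbouring colonies grow together.

## Evaluation statistics

Agreement with a reference mask is summarised by the pixel F-score
2TP / (2TP + FP + FN). Confluency error is analysed over a set of image
pairs as: bias (mean signed error) with a Student-t 95% confidence
interval; RMSE; and precision defined as sqrt(RMSE^2 - bias^2), i.e. the
scatter left after removing the systematic component. The t-interval was
chosen because evaluation sets in this setting are small (tens of
images); the identity precision^2 + bias^2 = RMSE^2 holds exactly by
construction. With one image pair the CI is omitted with a warning.

## The synthetic image generator

No public image corpus exists for feeder-attached hESC phase-contrast
frames, so the package ships a procedural generator that emulates the
structure the classifier exploits:

* colony regions: unions of discs whose boundaries are perturbed by a
  low-order random Fourier series (default relative amplitude 0.15), so
  rim pixels are genuinely ambiguous; interiors carry fine isotropic
  speckle (SD 0.18 about the base intensity) plus stamped 2–5 px dark
  micro-blobs, emulating tightly packed small cells;
* background: sparse elongated dark strokes with a faint bright border
  (length 30–80 px, width 3–6 px), emulating fibroblast bodies;
* field effects: a smooth tilted-plane-plus-bowl illumination gradient
  (amplitude 0.08), additive Gaussian noise (SD 0.03), and a bright
  3 px halo band outside colony rims, the most recognisable
  phase-contrast artefact.

Defaults are 500 x 500 frames with 1–6 colonies of radius 40–150 px.
Every draw is a deterministic function of the config seed, and the
rasterised mask is returned as exact ground truth: the generator is how
the package's end-to-end claims are made testable.

What the generator does *not* model: true phase-contrast optics
(shade-off, contrast inversion), colony-interior differentiation
gradients, fibroblasts running underneath colonies, debris, or focus
drift. Passing the synthetic benchmark therefore demonstrates that the
feature/classifier/cleanup chain works end to end and recovers known
truth under realistic texture statistics — it does not certify the
headline accuracy on real microscope images, which can only be measured
against expert annotation.

## Numerical choices

* Gaussian kernels are sampled analytically and truncated at 4 sigma;
  the truncation error is far below classifier noise. The
  second-derivative kernel is corrected to sum exactly to zero so
  constant images have exactly zero response; the first-derivative
  kernel is odd and cancels by symmetry.
* All filtering and the histogram windows use half-sample symmetric
  (reflective) padding. This avoids the artificial "slope" ring a
  zero-padded border would create, and makes the bin-sum invariant hold
  at border pixels too.
* Separable filtering is verified in the test suite against a direct
  O(L^2) convolution oracle to < 1e-8 relative error; connected-
  component labelling is verified against a flood-fill oracle (and, for
  4-connectivity, against an independent implementation).
* Component labelling is a run-based two-pass union-find, chosen because
  the cleanup stage needs both 8- and 4-connectivity.

## Perfusion arithmetic

The chamber is treated as an infinite parallel-plate gap: wall shear
tau_w = 6 mu Q / (h^2 w), and at height z above the culture plane the
plane-Poiseuille profile gives tau(z) = tau_w (1 - 2 z / h). Defaults
are the standard operating point: Q = 300 ul/h, chamber 13 mm across the
flow by 4 mm along it, gap height 450 um, dynamic viscosity 6.96e-4 Pa s
(water at 37 C). These give tau_w of about 1.3e-4 Pa, a residence time
V/Q of 4.68 min, a culture area of 0.52 cm^2 and a media-exchange rate
of 13.8 ml/day/cm^2. The analytical model ignores the 120 um recess
between the flow layer and the culture plane, so it slightly
overestimates the shear actually experienced at cell height; it should
be read as an upper bound on the order of 1e-4 Pa rather than a
field-resolved prediction. All quantities are stored in SI internally;
constructors accept the bench units (mm, um, ul/h) the chamber is
described in.

## Problem sizes used in the shipped checks

The package's own validation trains on 10 generated 500 x 500 images
(2e5 balanced pixels) and evaluates on 20 held-out images — a scale
chosen so a complete run finishes in minutes on a laptop while still
exercising every stage at the default parameters. Unit tests use 128 px
frames with proportionally scaled colonies, strokes and cleanup
thresholds. The spatial calibration attached to synthetic frames is the
4x profile (2.86 um^2/px) purely so that area reporting is exercised;
synthetic pixels have no physical size.

## Known limitations

* The texture model is phenomenological; classifiers trained on
  synthetic frames will not transfer to real microscopes without
  retraining on annotated frames from that instrument.
* Touching colonies merge into one reported object.
* The voting threshold (0.5) and tree depth are the classifier's
  defaults; the forest parameters themselves (20 trees, mtry 5) follow
  the standard configuration for this feature set.
* The perfusion module is deliberately analytical; resolving the recess
  or chamber-edge effects requires finite-element simulation, which is
  out of scope.
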
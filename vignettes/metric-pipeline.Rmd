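---
title: "Metric-based classification of FTIR tissue images: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metric-based classification of FTIR tissue images: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ftirmetrics)
```

## The problem and the model

Mid-infrared hyperspectral images of tissue sections record, at each pixel,
an absorbance spectrum whose band intensities reflect the local molecular
composition (protein backbone Amide I and II bands near 1650 and
1540 cm^-1^, nucleic-acid and carbohydrate bands in the fingerprint
region). Different tissue types — carcinoma, stroma, epithelial layers,
muscle, lymphoid tissue — differ subtly but reproducibly in these
profiles, so a supervised classifier can paint a label map over an image
without staining.

The discriminator used here is deliberately simple and interpretable. A
*metric* is an ordered pair of wavenumbers $(\nu_1, \nu_2)$; its value on a
spectrum $A(\nu)$ is the absorbance ratio $A(\nu_1)/A(\nu_2)$, which is
invariant to per-pixel scaling. During training, one metric is generated
for **every** ordered pair of analysis channels ($n(n-1)$ metrics for $n$
channels; 35,156 on the default 188-channel grid), and each metric stores
one probability density function (PDF) of training ratios per tissue
class. Each metric is then scored on held-out spectra by the one-vs-rest
area under the ROC curve (AUC) of its ratio values, and the top-ranked
metrics per class are assembled into a committee. At prediction time every
committee metric converts the observed ratio $r$ into class likelihoods
$p_c(r)$ via its PDFs; these become a per-metric posterior (likelihood
times prior, normalised over classes), and the class probabilities are the
mean posterior over all metrics with a defined ratio. The predicted label
is the argmax; the confidence is the maximum probability divided by the
sum of all probabilities (equal to the maximum once the vector is
normalised, and bounded below by $1/K$ for $K$ classes).

Because both orderings of a wavenumber pair are kept as distinct metrics
and a PDF-based vote has no preferred direction, AUC is used in oriented
form, $\max(a, 1-a)$: a perfectly anti-ordered metric is exactly as useful
as a perfectly ordered one. Ties in the ranking are broken by lower
numerator and then lower denominator wavenumber, so rankings are fully
deterministic.

## Preprocessing chain

The chain matches standard practice for formalin-fixed paraffin-embedded
(FFPE) sections imaged in transmission, in this fixed order:

1. **Quality gate.** Pixels whose Amide I absorbance (channel nearest
   1650 cm^-1^) is below 0.1 or above 2 are masked — outliers from
   sub-optimal sample thickness. The inequalities are strict, so values
   exactly at the bounds are kept. A window-maximum lookup around
   1650 cm^-1^ is available as an option.
2. **Truncation and paraffin omission.** Channels outside 900–1800 cm^-1^
   are dropped; the paraffin-dominated 1350–1500 cm^-1^ band (closed
   interval) is masked from analysis but kept in storage so ratio images
   can still be rendered there. On the default 4 cm^-1^ grid this leaves
   226 stored and 188 analysis channels.
3. **Rubber-band baseline correction.** The greatest convex minorant (the
   lower convex-hull boundary through the spectrum's points, linearly
   interpolated between hull vertices) is subtracted. The hull is computed
   over the full retained 900–1800 range *including* the masked paraffin
   channels: the minorant is more stable on a contiguous range, and the
   paraffin region is excluded from analysis, not from correction.
4. **Vector normalisation.** Each spectrum is scaled to unit Euclidean
   norm computed over the analysis channels only, so paraffin intensity
   cannot influence the tissue-spectrum scale; masked channels are scaled
   by the same factor for display consistency.

Resonant-Mie and atmospheric corrections are out of scope; for FFPE
sections in paraffin the refractive-index matching makes scattering
correction unnecessary.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `amide_low`, `amide_high` | 0.1, 2 AU | quality-gate bounds at 1650 cm^-1^ |
| `keep` | 900–1800 cm^-1^ | retained spectral range |
| `omit` | 1350–1500 cm^-1^ | paraffin band masked from analysis |
| `eps` | 1e-6 | ratio denominator guard on the normalised scale |
| `k` | 5 | committee size per class |
| `estimator` | `"kernel"` | ratio PDF estimator (`"histogram"` available) |
| `inner_frac` | 0.5 | share of a training fold used for PDF fitting vs AUC scoring |
| `n_folds` | 5 | cross-validation folds |

The ratio guard `eps` marks a ratio *undefined* rather than imputing it:
the affected spectrum is excluded from that metric's PDFs and scoring, and
at prediction time the metric abstains from the vote. A spectrum on which
every committee metric abstains is reported unclassifiable and its pixel
rendered as excluded.

## Density estimation choices

The default ratio PDF is a Gaussian kernel density with Silverman's
rule-of-thumb bandwidth, tabulated on a 512-point grid spanning the
central 99.9% of the training ratios padded by four bandwidths, and
renormalised (trapezoid rule) to integrate to exactly 1 over its support.
The quantile clipping keeps a single extreme ratio from stretching the
grid and flattening the density; the renormalisation keeps the
integrates-to-1 invariant true even then. Evaluation uses linear
interpolation with a floor of 1e-12 inside and outside the support, so no
committee likelihood is ever exactly zero and degenerate posteriors
reduce to the uniform vector rather than 0/0.

When a class's training ratios are all identical (zero spread), Silverman's
bandwidth is undefined; the fallback bandwidth is `1e-3 * |mean|` (floored
at 1e-12). Scaling the fallback with the ratio magnitude — rather than
using an absolute floor — matters in near-noise-free data, where distinct
classes can sit at distinct tiny ratio values that an absolute bandwidth
would blur together.

## Evaluation protocol

Training data are sampled with an equal number of spectra per image to
avoid image-related bias, then split into five class- and
patient-stratified folds (round-robin dealing with a rotating offset, so
every fold's share of each class-by-patient cell is within one spectrum of
every other fold's). Within each training fold, a class-stratified 50/50
split separates the *metric-training* stage (PDF fitting) from the
*metric-scoring* stage (AUC ranking), mirroring the three-stage
train/score/evaluate structure of the method; the committee model built
from the top-k metrics then labels the held-out fold. Per-class
sensitivity, $100\,TP/(TP+FN)$, and specificity, $100\,TN/(TN+FP)$, are
computed one-vs-rest from the multi-class confusion matrix and reported as
mean ± standard deviation across folds (a standard-error option exists;
the choice of fold-to-fold SD is the package's reading of the usual
"mean ± uncertainty" reporting).

One global seed drives everything; per-stage seeds are derived through a
fixed affine counter scheme (`stage_seed`), so stages rerun in isolation
reproduce their draws and a rerun with the same configuration reproduces
the report byte for byte.

## The synthetic phantom generator

There is no instrument data in the package; every test runs on phantoms
from `generate_phantom()`. A phantom pixel is the sum of

- class-specific Gaussian absorption bands (centre, amplitude, sigma) —
  every profile includes an Amide I band at 1650 cm^-1^ so the quality
  gate is meaningful;
- a smooth per-class polynomial baseline drift;
- shared paraffin contamination bands at 1378 and 1462 cm^-1^ (CH bends)
  inside the omitted region;
- independent zero-mean Gaussian channel noise, the simplest model
  consistent with detector noise.

`default_seven_class_spec()` mirrors the seven-tissue roster of the oral
cancer setting (OSCC, CS, BL, ML, NS, SM, LYM). All classes share Amide
I/II and fingerprint bands; each carries two class-specific shoulder bands
at wavenumbers in the 1510–1715 cm^-1^ region where real tissue contrasts
concentrate, with amplitudes 0.12–0.18 AU against a 0.9 AU Amide I peak.
The documented default noise (`noise_sigma = 0.012`, about 1.3% of Amide
I) and a 42 × 49 image (seven equal-width class stripes) were chosen once
as a realistic, clearly-but-not-trivially separable regime; cross-validated
sensitivities and specificities on it are essentially 100%, comfortably
above the 85%/90% recovery thresholds asserted in the acceptance tests.
The default problem sizes used throughout the tests and the acceptance
script — two 42 × 49 phantom images, 210 spectra sampled per image, the
full 226-channel grid — are the package's standard study conditions.

Planted quality-gate violators are created by rescaling whole pixel
spectra so the Amide I channel lands at 0.05 (half of them) or 2.5 (the
rest), exercising both gate branches; the planted count is exact because
non-outlier pixels whose noise draw would itself breach the gate have
their noise redrawn (bounded retries). This truncation of the pixel-level
noise distribution is the price of an exact planted count and is
negligible at default noise.

What the phantoms deliberately do **not** emulate: resonant-Mie scattering
fringes, detector drift and striping, spatial correlation of noise,
mixed-tissue boundary pixels, and the full biochemical complexity of real
band shapes. Passing the recovery tests therefore demonstrates the
pipeline's correctness and statistical behaviour under its own
assumptions, not clinical performance; the published per-tissue
sensitivities and specificities of the real study are computed on a
deposited patient dataset and are not reproducible from phantoms.

## Numerical and degenerate-case decisions

- **Convex minorant.** Computed by a monotone-chain lower hull in compiled
  code; hull vertices (including both endpoints) take their input values
  exactly, so corrected spectra are exactly zero there and non-negative
  within 1e-12 elsewhere. An O(n²) chord-minimum oracle cross-checks it in
  the tests.
- **AUC.** Average ranks implement the Mann–Whitney tie-½ convention
  exactly; the compiled all-pairs scan and the single-metric R path are
  cross-checked against exhaustive pair counting to 1e-12.
- **Committee edge cases.** Metrics whose metric-training ratios leave any
  class without a PDF are skipped when assembling the committee (the next
  ranked metric moves up). Exact probability ties at prediction resolve to
  the first class in model order.
- **Wavenumber lookup** is nearest-channel everywhere; rendering requires
  the target to lie within half a grid step.
- **Serialisation.** Models round-trip through JSON at 17 significant
  digits, which reproduces IEEE doubles — and therefore predictions —
  bit-identically.

## Known limitations

- Redundancy among committee metrics is not penalised; the top-five lists
  for a class are often reciprocal/near-duplicate pairs, which is faithful
  to the ranking rule but means the committee carries fewer than k
  independent pieces of evidence.
- The HDF5 cube container common in hyperspectral work is not provided;
  cubes are exchanged in the ENVI-style header+binary layout plus a JSON
  sidecar for masks and provenance.
- Patient balancing is implemented as class × patient stratification of
  folds; with very few patients per class, fold-level patient disjointness
  (leave-patient-out) would be the stricter protocol and is not what this
  implements.
- Ratio images default to 1252/1285 cm^-1^, a pair known to highlight
  epithelial cells in general rather than carcinoma specifically; the
  multi-class committee map is the more discriminating visualisation.

## A compact worked run

```{r, eval = FALSE}
set.seed(1)
ph <- generate_phantom(default_seven_class_spec(seed = 1))
cube <- preprocess_cube(ph$cube)
data <- cube_to_labelled(cube, ph$ground_truth)
report <- cross_validate(data, cv_params(), seed = 1)
print(report)
```

The pipeline wrapper `run_pipeline(run_config(seed = 1), "run1")` executes
the same stages end-to-end and writes the model, report, ranked-metric
table, label map, pseudo-colour PNG and a manifest with the configuration
hash.
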
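---
title: "Methods: multispectral Breslow-thickness classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multispectral Breslow-thickness classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msibreslow)
```

## The problem and the model

Breslow thickness — the maximum depth of dermal invasion of a melanoma —
drives the choice of surgical safety margins, but it is a histological
quantity, unavailable at the time of the initial excision decision.
`msibreslow` implements a rule-based classifier that estimates a coarse
thickness category from a multispectral image set: three co-registered
single-band photographs of the lesion under narrow-band LED illumination at
525 nm (G), 660 nm (R) and 940 nm (IR). The three wavelengths probe
increasing skin depths, and melanin attenuates them to degrees that depend
on tumour pigment load and depth.

The pipeline has three stages, all operating on a manually drawn lesion ROI
shared by the three channels:

1. **Nevus exclusion.** The spectral score

   $$s' = \log_{10}\frac{I_G \cdot I_{R,\mathrm{skin}}^2}
                        {I_{G,\mathrm{skin}} \cdot I_R^2}$$

   compares each lesion pixel's G and R intensities with the mean
   intensities of the surrounding skin. The lesion-level statistic is the
   **maximum** of the per-pixel map over the ROI; lesions scoring below
   0.511 A.U. are called nevi and excluded.

2. **Shape gate.** Melanomas are split by circularity
   ($4\pi\,\mathrm{area}/\mathrm{perimeter}^2$) at 0.727: thin, superficially
   spreading melanomas tend to have irregular outlines (low circularity),
   thick nodular ones compact outlines (high circularity).

3. **Intensity gate.** Low-circularity melanomas with mean G above
   8.0 A.U. are classified Breslow &le; 1 mm (little melanin, bright in G),
   otherwise 1–2 mm. High-circularity melanomas with mean IR below
   107.9 A.U. are classified Breslow &gt; 2 mm (deep pigment attenuates the
   IR band), otherwise 1–2 mm.

The four thresholds are fixed calibration constants of the original device
and of the feature conventions described below; the package deliberately
does not re-fit them.

### A resolved ambiguity in the decision tree

The narrative description of step 3 refers to "low circularity" for both
intensity gates, which cannot be meant literally (the tree would then never
use the high branch). The implementation assigns the G gate to the
low-circularity branch and the IR gate to the high-circularity branch.
This is the only assignment consistent with the reported feature
directions: G separates &le; 1 mm melanomas from thicker ones, thin
melanomas have low circularity, and IR separates 1–2 mm from &gt; 2 mm
tumours, which are the circular ones. The choice is prominent here because
it is a genuine interpretation, not a transcription.

### Tie-breaks

All comparisons at a threshold are resolved from the comparative wording of
the rules and documented in `classify_acquisition()`:

* s&prime; exactly 0.511 &rarr; melanoma (a rule-out step favours sensitivity);
* circularity exactly 0.727 &rarr; low branch ("higher" circularity is strict);
* mean G exactly 8.0 &rarr; 1–2 mm (strict "&gt;" required for &le; 1 mm);
* mean IR exactly 107.9 &rarr; 1–2 mm (strict "&lt;" required for &gt; 2 mm).

## Shape morphometry conventions

The descriptors follow the ImageJ particle-analysis definitions, but ImageJ's
exact perimeter algorithm is configuration-dependent, so the package fixes
its own deterministic convention:

* **Boundary tracing.** The outer boundary of the (4-connected) mask is
  traced along inter-pixel edges; the corner-cut polygon through the edge
  midpoints is then smoothed with a circular 5-point moving average of its
  vertices. The smoothed polygon's length is the default perimeter
  (`perimeter_method = "boundary_polygon"`). On rasterised disks of radius
  30–150 px this estimator is accurate to about 0.4%, and on axis-aligned
  rectangles to about 1%; the raw crack length (`"pixel_edge"`) is exact
  for axis-aligned shapes but overestimates curved outlines by up to ~30%
  and is provided only for comparison with pixel-counting workflows.
* **Polygon ROIs are exact.** When an ROI carries a polygon outline, area,
  perimeter, convex hull and second moments are computed in closed form on
  the polygon, so square/rectangle circularity and plus-shape solidity
  match their analytic values exactly.
* **Convex hull.** For raster masks the hull is taken over the mid-crack
  boundary vertices, which straddle the true outline; hulls over the outer
  pixel corners would bias convex-mask solidity about 1.5% low. The hull
  area is floored at the pixel area so `area <= convex_area` always holds.
* **Moments.** The roundness major axis comes from the ellipse with the
  region's second-order central moments; pixel moments include the 1/12
  unit-square variance, which keeps one-pixel-wide regions finite and is
  negligible for realistic lesions.
* **Holes and components.** Interior holes are filled before both shape and
  intensity measurement, so all features refer to one filled region.
  Disconnected masks are an error by default; `largest_component = TRUE`
  selects the biggest component.
* **Clamping.** Circularity, solidity and roundness are clamped at 1:
  rasterisation can push a near-ideal shape marginally above its
  theoretical bound.

Because the thresholds were calibrated under a (slightly different, not
fully documented) ImageJ convention, circularity values near 0.727 on real
data could shift by a percent or so relative to the original workflow; the
package treats this as an inherent calibration caveat rather than guessing
the original settings.

## s&prime; numerics

* "lg" is log base 10; the product form and the decomposed form
  $\log_{10}(I_G/I_{G,\mathrm{skin}}) + 2\log_{10}(I_{R,\mathrm{skin}}/I_R)$
  agree to 1e-12, which the tests pin.
* Intensities below 1.0 (on the 0–255 scale) are clamped to 1.0 before
  ratios, bounding the score for saturated-dark pixels; the bound matches
  the &plusmn;1.5 A.U. display range of the rendered map.
* The skin reference defaults to an annulus starting 10 px outside the ROI
  and 20 px wide, clipped to image bounds, lesion pixels excluded, with at
  least 100 px required. The original region definition is unpublished, so
  the annulus is configurable and echoed into all outputs; an explicit skin
  mask overrides it.
* The lesion statistic is the ROI maximum (as published); a 99th-percentile
  alternative (`statistic = "p99"`) is available for robustness studies and
  off by default.
* The rendered map clamps to [-1.5, 1.5] on a continuous diverging scale,
  deep blue &rarr; white &rarr; rufous red, transparent outside the ROI.
  The float map is persisted as tab-separated text at 17 significant
  digits — an exact double round trip — rather than float TIFF, whose R
  encoders clamp values to [0, 1].

## Evaluation statistics

Per-class sensitivity and specificity are one-vs-rest; overall summaries
are reported **both** macro-averaged (unweighted class mean) and micro
(pooled counts) because single unlabelled "overall" figures are ambiguous
for multi-class problems — micro sensitivity equals accuracy. Cohen's
kappa uses the unweighted estimator with the Fleiss–Cohen–Everitt
large-sample standard error and a normal-approximation CI clipped to
[-1, 1]. The ROC steps through all distinct score thresholds; its
trapezoidal AUC equals the Mann–Whitney pair statistic with ties counted
half, an identity the tests verify on random instances. The AUC confidence
interval is a seeded stratified percentile bootstrap (2000 resamples,
positives and negatives resampled separately); a closed-form AUC CI was
deliberately not reimplemented from an unpublished vendor procedure.
Pearson correlation delegates to `stats::cor.test` (Fisher-z CI).

## The synthetic cohort generator

No images from the original cohorts are publicly deposited, so the package
ships a seeded phantom generator that emulates the *statistical* structure
the classifier relies on, not skin optics:

* **Shape.** Lesion outlines are star-like polygons
  $r(\theta) = R\,(1 + \sum_k a_k \sin(k\theta + \varphi_k))$, rasterised by
  the package's own polygon rasteriser; total amplitude controls expected
  circularity/solidity monotonically (measured: amplitude 0.55–0.75 over
  harmonics 3–7 yields circularity roughly 0.41–0.65; amplitude &le; 0.08
  yields &gt; 0.97).
* **Intensity.** Channels are a uniform skin background (G 120, R 140,
  IR 180 A.U.) plus clipped additive Gaussian noise (sd 3); inside the
  lesion the skin mean is multiplied by a class-drawn attenuation factor
  and blended into the background over a 2 px transition strictly inside
  the mask (weight $\min(1, d/\mathrm{blend})$ in the distance $d$ to the
  nearest background pixel).
* **Class design.** Attenuation and irregularity ranges are calibrated so
  each class clears its decision threshold with margin: nevi keep enough R
  signal that the maximum s&prime; stays below 0.511; thin melanomas are
  irregular and clearly G-bright; intermediate melanomas can take either
  circularity branch, staying below the G threshold on the irregular route
  and above the IR threshold on the circular route; thick melanomas are
  compact and IR-dark. A single `overlap` knob linearly widens every range
  toward the pooled across-class range, erasing the class signal at 1 — the
  package's accuracy-degradation checks use it at 0, 0.5 and 1.
* **Truth.** Each record carries its class, a class-consistent true Breslow
  thickness in mm, and the drawn generating parameters.

The reference study conditions used by the validation suite and by
`scripts/acceptance.R` are the generator defaults with 75 lesions per class
(300 total, 500&times;500 px); the overlap-degradation check uses 25 per
class per level, and unit tests use a geometrically scaled-down
configuration (180&times;180 px) for speed.

**What passing tests show — and what they do not.** The end-to-end checks
demonstrate that the implementation is faithful: with data whose feature
distributions straddle the published thresholds the way the publication
describes, the pipeline recovers the classes (accuracy &ge; 0.95,
&kappa; &ge; 0.90 under the reference conditions) and degrades as class
overlap grows. They say nothing about performance on real skin: the
phantoms have uniform backgrounds, no hair, shading, specularities,
mis-registration, or dermoscopic texture, and their attenuation factors are
statistical knobs, not melanin optics.

## Known limitations

* ROIs are inputs; segmentation, fiducial-marker detection and channel
  registration are out of scope.
* Thresholds are device-specific constants; applying them to images from a
  different device or bit depth requires recalibration.
* The original acquisitions' bit depth is inferred to be 8-bit from the
  threshold scales; the intensity scale factor is configurable.
* In-situ melanomas and special-site lesions are outside the decision
  tree's design.
* The per-lesion aggregation rule for multiple acquisitions of one lesion
  is not specified in the source material; the package defaults to
  worst-case (thickest class wins) with a majority alternative, and records
  the policy in the decision trace.
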
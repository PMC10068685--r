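---
title: "Quantitative PSMA PET response assessment: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative PSMA PET response assessment: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psmaquant)
```

## The problem

In castration-sensitive prostate cancer (CSPC), treatment response is
traditionally tracked through serum prostate-specific antigen (PSA). PSA is
a single number per patient: it cannot say *which* lesions responded, and a
composite decline can mask progression at individual sites. PSMA-targeted
PET imaging resolves disease spatially, and platforms built on the PROMISE
framework quantify each tracer-avid lesion so that whole-body tumor burden
can be scored, compartmentalized anatomically, and compared across
timepoints.

`psmaquant` implements that quantification chain as an auditable pipeline:

1. **Reference uptake** — mean standardized uptake value (SUV) over liver
   and blood-pool (aorta) segmentations.
2. **Hot-spot detection and segmentation** — supra-reference peaks,
   segmented by an adaptive peak-relative threshold.
3. **Physician review** — accept/reject decisions per lesion.
4. **PSMA scoring** — per lesion, per anatomic compartment
   (prostate/prostate bed, nodal, osseous), and composite.
5. **Response** — signed percent change between baseline and follow-up.
6. **Correlation** — Pearson association of imaging response with PSA
   response, with two-tailed t significance.

A synthetic phantom and cohort generator exercise every stage without
clinical data; the per-patient response tables of a published 30-patient
CSPC cohort ship as packaged fixtures and form the real-data surface.

## The PSMA score

For a segmented lesion with volume $V$ (mL) and mean uptake
$\mathrm{SUV}_{\text{mean}}$, normalized by the reference-organ mean
$\mathrm{SUV}_{\text{ref}}$:

$$\mathrm{score} \;=\; V \cdot
\frac{\mathrm{SUV}_{\text{mean}}}{\mathrm{SUV}_{\text{ref}}}$$

The SUV ratio is dimensionless, so the score has units of mL — an
uptake-weighted lesion volume. Compartment scores are sums of lesion scores
(regional and non-regional nodal stations pool into one nodal compartment);
the composite is the sum of compartment scores. Two consequences the test
suite checks as invariants:

* **Intensity-scale invariance.** A global rescaling of PET intensities
  multiplies lesion and reference SUV alike and cancels; every score is
  unchanged.
* **Additivity.** The composite equals the sum of accepted per-lesion
  scores, so rejecting a lesion in review lowers the composite by exactly
  that lesion's score.

A compartment with no accepted lesion is *missing*, not zero — the "N/A"
convention of clinical response tables, which matters downstream because
missing cells drop out of medians and correlations pairwise rather than
dragging them toward zero.

## Detection and segmentation

The platform this analysis emulates detects hot spots with a trained
neural network whose weights are not public. `psmaquant` instead uses a
classical detector, fully specified so that results are reproducible from
the description alone:

* optional Gaussian pre-smoothing (`smoothing_fwhm_mm`, default 0 — the
  phantoms are noise-controlled; 4–6 mm is reasonable on noisy data);
* detection threshold $\max(\texttt{detect\_abs},\;
  \texttt{detect\_rel} \times \mathrm{SUV}_{\text{blood pool}})$ with
  `detect_rel = 2` by default; one seed per 26-connected supra-threshold
  component, at the component's SUV maximum; reference-organ voxels are
  excluded (physiologic liver and aortic uptake is not disease);
* segmentation threshold $\max(f \times \mathrm{SUV}_{\text{max}},\;
  \mathrm{SUV}_{\text{blood pool}})$ with `seg_fraction` $f = 0.4$, the
  common fixed-fraction-of-peak convention in PET volumetry, floored at the
  blood-pool level so a region can never grow into sub-reference
  background; the mask is the 26-connected component containing the seed;
* lesions below `min_volume_ml` (default 0.1 mL) are discarded as
  single-voxel noise.

This detector is *not* a reimplementation of the proprietary one; its
contract is the testable part — on noise-free phantoms every lesion above
the detection threshold is found (100% recall), the segmented volume of a
uniform sphere is within voxelization error of the analytic
$\tfrac{4}{3}\pi r^3$, and increasing $f$ never enlarges a mask.

Compartment assignment is by arg-max fractional overlap with the
prostate/bed, skeleton, and nodal-region masks, with exact ties resolved by
the fixed priority osseous > nodal > prostate/bed. Nodal lesions split at
the common-iliac bifurcation plane by mask-centroid axial position:
strictly above is non-regional, at or below regional. Coordinates are
physical millimetres with the origin at the first voxel centre.

## Response and correlation

Percent change is $100\,(x_1 - x_0)/x_0$, defined only for $x_0 > 0$. A
positive follow-up score over a zero or missing baseline raises a
*new-disease* flag instead of a percent, and such cells never enter
percent-change statistics. PSA change enters correlations as a signed
percent (negative for decline) so that concordant imaging and PSA declines
correlate positively. Display rounding is half-away-from-zero to integer
percent; full precision is kept internally.

Correlations are Pearson, pairwise-complete per compartment column, with
two-tailed significance from
$t = r\sqrt{(n-2)/(1-r^2)}$ on $n-2$ degrees of freedom (cross-checked in
the test suite against a 10,000-draw permutation null). A column is
*suppressed* when the correlation is undefined (fewer than three complete
pairs, or zero variance). A computable column is additionally flagged
`low_variance` when at least 80% of its pairwise-complete values are
identical: in the packaged cohort the prostate/bed column is ‑100% for 22
of 26 pairs, so its correlation magnitude hinges on four patients — the
situation in which the source analysis declined to report a p value
("not calculated"). The 80% threshold was chosen once to separate that
column (85% modal share) from the nodal column (70%), and is configurable.

## The synthetic-data generator

`generate_phantom()` builds a whole-body-like grid (default 48×48×80
voxels at 4 mm): uniform soft-tissue background (SUV 0.5), a liver
ellipsoid (SUV 5), an aorta cylinder for blood pool (SUV 1.5), a prostate
sphere, a spine column, and a nodal region around the aortic path, with
spherical uniform-uptake lesions and optional additive Gaussian SUV noise
truncated at zero (SUV is non-negative). Spheres are deliberate: the
analytic volume is an exact oracle for segmentation accuracy. The default
lesion radii (8–11 mm) keep voxelization error under ~5% at 4 mm spacing.
Organ masks are pairwise disjoint so the labeled-mask NIfTI serialization
is lossless.

`generate_cohort()` draws per patient: compartment involvement
(prevalences 27/30 prostate/bed, 25/30 nodal, 18/30 osseous — the
marginals of the packaged cohort), log-normal baseline compartment scores
(medians 21.6, 5.3, 2.2 with sdlog 1, spanning the published 0.1–150.5
score range), a multiplicative treatment residual per involved compartment
(complete response, residual 0, with probability 0.5, matching roughly
half of the published cohort at −100%; otherwise log-normal with median
0.15, so residuals above 1 — progression — occur), and PSA at both
timepoints from the burden link

$$\mathrm{PSA} = s\,(\text{composite} + c_0)^{\beta}\,
e^{\sigma Z}, \qquad Z \sim \mathcal{N}(0,1).$$

The power law with multiplicative log-normal noise is the simplest
strictly positive link whose noise-free limit ($\sigma = 0$, $c_0 = 0$,
$\beta = 1$) forces the PSA percent change to *equal* the composite
percent change — giving a machine-precision correlation-of-1 oracle for
the whole response-and-correlation chain. With $\sigma = 0.1$ and 200
patients, $\beta$ is recoverable to within ±0.1 by log–log regression,
which the acceptance checks verify.

Three deliberate edge-case decisions:

* A patient drawn with no involved compartment is redrawn: an imaging
  response cohort is disease-positive by construction, and zero burden
  makes the link degenerate at $c_0 = 0$.
* `psa_from_burden()` returns exactly 0 in the single limit case of zero
  burden with $c_0 = 0$ and $\beta > 0$ — a complete responder with PSA at
  the assay floor, which is what printed "−100%" PSA rows imply. PSA is
  strictly positive everywhere else.
* Uninvolved compartments are structurally missing, never zero, to
  exercise the N/A conventions end to end.

What the generator does **not** emulate: realistic organ shapes, CT
anatomy, attenuation and reconstruction physics, heterogeneous
intra-lesion uptake, lesion shapes other than spheres, inter-lesion
response heterogeneity within a compartment, and new-disease appearance at
follow-up (the flag logic is unit-tested directly). Passing phantom tests
therefore demonstrates correctness of the quantification arithmetic and
the statistical chain, not detector performance on clinical scans.

## Packaged cohort tables

The per-patient tables of the 30-patient cohort are transcribed into
`inst/extdata/` (CSV, MD5-verified at load). Notable properties the
package preserves rather than "fixes":

* One patient's treatment course and PSA response is unknown; that patient
  is excluded pairwise from PSA-involving statistics but retained in
  imaging-only summaries.
* The baseline table marks prostate/bed disease in 27 patients but the
  response table has 26 scoreable prostate cells; similarly the printed
  percent cells are integer-rounded with occasional ±1 inconsistencies
  against the raw scores quoted in the text. The percent cells are treated
  as the inputs they are, and recomputed correlations from them agree with
  the published row to within ±0.05 (the source computed from unrounded
  values).
* One patient's printed compartment scores sum to 69.82 against a printed
  composite of 69.72; worked examples use the printed composite.

## Problem sizes and numerical choices

The default test and acceptance workloads are sized for interactive runs:
phantoms of 48×48×80 voxels (~184k), cohorts of 30 patients for the
noise-free identity and 200 for exponent recovery, and 10,000 permutations
for the significance cross-check. Connected-component labelling is a
vectorized frontier flood fill in R, adequate at these scales. All
simulation entry points take an integer seed and restore the caller's RNG
state, so identical specs serialize byte-for-byte identically.

## Limitations

Lesion-level longitudinal matching between timepoints (which lesion became
which) is out of scope, as are DICOM ingestion, automated organ
segmentation, and any claim of concordance with the proprietary detector
on clinical scans. The baseline-burden-vs-baseline-PSA correlation is
implemented (`correlate_baseline()`) but can only be validated on
simulated cohorts, since per-patient baseline scores of the packaged
cohort are not published.
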
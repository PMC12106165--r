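---
title: "Anatomy-driven eyelid screening: models, defaults, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Anatomy-driven eyelid screening: models, defaults, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lidmorph)
```

## The screening model

lidmorph diagnoses eyelid disorders the way an oculoplastic examiner does:
it first fixes the anatomy (where is each canthus, where do the lid margins
run), then measures calibrated morphology, then asks which region carries
which pathological change, and finally composes those findings into disease
labels through a declarative *morphological atlas*. Four regions (inner
canthus, outer canthus, upper eyelid, lower eyelid) and eight changes
(ptosis, upper retraction, lower retraction, combined entropion/trichiasis,
ectropion, tumor, epicanthus inversus, other epicanthus) span the label
space; an admissibility table (`admissibility_table()`) fixes which change
may be reported in which region, and every diagnosis cites the findings and
parameter values that produced it.

The approach assumes standardised frontal photographs at primary gaze with a
10-mm circular fiducial on the forehead as the only absolute length
reference, and a segmenter that labels skin, palpebral fissure, cornea,
lesion and marker pixels. The segmenter is a contract, not a model: the
shipped baseline inverts the synthetic palette and exists so the rest of the
pipeline is testable; a learned segmenter for clinical photographs slots in
via `pipeline_config(segmenter = ...)` without touching any downstream
module. The same pluggability holds for the region classifiers.

## The eight parameters

All vertical measurements run along image columns (frontal, standardised
photographs; an optional chord-alignment rotation is deliberately left out).
On the *corneal axis column* — the column through the estimated corneal
centre, a reproducible stand-in for the corneal light reflex that a binary
mask cannot contain:

* `MRD1 = (y_cornea − y_upper_margin) · s`, `MRD2 = (y_lower_margin −
  y_cornea) · s`, with `s` the calibrated mm/px. A margin crossing the
  corneal centre yields a *negative* MRD, so severe ptosis is representable.
* `PF = MRD1 + MRD2` identically — all three are built from the same column
  and the same margin estimates, so the identity holds to machine precision
  rather than being a measured coincidence.
* The corneal area is the visible (unoccluded) cornea pixel count times
  `s²`; the lateral and medial areas split the fissure-minus-cornea region
  at the axis column (axis pixels count as medial), so lateral + medial +
  corneal area equals the total palpebral area pixel-exactly.
* Lid lengths are arc lengths of the margin polylines after
  smoothing-spline regularisation (below).

The medial/lateral split at the corneal axis is an explicit stand-in for a
boundary the source protocol leaves unspecified; it is isolated in one place
(`compute_morphometry`) so a different convention can be swapped in.

## Tunable parameters

| Parameter | Default | Unit | Rationale |
|---|---|---|---|
| `ptosis_mrd1_max_mm` | 2.0 | mm | common oculoplastic screening bound for ptosis |
| `upper_retraction_mrd1_min_mm` | 5.0 | mm | upper-lid retraction (TAO screening) |
| `lower_retraction_mrd2_min_mm` | 5.5 | mm | lower-lid retraction (TAO screening) |
| `tumor_min_area_mm2` | 1.0 | mm² | smallest reportable lesion |
| `bpes_icd_max_mm` | 30.0 | mm | short horizontal fissure required by the BPES rule |
| `score_slope_mm` | 0.5 | mm | logistic slope of detector scores; score = 0.5 exactly at threshold |
| `marker_diameter_mm` | 10 | mm | fiducial diameter of the photographic protocol |
| `box_margin_frac` | 0.25 | – | eye-box expansion (fraction of blob diagonal) so canthus squares fit |

All detectors use *strict* inequalities, and each score is the logistic of
the signed threshold margin, so "finding emitted" and "score > 0.5" are the
same event — sweeping the score threshold at 0.5 reproduces the rule.

## The atlas

Rules are data (YAML, `inst/extdata/atlas_rules.yaml`), not code: a rule
lists required (region, change) pairs, optional parameter predicates, a
priority, and an output disease. Single-change rules map each change to its
disease (both retractions map to thyroid-associated ophthalmopathy; the
epicanthus labels are reported at change level; entropion and trichiasis
form one combined class). The one composite rule — BPES — requires ptosis,
epicanthus inversus *and* a short inter-canthal distance, and, firing at
higher priority, consumes the findings it matched so the component diseases
are not co-reported (the subsumption is logged on the diagnosis).
Multimorbidity needs no enumeration: any other surviving findings fire their
own rules and the diagnosis is the union. Extending the system to a new
disease means adding a rule, not code; unknown change labels are rejected
with an error naming them.

Evaluation is per eye, one-vs-rest per class: accuracy, sensitivity,
specificity, F1, and AUROC as the Mann–Whitney rank statistic over
per-disease supporting scores (ties count one half). The average accuracy is
the unweighted mean of per-class accuracies, and each eye is categorised as
correct / over-detection (proper superset) / under-detection (proper subset)
/ misdetection (any other mismatch).

## The synthetic scene generator

`generate_scene()` emulates the photographic protocol, not photographs: lid
margins are quadratic arcs through the two canthi with a signed extremum
relative to the inter-canthal chord (the minimal smooth family matching
clinical lid shape, with arc length available by quadrature for the truth
report); the cornea is a disc clipped to the fissure; the marker is a
rendered disc; epicanthal folds are crease arcs over the inner canthus
(below the canthus for inversus, above otherwise); entropion/trichiasis and
ectropion are deterministic margin textures (inward lash strokes, an everted
red tarsal band) drawn as lid tissue so the noiseless palette segmenter
still inverts the renderer exactly. Noise is additive Gaussian on image
intensities only — never on the mask — so a seed changes pixel values but
not ground truth.

Condition templates (`inst/extdata/condition_templates.yaml`) encode the
study conditions: a 64 × 44 mm field at 0.2 mm/px, inter-canthal length
28–31 mm (20–24 mm for BPES), MRD1 3.0–4.2 mm for normals, 0.8–1.6 mm for
ptosis templates, retraction targets comfortably beyond their thresholds,
corneal radius 5.5 mm, lesion radii 1.2–2.2 mm, intensity noise sd 0.02.
Each defining parameter stays at least one jitter margin clear of its
screening threshold, so a template's geometric predicate holds for every
draw. The generator solves the lid extrema so the *truth* MRD values hit
the sampled targets exactly even when the cornea is jittered off the chord.

What the generator does **not** emulate: specular reflexes, lashes and brow
texture, skin-tone variation, illumination gradients, head tilt, gaze error,
motion blur, or segmentation failure modes of real photographs. Green tests
therefore certify the geometry, measurement, rule and evaluation machinery —
not clinical segmentation accuracy, which enters through whatever segmenter
a user plugs in.

## Numerical choices

* **Margins at the pixel boundary.** Column-wise first/last fissure pixel
  *centres* sit half a pixel inside the true margin; measurements shift each
  chain by ±0.5 px to the skin/fissure boundary. Without this, corners bias
  ~1.2 px inward and lid lengths run ~0.5 mm short. `extract_contours()`
  itself stays pixel-pure, preserving its degenerate contract (a 1-px-tall
  fissure yields coinciding chains).
* **Canthus refinement.** The extreme fissure pixel can sit 1–2 px inside
  the true canthus (the last columns are sub-pixel thin). Each margin chain
  is fitted with a global quadratic (one outlier-trim pass at 1.5 px, which
  also rejects lash-stroke notches) and the two curves are intersected at
  each end; the refinement falls back to the extreme pixel when the gap
  polynomial has no nearby root. Ambiguous equal-x endpoints break the tie
  toward smaller y.
* **Corneal centre under occlusion.** The visible-area centroid is biased
  by lid occlusion (a 30 % cap shifts it by roughly 0.2 r), so the centre
  comes from full-width rows — rows whose lateral cornea boundary touches
  fissure on both sides are complete chords of the corneal circle; their
  midpoints give the horizontal centre and a linear regression of
  `width²/4 + y²` on `y` gives the vertical centre. With fewer than five
  full rows the centroid is used and flagged.
* **MRD margin localisation** takes the median margin height over a
  7-column window at the axis, so single-column texture notches cannot bias
  MRD (the quadratic margin's curvature bias over ±3 columns is < 0.05 px).
* **Arc lengths.** Raw pixel chains overestimate curve length by up to
  ~8 %; chains are regularised with a smoothing spline (df ≤ 6) fitted on
  the interior chain and evaluated at every column, so a degenerate straight
  margin still measures its chord exactly.
* **Calibration.** The marker diameter starts from the equivalent-circle
  formula `2·sqrt(area/π)`. Raw pixel counts of rasterised discs carry
  lattice fluctuations (worst near radius 12 px, where an empty lattice
  annulus deflates the count by ~2.5 %), so by default the estimate is
  refined by rasterisation matching: coordinate descent on the row-extent
  mismatch between the observed component and a rendered disc, taking the
  midpoint of the mismatch-minimising radius interval. Near half-integer
  centres and small radii, distinct radii can rasterise to *identical*
  pixel sets, which bounds what any estimator can recover; the refinement
  attains that bound. `refine = FALSE` restores the plain formula.
* **Determinism.** All randomness flows through explicit seeds
  (per-scene seeds derived from a master seed by a fixed integer mix);
  repeated runs produce byte-identical JSON reports, which is why reports
  carry no timestamp unless one is passed in.

## Degenerate inputs

Zero fissure pixels yield an empty eye list with a warning; a missing
marker is an error unless an explicit `mm_per_px` is configured (then a
tagged warning); an axis column outside the fissure span (pathological
occlusion) is an error; canthus patches clipped past half their area carry
a warning flag; degenerate (≤ 4 px) patches return no finding plus a
warning rather than guessing.

## Problem sizes

The shipped tests exercise 100-scene geometry sweeps, a 200-scene
morphometry-recovery cohort, 50 scenes per condition class for the
closed-loop atlas check, and a calibration sweep over marker radii
10–60 px; `scripts/acceptance.R` uses cohorts of 180 single-disease and 80
multimorbidity eyes. These sizes keep full runs in the minutes range on one
CPU while leaving the per-class counts large enough for exact-match rates
to be meaningful.

## Known limitations

* The baseline segmenter and classifiers are palette/texture inversions for
  synthetic scenes; on clinical photographs they must be replaced through
  the documented contracts.
* MRD is measured to the corneal centroid column, not a light reflex, and
  along the true vertical rather than perpendicular to the inter-canthal
  chord; both choices are documented conventions, adequate for standardised
  frontal photographs.
* The medial/lateral area boundary at the corneal axis is a stand-in
  convention.
* Laterality for a monocular patch is inferred from image-half position;
  scenes cropped so that an eye crosses the midline would need an explicit
  laterality override.
* Texture-rendered classes (trichiasis strokes, ectropion band) slightly
  perturb the measured margins and areas by design; the parameter-recovery
  guarantees are stated for the texture-free normal/ptosis/retraction
  templates.
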
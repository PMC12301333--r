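---
title: "Quantifying lesion dissemination on PET and evaluating its prognostic value"
author: "petdix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying lesion dissemination on PET and evaluating its prognostic value}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petdix)
```

## Motivation

Total metabolically active tumour volume (MTV) summarises burden but not
geography: two patients with the same MTV may have one contiguous mass or
lesions scattered from neck to pelvis, and the scattered pattern carries
worse prognosis in diffuse large B-cell lymphoma. Dissemination indices
condense that geography into a single length. `petdix` implements the full
family — Dmax, Dmax_bulk, SPREAD_bulk, SPREAD_patient, Dmax_Vox — and its
2D surrogate Dmax_VoxMIP, the outermost-voxel distance read off a coronal
maximum-intensity projection (MIP). The attraction of Dmax_VoxMIP is
practical: it requires no 3D segmentation software, works for single-lesion
patients (longest intra-lesion diameter), and can be measured with a ruler
tool in any DICOM viewer.

## Data model and conventions

* **PetVolume** — a 3D grid of body-weight SUV values with per-axis voxel
  spacing in mm. On reading a NIfTI file the grid is reoriented into a
  canonical axis order (left–right, anterior–posterior, cranio–caudal) from
  the affine, so every downstream quantity is invariant to how the file was
  stored; the coronal MIP is then simply a maximum over axis 2. Input
  volumes are expected to already be in SUV units; converting raw DICOM
  series (decay correction, vendor conventions) is intentionally outside
  the package's contract.
* **Coordinates** — voxel indices are 0-based and the physical position of
  a voxel centre is `index * spacing` mm. All distances are computed in mm
  between voxel centres and reported in cm; volumes in mL. Voxel-centre
  (rather than voxel-face) distances are the simplest consistent
  convention; the difference is sub-voxel.
* **LesionSet** — lesions sorted by descending volume; label 1 is the
  *bulk* lesion. Ties are broken by higher SUVmax, then by lower original
  label.
* **Single-lesion convention** — centroid-based indices (Dmax, Dmax_bulk,
  SPREAD_bulk, SPREAD_patient) are 0 and a `singleLesion` flag is set, so
  cohort analyses can exclude such patients; voxel-based indices
  (Dmax_Vox, Dmax_VoxMIP) remain meaningful as the intra-lesion diameter.
  An empty lesion set yields an all-zero profile with `nLesions = 0`.

## Segmentation

The adaptive SUV-threshold rule operates per candidate focus (a connected
component of voxels above `seed_suv_min`, default 2.5):

\[ T = \beta \cdot I_{mean70} + I_{bg} \]

with \(I_{mean70}\) the mean SUV of focus voxels at or above 70% of the
focus SUVmax, and \(I_{bg}\) the mean SUV in a peri-lesional shell
(voxels within `background_shell_mm`, default 8 mm, of the 70%-isocontour
region, excluding all candidate-lesion voxels). The region of voxels above
\(T\) connected to the focus maximum is grown; grown regions are pooled,
relabelled by connected components (6/18/26-connectivity, default 26), and
components below `min_lesion_ml` (default 0.1 mL) discarded.

The multiplier \(\beta = 0.3\) is the widely used default for this family
of adaptive thresholds; every constant is exposed in
`segmentationParams()` because published applications of the rule vary in
these details. The background-shell definition is our own design choice —
adaptive-threshold descriptions rarely pin it down — and was chosen so that
\(I_{bg}\) tracks local background rather than a global statistic. For a
hot homogeneous sphere on background 1.0 with peak SUV 10 the rule gives
\(T \approx 0.3 \times 10 + 1 = 4\) and recovers the analytic 7.24 mL
(radius 12 mm) volume to well within 15% at 4 mm voxels.

Whether a clinical workflow computes "metabolic centres" SUV-weighted or
unweighted is usually unstated; both are implemented
(`metabolicCenter(mode =)`) and the SUV-weighted mean is the default, as
it is the natural reading of a *metabolic* centre. For uniform lesions the
two coincide.

External masks (`lesionsFromMask()`) are first-class inputs so the index
core can be validated independently of any particular segmentation. Fixed
41%-SUVmax thresholds and majority-vote ensembles are out of scope.

No smoothing is applied to input volumes, and none is needed by the
method; a pre-filter hook exists in the configuration but is disabled by
default.

## The distance indices

Centroid indices are exact maxima/sums over the \(K \times K\) centroid
distance matrix. The voxel-based diameter Dmax_Vox is defined as the
diameter of the **union** of lesion voxels rather than "max over
cross-lesion pairs": for two or more well-separated lesions the
definitions coincide, and the union definition extends seamlessly to
single lesions. The two can only differ when one lesion's own diameter
exceeds every cross-lesion distance — a geometry in which reporting the
larger intra-lesion diameter is arguably the more honest statement of
spatial extent.

The diameter scan is accelerated by an exact reduction: a voxel whose six
face neighbours are all present lies at the average of its neighbours'
centres, hence strictly inside their convex hull, and can never attain the
pairwise maximum. Only boundary voxels survive the reduction and a
vectorised all-pairs scan (chunked to bound memory) finishes the job. The
result is contractually identical to the exhaustive \(O(n^2)\) scan and is
tested against a `stats::dist()`-based oracle on every change.

## MIP geometry

`makeMip()` takes the exact per-column maximum along the collapsed
anatomical axis — no interpolation — so a MIP pixel value is always an SUV
actually present in the column. Two production modes exist for 2D lesions:

* `projectMask()` (default): the union of projected 3D lesion voxels,
  re-separated by 2D 8-connected components. Deterministic and tied to the
  3D segmentation. Lesions separated only along the collapsed axis merge;
  the profile flags this (`projectionMerged`) since a human reader of the
  MIP would face the same ambiguity.
* `segmentMip()`: thresholding of the MIP itself, mimicking a viewer-based
  reading. A threshold below background degenerates to one giant component
  — documented, not an error.

8-connectivity in 2D matches the 26-connectivity default in 3D.
Physiologic uptake (heart, bladder) that would occlude a lesion is handled
as it is in practice — by inspection, not inference: exclusion regions are
user-supplied 2D boxes whose fully-contained components are discounted
before measuring, and the sagittal view is available as the cross-check.

Since projection cannot increase distances, Dmax_VoxMIP ≤ Dmax_Vox always,
with equality when the extreme voxel pair lies in a plane orthogonal to
the beam. Across random multi-lesion phantoms the coronal Dmax_VoxMIP
correlates with Dmax_Vox at r > 0.95 with a non-positive mean difference —
the package's synthetic analogue of the near-unity correlation reported
for clinical cohorts; the exact value is cohort-specific and is not a
package constant.

## Survival machinery

Records are `(time, event)` pairs in months; PFS events are recurrence,
progression, or death from any cause. Kaplan–Meier estimation, Cox partial
likelihood (Efron tie handling — month-resolution times tie often) and the
two-group log-rank test delegate to the `survival` package; the "5-year"
rate is read at exactly 60 months.

The optimal cutpoint search is authored here. Each subject receives the
log-rank score \(U_i = \delta_i - \hat\Lambda(t_i)\) (event indicator
minus Nelson–Aalen cumulative hazard at the subject's time). For a
candidate cutoff \(c\), \(S(c) = \sum_{x_i \le c} U_i\) is exactly the
O−E log-rank numerator of the low group, so the whole scan is one
cumulative sum over subjects sorted by index value. The standardised
maximum

\[ q = \frac{\max_c |S(c)|}{s\sqrt{n-1}}, \qquad
   s^2 = \frac{1}{n-1}\sum_i U_i^2 \]

is referred to the supremum distribution of a Brownian bridge,
\(p = 2\sum_{j\ge1} (-1)^{j+1} e^{-2j^2q^2}\), truncated when terms fall
below 1e−10 and clamped to [0, 1] (the series is asymptotic and exceeds 1
for small \(q\)). Candidates are the distinct observed values inside the
inner 10–90% quantile band — the band is our choice (the method itself
does not prescribe a grid) and prevents degenerate tiny groups; it is
configurable. Ties in the candidate score are broken toward the lowest
cutoff. Because the adjustment targets the supremum over the whole bridge
while the scan is restricted to the band, the adjusted p is conservative
relative to the naive minimum — a property the test suite checks, along
with exact equivalence of the maximiser with a brute-force per-candidate
log-rank scan.

Reported alongside the adjusted p is the naive log-rank p at the selected
cutoff, since published tables typically print the latter; both are
exposed rather than choosing for the reader. Hazard-ratio confidence
intervals are Wald intervals; groups without events (monotone likelihood)
are flagged and their CI reported as unbounded rather than as a spuriously
finite interval.

Cutpoint-dichotomized indices drive the per-index risk tables and the
cross-classification (Low-Low / Mixed / High-High on MTV × Dmax_VoxMIP,
hazard ratios against Low-Low); *continuous* indices are used in the
added-variable models over the categorical IPI, where the Wald chi-square
on the index coefficient answers whether imaging adds prognostic
information to the clinical score. An index perfectly collinear with IPI
is reported as adding no information (p = 1, flagged) rather than erroring.

Bland–Altman agreement is the standard bias ± 1.96·sd of paired
differences, with the difference-vs-mean plot as an artifact.

## Synthetic data

`makePhantom()` renders voxelized ellipsoid lesions over a uniform
background with Gaussian SUV noise (clamped at zero), 4 mm isotropic
voxels by default, and returns the ground-truth mask plus the true index
profile computed from it. The noise model is deliberately *not* scanner
physics — no Poisson counting, reconstruction, or point-spread modelling —
which is sufficient for exercising thresholding and geometry but means
passing phantom tests does not certify performance on reconstructed
clinical images (partial-volume effects and heterogeneous uptake are the
main absences). The `gaussian` falloff profile drops to half-maximum at
the ellipsoid boundary (`value = bg + (peak − bg)·exp(−ln2·ρ²)`), a shape
chosen so the adaptive threshold lands near the nominal lesion edge.
Physiologic hot regions (heart/bladder surrogates) can be added to the
image without entering the truth mask.

`simulateCohort()` draws index values from log-normal distributions on the
scale of published whole-body PET cohorts (MTV ~ logN(log 300, 1.2) mL,
distances ~ logN(log 30, 0.8) cm), an IPI category, and exponential
proportional-hazards survival with independent uniform censoring whose
window is solved numerically for the target censoring fraction. Effects
can act on dichotomized indices (known true cutoffs) or standardised
continuous values. Everything is seed-deterministic: same spec + seed is
bit-identical.

## Numerical choices and degenerate inputs

* Connected components: sparse breadth-first search over foreground voxels
  (no dense relabelling passes); used for 3D (6/18/26) and 2D (4/8).
* Pairwise maxima: boundary-voxel reduction (exact, see above) + chunked
  vectorised scan; chunk size bounds the distance-matrix memory at a few
  MB.
* Empty segmentations are valid results (zero profile, flag), not errors;
  empty lesion sets passed to individual index functions are errors.
* Bridge p-series: truncation at 1e−10, clamped to [0, 1].
* Censoring-window solver: `uniroot` on the expected censoring fraction;
  falls back to the search bound for extreme targets.

## Problem sizes used in the validation suite

The property-based suite runs 200 random lesion sets (≤ 2500 voxels) for
oracle equivalence, 500 random phantoms for the index-ordering chain, 300
multi-lesion phantoms for MIP-vs-3D agreement, 1000 null replicates
(n = 200) for cutpoint calibration, 200 replicates (n = 300, HR = 3) for
cutpoint recovery with 50 brute-force cross-checks, 50 seeds of n = 1000
for Cox recovery, and 50 replicates of 200 pairs for Bland–Altman limits.
These sizes give Monte-Carlo standard errors comfortably inside the
asserted bands while keeping the default test run fast.

## Known limitations

* Input must already be in SUV units; DICOM conversion is out of scope.
* The segmentation is a faithful adaptive-threshold implementation, not a
  reproduction of any particular vendor tool; parameter defaults matter
  and are exposed.
* `projectMask()` merges lesions that overlap in projection (flagged); no
  attempt is made to re-split them the way a human reader might.
* No BSA normalisation of distance indices, no SUVpeak/TLG, no
  competing-risks or multivariable model selection.
* Phantoms do not emulate scanner resolution or anatomical context; see
  the synthetic-data section for what that implies about test coverage.
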
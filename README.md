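# petdix — PET lesion dissemination indices and their prognostic evaluation

In diffuse large B-cell lymphoma (DLBCL) and related malignancies, how *far*
the lesions are spread through the body on a baseline FDG-PET scan carries
prognostic information beyond total tumour burden. `petdix` computes the
family of quantitative dissemination indices used for this purpose and the
survival-analysis toolchain needed to evaluate them, and ships a synthetic
phantom/cohort generator so every step is testable without clinical data.

The package is aimed at quantitative-imaging and biostatistics researchers
working with whole-body PET in SUV units (NIfTI input; 3D label masks from
any segmentation tool are accepted as first-class inputs).

## The indices

For a patient with lesions \(1 \dots K\) (metabolic centres \(c_k\), bulk
lesion \(b\) = largest volume):

| Index | Definition | Units |
|---|---|---|
| MTV | total lesion volume \(\sum_k V_k\) | mL |
| Dmax | \(\max_{k,l} \lVert c_k - c_l \rVert\) | cm |
| Dmax_bulk | \(\max_{k \ne b} \lVert c_k - c_b \rVert\) | cm |
| SPREAD_bulk | \(\sum_{k \ne b} \lVert c_k - c_b \rVert\) | cm |
| SPREAD_patient | \(\max_k \sum_{l \ne k} \lVert c_k - c_l \rVert\) | cm |
| Dmax_Vox | max distance between any two tumour-voxel centres | cm |
| Dmax_VoxMIP | the same outermost-voxel distance measured on the 2D coronal maximum-intensity projection | cm |

Dmax_VoxMIP is the point of the family: it needs nothing beyond a 2D MIP
image in an ordinary viewer, is defined even for single-lesion patients
(longest intra-lesion diameter), and by projection geometry is always
bounded above by the 3D Dmax_Vox.

Lesions come either from an external label mask or from the built-in
adaptive SUV-threshold (Nestle-type) segmentation, which thresholds each
candidate focus at `T = beta * I_mean70 + I_bg` (`I_mean70` = mean SUV of
voxels above 70% of the focus SUVmax, `I_bg` = peri-lesional background
mean, `beta = 0.3` by default).

The prognostic toolchain implements the Contal–O'Quigley optimal cutpoint
(maximally selected log-rank statistic with a Brownian-bridge adjusted
p-value), Kaplan–Meier rates, two-group and added-variable Cox models
(Wald chi-square over a categorical IPI), the Low-Low / Mixed / High-High
cross-classification of MTV × Dmax_VoxMIP, and Bland–Altman observer
agreement.

## Worked example

```r
library(petdix)

# a three-lesion synthetic phantom: 4 mm voxels, SUV background 1.0
ph <- makePhantom(
  lesions = list(
    list(center = c(60, 80, 90),   radii = 14, peak = 9),
    list(center = c(160, 100, 260), radii = 10, peak = 7),
    list(center = c(110, 70, 330),  radii = 8,  peak = 6)),
  seed = 42)

les <- segmentAdaptive(ph$volume)   # adaptive SUV-threshold segmentation
disseminationProfile(les)
#> DisseminationProfile (3 lesions)
#>   MTV                19.5 mL
#>   Dmax               24.5 cm
#>   Dmax_bulk          24.5 cm
#>   SPREAD_bulk        44.4 cm
#>   SPREAD_patient     44.4 cm
#>   Dmax_Vox           26.5 cm
#>   Dmax_VoxMIP        26.5 cm
```

MTV is the summed segmented volume; Dmax is the largest centre-to-centre
distance (here between the first and third lesion, so Dmax = Dmax_bulk);
Dmax_Vox exceeds Dmax because it reaches to the outermost voxels; and
Dmax_VoxMIP equals Dmax_Vox here because the extreme voxel pair is barely
foreshortened by the coronal projection.

Cohort level, on a simulated 104-patient cohort with a true step effect
(hazard ratio 3 above a Dmax_VoxMIP of 30 cm):

```r
coh <- simulateCohort(n = 104, seed = 1,
                      betas = c(mtv = 0.5, dmax_voxmip = 0.7),
                      cutpoints = c(mtv = 300, dmax_voxmip = 30))
rec <- data.frame(time = coh$os_months, event = coh$os_event)
contalOQuigley(rec, coh$dmax_voxmip)
#> Contal-O'Quigley cutpoint: 33.26 (q = 1.909, adj. p = 0.0014)
#>   High (n = 45) vs Low (n = 59): HR = 3.01 (1.79-5.07), log-rank p = 0.0000
#>   Survival rate: high 24%, low 57%
```

The scan recovers a cutoff near the generating 30 cm, a hazard ratio near
the true 3, and a search-adjusted p-value. `runCohort()` wraps this into
the full report (group comparisons, cutpoints for OS and PFS, added-variable
Wald tests, risk-group cross-classification) and writes the tables as CSV.

A thin command-line wrapper is installed at
`system.file("scripts", "petdix.R", package = "petdix")` with subcommands
`indices`, `mip`, `cohort`, `agreement` and `phantom`.

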
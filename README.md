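# spinemorph

Quantitative morphometry of the developing spine and rib cage from 3D
landmark curves.

Embryonic studies of vertebral column development — for example chick
embryos immobilised for a single embryonic day and harvested between
E5 and E9 — phenotype their specimens through a small set of geometric
measurements made on landmark curves digitised from volumetric scans:
the sagittal curvature of the vertebral-body line, spine height,
endplate wedge angles, and the length and tortuosity of the vertebral
ribs. `spinemorph` implements that measurement pipeline as a tested R
package for developmental biologists and morphometricians, together
with the group statistics such studies report and a seeded synthetic
specimen generator, calibrated to published cohort values, that
validates the pipeline end to end.

## What it computes

**Geometric curvature.** A cubic spline `C(p)` is fitted through the
ordered vertebral-body centres (parameter `p` = vertebra ordinal), and
the geometric curvature at each vertebra is the reciprocal of its
osculating-circle radius,

```
GC(p) = |C'(p) × C''(p)| / |C'(p)|³ = 1 / R(p)      [mm⁻¹]
```

evaluated by default on the sagittal (x–y) projection, with the 3D
form available for rib curves. Profiles cover the C8–L7 analysis
window; a signed variant distinguishes kyphotic (+) from lordotic (−)
bending.

**Vertebral anatomy.** The wedge angle is the angle between lines
along the superior and inferior endplate surfaces; a vertebra is
wedged when the angle is strictly greater than 10°, fused when
annotated or when adjacent endplates overlap, and abnormal when either.
Spine height is the straight C8–L7 centre distance in the sagittal
plane.

**Rib morphometry.** Each rib centerline yields its curved length
`L_C`, endpoint chord `L_S`, inflection count `N` (discrete
Frenet-normal flips after uniform resampling) and the inflection count
metric

```
ICM = N · L_C / L_S
```

plus presence/absence and fusion censuses per specimen.

**Statistics.** Per-vertebra one-way ANOVA with Tukey HSD across
treatment groups, or two-tailed unpaired t-tests against age-matched
controls, at α = 0.05 per location; fused-joint proportions
(`n_fused / n_total`) summarise histology joint tables.

## Worked example

```r
library(spinemorph)

ctl <- generateCohort(defaultConfig(9, "control"), n = 6, baseSeed = 1)
im4 <- generateCohort(defaultConfig(9, "Im4"),     n = 6, baseSeed = 100)

spineHeight(ctl[[1]])
#> [1] 10.50805

classifyVertebrae(im4[[1]])
#> WedgeReport 'Im4_E9_01' (Im4, E9): 7 wedged, 0 fused, 7 abnormal (threshold 10 deg)

cohortRibSummary(ctl)[, c("mean_L_C", "sd_L_C", "mean_ICM", "prop_absent")]
#>   mean_L_C sd_L_C mean_ICM prop_absent
#> 1      2.7   0.36        0           0

prof <- profilesTable(lapply(c(ctl, im4), computeGCProfile))
cmp <- perLocationComparison(prof, design = "critical_timings")
head(cmp[cmp$significant, ], 4)
#>  location stage        test statistic      p_value significant
#>        C8    NA anova_tukey  18.09146 1.680442e-03        TRUE
#>        C9    NA anova_tukey  13.34640 4.438205e-03        TRUE
#>       C10    NA anova_tukey 107.36514 1.146634e-06        TRUE
#>       C11    NA anova_tukey  10.45117 8.977854e-03        TRUE
```

The first specimen of this control cohort is 10.51 mm tall (the cohort
mean sits on the 10.9 mm E9 calibration), the immobilised specimen
carries 7 wedged vertebrae (its cohort mean is 8), the control cohort's
fifth-left rib averages 2.70 ± 0.36 mm with zero tortuosity, and the
per-vertebra ANOVA flags locations concentrated around the planted
deformities (17 of 21 window locations in this severe-phenotype
comparison).

Cohorts can be written to and read from a JSON specimen format
(`writeSpecimen` / `readSpecimen`), and `runPipeline()` produces the
full set of result CSVs in one call. A thin command-line front end is
installed at `inst/cli/spinemorph.R` with `simulate`, `measure`,
`compare` and `report` subcommands.

## Documentation

The methods vignette (`vignettes/spinemorph-methods.Rmd`) describes
the model and its assumptions, every tunable parameter with units and
defaults, the generator's calibration table (published values vs.
invented ones), numerical choices, and the limitations of validating
against synthetic cohorts.
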
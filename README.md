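# hcindex

Quantitative hip congruency from annotated canine radiographs.

## The problem

Screening for canine hip dysplasia (HD) on ventrodorsal hip-extended
radiographs scores each hip into the five FCI grades A–E. One of the
key criteria — how congruent femoral head and acetabulum are — is
traditionally judged by eye, with well-documented observer
disagreement. The **Hip Congruency Index (HCI)** replaces the visual
judgement with a number: after an examiner outlines the projected
acetabular coverage area and the proximal femur as polygons (e.g. with
LabelMe), the index is

```
HCI = AAOFH / AA
```

where `AA` is the acetabular polygon's area and `AAOFH` the area of
overlap between acetabular and femoral-head polygons. Congruent hips
have little acetabular free space (HCI ≈ 0.74 for grade A on average);
subluxation lowers HCI toward 0. Being a ratio of areas on one
projection, HCI cancels image magnification. The package also measures
the **Norberg angle** from point landmarks (femoral head centers and
cranial effective acetabular rim).

`hcindex` is aimed at veterinary imaging researchers who need (a) the
measurement itself from annotation files, (b) the validation battery
that establishes a measurement protocol — paired t-tests, Bland–Altman
limits of agreement (mean ± 1.96 SD), intraclass correlation ICC(3,1)
with the 0.5/0.75/0.9 interpretation bands — and (c) unequal-variance
group comparison across HD grades (Welch's ANOVA with Games–Howell post
hoc), plus a synthetic hip generator with known ground truth so every
stage is testable without radiographs.

## Worked example

```r
library(hcindex)

params <- hip_shape_params(acetabular_radius = 100, femoral_radius = 90,
                           displacement = 12, opening_halfangle = 70,
                           n_vertices = 128)
hip    <- make_hip(params, center = c(1250, 600), side = "left",  dog_id = "demo")
contra <- make_hip(params, center = c(750, 600),  side = "right", dog_id = "demo")

m <- measure_hip(hip$annotation, contra$annotation$femoral_head_center)
print(m$hci)
#> HCI = 0.7440  (AA = 22409.6 px^2, AAOFH = 16673.0 px^2)
cat(sprintf("Norberg angle: %.1f deg\n", m$norberg))
#> Norberg angle: 103.3 deg
cat(sprintf("ground-truth HCI: %.4f\n", hip$truth$true_hci))
#> ground-truth HCI: 0.7438
```

The measured index (polygon clipping on the annotation outlines) agrees
with the generator's ground truth (brute-force rasterization of the
underlying shapes) to ~2×10⁻⁴; a 12 px lateral subluxation of a 90 px
head in a 100 px cup costs about 0.07 of HCI relative to the concentric
case. A duplicate-measurement series is summarized the same way a
reliability study would report it:

```r
s1 <- c(0.74, 0.69, 0.61, 0.55, 0.72, 0.66, 0.58, 0.49, 0.70, 0.63)
s2 <- c(0.73, 0.70, 0.60, 0.56, 0.71, 0.67, 0.59, 0.50, 0.71, 0.62)
print(agreement_report(s1, s2, label = "E1S1 vs E1S2"))
#> == E1S1 vs E1S2 ==
#> paired t: mean diff -0.0020 +/- 0.0103, t(9) = -0.612, p = 0.555
#> Bland-Altman (n = 10)
#>   mean difference -0.0020 (95% CI -0.0094 to 0.0054)
#>   95% limits of agreement -0.0222 to 0.0182
#> ICC(3,1) = 0.991 (95% CI 0.966 to 0.998) - excellent reliability
#>   F(9, 9) = 230.04, p = 1.51e-09; n = 10 units, k = 2 raters
```

Mean difference near zero with a CI spanning zero says no systematic
session bias; narrow limits of agreement say the sessions are
interchangeable; an ICC lower bound above 0.75 meets the adequate-
reliability rule.

## Command-line pipeline

```sh
Rscript inst/cli/hci simulate  --out cohort/ --seed 7 [--config run.cfg]
Rscript inst/cli/hci measure   --annotations cohort/ --out meas.csv
Rscript inst/cli/hci agreement --annotations meas.csv --out agr
Rscript inst/cli/hci compare   --annotations meas.csv --out cmp --alpha 0.05
```

`simulate` writes LabelMe-style JSON plus `ground_truth.csv` and is
byte-reproducible under a fixed seed; `measure` emits one row per hip
(`dog_id, side, examiner, session, aa_px2, aaofh_px2, hci, norberg_deg,
fci_grade`); `agreement` reproduces the three-contrast reliability
design (E1S1 vs E1S2, E2S1 vs E2S2, E1S2 vs E2S2); `compare` writes the
per-grade descriptive table, assumption checks, Welch ANOVA and the
Games–Howell matrix. Every CSV gets a JSON twin. Exit codes: 0 success,
1 validation error, 2 I/O error.

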
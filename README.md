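# placentaDCE

Non-invasive quantification of mouse placental perfusion and uterine
contractile motion from dynamic contrast-enhanced (DCE) MRI, for
preclinical imaging groups studying placental development and
fetoplacental disease models.

A pregnant mouse carries 6–12 fetoplacental units; reading each
placenta's function *in vivo* and longitudinally requires quantitative
imaging rather than ex vivo histology. From a T1-weighted DCE time
series (~50 frames at ~18 s), per-placenta segmentation masks and a
renal-hilum arterial ROI, plus pre/post-contrast variable-flip-angle
(VFA) stacks, the package computes:

* **Voxelwise perfusion** by the one-parameter steepest-slope model,
  `F/V_T ≅ [dC_T/dt]_max / [C_A]_max`, normalised by the arterial input
  function (AIF) peak and reported in mL/min/100 mL;
* **Perfusion chambers** per placenta by a physiological percentile
  threshold — the 55th percentile of perfusion values at E14.5 and the
  45th at E17.5, the stereological labyrinth/decidua volume proportions —
  separating a high-perfusion (labyrinth-like) from a low-perfusion
  chamber;
* **R1 mapping and apparent Gd uptake**: voxelwise T1/R1 from the Ernst
  equation `S = M0 sin(a)(1-E1)/(1-E1 cos(a))`, `E1 = exp(-TR/T1)`, fitted
  over five flip angles; `AGU = mean(ΔR1) × #voxels` per chamber;
* **Distribution biomarkers**: a two-component Gaussian mixture fitted by
  EM to log10 perfusion, with per-component peak, FWHM, AUC, and the
  apparent blood volume `ABV = v_voxel Σ F / 100` (mL/min);
* **Contraction quantification**: Horn–Schunck optical flow velocity
  fields and chamber traces, Welch periodograms, Bartlett-window STFT
  spectrograms, voxelwise relative 8–12 mHz sub-band power maps, and a
  per-placenta phasic-motion flag.

A digital phantom (`phantom_spec()` / `synthesize_dce()`) emulates the
whole acquisition — gamma-variate bolus, Ernst-equation signal synthesis,
programmed chamber perfusion, phasic motion at the study's prevalences
(11.1% of placentas at E14.5, 82.1% at E17.5) — so the entire pipeline is
verifiable with no animal data. Volumes are read and written as NIfTI-1
with JSON sidecars.

## Worked example

Generate and analyse one mid- and one late-gestation phantom litter
(about a minute on one CPU):

```r
library(placentaDCE)
cfg <- study_config(list(phantom_spec(gestational_age = "E14.5", seed = 11),
                         phantom_spec(gestational_age = "E17.5", seed = 12)))
report <- run_pipeline(cfg)
print(report)
#> Study report: 2 sessions (E14.5, E17.5), 48 placenta rows
#> mean chamber perfusion (mL/min/100 mL):
#>     age chamber mean_perfusion
#> 1 E14.5    high       60.19259
#> 2 E17.5    high       98.46831
#> 3 E14.5     low       34.21757
#> 4 E17.5     low       47.54749
#> 5 E14.5   whole       45.91037
#> 6 E17.5   whole       75.55504
```

Chamber perfusion rises from mid to late gestation in both chambers
(programmed truth: low 30 → 45.6, high 55 → 79.97 mL/min/100 mL; the
late-gestation high chamber is overestimated because its programmed
phasic motion inflates steepest slopes — a documented property of the
model). Group statistics use Welch's unequal-variance t-test (Tukey–Kramer
after one-way ANOVA for three or more groups):

```r
report$group_table
#>   chamber     comparison difference statistic      p_value       method
#> 1    high E14.5 vs E17.5  -38.27572 -10.74427 4.473616e-08 Welch t-test
#> 2     low E14.5 vs E17.5  -13.32991 -92.06614 1.464637e-13 Welch t-test
#> 3   whole E14.5 vs E17.5  -29.64467 -16.18133 6.828370e-10 Welch t-test
```

The per-placenta phasic flags recover the programmed contraction
prevalence exactly — 1 of 8 placentas at E14.5, 7 of 8 at E17.5:

```r
aggregate(phasic ~ age, unique(report$placenta_table[, c("age", "placenta", "phasic")]), sum)
#>     age phasic
#> 1 E14.5      1
#> 2 E17.5      7
```

`report$placenta_table` holds the full per-placenta × chamber table
(mean perfusion, steepest slope, voxel counts and volumes, ABV, AGU and
mean ΔR1, mean speed, sub-band power, phasic flag); `report$gmm_table`
the mixture biomarkers. A thin command-line wrapper is provided at
`inst/cli/placenta-dce.R` (`phantom` and `analyze` subcommands).

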
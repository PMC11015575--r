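# phagoglia

Volumetric quantification of glial phagocytosis and microglial morphology
from multi-channel 3D fluorescence stacks.

## What it measures, and for whom

In mouse models of dopaminergic degeneration, microglia (Iba1⁺) and
astrocytes (GFAP⁺) engulf tyrosine-hydroxylase-positive (TH⁺) terminals and
cell bodies. The standard confocal readout is volumetric: with voxel
calibration (Δz, Δy, Δx) in µm, each channel is thresholded and reduced to
3D *particles* — connected components of more than 20 voxels — and the
package reports

- per-channel signal volume  V = (number of particle voxels) × Δz·Δy·Δx  (µm³),
- the phagocytosis index  %TH-in-glia = 100 · V(TH ∩ glia) / V(TH),
- astrogliosis as total GFAP⁺ particle volume,
- per-cell microglial morphometrics: soma volume from the Euclidean
  distance transform, process length and thickness from a 3D curve
  skeleton, Sholl intersection profiles, and a rule-based three-way
  classification (ramified / hypertrophic / bushy),
- normality-routed group statistics: Shapiro–Wilk gate, Student/Welch t or
  Mann–Whitney U for two groups, one-way ANOVA or Kruskal–Wallis + Dunn
  for several, two-way ANOVA + Bonferroni for crossed designs, all
  reported as means with 95% CIs and with every routing decision recorded.

It is written for image-analysis and neuroimmunology researchers who want
this pipeline as reviewable code rather than a chain of GUI steps, and it
bundles a ground-truthed confocal-stack simulator (parametric glial cells,
controlled engulfed fraction, Gaussian PSF, Poisson noise) so every stage
is testable without tissue.

## Worked example

Simulate a field with 30% of TH⁺ volume engulfed, segment it, and quantify:

```r
library(phagoglia)

cfg <- simulation_config(engulfed_fraction = 0.3, seed = 7)
set.seed(7); cfg <- populate_cells(cfg, n_cells = 3)
sim <- simulate_stack(cfg)
sim$stack
#> <image_stack> 2 channel(s) [TH, GLIA_IBA1], 20 z x 96 y x 96 x voxels, spacing (1, 0.5, 0.5) um

seg <- segment_stack(sim$stack)            # Otsu + 3D particles > 20 voxels
quantify_phagocytosis(seg)
#>   glial_role th_volume_um3 glial_volume_um3 overlap_volume_um3 percent_th_in_glia
#> 1  GLIA_IBA1         470.2             1177              131.0              27.86
sim$truth$true_engulfed_fraction
#> [1] 0.2866
```

The measured index (27.9%) recovers the realised ground-truth fraction
(28.7%) through blur, photon noise, Otsu thresholding and the size filter.
Per-cell morphometrics on simulated hypertrophic cells:

```r
cells <- simulate_cells("hypertrophic", 3, seed = 11)
dplyr::bind_rows(lapply(seq_along(cells), function(i)
  measure_cell(cells[[i]]$mask, cells[[i]]$spacing, cell_id = i)))
#>   cell_id soma_volume_um3 total_process_length_um mean_process_radius_um class_label
#> 1       1            401.                   189.                    1.07 hypertrophic
#> 2       2            426.                   157.                    1.03 hypertrophic
#> 3       3            407.                    93.8                   1.02 hypertrophic
```

Large somas (~400 µm³ > the 250 µm³ cut), long (> 60 µm) and thick
(> 0.8 µm) processes put all three in the hypertrophic class. Group
comparison of phagocytosis indices from 7 animals per group:

```r
set.seed(1)
route_and_compare_two(rnorm(7, 9, 3), rnorm(7, 28, 4),
                      names = c("control", "lesion"))
#> <group_comparison> two_group design, route: student_t
#>   statistic = -10.03, p = 3.469e-07
#>   group       n  mean lower upper
#> 1 control     7  9.03  5.69  12.4
#> 2 lesion      7 28.2  24.9   31.4
```

Both groups passed Shapiro–Wilk and the F test found no variance
difference, so the route is Student's t; the object records those
decisions, `tidy()`/`glance()` return the summaries, and `autoplot()`
draws the mean ± 95% CI panel.

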
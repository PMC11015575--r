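---
title: "Quantifying glial phagocytosis and microglial morphology in 3D stacks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying glial phagocytosis and microglial morphology in 3D stacks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phagoglia)
```

## The measurement problem

In models of dopaminergic degeneration, microglia and astrocytes engulf
tyrosine-hydroxylase-positive (TH⁺) terminals and cell bodies. The standard
readout from double-immunofluorescence confocal z-stacks is volumetric: the
TH⁺ volume of a field, the glial (Iba1⁺ or GFAP⁺) volume, and the share of
TH⁺ volume that lies inside the glial mask — a phagocytosis index.
Alongside it, microglial activation is scored from cell shape (ramified,
hypertrophic, bushy) and from Sholl ramification profiles. phagoglia
implements that whole quantification chain as inspectable, tested code, plus
a ground-truthed simulator so every stage can be validated without tissue.

All quantification runs on the full calibrated 3D grid. Z-projections
(`project_stack()`) exist for display only: a volume in µm³ cannot be read
off a projection, and both maximum and sum reductions are offered because
display conventions differ between laboratories.

## Segmentation and the particle definition

A channel is thresholded (Otsu on the channel's full 3D histogram by
default, a fixed threshold as override), and supra-threshold voxels are
grouped into 3D connected components under 26-connectivity. **Signal** is
then defined as the components whose voxel count strictly exceeds
`min_size` (default 20): a 20-voxel blob is noise, a 21-voxel blob is a
particle. Volumes are voxel counts × voxel volume, so totals are exact
arithmetic, and every `segmentation_result` records the threshold, method,
cutoff and connectivity that produced it.

Two conventions deserve flagging. The size filter is applied to 3D
components, not per-slice 2D particles, because the readout is a 3D volume;
the per-slice reading of "20 pixels" would make the cutoff depend on slice
spacing. And 26-connectivity is the default because it matches the common
particle-analysis convention in 3D; both the cutoff and the connectivity
are arguments, not constants.

## The phagocytosis index

`quantify_phagocytosis()` reports, per field: TH⁺ volume, glial volume,
their overlap, and `percent_th_in_glia` = 100 × overlap / TH⁺ volume. The
denominator is the total TH⁺ volume of the field — the index answers "what
share of the dopaminergic signal sits inside glia". The alternative
normalisation (share of the glial volume occupied by TH) is available via
`denominator = "glia"`. When no TH⁺ signal survives the size filter the
percentage is defined as 0 and flagged (`th_empty`), rather than NaN.
Overlap is computed on the size-filtered masks so that numerator and
denominator use the same particle definition.

Fields are the sampling unit but animals are the statistical unit: per-field
rows should be averaged per animal (`compare_groups(..., animal = )`) before
any group test, since fields within an animal are pseudo-replicates.

## Soma, skeleton, Sholl

Per-cell morphometrics treat each size-filtered glial particle as one cell
(touching cells are not split; border-clipped cells are flagged).

* **Soma.** The soma centre is the argmax of the Euclidean distance
  transform (exact, anisotropic-spacing-aware; the grid border counts as
  background; ties broken at the lowest (z, y, x)). The soma is the ball of
  radius max-EDT around that centre: for a convex cell body this recovers
  the body, while processes — thinner than the body by the very vocabulary
  of the morphology classes — remain outside.
* **Skeleton.** The whole cell mask is thinned to a curve skeleton
  (iterative removal of simple points, 26-connected foreground /
  6-connected background, endpoints preserved). Skeleton voxels inside the
  soma ball are discarded; what remains traces the processes. Chain lengths
  are summed under the physical voxel metric after resampling each chain
  with a 3-voxel stride — summing single-voxel steps overestimates the
  length of oblique lines by up to ~12%, and the stride removes most of
  that staircase bias. Leaf spurs shorter than 3 µm attached to longer
  structure are pruned as thinning artefacts of thick, uneven tubes; an
  isolated short chain is a genuinely short process and is kept. Mean
  process radius is the mean distance-to-background along the kept
  skeleton.
* **Sholl.** Intersections are counted per spherical shell as connected
  components of cell voxels whose distance to the soma centre falls within
  half a voxel diagonal of the shell radius. By default the thresholded
  mask is probed — the behaviour of Sholl analysis on segmented images —
  because a thinned skeleton loses up to one tube radius at each tip,
  which would wrongly empty the outermost shell; `on = "skeleton"` is
  available. Default shell spacing is 2 µm.

## The three-way morphology classifier

The field's qualitative definitions — ramified: small body, long thin
processes; hypertrophic: big body, long thick processes; bushy: big body,
short processes — become ordered threshold rules on (soma volume, total
process length, mean process radius). Rules apply in that order, bushy
ignores process thickness, and every comparison is strict: a feature
exactly on a cut satisfies neither side, so such cells come out
`unclassified` rather than silently falling into a class.

No published numeric boundaries exist for "small/big" or "short/long,
thin/thick"; the defaults (`soma_volume_cut` 250 µm³, `process_length_cut`
60 µm, `process_radius_cut` 0.8 µm) are package conventions calibrated on
the simulator presets: each cut sits in the gap between the relevant
feature distributions of the presets on either side (preset soma volumes
~115 vs ~525/700 µm³; total lengths ~40 vs ~90–130 µm; radii ~0.45 vs
~1.1 µm). They are parameters of `classifier_thresholds()`, not constants,
and real tissue will need its own calibration.

## The simulator

`simulate_stack()` renders two-channel fields with known ground truth,
defined before blur and noise so that segmentation accuracy is a measurable
property rather than a definition:

* **Cells** are soma spheres plus tube-swept persistent random walks
  (1 µm steps, Gaussian direction perturbation, branching with a per-step
  probability, children inheriting the remaining path length). Primary
  directions are kept ≥ ~40° apart — processes radiate — and their z
  component is damped (`z_flatten` 0.5) the way cells spread in a thin
  section. Preset dimensions for the three classes are package conventions
  chosen to be plausible for striatal/nigral microglia and mutually
  orderable; tests assert the orderings, not the absolute values.
* **TH⁺ signal** is placed as spherical puncta (default radius 1.25 µm,
  ~33 voxels at the coarse spacing, safely above the 20-voxel filter).
  Engulfed puncta are seeded at interior glial voxels and clipped to the
  glial mask — engulfed material is inside the cell; free puncta keep a
  1 µm clearance from glia so that PSF blur cannot manufacture false
  overlap. Placement steers the engulfed voxel count towards
  `engulfed_fraction` × target volume, stopping half a punctum short of
  overshooting, which keeps the realised fraction within `engulfed_tol`
  (0.02) whenever the field carries enough puncta (the default field does;
  deliberately tiny fields should declare a larger tolerance).
* **Optics and noise.** Masks become intensities (background 20,
  foreground 180 counts), blurred by an anisotropic Gaussian PSF (default
  σ = 0.7 µm axial, 0.25 µm lateral) and degraded by Poisson photon noise
  plus Gaussian read noise (σ = 3 counts) — the standard fluorescence
  model. Two named voxel regimes, `"coarse"` (1.0 × 0.5 × 0.5 µm,
  20×-like) and `"fine"` (0.5 × 0.2 × 0.2 µm, 63×-like), are conventions,
  not claims about any specific acquisition.

What the simulator does **not** emulate: autofluorescent background and
vasculature, spatially varying PSFs, touching/overlapping cell somas,
partial-membrane contact versus true engulfment, and anything dynamic.
Passing tests therefore demonstrate that the pipeline recovers known
geometry under realistic blur and noise — not that a particular biological
threshold is correct for any given tissue batch.

Determinism is a contract: identical configurations (including seeds)
produce bit-identical stacks, and cohorts derive per-animal seeds from one
master seed.

## Group statistics

`route_and_compare_two()` mirrors the conventional normality-routed
workflow: Shapiro-Wilk per group at α = 0.05; both normal → F test on the
variances → Student's t (equal) or Welch's t (unequal), two-tailed; any
group non-normal → Mann-Whitney U. With three or more groups the route is
one-way ANOVA versus Kruskal-Wallis followed by Dunn's test with Bonferroni
adjustment, and crossed designs (for example morphology-class counts ×
treatment) use two-way ANOVA with pooled-variance Bonferroni post hoc
comparisons (`p_adj = min(1, m·p)`, exactly). Every routing decision —
normality p per group, variance-test p, route taken — is stored in the
returned object, so the route is reproducible from the provenance alone.

Choices the convention leaves open, set here as documented defaults: the
normality gate routes nonparametric if *any* group fails (conservative);
the equal-variance check is the F test (Levene is a reasonable substitute
but the F test matches the "equal variances" vocabulary of t-test
workflows); the routing α is 0.05. Degenerate zero-variance samples cannot
be Shapiro-tested, are flagged, and route nonparametric. Results are
reported as means with t-based 95% confidence intervals.

## Problem sizes and numerical notes

The test-suite and acceptance experiments use default 20 × 96 × 96-voxel
coarse fields (three cells, ~1 800 TH voxels) and 16 × 80 × 80 fields for
cohort replicates — sizes at which punctum granularity stays below the
steering tolerance and a full simulate–segment–quantify cycle takes well
under a second, so Monte-Carlo calibrations (1000-replicate type-I error,
20-replicate cohort power at n = 7 animals/group) remain cheap.
Classification experiments grow 100 cells per preset in tight per-cell
boxes at 0.6 × 0.4 × 0.4 µm.

Numerical conventions: intensities are stored as native 16-bit integers and
round-trip bit-exactly through the package's TIFF writer; the distance
transform is the exact squared-distance lower-envelope algorithm with
physical spacing; Otsu runs on 256 histogram bins and refuses
constant-intensity input instead of inventing a threshold; thresholding is
strict (`> t`); reading a file without spacing metadata fails unless an
explicit override is given — volumes silently computed at a guessed
calibration are worse than an error.

## Known limitations

Touching cells are flagged, not split (no watershed); the ameboid
morphology is not part of the three-class scheme; engulfment is overlap of
size-filtered masks, which cannot distinguish surface contact from
internalisation without a membrane marker; and the classifier cuts, like
the simulator presets they were calibrated on, are conventions to be
re-examined against annotated real data before any biological use.
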
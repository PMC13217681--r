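---
title: "Evaluating CTV delineation quality: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating CTV delineation quality: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(contoureval)
```

## The problem this package addresses

Structured training programmes for radiotherapy target delineation are
evaluated by comparing each observer's clinical target volume (CTV) contour
against an expert reference, before and after the intervention. `contoureval`
implements the full quantitative side of such a study for 3D binary masks on
a regular, anisotropic voxel grid: the per-contour quality metrics, the
cohort-level interobserver-variability (IOV) indices, the paired pre/post
hypothesis tests with effect sizes, the quality-control (QC) exclusion
rules, and the directionally adjusted rank correlations between Likert
self-assessment and objective quality. Because participant contours from
such studies are generally not publicly deposited, the package also ships a
synthetic cohort generator so that every stage is exercisable and testable
without any external data.

## Contour quality metrics

All metrics operate on pairs of `voxel_mask` objects that share a grid
(shape, spacing, origin); the package never resamples. With $A$ the test
contour, $B$ the reference, $|\cdot|$ voxel counts:

* **DSC** $= 2|A\cap B| / (|A|+|B|)$ — spatial overlap.
* **CI** (conformity index) $= |A\cap B| / |A\cup B|$, the Jaccard index.
  It is bound to Dice by $CI = DSC/(2-DSC)$, an identity the test suite
  checks to $10^{-9}$. Published delineation studies use "CI" for several
  different quantities; the Jaccard reading is the one consistent with
  jointly reported Dice/CI pairs in this literature (a mean Dice of 0.81
  predicts a Jaccard of 0.68), and is flagged here because supplementary
  formula tables are not always available to settle it.
* **Inclusion** $= |A\cap B| / |B|$ — the fraction of the reference covered
  by the test contour. The reference denominator is the only reading that
  keeps Inclusion consistent with jointly reported Dice and signed volume
  differences (e.g. Dice 0.81 with RVD $+0.02$ predicts Inclusion 0.82;
  Dice 0.78 with RVD $-0.11$ predicts 0.74).
* **RVD** $= (V_A - V_B)/V_B$ — signed; negative when the test contour is
  smaller than the reference.
* **ASD** — average surface distance, computed *symmetrically as the mean of
  the pooled bidirectional distance list* (all distances $a\to b$
  concatenated with all $b\to a$), not as the mean of the two directed
  means. The two conventions differ only when the surfaces have unequal
  numbers of surface voxels; the pooled version weights every surface point
  equally and the alternative is a one-line change in
  `average_surface_distance()`.
* **95%HD** — the maximum of the two directed 95th-percentile distances,
  with the linear-interpolation percentile (R's default type-7 quantile).
  `hausdorff_percentile(a, b, 100)` recovers the classical Hausdorff
  distance.
* **DC** — Euclidean distance between centres of mass (unweighted means of
  foreground voxel centres in physical coordinates).
* **Volume** — foreground count times voxel volume, in cm³.

**Surface definition.** A surface voxel is a foreground voxel with at least
one background 6-neighbour, with out-of-bounds counting as background.
Distances are measured between voxel centres, honouring anisotropic spacing,
via an exact Euclidean distance transform (a separable lower-envelope
algorithm implemented in C++). This definition is deliberately simple: it is
checkable against an exhaustive all-pairs oracle (the test suite does so on
random masks up to $15^3$ voxels at $10^{-9}$), and converges to the
continuum surface distance as the grid is refined. Sub-voxel (mesh-based)
surface distances are out of scope.

**Degenerate input policy.** Metrics on empty masks raise classed errors
(`ce_undefined_metric`) rather than returning sentinel zeros: a silent 0
from an empty submission would register as a perfect distance and corrupt
cohort statistics. Masks that do not share a grid raise
`ce_invalid_geometry`; NIfTI inputs with rotated (oblique) orientation are
rejected because resampling is a non-goal.

## Cohort statistics

**IOV.** `iov_summary()` reports the sample SD (with the $n-1$ denominator —
the standard choice for observer cohorts, used here because study reports
rarely state the denominator), the coefficient of variation SD/mean, and the
max/min volume ratio (MVR), with the extremes.

**Paired pre/post testing.** `paired_compare()` follows the common clinical
reporting convention "paired t-test or Wilcoxon signed-rank test depending
on the distribution": a Shapiro–Wilk test on the paired differences at
$\alpha = 0.05$ (configurable) gates the choice, since published reports
rarely state which normality test or level they used. The Wilcoxon
implementation drops zero differences, uses the tie-corrected normal
approximation *without* continuity correction, and reports a signed $z$ —
the convention of mainstream statistics packages, so published $Z$ values
can be compared directly. The statistic is the positive-rank sum of
(pre − post); swapping the arguments negates $z$ and $t$ and leaves p
unchanged. Effect sizes follow the test: $r = |Z|/\sqrt{n}$ for Wilcoxon and
$d = |t|/\sqrt{n}$ for the paired t, with $n$ the number of paired
observations entering the comparison.

A note on the small-sample accuracy of the Wilcoxon approximation: the
uncorrected normal approximation estimates the exact *mid*-p (half weight on
the observed atom) rather than the conventional exact p. At $n = 5$–$8$ the
approximation stays within a few hundredths of the exact mid-p, while its
distance from the conventional exact p can exceed 0.1; the unit tests
enumerate all $2^n$ sign assignments and assert exactly these bounds. For
cohort sizes in the design range (16–19 pairs) the distinction is
immaterial.

No multiple-testing adjustment is applied anywhere — matching the
exploratory reporting convention of such studies — and all p-values are
printed raw, with a single-star marker at p < 0.05 in formatted tables.

**Correlations.** `spearman_rho()` (average ranks for ties) correlates
Likert items with objective metrics per observer, in `pre`, `post` or
`delta` (post − pre on both sides) mode. Because the metrics disagree on
direction (higher Dice is better, lower Hausdorff is better), displayed
coefficients for `hd95`, `asd`, `dc` and `rvd` are negated
(`directional_adjust()`), so that positive always means "better contours go
with higher self-assessment". RVD is negated *literally* (not via $|RVD|$),
following the heatmap convention of the study design this package
operationalises; note that for cohorts that systematically under-contour,
"lower RVD" and "better volume agreement" differ, and `|RVD|` would be the
alternative reading. Items are joined to structures via an explicit mapping
table; by default an item named like a structure maps to it and all other
items map to the whole-CTV structure.

**QC rules.** `qc_filter()` operationalises the usual inclusion flowchart:
(a) unreadable, empty or grid-mismatched masks; (b) a missing pre or post
phase; (c) pre and post masks voxelwise identical across all structures
(detected on voxel content, not file checksums, to catch re-saved identical
contours); and, for the questionnaire only, (d) all pre-training scores at
the scale maximum — a ceiling that makes improvement unmeasurable. The
ceiling rule is operationalised as "all pre scores at maximum" because no
numeric criterion is standard. Filtering is total: each excluded observer
lands in a machine-readable log with exactly one reason per analysis scope.

## The synthetic cohort generator

The generator emulates the geometry of a pelvic CTV study: an axis-aligned
ellipsoid reference (default semi-axes 60 × 50 × 52 mm, analytic volume
≈ 654 cm³, optionally with spherical side-lobes for nodal regions) rasterised
on a 5 mm-slice grid with 1.25 mm in-plane spacing. Observer contours are
produced by three interpretable perturbations, each mapping onto one failure
mode the metric battery separates:

1. **Rigid translation** — per-axis normal with SD `translation_sd`,
   quantised to whole voxels (drives DC);
2. **Uniform growth/erosion** — a signed margin drawn per realisation from
   $N(\texttt{boundary\_growth}, \texttt{growth\_sd})$ (drives RVD and the
   cohort volume dispersion);
3. **Radial surface jitter** — a spatially correlated Gaussian field
   (default correlation length 25 mm) evaluated where each centroid ray
   pierces the mean-radius sphere, so the noise is constant along rays and
   the boundary deforms coherently without spawning disconnected islands
   (drives ASD/95%HD and, with the others, Dice).

The growth and jitter are applied by thresholding a signed distance field
measured to the rasterised *region* (voxel boxes) rather than to voxel
centres, which removes the half-voxel bias that would otherwise suppress
growth across 5 mm slices; a +2 mm margin on a sphere reproduces the
analytic shell volume within a few percent. The jitter field is centred
over directions (its spherical mean is subtracted) so that it carries no
net-volume mode. The `growth_sd` field is not part of a minimal perturbation
taxonomy but is essential: without a per-observer volume offset no
combination of translation and boundary-neutral jitter reproduces the
volume dispersion (SD of tens of cm³, MVR near 1.9) that delineation
cohorts actually show.

**Default severities.** The defaults were calibrated once, against the
orders of magnitude such studies report, and then frozen: pre-training
(translation 3 mm, growth −1.2 ± 1.9 mm, jitter 12 mm) gives mean Dice
≈ 0.81 with volumes ≈ 650 ± 70 cm³; post-training (2 mm, −0.8 ± 1.35 mm,
10 mm) gives Dice ≈ 0.85 with volumes ≈ 650 ± 52 cm³. The small negative
growth means offset the systematic volume inflation that radial jitter
induces on a convex body. One deliberate infidelity: a compact ellipsoid has
far less surface area than a real CTV (which strings thin nodal regions
along vessels), so a Dice of 0.81 on the ellipsoid corresponds to much
larger surface distances (ASD of a few mm) than the sub-millimetre ASD
values real studies print at the same Dice. The generator is calibrated to
volume and Dice; ASD/95%HD magnitudes are internally consistent but not
comparable to published tables.

**Reproducibility.** Every output is a pure function of the spec and the
master seed. Per-observer sub-seeds are derived with a counter scheme, so
enlarging a cohort never reshuffles earlier observers' data; the Likert
module uses its own counter. Likert responses come from a latent normal
model (shared per-observer aptitude + item noise, post = pre + shift),
rounded and clipped to 1–5 — monotone in the latent shift by construction.

**What passing tests do and do not show.** The simulation suites demonstrate
that the pipeline recovers a designed improvement (power) and does not
invent one (type-I error near 0.05 under identical pre/post severities), on
cohorts whose geometry is a smooth convex blob. They do not certify
behaviour on real anatomies, non-star-shaped structures, or observer error
modes outside the three modelled ones (e.g. topological mistakes,
wrong-organ contours).

## Problem sizes and numerical choices

Simulation-heavy checks run at reduced scale, chosen as the package's own
demonstration conditions: a 30 × 60 × 60 grid at 5 × 2.5 × 2.5 mm (the
full-size reference shape) for the 50-seed parameter-recovery suite, and a
20 × 40 × 40 grid with a proportionally smaller ellipsoid for the 200-cohort
type-I suite. Metric-level oracle checks use random masks up to 15³ voxels
against exhaustive brute force at $10^{-9}$. The distance transform is exact
(not an approximation) at any scale; grid coarseness affects only the
generator's realism, not the metric definitions.

Ties in `quantile` percentiles, rank ties in Spearman and Wilcoxon, and the
p ∈ (0, 1] cap are all inherited from the standard conventions of R's
`stats` primitives, which the package calls wherever one exists
(`t.test`, `cor.test`, `shapiro.test`); the Wilcoxon z is computed
in-package only because `wilcox.test` does not expose it, and is tested
against `wilcox.test`'s p-values exactly.

## Known limitations

* No DICOM RT-STRUCT parsing, registration or resampling: masks must arrive
  on a shared grid (NIfTI, axis-aligned).
* Mesh-based sub-voxel surface distances are not implemented; on 5 mm
  slices the voxel-centre convention can differ from mesh-based tools by
  a fraction of the slice thickness.
* The normality gate and the ceiling rule are documented operationalisations
  of reporting conventions that published studies leave unspecified.
* The generator's realism boundary is described above; its defaults are
  calibrated to volume and Dice scales only.
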
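# contoureval

Quantitative evaluation of radiotherapy target-volume delineation, for
studies that score observer contours against an expert reference — typically
pre/post a structured training intervention. The package is aimed at
radiation-oncology and medical-image-analysis researchers who have 3D binary
masks (NIfTI) on a shared planning grid and need the standard metric
battery, cohort statistics and reporting tables, plus a fully synthetic
cohort generator for method development when study data cannot be shared.

## What it computes

For a test contour *A* and reference *B* on a shared anisotropic voxel grid:

| metric | definition | direction |
|---|---|---|
| DSC | 2\|A∩B\| / (\|A\|+\|B\|) | higher better |
| CI (Jaccard) | \|A∩B\| / \|A∪B\| = DSC/(2−DSC) | higher better |
| Inclusion | \|A∩B\| / \|B\| | higher better |
| RVD | (V_A − V_B)/V_B (signed) | smaller better |
| ASD | mean of pooled bidirectional nearest-surface distances (mm) | smaller better |
| 95%HD | max of the two directed 95th-percentile surface distances (mm) | smaller better |
| DC | distance between centres of mass (mm) | smaller better |
| Volume | foreground volume (cm³) | — |

Surface distances use voxel centres and an exact anisotropic Euclidean
distance transform (C++). On top of the per-contour metrics the package
provides:

* interobserver variability: SD, CV and max/min volume ratio (`iov_summary()`);
* paired pre/post comparisons with a Shapiro–Wilk gate between the paired
  t-test and the Wilcoxon signed-rank test, and matched effect sizes
  r = |Z|/√n, d = |t|/√n (`paired_compare()`, `effect_size_r()`, `effect_size_d()`);
* QC exclusion rules (missing phase, identical pre/post submission,
  questionnaire ceiling, invalid masks) with a machine-readable log
  (`qc_filter()`);
* directionally adjusted Spearman correlations between 5-point Likert
  self-assessment and objective metrics, in pre/post/delta modes
  (`correlation_matrix()`, `plot_correlation_heatmap()`);
* a synthetic cohort generator (ellipsoid reference + translation, growth
  and radial-jitter perturbations + Likert responses with a training shift)
  (`simulate_cohort()`);
* a deterministic end-to-end pipeline writing tidy CSV reports
  (`run_pipeline()`), with a thin CLI at `inst/cli/contoureval.R`
  (`simulate`, `evaluate`, `compare`, `correlate`, `run` subcommands).

See the methods vignette (`vignettes/contour-evaluation-methods.Rmd`) for
conventions, design choices and the generator's realism boundary.

## Worked example

Simulate a 19-observer training cohort on a demonstration grid, run the
whole pipeline and print the journal-style comparison table:

```r
library(contoureval)

spec <- cohort_spec(n_observers = 19,
                    grid = grid_spec(dim = c(30, 60, 60),
                                     spacing = c(5, 2.5, 2.5)))
res <- run_pipeline(run_config(simulation = spec, seed = 42,
                               out_dir = "demo-out"))
summarize_table(res$comparisons)
```

which prints (among the eight metrics):

```
     metric                            pre                           post  statistic      p    effect
        dsc        0.81 ± 0.03 (0.75–0.86)        0.85 ± 0.01 (0.83–0.88) t = -5.020 0.000* d = 1.152
     asd_mm        5.86 ± 0.91 (4.56–8.03)        4.73 ± 0.51 (3.68–5.52)  t = 4.588 0.000* d = 1.053
 volume_cm3 669.02 ± 68.91 (548.50–813.03) 646.30 ± 57.99 (536.31–761.12)  t = 1.804  0.088 d = 0.414
```

Read: mean Dice improves from 0.81 to 0.85 (paired t, p < 0.001, large
effect), average surface distance drops by ~1.1 mm, and the volume means do
not differ significantly while their spread tightens — the signature of a
training effect. The IOV table from the same run:

```
 phase  n mean_volume       sd         cv      mvr
   pre 19    669.0230 68.91389 0.10300676 1.482281
  post 19    646.3026 57.99136 0.08972787 1.419182
```

Scoring a single contour pair directly:

```r
ref <- make_reference_mask()   # ~654 cm^3 ellipsoid, 5 mm slices
obs <- perturb_mask(ref, perturbation_spec(translation_sd = 3,
                                           growth_sd = 1.9,
                                           surface_noise_sd = 12, seed = 7))
metric_set(obs, ref)
#> <metric_set> dsc 0.832 | ci 0.712 | inclusion 0.822 | rvd -0.024 |
#>              asd 5.22 mm | dc 8.62 mm | hd95 15.00 mm | volume 638.79 cm^3
```

Real study data enter the same pipeline through a manifest CSV
(`observer_id, case_id, phase, structure, mask_path`) plus reference NIfTI
mask(s), and optionally a Likert CSV (`observer_id, item_id, pre, post`);
see `?run_config`.

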
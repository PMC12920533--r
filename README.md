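# lvflow

Quantifying left-ventricular rotational flow from 4D flow MRI, and tracking
its change over post-infarction follow-up.

## What this is for

After myocardial infarction the left ventricle remodels — the infarcted wall
thins, volumes rise — and diastolic filling reorganises. 4D flow MRI yields a
velocity vector per voxel per cardiac phase, from which two rotational-flow
markers are computable: voxel-wise **vorticity** `ω = ∇ × v` (local spin
rate, 1/s) and coherent vortex cores from the **Lambda2 criterion** — λ₂ is
the middle eigenvalue of `S² + Ω²` (S, Ω the symmetric/antisymmetric parts of
the velocity gradient); λ₂ < 0 marks cores while excluding irrotational
shear. During diastole the LV shows a mitral-valve vortex ring and a helical
**vertical vortex core (VVC)**; the angle between the VVC centerline and the
anatomical centerline (basal-to-apical centroid line) is a candidate marker
of inflow reorientation during remodeling.

`lvflow` is aimed at cardiac-flow researchers. It implements:

* velocity preprocessing: VENC anti-aliasing, noise masking, first-order
  eddy-current correction, PC-MRA;
* vorticity and λ₂ on masked voxel grids (shared finite-difference stencils),
  vortex-component extraction (relative λ₂ threshold, 26-connectivity),
  MV-ring/VVC classification, VVC centerline fit and angle/orientation;
* AHA-analogous 16-segment blood-pool regions with infarct (>25% LGE) /
  adjacent / remote classes, regional vorticity over the diastolic window,
  LGE extent and ECV;
* basal-plane flow-rate curves and E/A peak-flow ratios;
* longitudinal statistics: Theil–Sen slopes
  `median{(y_j − y_i)/(t_j − t_i)}`, 1,000-resample residual-bootstrap 95%
  CIs, directional-trend classification, Pearson/Spearman correlations;
* a synthetic LV phantom (half-spheroid pool, biphasic transmitral jet,
  tilted Lamb–Oseen vortex tube, basal vortex ring, seeded noise) with known
  ground truth, so the whole chain is testable without scanner data.

The packaged longitudinal tables of a two-animal porcine infarction study
(LGE, T1/T2, ECV, global function, strain, VVC angle, E/A, regional
vorticity across ten MRI sessions) drive the statistics stage.

## Worked example

```r
library(lvflow)
library(dplyr)

# Trend of infarct LGE extent in pig 2 over follow-up
tbl <- load_study_measurements()
lge <- tbl %>% filter(pig == "pig2", variable == "lge_percent", session != "pre")
est <- residual_bootstrap_ci(session_to_weeks(lge$session), lge$value,
                             n_boot = 1000, seed = 1)
est
#> <trend_estimate> slope -1.177 /week (95% CI -1.836 to -0.488), n=9, predominantly_unidirectional

# Infarct size vs apical infarct-region vorticity (same sessions)
vort <- tbl %>% filter(pig == "pig2", variable == "vorticity_apical_s1",
                       region == "infarct", session != "pre")
correlate_series(lge$value, vort$value, method = "spearman")$estimate
#> [1] 0.85

# A synthetic session with a 20-degree helical vortex core, analysed end to end
ph <- make_lv_phantom(phantom_config(seed = 7),
                      phantom_truth(vvc_polar_deg = 20, vvc_azimuth_deg = 90,
                                    ea_ratio_true = 2))
res <- analyze_session(ph$field, ph$magnitude, ph$mask)
round(res$metrics[, c("angle_deg", "orientation_azimuth_deg", "ea_ratio")], 2)
#> # A tibble: 1 × 3
#>   angle_deg orientation_azimuth_deg ea_ratio
#>       <dbl>                   <dbl>    <dbl>
#> 1      18.9                    84.8     1.98
```

The LGE extent of the infarcted region falls by about 1.2 percentage points
per week with a CI entirely below zero (a predominantly unidirectional
decline), and correlates strongly (ρ = 0.85) with apical infarct-region
vorticity. On the phantom, the pipeline recovers the embedded 20° tilt at
90° azimuth to within ~1° and 5°, and the prescribed E/A of 2.0 to within
0.02 — the kind of ground-truth recovery the in vivo measurement chain rests
on.

## Analysis workflow

Numbered drivers under `analysis/` reproduce the package's validation and
study-level results, writing tables under `results/`:

1. `01_phantom_validation.R` — analytic identities (solid-body rotation,
   pure shear) on a 64³×25 grid;
2. `02_angle_recovery.R` — VVC angle recovery across tilts 0–30° and seeds;
3. `03_inflow_recovery.R` — E/A recovery for prescribed ratios 0.5–2.0;
4. `04_longitudinal_trends.R` — Theil–Sen slopes, bootstrap CIs and
   classifications for every packaged series, plus the LGE–vorticity
   correlations;
5. `05_phantom_study.R` — a ten-session synthetic study with a rising VVC
   tilt, run end to end through `run_study()`/`export_report()`.

Run any of them from the repository root with `Rscript analysis/<file>`.

## Vignette

`vignettes/lv-rotational-flow-methods.Rmd` documents the models and their
assumptions, every tunable parameter with its default and rationale, what
the phantom does and does not emulate, numerical choices, and known
limitations (including the small-sample undercoverage of residual-bootstrap
CIs).
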
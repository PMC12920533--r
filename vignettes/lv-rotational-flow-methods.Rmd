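---
title: "Quantifying intracardiac rotational flow and its longitudinal change"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying intracardiac rotational flow and its longitudinal change}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lvflow)
```

## The problem

After a myocardial infarction the left ventricle (LV) remodels: the infarcted
wall thins, the chamber dilates, and diastolic filling reorganises. 4D flow
MRI measures a full velocity vector in every voxel of the chamber at every
cardiac phase, which makes two rotational-flow markers computable
non-invasively: the voxel-wise **vorticity** (the curl of the velocity field,
the local spin rate of blood in 1/s) and coherent **vortex cores** identified
by the Lambda2 criterion. During diastole two cores dominate: a toroidal ring
shed at the mitral valve (MV vortex ring), and an elongated helical core along
the long axis formed by helical filling flow — the *vertical vortex core*
(VVC). The angle between the VVC centerline and the anatomical centerline of
the chamber is a candidate marker of inflow reorientation during remodeling;
`lvflow` implements the full measurement chain for it, together with regional
vorticity averaging, transmitral E/A inflow metrics, tissue metrics (LGE
extent, ECV) and the longitudinal trend statistics used to summarise change
over follow-up.

Because in vivo velocity data cannot ship with a package, every stage is
driven and validated by a synthetic LV phantom with known ground truth.

## Models and procedures

### Velocity preprocessing

Measured phase-contrast velocities carry three standard artefacts, each with
its own correction:

* **Aliasing.** Velocities beyond the encoding limit VENC wrap by multiples
  of 2·VENC. `unwrap_velocity()` compares every voxel with the median of its
  spatial 6-neighbourhood and adds the multiple of 2·VENC that minimises the
  difference. A single spatial pass resolves isolated single wraps — the
  regime relevant at VENC = 150 cm/s in the LV, where only noise spikes near
  the limit alias. Contiguous wrapped regions (true velocities far beyond
  VENC) are out of scope; they would need temporal or region-growing
  unwrapping.
* **Eddy currents** add a slowly varying spatial offset.
  `correct_eddy_currents()` fits a first-order polynomial in (x, y, z) to the
  velocities of static tissue — voxels at or above the 50th magnitude
  percentile whose temporal velocity SD is in the lowest decile (both
  configurable) — per phase and component, and subtracts it everywhere. With
  fewer than 100 static voxels the correction is skipped with a warning
  rather than extrapolated from an unstable fit.
* **Noise masking** zeroes velocities where the time-averaged magnitude falls
  below a fraction (default 0.1) of its maximum; such voxels carry no
  reliable phase.

PC-MRA is computed as the phase-average of magnitude times speed — a linear
form that is easy to verify and gives the same fluid/non-fluid contrast as
the root-sum-of-squares variant.

### Differential operators

Vorticity and the velocity-gradient tensor J share one set of difference
stencils: central differences on interior in-mask voxels, one-sided at mask
borders, with voxels lacking any valid neighbour pair excluded from the valid
mask. Velocities in cm/s over an mm grid give gradients in 1/s after a factor
of 10. Lambda2 is the middle eigenvalue (ascending) of S² + Ω², with
S = (J + Jᵀ)/2 and Ω = (J − Jᵀ)/2; negative values mark pressure-minimum
vortex cores while irrotational shear gives exactly zero. Eigenvalues come
from a vectorised closed-form (trigonometric) solver for symmetric 3×3
matrices; it is exact for the analytic validation fields and agrees with
`eigen()` to about 1e-7 relative on random fields — the double eigenvalue of
a pure rotation is its least accurate case, at about 1e-8 relative.

Two analytic fields anchor the operators: solid-body rotation (vorticity
exactly 2ω, Lambda2 exactly −ω², since central differences are exact on
linear fields) and planar pure shear (vorticity γ but S² + Ω² ≡ 0, so any
detected core is a defect).

### Vortex extraction and the VVC angle

Voxels with Lambda2 below a threshold are labeled by 26-connectivity
(26 rather than 6 so that thin tilted tubes do not fragment at 2 mm
resolution). The threshold is relative — a fraction (default 0.1) of the most
negative in-mask Lambda2 at the phase — making it scale-free across
acquisitions; components below 20 voxels are discarded. The VVC is the
largest component whose principal axis lies within 45° of the anatomical
direction and whose voxels cross the mid-plane; the MV ring is a component
centred within 1.5 slice-thicknesses of the basal plane with its principal
axis at least 45° off the long axis (a torus's leading axis lies in-plane).
All four thresholds are configurable defaults standing in for an
identification that is done visually in clinical practice.

The VVC centerline is fit by |Lambda2|-weighted per-slice centroids followed
by a total-least-squares (principal-component) line, oriented base to apex.
The anatomical centerline joins the in-mask centroids of the basal and apical
slices — a reference insensitive to mid-ventricular wall deformation. The
angle is arccos of the absolute dot product of the two unit directions; the
orientation azimuth locates the VVC's mid-plane crossing relative to the
anatomical line's crossing, counterclockwise from a configurable reference
azimuth (+x by default). For radial plots the angle is capped at π/6.
Assessment uses the E-wave peak phase when a VVC exists there, otherwise the
earliest later diastolic phase with one; if none exists the session reports
the angle as missing rather than guessing.

### Regional averaging and tissue metrics

The blood pool is divided analogously to the AHA 16-segment myocardial
scheme: thirds of the occupied long-axis extent form basal/mid/apical slabs;
the basal and mid slabs are split into 6 azimuthal sectors, the apical slab
into 4, counted counterclockwise from the reference azimuth about each slab's
centroid. A segment is *infarct* when its LGE extent strictly exceeds 25%,
*adjacent* when graph-adjacent to an infarcted segment (shared sector border
in a ring, the aligned sector one level away, or an overlapping mid/apical
sector), *remote* otherwise. Vorticity magnitude is averaged per (slab,
region class) over the diastolic window — phases 13–25 of 25, scaled
proportionally for other phase counts. LGE extent is enhanced over total
myocardial volume in percent; ECV follows the standard two-compartment
formula `100·(1−Hct)·ΔR1_myo/ΔR1_blood`, invariant to T1 units.

### Inflow metrics

The flow-rate curve sums the through-plane velocity component times voxel
face area over the in-mask basal plane (cm/s × cm² = mL/s, positive base to
apex). E and A peaks are the maxima of the early and late parts of the
diastolic window; the split defaults to the curve minimum strictly between
the two largest local maxima, falling back to phase 19 of 25 when the curve
has fewer than two local maxima. E/A is a ratio of peak *flow rates*, not
velocities.

### Trend statistics

Longitudinal change per series is summarised by the Theil–Sen estimator —
the median of all pairwise slopes over distinct times, with an even count
taking the mean of the two central order statistics — and its uncertainty by
a residual bootstrap: residuals from the fitted line are resampled with
replacement, added back to the fitted trajectory, and the slope re-estimated
1,000 times; the 95% CI is the 2.5th/97.5th percentile pair. A trend is
*predominantly unidirectional* when at least 90% of the bootstrap slopes
share the sign of the point estimate — a concrete operationalisation of "the
CI lies predominantly on one side of zero, possibly marginally crossing it".
Cross-sectional correlations use Pearson when both variables pass a
Shapiro–Wilk check at α = 0.05 and Spearman (average ranks) otherwise.

Sessions map to weeks post-infarction as post = 0, 72 h = 3/7, and
1W…11W = 1…11. The baseline (pre) session has no defined position on this
scale and is excluded from trends by default; a `pre_week` can be supplied.
Slopes of series that include a baseline value therefore reproduce published
per-week rates only approximately, while baseline-free series (such as LGE
extent) reproduce them at table precision.

## The phantom: what it emulates and what it does not

`make_lv_phantom()` emulates a 2.0 mm isotropic, 25-phase acquisition at
VENC 150 cm/s (all configurable). The blood pool is a half prolate spheroid
(long axis z, base at low z; short semi-axis 55% of the half-width, long
semi-axis 80% of the grid depth — roughly 110 mL at the default 96 mm grid,
a plausible porcine LV). The velocity field superposes:

* a transmitral jet through a basal disc (radius 8 mm, basal 35% of the long
  axis), uniform in space with a biphasic waveform: Gaussians in phase index
  centred at phases 15 (E) and 23 (A) of 25 with width 1.5 phases, amplitudes
  set so the peak-flow ratio equals the prescribed E/A (A-peak 30 cm/s);
* a Lamb–Oseen vortex tube (circulation 0.015 m²/s, core radius 6 mm)
  through the cavity centre at the prescribed polar angle and azimuth — the
  VVC analogue, with strictly negative Lambda2 in its core. The generator
  refuses tilts whose axis leaves the cavity before spanning the basal-to-
  apical thirds;
* a thin-core ring (circulation 0.008 m²/s, core 3 mm) at the basal plane,
  62% of the local cavity radius — the MV-ring analogue, oriented to pump
  base-to-apex;
* Gaussian measurement noise (SD 1 cm/s) inside the pool, from one seeded
  generator per call.

The rotational structures share the inflow waveform as a common envelope, so
the net basal-plane flux stays proportional to the waveform and the E/A ratio
of the flow curve equals the prescribed ratio by construction. Optional VENC
wrap simulation maps v to ((v + VENC) mod 2·VENC) − VENC.

The phantom does **not** emulate moving walls or a phase-dependent mask,
turbulence, MR acquisition physics (k-space, partial volume, phase noise
correlated with magnitude), or myocardial tissue contrast. Passing phantom
tests therefore demonstrates the correctness of the measurement chain —
operators, extraction, classification, geometry, statistics — not robustness
to segmentation error or acquisition artefacts in vivo.

## Numerical choices and degenerate inputs

* Analysis planes sit at fractions 0.25/0.50/0.75 of the occupied long-axis
  extent (rounded to the nearest slice); fewer than 4 occupied slices is an
  error.
* The closed-form eigenvalue solver clamps its acos argument to [−1, 1] and
  returns the trace/3 for near-zero deviatoric part.
* Even-count medians always average the two central order statistics (this
  is what reproduces the published LGE slope of −1.2 %/week for pig 2).
* Bootstrap resampling is fully determined by an integer seed; identical
  seeds give identical CIs, and study runs export byte-identical CSVs.
* A session in which no VVC qualifies at any diastolic phase reports the
  angle as missing; a study run records a failed session as one missing row
  and continues.

## Validation summary and known limitations

The analysis drivers under `analysis/` exercise the chain at the sizes used
throughout: a 64³ × 25 grid for the analytic identities; 20 phantoms (48³)
across tilts 0–30° for angle recovery, which lands well inside a 3° mean
absolute error with a mild attenuation bias growing with tilt (about −1.5° at
30°, from voxelising a 6 mm core at 2 mm); nine 32³ phantoms for E/A recovery
(maximum error ~0.014 against prescribed ratios 0.5–2.0); and the packaged
longitudinal tables for the statistics stage.

One property deserves an explicit caveat: the nominal 95% residual-bootstrap
CI undercovers at small n. At n = 10 time points with unit Gaussian noise the
empirical coverage over 500 replicates is about 84–87% — and an independent
`scipy.stats.theilslopes` + NumPy re-implementation gives the same — because
residuals of a fitted robust line underestimate the noise scale and the
percentile interval inherits that. No small-sample correction is applied
because none is part of the published procedure; CIs on 9–10 session series
should be read as mildly optimistic.

The blood-pool segment scheme anchors its first sector at a configurable
reference azimuth standing in for the anterior insertion point, and
"adjacency" is graph adjacency on the 16 segments; both are conventions the
underlying imaging literature leaves open, and regional averages are only
comparable across sessions analysed with the same convention.
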
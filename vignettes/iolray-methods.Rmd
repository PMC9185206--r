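---
title: "Optical models and statistics behind iolray"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Optical models and statistics behind iolray}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iolray)
```

`iolray` implements the two families of intraocular-lens (IOL) power
calculation that formula-accuracy studies compare — classic thin-lens
vergence formulas and exact ray tracing of the pseudophakic eye — together
with the statistical pipeline such studies use to compare them, and a
calibrated synthetic biometry cohort that makes the whole chain testable
without patient data. This vignette explains the models, the assumptions,
the tunable parameters and the deliberate design choices.

## The thin-lens vergence chain

All four classic formulas (SRK/T, Hoffer Q, Holladay 1, Haigis) share one
optical skeleton: a Gullstrand-style reduced eye in which the cornea and
the IOL are thin lenses in an aqueous medium of index 1.336, and Gaussian
(paraxial) vergence is propagated from a distant object through the cornea,
translated to the effective lens plane (ELP), augmented by the IOL power,
and required to land on the retina. `predict_refraction_vergence()` is this
chain; each formula contributes only

* its **corneal power convention** — the measured keratometry is converted
  back to a radius with the 1.3375 keratometric index (`r = 337.5/K`) and
  re-expressed with the formula's own corneal index: 1.333 (SRK/T), 4/3
  (Holladay 1), 1.3375 (Hoffer Q), 1.3315 (Haigis);
* its **optical axial length** — SRK/T adds its retinal-thickness term
  (`0.65696 − 0.02029·AL`), Holladay 1 adds 0.2 mm, the others use AL as
  measured; and
* its **ELP model** — corneal height plus an A-constant offset (SRK/T),
  corneal height plus surgeon factor (Holladay 1), the tangent-term
  personalized ACD (Hoffer Q), or the linear `a0 + a1·ACD + a2·AL`
  (Haigis).

Each formula is implemented from its original publication, including the
published clamps: the SRK/T corneal-height radicand is clamped at zero (a
warning is emitted), Hoffer Q clamps the axial length into [18.5, 31] mm
inside its ACD model, and Holladay 1 floors the corneal radius at 7 mm.
The predicted refraction is reported as a spherical equivalent at the
spectacle plane with a 12 mm vertex distance, the convention of the
original publications. The mean of the two keratometry readings carries
the astigmatic information into the SE (sphere + cylinder/2 is equivalent
to averaging the two meridians at this level of approximation).

Chosen powers live on a 0.5 D grid; an exact midpoint tie resolves to the
**higher** power, the common clinical preference for leaving the patient
slightly myopic rather than hyperopic. The implanted-power selection rule
of the simulated study is axial-length based (`select_formula_by_al()`):
Hoffer Q below 22 mm, Holladay 1 from 22 to 26 mm, SRK/T above 26 mm.

## Effective lens position for ray tracing

The raytracer predicts the postoperative IOL centre position from two
formulas and averages them when both inputs exist (`predict_iol_position()`,
mode `"mean"`):

1. an **AL-scaled** predictor,
   `A = C_m (AL/23.6)^0.7 + A_m − C_m − 0.5 (d − d_m)`, which rescales the
   4.6 mm reference depth (`C_m`) of a 21 D reference lens in a mean-sized
   eye and corrects for the thickness difference between the lens of
   interest (`d`) and the reference lens (`d_m`); `A_m`, the model's
   mean-eye depth, is a per-model constant stored in the IOL database
   (`am_mm`); and
2. an **ACD + lens thickness** predictor,
   `A = ACD + 0.574·LT − 0.632 − 0.5·d`.

Both are interpreted as posterior-cornea-to-IOL-centre distances; the
anterior-vertex position follows exactly as `A − d/2`. The constants
(`C_m` = 4.6 mm, mean AL 23.6 mm, exponent 0.7) are configuration defaults
and can be overridden. The preoperative ACD reported by optical biometers
is referenced to the corneal epithelium; `predict_iol_position()` subtracts
the corneal thickness (`cct/1000`) internally because the predictors are
posterior-cornea referenced. Whether the source device includes the cornea
in its ACD is genuinely ambiguous in the field; the subtraction is this
package's documented choice and changes the predicted ELP by roughly half a
millimetre — which is why the mean-eye constants (`am_mm`) are defined on
the same convention.

## Exact ray tracing

`build_pseudophakic_eye()` assembles a four-surface meridional model:
anterior cornea at `z = 0` with radius `337.5/K` per principal meridian,
posterior cornea at the corneal thickness with the fixed Gullstrand radius
ratio 0.883 (index 1.376 inside the cornea, 1.336 in aqueous and vitreous),
then the IOL's two conic surfaces from the database geometry, and the
retina at the axial length. Rays are traced by solving the exact
ray-conic intersection (a stable quadratic in the conic implicit form) and
applying vector Snell's law, so spherical aberration and pupil dependence
are fully represented; `n·sin(theta)` is conserved to machine precision at
every interface and tracing is reversible (both are asserted in the test
suite at 1e-12 / 1e-9 tolerances on ten thousand random rays). Keratometry
supplies curvature only, so the corneal conic constant defaults to zero
(spherical); it is exposed in `raytrace_config()` for sensitivity analyses.

**Best focus.** The refraction of a finite-pupil eye is criterion
dependent. The default follows the ISO 11979-2 idea of a representative
zonal ray: for each principal meridian the reference ray crosses the pupil
plane at `pupil_radius/sqrt(2)` — the zonal height whose encircled area
halves the 2.5 mm default pupil — and the meridian's refraction is the
spectacle-plane power (12 mm vertex) that makes exactly that ray cross the
optical axis at the retina; the spherical equivalent is the mean over the
two meridians. Rather than iterating a bracketed search over spectacle
powers, the implementation launches the reference ray **backward** from the
retinal point through the pupil at the ISO height: by reversibility of
refraction the emerging ray is the corrected ray path, and the spectacle
power follows in closed form from its height and slope at the spectacle
plane. This is mathematically the same root a bisection on spectacle power
would find, but costs a single trace (plus a tiny secant solve for the
launch slope) and is exact to machine precision, which keeps the
5,000-eye known-truth simulation in the test suite fast. An optional
multi-ray mode (`mode = "rms_multiray"`) instead minimizes the
Stiles-Crawford-weighted RMS retinal spot of a ray fan
(`w = 10^(-0.116 y^2)`, the photometric apodization convention); it is a
coarser criterion kept behind a config flag and is not used by the
defaults.

IOL geometry between labeled powers is interpolated linearly in surface
curvature (not radius), because curvature is what scales near-linearly
with labeled power; thickness, index and asphericity interpolate linearly.
A curvature crossing zero inside an interpolation interval yields an
optically plano surface with a very large (1e5 mm) radius rather than a
division by zero.

## The statistics

Prediction error is **predicted minus actual** spherical equivalent.
The opposite sign convention also circulates in the IOL literature; the
choice here follows the definition's word order ("the refraction predicted
… and the actual postoperative refraction") and is applied consistently,
so a positive mean PE means formulas predicting more hyperopia than
observed. Absolute-error summaries use the sample SD (n−1), inclusive
thresholds (`ae <= t`), and the five axial-length bins `<22, [22,24),
[24,26), [26,30), >=30` mm — half-open on the left-closed boundaries, so
24.0 mm falls in 24-26.

* `compare_mae_mixed()` fits `ae ~ formula + (1 | patient)` by REML
  (lme4/lmerTest) with Satterthwaite degrees of freedom and reports **all**
  pairwise contrasts with Bonferroni adjustment over the full family
  `C(k,2)` (a reference-versus-others table is a filtered view, not a
  smaller family). With one eye per patient and two formulas this reduces
  exactly to the paired t-test, which the tests assert.
* `levene_heterogeneity()` is the classic mean-centred Levene test (a
  one-way ANOVA on absolute deviations from group means), chosen over the
  Brown-Forsythe median variant because the study names Levene.
* `gee_threshold_comparison()` models the within-threshold indicator with
  a logit link and an exchangeable working correlation clustered on
  patient, with Liang-Zeger moment estimators and robust sandwich
  covariance (implemented in the package), run separately at 0.25, 0.50
  and 1.00 D. With singleton clusters it reproduces the independence
  logistic model, asserted against `glm` + `sandwich::vcovCL` in the
  tests. Completely separated formulas (all eyes inside or outside a
  threshold) keep their reported proportions, and their contrasts are
  flagged undefined rather than extrapolated.

## The synthetic cohort

`generate_biometry()` draws axial length from a two-component mixture of
truncated normals on [19, 35] mm — a dominant narrow component
(N(23.43, 0.69)) and a broad minor component (N(21.75, 5.09)) with weights
0.678/0.322 — calibrated by least squares against the study population's
printed moments and bin frequencies (mean 23.66 mm, SD 2.07; 11.7 / 59.6 /
19.7 / 6.9 / 2.1 % across the five bins). The calibration was done once,
analytically, against those targets; at n = 20,000 the sampled moments and
bins reproduce them within sampling error, which is the module's acceptance
surface. The remaining biometry is physiologic and AL-correlated: ACD
rises and lens thickness falls with AL (`ACD = 1.10 + 0.098·AL ± 0.22`,
`LT = 7.15 − 0.115·AL ± 0.20`), mean keratometry declines mildly with AL
(slope −0.21 D/mm, SD 1.35 D) with a half-normal corneal cylinder (scale
0.75 D), CCT is N(540, 32) um. No covariances are published for the study
population, so these slopes are documented, overridable package constants
at textbook physiologic values. About 8/180 of patients contribute both
eyes, the study's bilateral share; fellow eyes share patient-level random
effects.

`simulate_surgery()` implants the AL-rule formula's chosen power at a
0.00 D target and computes the **true** refraction with the package's own
ray tracer at a true ELP perturbed by N(0, 0.25 mm); the recorded
refraction adds N(0, 0.35 D) measurement noise rounded to clinical 0.25 D
steps (rounding is configurable and disabled in analytic tests; the
defaults are realistic subjective-refraction repeatability and healing
variability). Half of each noise variance is a patient-shared component,
which induces the positive fellow-eye correlation the mixed model and GEE
are there to absorb. Because the truth model *is* the package's ray
tracer, the ray-tracing method's superiority inside the simulation is a
construction artifact: the simulation validates the analysis machinery
(error propagation, summaries, contrasts, subgroup behaviour), never the
clinical ranking of methods, and no test asserts cross-formula clinical
claims.

Problem sizes used by the shipped tests were chosen to keep the suite
quick while leaving the statistical assertions well-powered: 20,000 eyes
for the distribution calibration, 5,000 for known-truth noise recovery
(tolerances at 3 standard errors of the analytic half-normal values),
200 for the end-to-end reproducibility run.

## Worked example

```{r example, eval = FALSE}
library(iolray)
db <- synthetic_iol_database()
cfg <- cohort_config(n = 200, seed = 606)
report <- run_study_pipeline(cfg, db)
report
```

## Known limitations

* Meridional (2-D) tracing of the two principal meridians supports
  spherical-equivalent predictions; full 3-D skew tracing, decentration,
  tilt and chromatic dispersion are out of scope.
* The cornea is a keratometry-derived conic with a fixed
  posterior/anterior ratio — no topography ingestion, and post-refractive
  corneas are not modelled.
* Thin-lens constants are used as supplied; constant optimization (zeroing
  the mean PE) is deliberately not performed.
* The synthetic cohort matches the study's AL distribution and plausible
  physiology, but its covariances are assumptions; passing tests show the
  machinery is correct under those conditions, not that any formula is
  clinically superior.
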
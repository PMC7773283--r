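---
title: "Quantifying intrathecal CSF geometry and hydrodynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying intrathecal CSF geometry and hydrodynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csfdyn)
```

## The problem

Cerebrospinal fluid (CSF) in the spinal subarachnoid space (SAS) — the
annular, fluid-filled region between the spinal cord and the dura —
oscillates with every heartbeat: caudally during systole, cranially
during diastole. The amplitude and spatial structure of this pulsation
govern how intrathecally delivered drugs spread along the neuraxis. An
indwelling intrathecal catheter partially obstructs the SAS, raising
its hydraulic resistance and damping CSF pulsations, and the size of
that effect depends on how much of the spine the catheter traverses.

`csfdyn` implements the quantitative pipeline used to characterize this
situation in preclinical (non-human primate) imaging studies: axial
geometric profiles from anatomical segmentations, cardiac-gated flow
waveforms from phase-contrast MRI, dimensionless-number
characterization of the flow regime, a Hagen–Poiseuille prediction of
the catheter's flow reduction, and a mixed-effects statistical battery
comparing implantation groups and scan timepoints. A synthetic-cohort
generator reproduces the structure of such a study so the entire
pipeline can be exercised, and its estimators validated against known
ground truth, without any external data.

## Conventions and fluid properties

The axial coordinate `z` is measured in millimetres from the foramen
magnum (FM), increasing caudally; the grid ends at the thecal-sac
termination, so `L_sas = max(z)`. Caudally directed flow is negative.
Internally all computation uses mm, s and mm²/s, which makes every
dimensionless number unit-consistent without hidden factors.

CSF kinematic viscosity defaults to `nu = 0.693` mm²/s, the
body-temperature value for CSF (numerically equal to a dynamic
viscosity of 0.693 mPa·s at a CSF density of ~1 g/mL; sources
sometimes quote the number with the dynamic-viscosity unit, and with
unit density the two coincide). The reference cardiac period defaults
to `T_ref = 0.53` s, giving angular frequency `omega = 2*pi/T_ref`.
Both are configurable through `fluid_properties()`.

## Geometry

Per-position cord and dura cross-sections give the derived SAS
quantities

$$A_{sas}(z) = A_d(z) - A_c(z) - A_{cath}(z), \qquad
  P_{sas}(z) = P_c(z) + P_d(z) + P_{cath}(z), \qquad
  D_h(z) = \frac{4\,A_{sas}(z)}{P_{sas}(z)},$$

where the catheter footprint — $A_{cath} = (\pi/4)\,OD^2$ occluded
area and $P_{cath} = \pi\,OD$ added wetted perimeter — is assigned by
walking the catheter's segment table caudally from the tip
(`catheter_footprint()`). The default segment table is a three-piece
infusion catheter (100 mm of OD 0.99 mm distal to the tip, then
240 mm of OD 1.98 mm, then 15 mm of OD 1.93 mm); the proximal piece
normally lies outside the SAS and then contributes nothing. The
catheter lumen is far too narrow to carry meaningful CSF flow, so the
whole outer cross-section is treated as occluding. Nerve roots are
excluded from all areas and perimeters: they are below typical
anatomical-MRI resolution, and the segmentations these profiles come
from do not contain them.

Volumes and surface areas are trapezoidal axial integrals
($V_x = \int A_x\,dz$ in mL, $SA_x = \int P_x\,dz$ in cm²); the
summary identities $SA_{sas} = SA_c + SA_d$ and $V_{sas} = V_d - V_c$
hold exactly by construction. Axial integration is a surrogate for
integrating the 3-D segmentation itself, which is upstream of this
package. Cross-subject comparison uses `normalize_axial()`: each
profile's coordinate is rescaled by `L_mean / L_sas` and linearly
resampled onto a common grid.

One caveat worth knowing: in published group summaries of this kind of
cohort, the catheter-free SAS perimeter cell can slightly exceed
$P_c + P_d$; the definition implemented here is the methodological one
($P_{sas} = P_c + P_d$ plus catheter perimeter where present), and no
attempt is made to force agreement with such cells.

## Flow processing

Heart rate varies between scans, so each waveform's time axis is
affinely rescaled to the reference period (`normalize_cycle()`).
Only timing is rescaled: flow values are untouched, which preserves
extrema exactly and, deliberately, stroke volume — rescaling `Q` as
well would silently alter the displaced volume.

`fit_spatiotemporal()` smooths the per-level waveforms into a
continuous surface $Q(z, t)$ with a tensor-product penalized spline
(`mgcv`), cubic in `z` and *cyclic* cubic in `t` so the surface is
periodic over the cardiac cycle. The smoothing parameter is chosen by
generalized cross-validation by default; a fixed value or `"none"`
(exact separable interpolation) can be requested. Basis dimensions are
`min(n_levels, 6)` in `z` and `min(n_t, 10)` in `t`; on noiseless
separable test fields the default reconstruction error is well under
1% of the peak.

From the surface: `Q_sys(z)` and `Q_dia(z)` are the global minimum
and maximum over the cycle (systole is the most negative value under
the sign convention), `Q_a = Q_dia - Q_sys`, and stroke volume is
$SV(z) = \int_0^T |Q(z,t)|\,dt$ by the trapezoidal rule with the cycle
closed periodically. No ½ factor is applied to SV: with
`Q_a ≈ 0.36` mL/s and `T = 0.53` s this yields the ~0.06 mL scale
observed in such cohorts, confirming the unhalved definition.

### Pulse wave velocity

The systolic peak propagates caudally; its speed is estimated from the
slope of the peak's arrival time against position: arrival times are
regressed on `z` by ordinary least squares and PWV is the inverse
slope, in m/s, positive for caudal propagation (a constant arrival
profile is flagged as infinite PWV rather than an error). Two
numerical details matter:

* Arrival times are refined by parabolic interpolation around the
  discrete minimum (on the cyclic time grid), removing most of the
  time-quantization error.
* Arrival times are anchored **at the measured levels**, not on the
  densely interpolated grid. Between widely spaced levels the fitted
  surface blends time-shifted pulses, which systematically distorts
  peak timing in the gaps and biases the slope by a few percent;
  at the measured levels the peak is pinned by data. With six levels
  over a 300 mm spine this choice brings noiseless self-recovery of a
  1.15 m/s wave to within 1%. `pulse_wave_velocity(..., at = "grid")`
  restores the dense-grid behaviour if wanted.

## Hydrodynamic characterization

With $\bar U_{sys}(z) = Q_{sys}(z)/A_{sas}(z)$ (reported in cm/s; used
as a magnitude in mm/s internally), `dimensionless_numbers()` computes
Reynolds number $Re = |U| D_h/\nu$, Stokes-layer thickness
$\delta = \sqrt{2\nu/\omega}$ and $Re_\delta = |U|\delta/\nu$,
nerve-root Reynolds number $Re_{NR} = |U| D_{NR}/\nu$, Womersley
number $\alpha = (D_h/2)\sqrt{\omega/\nu}$, Keulegan–Carpenter number
$K = |U| T/D_{NR}$, the velocity-independent
$\beta = Re_{NR}/K = D_{NR}^2/(\nu T)$, and Hall's critical value
$K_{cr} = 5.778\,\beta^{-1/4}(1 + 0.205\,\beta^{-1/4})$ for
Honji-type instability of oscillatory flow around a cylinder.
Magnitudes are used throughout because the instability and transition
thresholds ($Re < 2300$ laminar, $Re_\delta < 550$ no conditional
turbulence, $K < K_{cr}$ no Honji instability) are defined on
magnitudes; signed velocities would produce meaningless negative
Reynolds numbers.

The nerve-root diameter defaults to a constant 0.25 mm, the middle of
the anatomically reported 0.2–0.3 mm range, and accepts an axial
profile. A known inconsistency in the literature for this cohort type
is worth flagging: a reported $\beta = 2.79$ cannot be produced by
$D_{NR}^2/(\nu T)$ with any $D_{NR} \le 0.3$ mm (which caps
$\beta$ at about 0.25), and the printed $K_{cr}$ formula evaluated at
$\beta = 2.79$ gives about 5.2, not the ~22 sometimes quoted alongside
it. `csfdyn` implements the formulas verbatim and therefore does not
reproduce those two scalars; with physiological velocities and a
0.2–0.3 mm root diameter, `K` readily exceeds `K_cr`, so the
Honji-margin flag should be read with that definitional caveat in
mind.

## The Hagen–Poiseuille flow-reduction estimator

Under steady laminar pipe flow at constant driving pressure, flow
scales as $D^4$. Summing the $D_h^{-4}$ resistance proxy along the
spine with and without the catheter footprint gives the predicted
fractional flow reduction

$$\mathrm{reduction} \;=\; 1 - \frac{\sum_z D_h(z)^{-4}}{\sum_z D_{h\text{-}w}(z)^{-4}},$$

implemented exactly as written: equal-weight sums over the uniform
grid, no $\Delta z$ weighting (available behind a flag; identical on a
uniform grid) and no annulus correction to the $D^4$ law. For a
uniform SAS the sums collapse to $1 - (D_{h\text{-}w}/D_h)^4$, which
the tests verify to machine precision, and grid refinement changes the
estimate by well under 0.1% for smooth profiles. Because the catheter
can only shrink $D_h$, the reduction lies in $[0, 1)$ and is monotone
in catheter OD and in-SAS extent — which is why a cervical catheter
(traversing most of the spine) is predicted to reduce flow several
times more than a lumbar one entering near the sac's caudal end.

## The statistical battery

Each parameter's axial distribution is compared between two cells
(two timepoints within a group, or the two groups at one timepoint)
with the linear mixed-effects model

$$y_i = \beta_0 + \beta_1 x_{1i} + \beta_2 x_{1i}^2 + \beta_3 x_{2i}
 + \beta_4 x_{3i} + \beta_5 x_{4i}
 + z_{0i} + z_{1i} x_{1i} + z_{2i} x_{1i}^2 + \varepsilon_i,$$

where $x_1$ is the normalized axial location (rescaled to $[0,1]$ for
conditioning of the quadratic term), $x_2$ the 0/1 comparison
indicator, $x_3$ age, $x_4$ weight, and $(z_0, z_1, z_2)$ per-subject
random intercept/linear/quadratic coefficients with unstructured
3×3 covariance. Estimation is REML via `lme4`; the design matrices are
built by `fit_lme()` exactly as the model reads. Inference on
$\beta_3$ uses a Wald z test — the fitting literature for this design
does not prescribe an inference flavour, and with the row counts
involved (hundreds of observations per fit) the z approximation is
adequate, which the type-I-error calibration test confirms
(empirical size within [0.03, 0.07] at nominal 0.05 with 20
subjects per cell).

Each of the 7 comparisons is refit on its own data subset (matching
the per-pair testing described for this design), rather than pulled as
contrasts from one joint model. The full battery is 13 parameters ×
7 comparisons = 91 tests with Bonferroni threshold
$0.05/91 = 5.49\times 10^{-4}$ and graded stars at
$\{0.05, 0.01, 0.005, 0.001\}/91$. Singular unstructured covariances
trigger a flagged refit with independent random effects; fits that
still fail to converge enter the battery as `NA` with a warning —
never silently dropped. With realistic cohort sizes (4 per group)
singular fits are expected and are part of honest reporting.

## The synthetic cohort

`synthetic_config()` defaults encode the emulated study conditions:

* 4 subjects per implantation group; SAS length 300 ± 15 mm.
* Geometry from smooth natural-spline taper templates scaled to
  cohort-mean targets of 15.4 mm² (cord area), 23.7 mm² (SAS area),
  13.9 / 22.1 mm (cord / dura perimeter) — which puts SAS volume at
  the ~7 mL scale of a cynomolgus monkey — with per-subject lognormal
  size factors (unit mean, `sdlog` 0.06) and perimeters following a
  $\sqrt{A}$ shape. The dura area is built as cord + SAS area, so the
  open-SAS invariant holds by construction.
* Flow measured at six levels (FM to lower lumbar), 32 samples per
  cycle; a two-harmonic pulse (second-harmonic weight 0.35) with its
  systolic peak arriving 0.10 s into the cycle at the FM and
  propagating caudally at 1.15 m/s; amplitude peaking in the cervical
  spine at ~0.4 mL/s and decaying to ~5% at the sac termination;
  heart period 0.53 ± 0.03 s; additive Gaussian flow noise of
  0.005 mL/s and a per-subject lognormal amplitude factor
  (`sdlog` 0.25) reproducing the between-subject spread seen in such
  cohorts.
* Catheters enter at 290 mm with the tip at 55 mm (cervical group) or
  210 mm (lumbar group), scaled to each subject's spine length.
  Post-implantation scans attenuate each subject's flow amplitudes by
  that subject's own Hagen–Poiseuille reduction (uniform along `z` by
  default — spine-wide damping is what such implants produce, and a
  z-modulation hook exists for localized effects) and add fresh
  measurement noise per scan.

The generator records ground truth (lengths, size factors, periods,
amplitudes, arrival times, attenuations) losslessly, and the same seed
and configuration reproduce a cohort byte-for-byte.

What the generator does **not** emulate — and what passing tests
therefore do not establish about real data: respiratory modulation of
CSF flow, localized geometric remodelling around the catheter,
segmentation and velocity-ROI errors (noise here is additive and
well-behaved), vertebral-level anatomy (levels are positions, not
vertebrae), and any coupling between geometry and flow amplitude
beyond the catheter effect.

## Problem sizes and runtime choices

The test-suite and acceptance-script simulations use the default
cohort (8 subjects, ~300-point geometry grids, 6 × 32 flow samples,
19 axial stations in the statistical long table), 200 replicates for
PWV noise calibration and 500 simulated null fits (20 subjects per
cell, 11 stations) for the type-I-error check — sizes at which the
Monte-Carlo error of each check is comfortably below the tolerance it
is compared against, while a full run stays in the minutes range on a
single core.

## Known limitations

* The pipeline starts from segmented profiles and extracted waveforms;
  image segmentation and velocity-ROI extraction are upstream.
* The flow-reduction estimator is a steady laminar resistance
  argument: no unsteadiness, no wall compliance, no pressure-field
  prediction, and it assumes the driving pressure is unchanged by the
  implant.
* MRI-scale velocity fields cannot resolve Stokes boundary layers;
  the dimensionless numbers characterize regime, not resolved
  profiles.
* With 4 subjects per group, mixed-model convergence failures are a
  real possibility; they are flagged and reported, and conclusions
  from such cells should rest on the larger synthetic cohorts the
  generator can produce.
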
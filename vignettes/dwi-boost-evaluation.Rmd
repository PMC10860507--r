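---
title: "DWI-guided boost delineation and plan evaluation: methods"
author: "adcboost"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{DWI-guided boost delineation and plan evaluation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adcboost)
```

## The workflow

`adcboost` implements the evaluation chain for a dose-escalation strategy
in locally advanced rectal cancer: a single-fraction stereotactic-style
boost to an intra-tumoural region of restricted diffusion, delivered
before conventional long-course radiotherapy (50 Gy in 25 fractions).
The chain is:

1. **Delineation** — threshold the apparent diffusion coefficient (ADC)
   map at the 40th percentile of its values inside the gross tumour
   volume (GTV), clean non-contiguous voxels, grow anisotropic margins
   (11 mm anteroposterior, 7 mm transverse, 13 mm craniocaudal) into a
   boost target volume (BTV) clipped to the clinical target volume
   (CTV), and build the EVAL fall-off shell (BTV minus the 1 mm-expanded
   nucleus).
2. **Phase-1 audit** — cumulative DVH metrics and SBRT conformality
   indices for the boost plan, graded optimal / minor / major against
   the boost constraint table.
3. **Combined audit** — organ-at-risk (OAR) metrics of the physically
   summed boost + long-course dose against long-course constraints.
4. **Gamma QA** — 3-D gamma-index comparison of dose distributions at
   2%/2 mm and 3%/3 mm.

Everything runs on a shared regular grid; combining volumes from
different grids is an error, never an implicit resample. Array axes are
held in a fixed anatomical order (craniocaudal, anteroposterior,
transverse) so that margin directions are unambiguous; NIfTI files are
permuted into this order at load time.

## Delineation model and conventions

The subvolume threshold is the `centile`-th percentile of GTV ADC values
with linear interpolation between order statistics (the same convention
as `stats::quantile` type 7). The percentile rule is scale-invariant, so
ADC units only need to be internally consistent. Ties are included
(`ADC <= threshold`), which makes a constant-ADC tumour segment to the
whole GTV rather than to nothing.

"Cleaning of non-contiguous voxels" keeps the single largest
26-connected component. 26-connectivity is chosen because thin,
obliquely oriented low-ADC sheets fragment under 6-connectivity. A size
tie is broken toward the component whose centroid is most caudal
(consistent with boosting the dominant distal disease) and reported via
a message.

Margin growth uses an ellipsoidal structuring element: voxel `v` enters
the expansion iff some source voxel `u` satisfies

$$\left(\frac{\Delta_{ap}}{m_{ap}}\right)^2 +
  \left(\frac{\Delta_{tr}}{m_{tr}}\right)^2 +
  \left(\frac{\Delta_{cc}}{m_{cc}}\right)^2 \le 1,$$

with center-to-center distances in mm. This matches how treatment
planning systems grow margins; a box element would overshoot corners. A
voxel belongs to a structure iff its center is inside — an unambiguous,
testable convention used consistently by `expand_mask`, `shell_beyond`
and all volume metrics. Zero margin on an axis means no growth along
that axis. The implementation is an exact anisotropic Euclidean distance
transform (separable lower-envelope algorithm, compiled); the test suite
proves exact agreement with brute-force Minkowski enumeration on
hundreds of random small grids.

## DVH engine

Cumulative DVHs use fixed 0.005 Gy (0.5 cGy) bins, the resolution at
which clinical systems export curves. `cum_volume_pct(d)` is the percent
of structure voxels with dose `>= d` (closed lower bound, which makes
step-function cases exact). Dx% inverts the curve with linear
interpolation between bracketing edges; D100% returns the exact voxel
minimum. Point metrics (Dmax, D0.03cc, D1cc) are computed from sorted
voxel doses, not the binned curve, so maxima are not quantized by the
binning; a structure smaller than the requested volume falls back to
Dmax with a message. Vx metrics are computed directly from voxels; the
suite checks that the binned curve brackets the voxel value within one
bin for random fields.

## Conformality indices

With `px` the prescription dose, `TV` the target (the BTV for the boost
phase), `PIV` the prescription isodose volume, `TV_PIV` their overlap
and `V50` the half-prescription isodose volume:

* `PDS = PIV / TV` (prescription dose spillage; convention switchable to
  the coverage form `TV_PIV / PIV` because consortium guidelines do not
  print a formula),
* `MGI = V50 / PIV`, `R50 = V50 / TV` — the only pair of definitions
  consistent with published triplets of MGI, R50 and conformity index;
  the identity `MGI * PIV = R50 * TV` is asserted on every plan,
* `RTOG CI = PIV / TV` (the coverage variant `TV_PIV / TV` is also
  reported),
* `Paddick CI = TV_PIV^2 / (TV * PIV)` = coverage x selectivity,
* `NTT = PIV - TV_PIV` (non-target tissue at prescription dose, cc),
* `NTT_2cm` = maximum dose in the body at least 20 mm from the PTV, as a
  percent of `px`. For the boost phase the PTV is the BTV itself.

R50 and NTT_2cm limits depend on PTV volume and are linearly
interpolated — and, outside the tabulated range, linearly extrapolated —
from an editable YAML copy of the RTOG 0813 reference table. The values
belong to an external protocol, so they ship as configuration, not code.
An empty PIV leaves MGI and the Paddick index undefined; they are
returned as `NA` with a flag rather than as infinities.

## Constraint grading

Limits are strict inequalities as printed; equality counts as meeting
the limit on the permissive side. A value meeting the primary limit is
*optimal*; failing it but meeting the acceptable variation is a *minor*
violation; anything else *major*. Constraints without a printed
variation are binary. Percent limits are converted to absolute dose via
the phase prescription before comparison (the boost table references the
boost prescription; bladder `Dmean < 35%` is interpreted against the
boost prescription, the reading consistent with the published
exceedances).

For combined plans the source tables print single OAR limits and grade
violations by clinical judgement. The shipped default makes that rule
explicit: exceedance within 10% of the limit is minor, beyond that
major; the fraction and every per-row boundary are user-overridable in
the YAML. PTV coverage rows (D98%, D2%, Dmean) describe the
conventional-phase targets, so they are measured on the conventional
dose when it is supplied and reported without a violation status; D98%
is reported as a percent of the phase prescription and D2% as the excess
over it.

Cohort summaries use median and interquartile range with interpolated
quartiles, plus minor/major counts — the layout of a clinical planning
study's dosimetry tables.

## Gamma comparison

For each reference voxel at or above the low-dose threshold (default
10% of the normalization), the gamma index is the minimum over nearby
evaluated positions `e` of

$$\gamma(r) = \min_e \sqrt{\frac{(D_r(r) - D_e(e))^2}{(\Delta D)^2} +
  \frac{\lVert r - e \rVert^2}{\delta^2}},$$

with `ΔD` the dose tolerance (percent of the global normalization, or of
the local reference dose behind a flag) and `δ` the distance to
agreement. The evaluated dose is interpolated trilinearly on an offset
lattice refined by a subsample factor (default 3) within a search radius
of 3 x DTA; offsets are visited in order of increasing distance so the
search terminates once the distance term alone exceeds the current
minimum. The pruned search is validated voxelwise against a separate
exhaustive implementation and against a plain-R reference. Normalization
defaults to the prescription dose — the physical measurement chain of a
QA protocol is not reproducible computationally, so a global reference
level is the documented stand-in. The comparison is asymmetric; the
reference is always the planned distribution.

## The synthetic phantom

No imaging or plan data are distributable, so validation runs on a
seeded pelvis phantom (96^3 voxels at 2 mm): a body ellipsoid, a
posterior rectal GTV of about 53 cc and 5 cm craniocaudal length
(matching the cohort medians reported for this clinical setting), an ADC
model with Gaussian noise (sd 5% of the background mean) and a planted
focus ball whose ADC is depressed by 30%, an anterior spherical bladder,
large- and small-bowel tubes, and a bowel-cavity envelope. Geometry is
deterministic given the spec; only ADC noise and per-subject cohort
jitter (GTV size +/-10%, focus offset +/-3 mm) consume random numbers,
all derived from one top-level seed.

Dose is modelled analytically rather than by beam simulation: plateau
`px * plateau_level` inside the target, halving every
`falloff_half_distance` mm outside (default 5 mm for the boost, 12 mm
for the conventional phase), plus a Gaussian hotspot (peak 1.12 px,
sigma 5 mm) at the nucleus centroid for the boost. Closed-form isodose
volumes make every conformality metric exactly checkable. The
conventional phase is a two-level field: an elective volume (PTV + 10 mm
at 90% of the prescription) combined with the boost volume at the full
prescription, mirroring simultaneous-integrated-boost practice.

One numerical choice deserves note. The dose model needs the distance
from a voxel center to the *surface* of a voxelized target. Raw
center-to-center distances place the surface at the outermost voxel
centers and under-grow isodose volumes by 2–3% on spheres; measuring to
the voxel cubes over-grows them by ~7% because cube corners stick out.
The package uses the center distance minus a quarter of the mean voxel
size (clamped at zero), which makes dilation volumes of smooth voxelized
shapes agree with the continuum to about 1% — inside the 2% band the
sphere oracle demands. This correction applies only to the analytic dose
model; mask geometry stays strictly voxel-center based.

The `compliant` preset keeps all OARs clear of the high-dose region and
satisfies every mandatory boost constraint at 5/7/10 Gy. The `stressed`
preset pushes the bladder into the planning target and routes the large
bowel through the intermediate-dose region, producing bladder V45/Dmax
and large-bowel V45 violations — the constraint families that limit
escalation in practice. What passing tests on the phantom do *not* show:
robustness to registration error, ADC artefacts from bowel content,
non-ellipsoidal anatomy, or the optimizer trade-offs of a real planning
system; the analytic fields are idealized surrogates with exactly known
geometry.

## Problem sizes and runtime choices

The shipped tests and the acceptance script use the phantom defaults:
96^3 voxels at 2 mm, cohorts of 10 subjects at three boost levels,
brute-force geometric oracles on grids up to 20^3, and a 48^3 gamma
oracle pair. These sizes keep each oracle exhaustive while the full
suite completes in a couple of minutes on one core.

## Known limitations

* DVHs are cumulative only; no differential DVHs or biological models
  (EQD2, gEUD, NTCP/TCP) — combined plans are summed as physical dose,
  as in biased-dose planning.
* No image registration or resampling; all volumes must share a grid.
* The connected-component cleaning always keeps a single component; a
  size-cutoff variant (keeping several large components) is not
  implemented because the source workflow does not specify one.
* Gamma analysis is computational only; detector geometry and
  measurement uncertainty are out of scope.
* Femoral-head constraints are not encoded (no printed limits to
  encode).
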
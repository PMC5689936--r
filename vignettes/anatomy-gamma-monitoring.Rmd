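---
title: "Monitoring anatomical change on serial CBCT with the gamma index"
author: "anatgamma"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monitoring anatomical change on serial CBCT with the gamma index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The clinical problem

Head-and-neck radiotherapy patients frequently lose weight or show tumour
regression over a 30–35 fraction course. When the external contour drifts
by a centimetre or more, the delivered dose can depart from the plan, and
the clinic must decide whether to order a repeat CT simulation (re-CT) and
possibly replan. That decision is traditionally made by humans reviewing
many image matches offline — slow, and most reviews end with "no action
needed". `anatgamma` implements an automated alert: every cone-beam CT
(CBCT) acquired for image guidance is compared quantitatively against the
course's first CBCT, a scalar match-quality trend is tracked by fraction,
and an alert fires when the trend crosses a trained threshold.

## The gamma index on CT numbers

For a reference volume $R$ and an evaluated volume $E$ on a common grid,
the per-voxel gamma index is

$$\gamma(\mathbf r) \;=\; \min_{\mathbf r'} \sqrt{
  \left(\frac{\lVert \mathbf r-\mathbf r' \rVert}{\mathrm{DTA}}\right)^2 +
  \left(\frac{E(\mathbf r') - R(\mathbf r)}{\Delta \mathrm{HU}}\right)^2 },$$

with a distance-to-agreement criterion DTA (mm) and a CT-number difference
criterion $\Delta$HU (Hounsfield units). A voxel *passes* when some nearby
evaluated voxel matches its CT number within the combined tolerance
($\gamma \le 1$) and *fails* otherwise ($\gamma > 1$). This is the
standard dose-QA comparison re-purposed for anatomy: instead of dose, the
quantity compared is the CT number itself.

Implementation notes (all in compiled code):

* The minimisation runs over **voxel centres of the full evaluated
  volume** within a radius `cap * dta` of the reference voxel. Because the
  distance term alone exceeds `cap` outside that radius, every value below
  the cap is exact. Candidates are visited in order of increasing physical
  distance and the scan stops as soon as the distance term reaches the
  running minimum, which makes typical (passing) voxels extremely cheap.
* Gamma values are clipped at `cap` (default 5). The default leaves the
  80th percentile of the failed-pixel histogram unsaturated in ordinary
  use; if more than 10% of failed voxels saturate, a warning is emitted.
* No sub-voxel interpolation is performed in the search. This is a
  documented design choice with a real consequence, discussed under
  *Limitations*.
* Distances honour anisotropic spacing (slice thickness differs from
  in-plane spacing).
* An unpruned exhaustive implementation (`gamma_bruteforce`) with an
  independent code path serves as the verification oracle in the test
  suite; the two agree to $10^{-9}$ per voxel on randomized volumes.

## The analysis mask

Failed pixels far outside the patient (couch, immobilisation devices,
reconstruction artifacts in air) must not influence the statistic, so the
comparison is restricted to the **external (body) contour dilated by 10
mm**, further limited in the superior/inferior direction to the axial
slice range spanned by the **highest-dose CTV** — the region of most
clinical concern. Dilation is a Euclidean-distance operation in physical
space. The mask is built once from the planning structure set and reused
for the whole course.

## The match quality parameter

Each comparison is reduced to the $x$-th percentile of the gamma values of
its *failed* voxels ($\gamma > 1$). With $\gamma_{x,\mathrm{ref}}$ from
the reference comparison (first vs second CBCT of the plan segment) and
$\gamma_{x,i}$ from the comparison of the first CBCT with fraction $i$:

$$\mathrm{MQP}_{x,i} \;=\; \gamma_{x,\mathrm{ref}} - \gamma_{x,i}.$$

Worsening anatomy shifts the failed-pixel histogram to the right, so the
MQP trends downward; values near zero mean the match is as good as it was
at the start of treatment. After a replan the reference resets to the
first two CBCTs of the new plan segment and the MQP restarts at zero.

Conventions that the tests pin down:

* Failure is strict: $\gamma = 1$ is a pass.
* The percentile interpolates linearly between closest order statistics
  (rank $1 + (n-1)x/100$, the common "type 7" convention).
* An empty failed set yields $\gamma_x := 1$, the pass/fail boundary, so a
  failure-free pair contributes a neutral MQP of 0 rather than an
  undefined value.
* The series is indexed by treatment fraction number, because the scoring
  window (below) is expressed in fractions.

## The re-CT decision rule and its training

An alert fires at the first comparison completing **`run_length` (default
3) consecutive acquired comparisons with MQP at or below a threshold**.
"Consecutive" means consecutive acquired CBCTs: calendar gaps do not break
a run, an MQP above threshold does. Only negative thresholds are
meaningful — a positive threshold would alert on matches *better* than the
reference.

Against a recorded re-CT order at fraction $f_o$, a segment scores

* **TP** if the rule is satisfied at some fraction within $\pm$`window`
  (default 3) of $f_o$;
* **FP** if the rule fires but only *before* $f_o - $`window` (premature
  alarm), or fires at all when no order exists;
* **FN** if the rule is never satisfied at or before $f_o + $`window`;
* **TN** if it never fires and no order exists.

Note the TP clause examines *every* fraction at which the run condition
holds, not only the first: with a persistently depressed MQP the
condition keeps holding, and an early first alarm does not erase the fact
that the alert is also active when the clinician actually ordered the
re-CT. (Only with this reading are sensitivity and false-alarm rate both
monotone in the threshold, which the suite asserts.) Segments with fewer
than `run_length` comparisons beyond the reference cannot satisfy the
rule meaningfully and are excluded as non-evaluable.

Training sweeps the threshold over the fixed 500-value grid $-0.001,
-0.002, \ldots, -0.5$ for every combination of DTA, $\Delta$HU and
percentile on the configured grids, scores the cohort, and selects the
operating point maximising the Youden index $J = \mathrm{TPF} -
\mathrm{FPF}$. Ties break deterministically: higher TPF, then more
negative threshold, then smaller DTA, smaller $\Delta$HU, smaller
percentile. Within each criteria pair the expensive stage (one gamma map
per comparison) runs once; percentiles and the threshold sweep reuse the
cached failed-histogram summaries.

## The synthetic phantom course

No clinical CBCT data ship with the package, so every end-to-end claim is
exercised on a simulated head-and-neck course with known ground truth:

* **Geometry** — an elliptical soft-tissue neck cylinder (default
  semi-axes 70 × 55 mm, 40 HU) containing a bony spine (800 HU) with a
  low-density canal, an air-filled airway, and a cylindrical high-dose CTV
  spanning a configurable slice range; 96 × 96 × 48 voxels at 2 × 2 × 3
  mm by default. This grid keeps a full 20-patient training sweep within
  desk-scale runtimes while preserving a realistic ratio of DTA to voxel
  size.
* **Edge profile** — interfaces follow a logistic profile of the signed
  distance to the boundary with a 3 mm 10–90% width, emulating the finite
  resolution of reconstructed CBCT. Binary steps would be unphysical and
  interact badly with the voxel-centre gamma search.
* **Weight loss** — from a programmable onset fraction, the lateral
  semi-axis of the body shrinks at `rate` mm/fraction on each side, with
  stripped voxels reverting to air. Lateral-only erosion mirrors where
  head-and-neck weight loss is clinically apparent.
* **Ground truth** — the simulated clinic orders a re-CT at the first
  CBCT whose cumulative erosion depth reaches 10 mm, mirroring the
  1-cm external-contour review trigger used in practice.
* **Degradation** — zero-mean Gaussian HU noise (default s.d. 20 HU);
  optional concentric ring artifacts (amplitude capped at 100 HU, the
  scale of artifact-induced CT-number error reported for CBCT) and radial
  streaks; optional rigid setup jitter. Ring patterns are
  **course-fixed** in phase with mild per-scan amplitude modulation,
  because ring artifacts are a fixed-pattern detector property of the
  treatment unit, not an independent draw per scan. Streak phase is
  per-scan: streaks genuinely differ between scans, and the suite shows
  they perturb the MQP at the decision-threshold scale while course-fixed
  rings stay within the noise floor — quantifying, on both sides, the
  concern that artifacts can confound an HU-based alert. Every volume is
  reproducible from the course seed.
* **Schedule** — CBCT on alternate fractions (1, 3, 5, …) by default.
  Clinics mix twice-weekly and daily volumetric imaging; alternate-day
  sampling is a realistic middle ground and, unlike a sparse twice-weekly
  pattern with 3–4 fraction gaps, makes a ±3-fraction agreement between
  any alert rule and the 10-mm order rule geometrically possible for
  every onset.

**Setup jitter defaults to zero.** In the clinical workflow the scans are
rigidly co-registered upstream (couch corrections are applied before the
comparison), so the generator's default emulates well-registered scans.
The jitter parameter remains available, and turning it on illustrates a
genuine limitation of the voxel-centre search rather than of the phantom:
a sub-voxel rigid shift of a steep intensity edge produces partial-volume
values that no voxel-centre candidate can match, inflating the failed
tail by amounts far exceeding the anatomical signal at 2 mm sampling.
Dose-QA gamma implementations solve this with sub-voxel interpolation of
the evaluated distribution; reproducing that here would change the
documented contract, so it is left as the main avenue for improvement.

What the simulation does **not** emulate: CBCT scatter and beam-hardening
physics, HU calibration drift between scans, deformable (as opposed to
volumetric-loss) anatomy change, couch and immobilisation hardware, and
real CBCT noise texture (which is correlated, not white). Passing the
suite therefore demonstrates the *mechanics* of the method — exactness of
the gamma computation, correctness of the statistic, rule and training
machinery, and recoverability of a designed effect from noisy data — not
clinical sensitivity or specificity, which can only come from patient
data.

## Study sizes used by the validation suite

The packaged suite trains on a simulated cohort of 10 changing patients
(onset uniform on fractions 10–20, 2 mm/fraction, 20 HU noise) and 10
stable patients, sweeping DTA ∈ {3, 6} mm × ΔHU ∈ {30, 60} HU ×
percentile ∈ {70, 80} over the full 500-value threshold grid, all with
fixed seeds. On this cohort the sweep attains an operating point with
TPF = 1 and FPF = 0 at the default criteria (3 mm, 30 HU, 80th
percentile), every changer's alert lands within ±3 fractions of its
simulated order, and course-fixed 100 HU ring artifacts perturb
individual MQP values by less than 0.05. `scripts/acceptance.R` recomputes
all of these quantities from scratch at a caller-supplied seed.

## Degenerate inputs and numerical corner cases

* Volumes must be finite; masks must be non-empty; criteria strictly
  positive; a CTV with no voxels has undefined axial limits and is an
  error.
* Comparing grid-incompatible volumes is an error; `resample_to_grid`
  (trilinear, −1000 HU fill outside the source extent) is the explicit
  escape hatch, applied automatically when a course's evaluated scans sit
  on a different grid than the mask.
* Segments with one CBCT have no reference comparison and are carried as
  non-evaluable rather than failing the course.
* Ties in the gamma minimisation need no special handling (a minimum over
  a finite candidate set); the visiting order cannot change the value.
* The brute-force oracle refuses volumes above $32^3$ voxels.

## Limitations

* Voxel-centre search without sub-voxel interpolation is sensitive to
  sub-voxel misregistration at steep edges (see above). With ~1 mm
  in-plane clinical grids this matters less than at the phantom's 2 mm.
* The failed-pixel percentile is not strictly monotone under worsening
  anatomy on very coarse grids: an influx of *moderate* new failures can
  briefly dilute the upper tail. At the default grid the effect is below
  the suite's 0.02 tolerance.
* The MQP compares each scan to fraction 1, so anatomy change that
  happened *before* treatment started is invisible — the same blind spot
  reported for the clinical method.
* DICOM inputs are not read directly; convert CT/CBCT series and
  structure sets to NIfTI (for contours, `rasterize_contours` accepts
  plain point lists extracted by any upstream tool).
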
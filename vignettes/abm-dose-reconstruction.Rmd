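---
title: "Reconstructing active bone marrow dose from radiotherapy records"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing active bone marrow dose from radiotherapy records}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(marrowdose)
```

## The problem

The active (red) bone marrow is the target tissue for radiation-induced
leukemia, but unlike a solid organ it is distributed over the whole
skeleton in age- and sex-dependent proportions. External beam
radiotherapy irradiates it extremely unevenly: a small portion of the
marrow near the target volume can receive the full prescription while
most of the skeleton receives little or nothing. A single mean-dose
number hides that heterogeneity, so epidemiological work on
therapy-related leukemia and clonal hematopoiesis benefits from
dose-volume metrics — the fraction of marrow above clinically relevant
dose levels — reconstructed per patient from the electronic treatment
records (CT series, RT-plan and RT-dose objects).

The obstacle is segmentation: dose-volume metrics need bone-site
contours on the patient CT, and manual contouring of 30+ skeletal sites
per patient does not scale to cohorts. `marrowdose` implements an
automatic, phantom-based route:

1. **Record completeness filter.** The per-beam prescribed doses
   extracted from the RT-plan are summed and compared with the delivered
   dose recorded in the cohort database; records disagreeing by more
   than 0.1 Gy are excluded as unreliable (the direction of the
   mismatch, plan-low vs. plan-high, is reported).
2. **Phantom selection.** A whole-body voxel phantom with 34 pre-labeled
   bone sites — each subdivided into cortical bone, trabecular spongiosa
   and medullary cavity — is chosen from a library by strict
   lexicographic priority: age, then sex, then height, then weight.
3. **Skeletal registration.** The patient skeleton is extracted from CT
   by Hounsfield-unit thresholding and the phantom skeleton is rigidly
   registered onto it with the iterative closest point (ICP) algorithm,
   carrying every labeled phantom bone voxel into the DICOM patient
   frame.
4. **Quality assurance.** Each registration is scored with the volume
   overlap fraction, VOF = |S_patient ∩ S_phantom| / |S_patient| × 100,
   and rendered as a two-colour skeletal overlay for review by two
   independent evaluators; a session is accepted only if both agree. A
   patient enters the analytical population only if *all* of their
   sessions are accepted.
5. **Marrow weighting and dosimetry.** Each site's reference marrow
   fraction is spread homogeneously over that site's non-cortical
   voxels (cortical bone holds no active marrow); the RT-dose grid is
   sampled at the registered voxel positions (zero outside the grid)
   and the weighted mean dose, exact cumulative dose-volume histogram
   (DVH), percentile doses D50/D10/D1 and volume metrics V5/V10/V20 are
   computed per session and, summed voxel-wise, per patient.

## The marrow fraction table

`abm_fraction_table()` packages the reference distribution of total
active marrow over 34 skeletal sites at ages 0, 1, 5, 10, 15 and 30
years (sex-specific from 15 on, derived from ICRP reference data). Each
column is a complete distribution: it sums to 1 within 0.002, the slack
being rounding of the printed four-decimal values.

```{r}
tab <- abm_fraction_table()
colSums(tab[, -1])
abm_fraction_lookup("Os coxae", age = 63, sex = "F")
```

Lookups snap to the nearest reference age with ties resolved toward the
older column; nothing is interpolated between columns, because the
reference values are published distributions, not samples of a smooth
curve, and an adult cohort overwhelmingly maps to the age-30 column
anyway. Ages 0–10 are sex-shared.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `hu_threshold` | 200 HU | CT bone floor for skeleton extraction. Conventional lower bound for bone attenuation; low enough to catch trabecular bone, high enough to exclude soft tissue. Surfaced in the config and logs. |
| `icp_config(max_iterations)` | 100 | Hard cap on ICP iterations. |
| `icp_config(convergence_tol)` | 0.01 mm | Stop when the mean correspondence distance improves by less than this. |
| `icp_config(subsample)` | 5000 | Per-side cap on points used in the ICP correspondence; larger clouds are uniformly subsampled under `seed`. |
| `icp_config(allow_scale)` | off | Optional isotropic (Umeyama) scale. Off by default: the phantoms are rigid bodies and body-size matching is the job of phantom *selection*, not warping. |
| `check_dose_consistency(threshold)` | 0.1 Gy | Record-completeness cutoff; strictly-greater mismatches reject. |

## Numerical choices

**ICP.** Point-to-point ICP with the closed-form SVD (Kabsch) update is
the canonical variant and what the package implements. Two details
matter in practice. First, regular voxel lattices have shallow local
minima at lattice-commensurate shifts; a centroid-only start can lock
into them. The fitter therefore starts from the centroid alignment *and*
the four proper principal-axes alignments and keeps the start with the
lowest final mean correspondence distance. Second, nearest-neighbour
distances are recomputed directly from coordinate differences rather
than taken from the expanded quadratic form, whose cancellation error
(~1e-7 mm at typical coordinates) would otherwise floor the objective
and defeat the convergence test. An update that fails to decrease the
mean correspondence distance is rejected and iteration stops, which
makes the recorded objective history non-increasing by construction.
The registration direction is phantom → patient, so bone labels land in
DICOM coordinates.

**D# convention.** The DVH is kept as the exact weighted empirical
distribution — one atom per distinct dose, no binning — so every binned
summary can be derived from it and no bin width parameter exists. D# is
the dose exceeded by #% of the marrow volume, i.e. the (100−#)th
weighted percentile with the lower boundary taken at probability ties.
With zero-inflated marrow dose distributions (most of the skeleton
outside the field) this yields D50 = 0 whenever at least half the
marrow weight is unirradiated, which is the clinically meaningful
reading of a median marrow dose. V(d) is the percentage of marrow
weight at doses ≥ d, so V(0) = 100 and the curve is non-increasing;
the mean equals the exact step-function integral of V(d)/100 over dose
(`dvh_integral_mean()`), a useful internal consistency check.

**Dose sampling.** Trilinear interpolation at voxel centers, node-exact
by construction, and exactly zero outside the dose matrix — marrow
beyond the planning grid is assumed unirradiated. This mirrors
treatment-planning convention and introduces the documented downward
bias for marrow far outside the imaged volume.

**VOF discretization.** The registered phantom points are snapped to
their nearest patient-grid voxel, duplicates collapsing to a set, and
the overlap is a pure set intersection with the *patient* set as
denominator (the score is deliberately asymmetric). VOF is reported for
review and cohort comparison but never used as an automatic acceptance
cutoff: thin bones (ribs, clavicles) can overlap poorly while remaining
geometrically close, and bones inside a near-uniform field can carry
low VOF with negligible dose error. Acceptance is an input — evaluator
flags or an explicit scripted policy.

**Phantom selection.** Strict lexicographic (age, sex, height, weight)
rather than a weighted distance, because the priority ordering is
given but no weights are; remaining ties go to the smallest phantom id
for determinism. If no same-sex candidate survives the age tier,
selection proceeds opposite-sex and flags the record rather than
failing. Multi-session patients are mapped on one shared phantom
(selected from the first session) so that voxel-wise dose summation
across sessions is well defined; each session is still registered
independently.

## The synthetic data generator

Because the cohort data behind the method are protected health
information, the package ships a generator (`make_phantom()`,
`make_ct_from_phantom()`, `make_dose_grid()`, `make_plan()`,
`make_cohort()`) that emulates every input:

* miniature labeled phantoms — six reference sites (femoral heads, os
  coxae, sacrum, lumbar vertebrae, ribs, craniofacial bones) as
  connected blobs with cortical shells, stacked inferior-to-superior
  with unequal, laterally offset footprints so the skeleton has no
  rotational near-symmetry;
* CT volumes with the phantom skeleton rendered at ~1000 HU over a
  0 HU background under a known rigid displacement, with optional
  seeded Gaussian HU noise, written as standard-conformant DICOM CT
  series;
* uniform-box or Gaussian-beam RT-dose grids and RT-plan objects with
  per-beam prescriptions, written as DICOM and read back through the
  same readers used for real data;
* whole cohorts with planted dose-record mismatches (> 0.1 Gy, in both
  directions) and planted mis-postured sessions pre-marked as rejected
  by both reviewers, so selection-flowchart counts are known by
  construction.

All generator randomness is seed-reproducible. Defaults represent a
mid-sized adult cohort: ages 35–75, heights ~N(170, 8) cm, weights
~N(72, 10) kg, 50 Gy prescriptions split over two beams, 4 mm isotropic
voxels.

What the generator does *not* emulate — and what green tests therefore
do not demonstrate — is the hard part of real data: realistic bone
shapes and intensity distributions, partial-body CTs that truncate the
skeleton, patient postures with no rigid match to a standardized
phantom (arms up vs. down, breast boards), couch hardware in the
HU-threshold range, and treatment-planning dose outside the calculation
region. On real cohorts those effects drive the rejection rate and the
reported VOF levels; the synthetic suite verifies the machinery
(registration recovery, weighting arithmetic, metric definitions,
bookkeeping), not clinical segmentation performance.

## Problem sizes used by the shipped checks

The packaged verification suite registers the 568-voxel miniature
skeleton under 20 random rigid displacements (rotations to ±45°,
translations to ±100 mm) noise-free and 5 more under 0.5 mm Gaussian
jitter; checks the VOF against brute-force set intersection on 100
random voxel-set pairs up to 10^4 voxels; compares the weighted DVH
metrics with a sort-and-scan oracle on 10^5-voxel samples; and runs a
10-patient synthetic cohort (12 sessions) with 3 planted dose
mismatches and 2 planted alignment failures. These sizes exercise every
code path while keeping the whole suite fast enough to run on every
change.

## Known limitations

* Rigid registration only. Posture differences and anatomy truncation
  are the dominant real-world failure modes and are out of scope; the
  acceptance-review stage exists precisely to catch them.
* Dose outside the planning grid is taken as zero, a systematic
  underestimate for marrow far from the imaged region (where absolute
  doses are, however, smallest).
* The DICOM layer reads and writes explicit-VR little-endian objects
  with axis-aligned orientation and uniform slice spacing; gantry-tilted
  or compressed-transfer-syntax series are rejected rather than
  silently mishandled.
* Treatment-region categorization is a configurable keyword/position
  stub intended for cohort bookkeeping, not a clinical taxonomy.
* The marrow-fraction table is used at its reference ages; no attempt
  is made to model individual marrow cellularity or conversion between
  active and inactive marrow.
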
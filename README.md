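# marrowdose

Active bone marrow (ABM) dose and dose-volume reconstruction for photon
external-beam radiotherapy patients, from their DICOM-RT records.

The active marrow — the target tissue for radiation-induced leukemia —
is spread over the whole skeleton in age- and sex-dependent fractions,
and radiotherapy irradiates it very unevenly: dose-volume metrics (the
fraction of marrow above a dose level), not just the mean dose, are
needed to characterize the exposure. Getting them retrospectively for a
cohort requires bone-site contours on every patient CT, which manual
segmentation cannot deliver at scale.

`marrowdose` automates the contouring with a phantom-based pipeline:

1. **Record filter** — per-beam prescribed doses extracted from the
   RT-plan are summed and checked against the recorded delivered dose;
   records mismatching by more than 0.1 Gy are excluded.
2. **Phantom selection** — a whole-body voxel phantom (34 labeled bone
   sites, each split into cortical bone / trabecular spongiosa /
   medullary cavity) is picked from a library by lexicographic priority
   age > sex > height > weight.
3. **Registration** — the patient skeleton is extracted from CT by HU
   thresholding (default 200 HU) and the phantom skeleton is rigidly
   registered onto it with the iterative closest point algorithm
   (point-to-point, closed-form SVD update, multi-start initialisation),
   placing every labeled phantom bone voxel in the DICOM patient frame.
4. **Quality assurance** — each registration gets a volume overlap
   fraction, `VOF = |S_patient ∩ S_phantom| / |S_patient| × 100`, and a
   purple/green skeletal overlay render; acceptance needs two
   independent evaluator approvals, and a patient is included only if
   *all* their sessions pass.
5. **Dosimetry** — each site's reference marrow fraction (packaged
   table by age and sex) is spread homogeneously over the site's
   non-cortical voxels; the RT-dose grid is sampled at the registered
   positions (trilinear, exactly zero outside the grid), yielding the
   marrow-weighted mean dose, the exact weighted cumulative DVH,
   percentile doses D50/D10/D1 (D10 = 90th percentile dose) and volume
   metrics V5/V10/V20 (% of marrow receiving ≥ 5/10/20 Gy), per session
   and summed over a patient's sessions.

A synthetic-fixture module (`make_phantom()`, `make_ct_from_phantom()`,
`make_dose_grid()`, `make_plan()`, `make_cohort()`) generates miniature
phantoms, DICOM CT/RT-dose/RT-plan files under known ground truth, and
whole cohorts with planted exclusions, so the entire pipeline runs and
is tested without any patient data.

## Worked example

```r
library(marrowdose)

# packaged miniature phantom (6 bone sites, 30-year-old male reference)
ph <- load_phantom(file.path(system.file("extdata",
                                         package = "marrowdose"),
                             "mini30M"))

# synthesize a patient CT: the phantom skeleton under a known pose
true_pose <- rigid_transform(rotation_about_axis("z", 12),
                             c(30, -15, 25))
ct <- make_ct_from_phantom(ph, true_pose, noise_sd = 20, seed = 7)

# segment and register
patient <- extract_skeleton(ct, hu_threshold = 200)
fit <- icp_register(phantom_skeleton_points(ph), patient)
fit
#> ICP registration: 2 iterations, mean correspondence 1.004 mm (converged)

vof <- compute_vof(patient$voxel_index,
                   predict(fit, phantom_skeleton_points(ph)),
                   ct$spacing, ct$origin)
round(vof, 1)
#> [1] 86.4

# a 45 Gy box covering the lower half of the skeleton
dose <- make_dose_grid("uniform_box", grid_dim = dim(ct$hu),
                       spacing = ct$spacing, origin = ct$origin,
                       dose_gy = 45,
                       box_lo = ct$origin + c(0, 0, 40),
                       box_hi = ct$origin + c(100, 100, 100))

smp <- sample_dose(dose, assign_voxel_weights(ph, fit$transform,
                                              age = 63, sex = "F"))
dose_metrics(smp, total_prescribed = 45)
#> Active bone marrow dose reconstruction
#>   mean ABM dose : 27.37 Gy (0.6082 Gy/Gy_Rx)
#>   D50/D10/D1    : 45 / 45 / 45 Gy
#>   V5/V10/V20    : 60.8 / 60.8 / 60.8 %
```

Reading: the box covers sites holding ~61% of this phantom's marrow, so
60.8% of the marrow volume sits at the full 45 Gy (hence V5 = V10 = V20
and D50 = D1 = 45 Gy) and the mean is 0.608 × 45 ≈ 27.4 Gy. On
realistic dose distributions those metrics separate: most marrow
receives little dose while a small fraction reaches the prescription,
which is exactly the heterogeneity the DVH metrics expose.

Cohort-scale use goes through `make_cohort()` / `run_cohort()` (or the
`inst/cli/marrowdose` script), which apply the record filter, the
review policy and the all-sessions-accepted patient rule, and emit
per-session and per-patient CSVs plus selection-flowchart counts.

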
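test_that("CT series round-trip is lossless for HU and geometry", {
  ph <- fix_phantom()
  ct <- make_ct_from_phantom(ph, rigid_transform(diag(3), c(3, -7, 11)),
                             noise_sd = 0)
  dir <- withr::local_tempdir()
  write_ct_series(ct, dir)
  ct2 <- read_ct_series(dir)
  expect_identical(dim(ct2$hu), dim(ct$hu))
  expect_equal(max(abs(ct2$hu - ct$hu)), 0)
  expect_equal(ct2$origin, ct$origin)
  expect_equal(ct2$spacing, ct$spacing)
  expect_equal(ct2$orientation, c(1, 0, 0, 0, 1, 0))
})

test_that("slice order is taken from positions, not filenames", {
  ct <- make_ct_from_phantom(fix_phantom(), noise_sd = 0)
  dir <- withr::local_tempdir()
  paths <- write_ct_series(ct, dir)
  # shuffle names so lexical file order disagrees with z order
  n <- length(paths)
  set.seed(8)
  perm <- sample(n)
  stage <- file.path(dir, sprintf("stage_%03d.tmp", seq_len(n)))
  for (k in seq_len(n)) file.rename(paths[k], stage[k])
  for (k in seq_len(n)) file.rename(stage[k], paths[perm[k]])
  ct2 <- read_ct_series(dir)
  expect_equal(max(abs(ct2$hu - ct$hu)), 0)
  expect_equal(ct2$origin, ct$origin)
})

test_that("mixed series and missing slices are rejected", {
  ct <- ct_volume(array(0, dim = c(4, 4, 3)), c(1, 1, 2), c(0, 0, 0))
  dir <- withr::local_tempdir()
  write_ct_series(ct, dir, id = "1")
  # a second series in the same directory
  write_ct_series(ct_volume(array(0, dim = c(4, 4, 2)), c(1, 1, 2),
                            c(0, 0, 50)), dir, id = "2")
  expect_error(read_ct_series(dir), "more than one CT series")

  dir2 <- withr::local_tempdir()
  paths <- write_ct_series(ct_volume(array(0, dim = c(4, 4, 4)),
                                     c(1, 1, 2), c(0, 0, 0)), dir2)
  file.remove(paths[3])  # gap in the z grid
  expect_error(read_ct_series(dir2), "non-uniform")
})

test_that("RT-dose applies the grid scaling factor at read time", {
  dose <- array(0, dim = c(3, 3, 2))
  dose[2, 2, 1] <- 50
  dg <- dose_grid(dose, c(2, 2, 2), c(0, 0, 0))
  f <- file.path(withr::local_tempdir(), "dose.dcm")
  # stored value 5000 at scaling 0.01 must read back as 50 Gy
  write_rt_dose(dg, f, scaling = 0.01)
  dg2 <- read_rt_dose(f)
  expect_equal(dg2$dose[2, 2, 1], 50)
  expect_equal(max(abs(dg2$dose - dose)), 0)
  expect_equal(dg2$spacing, dg$spacing)
  expect_equal(dg2$origin, dg$origin)
})

test_that("zero dose grids and missing scaling behave per contract", {
  dg <- dose_grid(array(0, dim = c(3, 3, 2)), c(2, 2, 2), c(0, 0, 0))
  f <- file.path(withr::local_tempdir(), "dose0.dcm")
  write_rt_dose(dg, f)
  expect_true(all(read_rt_dose(f)$dose == 0))
  expect_error(dose_grid(array(-1, dim = c(2, 2, 2)), c(1, 1, 1),
                         c(0, 0, 0)), "non-negative")
})

test_that("RT-plan total prescribed dose is the exact beam sum", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "plan.dcm")
  beams <- data.frame(label = c("AP", "PA"), dose = c(30, 20),
                      iso_x = 1, iso_y = 2, iso_z = 3)
  write_rt_plan(beams, f, plan_label = "PELVIS IMRT")
  plan <- read_rt_plan(f)
  expect_s3_class(plan, "plan_summary")
  expect_identical(plan$total_prescribed, 50)
  expect_identical(plan$plan_label, "PELVIS IMRT")
  expect_identical(plan$dose_source, "beams")
  expect_equal(plan$beams$prescribed_dose, c(30, 20))
  expect_equal(unlist(plan$beams[1, c("iso_x", "iso_y", "iso_z")]),
               c(iso_x = 1, iso_y = 2, iso_z = 3))

  f1 <- file.path(dir, "single.dcm")
  write_rt_plan(beams[1, ], f1)
  expect_identical(read_rt_plan(f1)$total_prescribed, 30)
})

test_that("plans without beam doses fall back to the dose reference", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "fallback.dcm")
  write_rt_plan(beams = data.frame(label = character(), dose = numeric(),
                                   iso_x = numeric(), iso_y = numeric(),
                                   iso_z = numeric()),
                f, plan_label = "RX ONLY", target_prescription = 45)
  plan <- read_rt_plan(f)
  expect_identical(plan$total_prescribed, 45)
  expect_identical(plan$dose_source, "dose_reference")

  f2 <- file.path(dir, "nodose.dcm")
  write_rt_plan(beams = data.frame(label = character(), dose = numeric(),
                                   iso_x = numeric(), iso_y = numeric(),
                                   iso_z = numeric()), f2)
  expect_error(read_rt_plan(f2), "no dose attributes")
})

test_that("dose-consistency filter rejects strictly above 0.1 Gy", {
  plan <- make_plan(c(30, 20))
  ok <- check_dose_consistency(plan, patient_characteristics(
    60, "F", recorded_delivered_dose = 50))
  expect_identical(ok$decision, "accept")
  expect_identical(ok$mismatch, 0)
  expect_identical(ok$direction, "match")

  rej <- check_dose_consistency(plan, patient_characteristics(
    60, "F", recorded_delivered_dose = 50.2))
  expect_identical(rej$decision, "reject")
  expect_identical(rej$direction, "plan-low")
  expect_equal(rej$mismatch, 0.2)

  # boundary: 0.05 and even exactly 0.1 are accepted (strict inequality)
  expect_identical(check_dose_consistency(make_plan(c(30, 20.05)),
    patient_characteristics(60, "F", recorded_delivered_dose = 50))$decision,
    "accept")
  expect_identical(check_dose_consistency(make_plan(c(30, 20.1)),
    patient_characteristics(60, "F", recorded_delivered_dose = 50))$decision,
    "accept")
  expect_identical(check_dose_consistency(make_plan(c(30, 20.11)),
    patient_characteristics(60, "F", recorded_delivered_dose = 50))$decision,
    "reject")

  miss <- check_dose_consistency(plan, patient_characteristics(60, "F"))
  expect_identical(miss$decision, "reject")
  expect_identical(miss$direction, "missing")
  expect_identical(miss$reason, "missing record")
})

test_that("mismatch magnitude is symmetric in sign", {
  a <- check_dose_consistency(make_plan(48), patient_characteristics(
    60, "F", recorded_delivered_dose = 50))
  b <- check_dose_consistency(make_plan(50), patient_characteristics(
    60, "F", recorded_delivered_dose = 48))
  expect_equal(a$mismatch, b$mismatch)
  expect_identical(a$direction, "plan-low")
  expect_identical(b$direction, "plan-high")
})

test_that("a toy batch with 3 planted mismatches keeps exactly 7 of 10", {
  recorded <- rep(50, 10)
  recorded[c(2, 5, 9)] <- c(50.5, 49.3, 51.2)
  decisions <- vapply(recorded, function(r) {
    check_dose_consistency(make_plan(c(30, 20)),
                           patient_characteristics(
                             60, "M", recorded_delivered_dose = r))$decision
  }, "")
  expect_identical(sum(decisions == "accept"), 7L)
  expect_identical(which(decisions == "reject"), c(2L, 5L, 9L))
})

test_that("treatment regions come from keywords, then isocenter bands", {
  plan <- make_plan(50, plan_label = "PELVIS IMRT")
  expect_identical(categorize_treatment_region(plan), "pelvic")

  blank <- make_plan(50, plan_label = "XXXX",
                     isocenter = c(0, 0, 950))
  # cranial band of a 0-1000 mm phantom extent
  expect_identical(
    categorize_treatment_region(blank, z_extent = c(0, 1000)),
    "intracranial")
  mid <- make_plan(50, plan_label = "XXXX", isocenter = c(0, 0, 700))
  expect_identical(categorize_treatment_region(mid, z_extent = c(0, 1000)),
                   "thoracic")
  outside <- make_plan(50, plan_label = "XXXX",
                       isocenter = c(0, 0, 2000))
  expect_identical(
    categorize_treatment_region(outside, z_extent = c(0, 1000)),
    "uncategorized")
  # no label, no extent -> uncategorized, never an error
  expect_identical(categorize_treatment_region(
    make_plan(50, plan_label = "")), "uncategorized")
})

test_that("written DICOM objects are readable by an independent parser", {
  dir <- withr::local_tempdir()
  ct <- ct_volume(array(seq_len(4 * 3 * 2) * 10, dim = c(4, 3, 2)),
                  c(1.5, 2, 2.5), c(-10, -20, -30))
  write_ct_series(ct, file.path(dir, "ct"))
  dg <- dose_grid(array(c(0, 12.5), dim = c(2, 2, 2)), c(5, 5, 5),
                  c(1, 2, 3))
  write_rt_dose(dg, file.path(dir, "dose.dcm"), scaling = 0.005)
  write_rt_plan(data.frame(label = "AP", dose = 42.5, iso_x = 1,
                           iso_y = 2, iso_z = 3),
                file.path(dir, "plan.dcm"), plan_label = "ORACLE")
  script <- file.path(dir, "oracle.py")
  writeLines(c(
    "import sys, pydicom",
    "d = sys.argv[1]",
    "ct = pydicom.dcmread(d + '/ct/ct_001.dcm')",
    "arr = ct.pixel_array * float(ct.RescaleSlope) + float(ct.RescaleIntercept)",
    "print('ct', arr[0,0], arr[2,3], ct.ImagePositionPatient[0],",
    "      ct.PixelSpacing[0], ct.PixelSpacing[1])",
    "do = pydicom.dcmread(d + '/dose.dcm')",
    "dd = do.pixel_array * float(do.DoseGridScaling)",
    "print('dose', float(dd.max()), float(dd.min()))",
    "pl = pydicom.dcmread(d + '/plan.dcm')",
    "rb = pl.FractionGroupSequence[0].ReferencedBeamSequence[0]",
    "print('plan', float(rb.BeamDose), pl.RTPlanLabel)"
  ), script)
  out <- system2("python", c(script, dir), stdout = TRUE)
  # pydicom pixel_array rows are y: [0,0] is voxel (1,1); [2,3] is
  # x index 4, y index 3 of slice 1
  expect_identical(out[1], "ct 10.0 120.0 -10 2 1.5")
  expect_identical(out[2], "dose 12.5 0.0")
  expect_identical(out[3], "plan 42.5 ORACLE")
})
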
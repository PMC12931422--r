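test_that("the miniature phantom matches its construction spec", {
  spec <- fixture_sites()
  ph <- make_phantom(spec)
  for (s in seq_len(nrow(spec))) {
    expect_equal(sum(ph$label_volume == s), spec$n_voxels[s])
    n_cort <- sum(ph$label_volume == s &
                    ph$tissue_volume == tissue_codes()[["cortical"]])
    expect_equal(n_cort, round(spec$cortical_fraction[s] *
                                 spec$n_voxels[s]))
  }
  # construction is deterministic
  expect_identical(make_phantom(spec)$label_volume, ph$label_volume)

  # cortical fraction zero leaves no cortical voxels
  spec0 <- spec; spec0$cortical_fraction <- 0
  ph0 <- make_phantom(spec0)
  expect_equal(sum(ph0$tissue_volume == tissue_codes()[["cortical"]]), 0L)

  # oversized sites are refused
  too_big <- spec; too_big$n_voxels[1] <- 1e6
  expect_error(make_phantom(too_big), "does not fit")
})

test_that("each phantom site is a connected blob", {
  ph <- fix_phantom()
  for (id in ph$site_map) {
    vox <- which(ph$label_volume == id, arr.ind = TRUE)
    # flood fill from the first voxel over 6-connectivity
    key <- function(m) paste(m[, 1], m[, 2], m[, 3])
    all_k <- key(vox)
    seen <- all_k[1]; frontier <- vox[1, , drop = FALSE]
    shifts <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                    c(0, 0, 1), c(0, 0, -1))
    while (nrow(frontier)) {
      nb <- do.call(rbind, lapply(seq_len(nrow(shifts)), function(i) {
        sweep(frontier, 2, shifts[i, ], "+")
      }))
      nb_k <- key(nb)
      new <- nb_k %in% all_k & !(nb_k %in% seen)
      seen <- c(seen, unique(nb_k[new]))
      frontier <- unique(nb[new, , drop = FALSE])
    }
    expect_equal(length(seen), nrow(vox))
  }
})

test_that("identity-rendered CT reproduces the skeleton voxel-for-voxel", {
  ph <- fix_phantom()
  ct <- make_ct_from_phantom(ph, rigid_transform(), noise_sd = 0)
  sk_ct <- extract_skeleton(ct, 200)
  sk_ph <- phantom_skeleton_points(ph)
  expect_equal(nrow(sk_ct$points), nrow(sk_ph$points))
  # same physical positions (order may differ)
  ord1 <- order(sk_ct$points[, 3], sk_ct$points[, 2], sk_ct$points[, 1])
  ord2 <- order(sk_ph$points[, 3], sk_ph$points[, 2], sk_ph$points[, 1])
  expect_equal(sk_ct$points[ord1, ], sk_ph$points[ord2, ],
               tolerance = 1e-12)
})

test_that("bone stays detectable under heavy HU noise", {
  ph <- fix_phantom()
  n_bone <- sum(ph$label_volume > 0)
  bone_key <- do.call(paste,
                      as.data.frame(which(ph$label_volume > 0,
                                          arr.ind = TRUE)))
  # sd 50 HU: bone at 1000 sits 16 sigma above a 200 HU threshold, so
  # every bone voxel survives thresholding
  ct <- make_ct_from_phantom(ph, rigid_transform(), hu_bone = 1000,
                             hu_soft = 0, noise_sd = 50, seed = 4)
  sk <- extract_skeleton(ct, 200)
  idx_ph <- round(world_to_voxel(sk$points, ph$spacing, ph$origin))
  got_key <- do.call(paste, as.data.frame(idx_ph))
  expect_true(all(bone_key %in% got_key))
  # at sd 30 the 0 HU background sits > 6 sigma below threshold too:
  # the extracted skeleton is exactly the bone set
  ct30 <- make_ct_from_phantom(ph, rigid_transform(), hu_bone = 1000,
                               hu_soft = 0, noise_sd = 30, seed = 4)
  expect_equal(nrow(extract_skeleton(ct30, 200)$points), n_bone)
  # same seed reproduces the identical volume
  ct2 <- make_ct_from_phantom(ph, rigid_transform(), hu_bone = 1000,
                              hu_soft = 0, noise_sd = 50, seed = 4)
  expect_identical(ct2$hu, ct$hu)
})

test_that("a clipping transform is refused", {
  ph <- fix_phantom()
  expect_error(
    make_ct_from_phantom(ph, rigid_transform(diag(3), c(500, 0, 0)),
                         grid_dim = c(10, 10, 10),
                         grid_origin = c(0, 0, 0)),
    "clipped")
})

test_that("uniform-box dose fields are exact inside and zero outside", {
  dg <- make_dose_grid("uniform_box", grid_dim = c(20, 20, 20),
                       spacing = c(2, 2, 2), origin = c(0, 0, 0),
                       dose_gy = 50, box_lo = c(10, 10, 10),
                       box_hi = c(26, 26, 26))
  expect_equal(sample_dose(dg, c(18, 18, 18)), 50)
  expect_equal(sample_dose(dg, c(36, 36, 36)), 0)
  expect_error(make_dose_grid("uniform_box", dose_gy = -5,
                              box_lo = c(0, 0, 0), box_hi = c(1, 1, 1)),
               "non-negative")
})

test_that("gaussian beams peak on the axis and respect the bound", {
  dg <- make_dose_grid("gaussian_beam", grid_dim = c(21, 21, 10),
                       spacing = c(2, 2, 5), origin = c(0, 0, 0),
                       peak_gy = 10, sigma_mm = 8)
  expect_lte(max(dg$dose), 10)
  expect_equal(max(dg$dose), 10)  # axis passes through a node here
  # lateral falloff: dose at 8 mm off-axis is exp(-0.5) of the peak
  axis_xy <- c(20, 20)
  on_ax <- sample_dose(dg, c(axis_xy, 20))
  off_ax <- sample_dose(dg, c(axis_xy[1] + 8, axis_xy[2], 20))
  expect_equal(off_ax / on_ax, exp(-0.5), tolerance = 1e-9)
})

test_that("synthetic cohorts are reproducible and carry their truth", {
  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  co1 <- make_cohort(dir1, n = 6, seed = 5, n_mismatch = 2,
                     n_badalign = 1, n_multisession = 1)
  co2 <- make_cohort(dir2, n = 6, seed = 5, n_mismatch = 2,
                     n_badalign = 1, n_multisession = 1)
  expect_identical(co1$manifest[, setdiff(names(co1$manifest),
                                          c("ct_dir", "dose_file",
                                            "plan_file"))],
                   co2$manifest[, setdiff(names(co2$manifest),
                                          c("ct_dir", "dose_file",
                                            "plan_file"))])
  # byte-identical DICOM payloads for the same seed
  f1 <- co1$manifest$dose_file[1]; f2 <- co2$manifest$dose_file[1]
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  expect_length(co1$truth$mismatch_patients, 2L)
  expect_length(co1$truth$badalign_sessions, 1L)
  expect_equal(nrow(co1$manifest), 7L)  # 6 patients + 1 extra session
  # manifest round-trips through its CSV
  mf <- utils::read.csv(file.path(dir1, "cohort_manifest.csv"))
  expect_equal(nrow(mf), nrow(co1$manifest))
})
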
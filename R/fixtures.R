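#' Default miniature phantom site layout
#'
#' Six reference sites spanning the cranio-caudal axis with realistic
#' relative extents, enough to exercise every stage of the pipeline
#' without a full 34-site anatomy.
#'
#' @return Data frame: `site`, `n_voxels`, `cortical_fraction`.
#' @export
fixture_sites <- function() {
  data.frame(
    site = c("Femora, proximal head", "Os coxae", "Sacrum",
             "Lumbar vertebrae", "Ribs", "Craniofacial bones"),
    n_voxels = c(48, 140, 60, 90, 110, 120),
    cortical_fraction = c(0.3, 0.25, 0.25, 0.3, 0.4, 0.35),
    # per-site footprint (voxels) and x/y offset: unequal extents and
    # laterally shifted blobs keep the skeleton free of the rotational
    # near-symmetries a stack of identical boxes would have
    width_x = c(4L, 10L, 5L, 4L, 9L, 7L),
    width_y = c(7L, 6L, 4L, 5L, 4L, 6L),
    off_x = c(0L, 0L, 2L, 3L, 1L, 2L),
    off_y = c(1L, 0L, 3L, 2L, 0L, 3L),
    stringsAsFactors = FALSE
  )
}

#' Build a miniature labeled phantom
#'
#' Each site is laid down as a connected cuboid blob in its own
#' cranio-caudal slab (sites are given in inferior-to-superior order);
#' within a blob, boundary voxels are marked cortical until the requested
#' cortical fraction is met and the interior is trabecular spongiosa.
#' Construction is fully deterministic.
#'
#' @param sites Data frame as [fixture_sites()].
#' @param spacing Voxel spacing in mm.
#' @param cross_section Edge length (voxels) of the square x-y region
#'   each site may occupy.
#' @param meta Phantom body metadata; defaults describe a 30-year-old
#'   male reference body.
#' @return A [phantom()].
#' @export
#' @examples
#' ph <- make_phantom()
#' table(ph$tissue_volume[ph$tissue_volume > 0])
make_phantom <- function(sites = fixture_sites(), spacing = c(4, 4, 4),
                         cross_section = 10L,
                         meta = list(age_years = 30, sex = "M",
                                     height_cm = 176, weight_kg = 73,
                                     id = "mini30M")) {
  sites <- as.data.frame(sites)
  if (!nrow(sites)) stop("need at least one site", call. = FALSE)
  cs <- as.integer(cross_section)
  if (is.null(sites$width_x)) sites$width_x <- cs
  if (is.null(sites$width_y)) sites$width_y <- cs
  if (is.null(sites$off_x)) sites$off_x <- 0L
  if (is.null(sites$off_y)) sites$off_y <- 0L
  per_slab <- sites$width_x * sites$width_y
  slab_h <- as.integer(ceiling(sites$n_voxels / per_slab)) + 1L
  if (any(slab_h > 13L) ||
      any(sites$off_x + sites$width_x > cs + 2L) ||
      any(sites$off_y + sites$width_y > cs + 2L)) {
    stop("site voxel count does not fit the grid cross-section",
         call. = FALSE)
  }
  nz <- sum(slab_h) + length(slab_h) + 1L  # one-voxel gaps between slabs
  nx <- cs + 4L; ny <- cs + 4L
  lab <- array(0L, dim = c(nx, ny, nz))
  tis <- array(0L, dim = c(nx, ny, nz))
  z0 <- 2L
  codes <- tissue_codes()
  for (s in seq_len(nrow(sites))) {
    n <- sites$n_voxels[s]
    wx <- sites$width_x[s]; wy <- sites$width_y[s]
    ox <- sites$off_x[s]; oy <- sites$off_y[s]
    # fill the slab in raster order (x fastest, then y, then z): connected
    filled <- 0L
    vox <- matrix(0L, nrow = n, ncol = 3)
    z <- z0
    while (filled < n) {
      take <- min(wx * wy, n - filled)
      ij <- arrayInd(seq_len(take), c(wx, wy))
      vox[filled + seq_len(take), ] <-
        cbind(ij[, 1] + 2L + ox, ij[, 2] + 2L + oy, z)
      filled <- filled + take
      z <- z + 1L
    }
    lab[vox] <- s
    # cortical shell: boundary voxels first (any face neighbour outside)
    in_blob <- array(FALSE, dim = dim(lab))
    in_blob[vox] <- TRUE
    nb_out <- vapply(seq_len(n), function(i) {
      v <- vox[i, ]
      for (d in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                     c(0, 0, 1), c(0, 0, -1))) {
        w <- v + d
        if (any(w < 1L) || any(w > dim(lab))) return(TRUE)
        if (!in_blob[w[1], w[2], w[3]]) return(TRUE)
      }
      FALSE
    }, NA)
    n_cort <- as.integer(round(sites$cortical_fraction[s] * n))
    cort_idx <- which(nb_out)
    if (length(cort_idx) < n_cort) cort_idx <- seq_len(n)  # thin blob
    cort <- vox[cort_idx[seq_len(n_cort)], , drop = FALSE]
    tis[vox] <- codes[["spongiosa"]]
    if (n_cort > 0) tis[cort] <- codes[["cortical"]]
    z0 <- z0 + slab_h[s] + 1L
  }
  phantom(lab, tis, spacing = spacing, origin = c(0, 0, 0),
          site_map = stats::setNames(seq_len(nrow(sites)), sites$site),
          meta = meta)
}

#' Render a CT volume containing a phantom's skeleton
#'
#' The phantom's bone voxels are placed into a fresh CT grid at their
#' positions under `true_transform`, rendered at `hu_bone` over an
#' `hu_soft` background, optionally with seeded Gaussian HU noise. The
#' grid is sized to enclose the transformed skeleton with a margin; a
#' caller-supplied geometry that clips the skeleton is an error. Under
#' the identity transform and zero noise the thresholded CT skeleton
#' reproduces the phantom skeleton voxel-for-voxel.
#'
#' @param ph A [phantom()].
#' @param true_transform [rigid_transform()] carrying the phantom into
#'   the patient frame (the ground truth a registration should recover).
#' @param hu_bone,hu_soft HU of bone voxels and background.
#' @param noise_sd Gaussian HU noise standard deviation (0 = none).
#' @param seed Seed for the noise draw.
#' @param margin_vox Margin around the skeleton, in voxels.
#' @param grid_dim,grid_origin Optional explicit CT geometry (defaults
#'   derived from the transformed skeleton).
#' @return A [ct_volume()].
#' @export
make_ct_from_phantom <- function(ph, true_transform = rigid_transform(),
                                 hu_bone = 1000, hu_soft = 0,
                                 noise_sd = 0, seed = 1L,
                                 margin_vox = 5L, grid_dim = NULL,
                                 grid_origin = NULL) {
  stopifnot(inherits(ph, "phantom"))
  sk <- phantom_skeleton_points(ph)
  pts <- apply_transform(true_transform, sk$points)
  spacing <- ph$spacing
  if (is.null(grid_origin)) {
    grid_origin <- apply(pts, 2, min) - margin_vox * spacing
    # snap to the phantom voxel lattice so identity transforms reproduce
    # voxel centers exactly
    grid_origin <- ph$origin +
      round((grid_origin - ph$origin) / spacing) * spacing
  }
  if (is.null(grid_dim)) {
    grid_dim <- ceiling((apply(pts, 2, max) - grid_origin) / spacing) +
      margin_vox + 1
  }
  grid_dim <- as.integer(grid_dim)
  idx <- round(world_to_voxel(pts, spacing, grid_origin))
  if (any(idx < 1) || any(sweep(idx, 2, grid_dim, ">"))) {
    stop("skeleton clipped by CT grid", call. = FALSE)
  }
  hu <- array(hu_soft, dim = grid_dim)
  hu[idx] <- hu_bone
  if (noise_sd > 0) {
    hu <- hu + with_seed(seed, array(stats::rnorm(prod(grid_dim),
                                                  sd = noise_sd),
                                     dim = grid_dim))
  }
  ct_volume(hu, spacing = spacing, origin = grid_origin)
}

#' Build a synthetic dose grid
#'
#' Either a uniform-dose box (exact `dose_gy` inside the mm extent, zero
#' outside) or a Gaussian pencil-beam profile along the z axis.
#'
#' @param kind `"uniform_box"` or `"gaussian_beam"`.
#' @param grid_dim Grid size in voxels.
#' @param spacing,origin Grid geometry (mm).
#' @param dose_gy Box dose (uniform_box).
#' @param box_lo,box_hi mm corners of the box (uniform_box); voxels whose
#'   centers lie inside receive `dose_gy`.
#' @param peak_gy,sigma_mm,center_xy Gaussian beam parameters
#'   (gaussian_beam): peak dose, lateral sigma, beam axis position.
#' @return A [dose_grid()].
#' @export
make_dose_grid <- function(kind = c("uniform_box", "gaussian_beam"),
                           grid_dim = c(30, 30, 40),
                           spacing = c(4, 4, 4), origin = c(0, 0, 0),
                           dose_gy = 50, box_lo = NULL, box_hi = NULL,
                           peak_gy = 10, sigma_mm = 20,
                           center_xy = NULL) {
  kind <- match.arg(kind)
  if (dose_gy < 0 || peak_gy < 0) {
    stop("requested dose must be non-negative", call. = FALSE)
  }
  grid_dim <- as.integer(grid_dim)
  ax <- lapply(1:3, function(a) origin[a] + (seq_len(grid_dim[a]) - 1) *
                 spacing[a])
  dose <- array(0, dim = grid_dim)
  if (kind == "uniform_box") {
    if (is.null(box_lo) || is.null(box_hi)) {
      stop("uniform_box needs box_lo and box_hi", call. = FALSE)
    }
    ix <- ax[[1]] >= box_lo[1] & ax[[1]] <= box_hi[1]
    iy <- ax[[2]] >= box_lo[2] & ax[[2]] <= box_hi[2]
    iz <- ax[[3]] >= box_lo[3] & ax[[3]] <= box_hi[3]
    dose[ix, iy, iz] <- dose_gy
  } else {
    if (is.null(center_xy)) {
      center_xy <- c(mean(range(ax[[1]])), mean(range(ax[[2]])))
    }
    r2 <- outer((ax[[1]] - center_xy[1])^2, (ax[[2]] - center_xy[2])^2, "+")
    prof <- peak_gy * exp(-r2 / (2 * sigma_mm^2))
    dose <- array(rep(prof, grid_dim[3]), dim = grid_dim)
  }
  dose_grid(dose, spacing = spacing, origin = origin)
}

#' Build a synthetic plan summary
#'
#' @param beam_doses Per-beam prescribed doses in Gy.
#' @param isocenter mm isocenter shared by the beams.
#' @param plan_label Plan label.
#' @return A `plan_summary` (as returned by [read_rt_plan()]); use
#'   [write_rt_plan()] to put it on disk.
#' @export
make_plan <- function(beam_doses = c(30, 20), isocenter = c(0, 0, 0),
                      plan_label = "PLAN") {
  if (any(beam_doses < 0)) stop("negative beam dose", call. = FALSE)
  beams <- data.frame(
    label = paste0("beam", seq_along(beam_doses)),
    prescribed_dose = beam_doses,
    iso_x = isocenter[1], iso_y = isocenter[2], iso_z = isocenter[3],
    stringsAsFactors = FALSE
  )
  structure(
    list(beams = beams, total_prescribed = sum(beam_doses),
         plan_label = plan_label, dose_source = "beams"),
    class = "plan_summary"
  )
}

# plan_summary -> the data frame write_rt_plan() expects
plan_to_beam_df <- function(plan) {
  data.frame(label = plan$beams$label, dose = plan$beams$prescribed_dose,
             iso_x = plan$beams$iso_x, iso_y = plan$beams$iso_y,
             iso_z = plan$beams$iso_z, stringsAsFactors = FALSE)
}

#' Generate a synthetic DICOM-RT cohort on disk
#'
#' Writes `n` patients under `dir`, each with one or more treatment
#' sessions of CT series, RT-dose and RT-plan files, plus a
#' `cohort_manifest.csv`. A chosen number of records are planted with a
#' prescribed/recorded dose mismatch above 0.1 Gy (alternating low/high
#' direction), and a chosen number of sessions are rendered under a large
#' posture rotation and pre-marked as rejected by both reviewers, so the
#' selection flowchart of a cohort run is known by construction.
#'
#' @param dir Output directory.
#' @param n Number of patients.
#' @param seed Seed controlling all randomness.
#' @param n_mismatch Patients planted with a dose-record mismatch.
#' @param n_badalign Patients planted with a misaligned (rejected)
#'   session.
#' @param n_multisession Patients given two sessions instead of one.
#' @param rx_gy Per-session prescription (Gy) used for plan and dose box.
#' @return List: `dir`, `manifest` (data frame, also written as CSV),
#'   `truth` (planted counts).
#' @export
make_cohort <- function(dir, n = 10, seed = 1L, n_mismatch = 3,
                        n_badalign = 2, n_multisession = 2, rx_gy = 50) {
  stopifnot(n >= 1, n_mismatch + n_badalign <= n)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ph <- make_phantom()
  # planted roles: first n_mismatch patients mismatch, next n_badalign
  # misaligned, next n_multisession get two sessions
  roles <- rep("clean", n)
  if (n_mismatch > 0) roles[seq_len(n_mismatch)] <- "mismatch"
  if (n_badalign > 0) roles[n_mismatch + seq_len(n_badalign)] <- "badalign"
  multi <- rep(1L, n)
  if (n_multisession > 0) {
    cand <- which(roles == "clean")
    multi[cand[seq_len(min(n_multisession, length(cand)))]] <- 2L
  }
  ages <- with_seed(seed, round(stats::runif(n, 35, 75), 1))
  sexes <- with_seed(seed + 1, sample(c("F", "M"), n, replace = TRUE))
  heights <- with_seed(seed + 2, round(stats::rnorm(n, 170, 8), 1))
  weights <- with_seed(seed + 3, round(stats::rnorm(n, 72, 10), 1))
  rows <- list()
  for (p in seq_len(n)) {
    pid <- sprintf("pt%03d", p)
    for (s in seq_len(multi[p])) {
      sid <- sprintf("%s_s%d", pid, s)
      sdir <- file.path(dir, pid, sprintf("session%d", s))
      dir.create(file.path(sdir, "ct"), recursive = TRUE,
                 showWarnings = FALSE)
      bad <- roles[p] == "badalign" && s == 1L
      tru <- if (bad) {
        rigid_transform(rotation_about_axis("y", 70), c(180, -60, 40))
      } else {
        ang <- with_seed(seed + 100 * p + s, stats::runif(1, -12, 12))
        shift <- with_seed(seed + 200 * p + s, stats::runif(3, -25, 25))
        rigid_transform(rotation_about_axis("z", ang), shift)
      }
      ct <- make_ct_from_phantom(ph, tru, noise_sd = 20,
                                 seed = seed + 10 * p + s)
      write_ct_series(ct, file.path(sdir, "ct"), id = sid)
      # uniform box over the pelvic slab region of the transformed grid
      ext <- apply(apply_transform(tru, phantom_skeleton_points(ph)$points),
                   2, range)
      dg <- make_dose_grid("uniform_box", grid_dim = dim(ct$hu),
                           spacing = ct$spacing, origin = ct$origin,
                           dose_gy = rx_gy,
                           box_lo = c(ext[1, 1:2] - 10,
                                      ext[1, 3] + 0.25 * diff(ext[, 3])),
                           box_hi = c(ext[2, 1:2] + 10,
                                      ext[1, 3] + 0.55 * diff(ext[, 3])))
      write_rt_dose(dg, file.path(sdir, "dose.dcm"), id = sid)
      plan <- make_plan(c(0.6, 0.4) * rx_gy,
                        isocenter = colMeans(ext),
                        plan_label = "PELVIS IMRT")
      write_rt_plan(plan_to_beam_df(plan), file.path(sdir, "plan.dcm"),
                    plan_label = plan$plan_label, id = sid)
      recorded <- plan$total_prescribed
      if (roles[p] == "mismatch" && s == 1L) {
        recorded <- recorded + if (p %% 2 == 0) 0.5 else -0.5
      }
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = pid, session_id = sid,
        ct_dir = file.path(sdir, "ct"),
        dose_file = file.path(sdir, "dose.dcm"),
        plan_file = file.path(sdir, "plan.dcm"),
        age = ages[p], sex = sexes[p], height = heights[p],
        weight = weights[p], recorded_dose = recorded,
        evaluator_1 = !bad, evaluator_2 = !bad,
        stringsAsFactors = FALSE
      )
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "cohort_manifest.csv"),
                   row.names = FALSE)
  list(
    dir = dir, manifest = manifest,
    truth = list(
      n_patients = n, n_sessions = nrow(manifest),
      n_mismatch = n_mismatch, n_badalign = n_badalign,
      mismatch_patients = unique(manifest$patient_id[
        abs(manifest$recorded_dose - rx_gy) > 0.1]),
      badalign_sessions = manifest$session_id[!manifest$evaluator_1]
    )
  )
}
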
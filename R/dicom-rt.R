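#' CT volume container
#'
#' @param hu 3-D array of Hounsfield units, dimension (nx, ny, nz), first
#'   index fastest along the patient x (L) axis.
#' @param spacing mm per axis (x, y, z).
#' @param origin mm position (LPS) of the center of voxel (1,1,1).
#' @param orientation Direction cosines of rows/columns (length 6);
#'   axis-aligned identity orientation is assumed throughout.
#' @return Object of class `ct_volume`.
#' @export
ct_volume <- function(hu, spacing, origin,
                      orientation = c(1, 0, 0, 0, 1, 0)) {
  stopifnot(length(dim(hu)) == 3L, length(spacing) == 3L,
            length(origin) == 3L)
  if (any(spacing <= 0)) stop("spacing must be positive", call. = FALSE)
  structure(list(hu = hu, spacing = as.numeric(spacing),
                 origin = as.numeric(origin),
                 orientation = as.numeric(orientation)),
            class = "ct_volume")
}

#' Dose grid container
#'
#' @param dose 3-D array in Gy, dimension (nx, ny, nz).
#' @param spacing,origin,orientation As in [ct_volume()].
#' @return Object of class `dose_grid`.
#' @export
dose_grid <- function(dose, spacing, origin,
                      orientation = c(1, 0, 0, 0, 1, 0)) {
  stopifnot(length(dim(dose)) == 3L)
  if (any(dose < 0)) stop("dose must be non-negative", call. = FALSE)
  if (any(spacing <= 0) || !all(is.finite(origin))) {
    stop("invalid dose grid geometry", call. = FALSE)
  }
  structure(list(dose = dose, spacing = as.numeric(spacing),
                 origin = as.numeric(origin),
                 orientation = as.numeric(orientation)),
            class = "dose_grid")
}

.SOP_CT <- "1.2.840.10008.5.1.4.1.1.2"
.SOP_RTDOSE <- "1.2.840.10008.5.1.4.1.1.481.2"
.SOP_RTPLAN <- "1.2.840.10008.5.1.4.1.1.481.5"
.IDENT_ORIENT <- c(1, 0, 0, 0, 1, 0)

# ---- CT series ----------------------------------------------------------

#' Write a CT volume as a DICOM series
#'
#' One explicit-VR little-endian CT image file per slice; HU values are
#' stored as signed 16-bit with rescale slope 1 / intercept 0.
#'
#' @param ct A [ct_volume()].
#' @param dir Output directory (created if needed).
#' @param id Series identifier folded into the generated UIDs.
#' @return Vector of file paths, invisibly.
#' @export
write_ct_series <- function(ct, dir, id = "1") {
  stopifnot(inherits(ct, "ct_volume"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  d <- dim(ct$hu)
  study_uid <- make_uid("7", id)
  series_uid <- make_uid("7", id, "1")
  paths <- character(d[3])
  for (k in seq_len(d[3])) {
    ipp <- c(ct$origin[1], ct$origin[2],
             ct$origin[3] + (k - 1) * ct$spacing[3])
    sop_uid <- make_uid("7", id, "1", as.character(k))
    slice <- as.integer(round(ct$hu[, , k]))  # x fastest = row-major rows
    elems <- list(
      el(0x0008, 0x0016, "UI", .SOP_CT),
      el(0x0008, 0x0018, "UI", sop_uid),
      el(0x0008, 0x0060, "CS", "CT"),
      el(0x0018, 0x0050, "DS", ct$spacing[3]),
      el(0x0020, 0x000D, "UI", study_uid),
      el(0x0020, 0x000E, "UI", series_uid),
      el(0x0020, 0x0013, "IS", k),
      el(0x0020, 0x0032, "DS", ipp),
      el(0x0020, 0x0037, "DS", .IDENT_ORIENT),
      el(0x0028, 0x0002, "US", 1),
      el(0x0028, 0x0004, "CS", "MONOCHROME2"),
      el(0x0028, 0x0010, "US", d[2]),           # Rows (y)
      el(0x0028, 0x0011, "US", d[1]),           # Columns (x)
      el(0x0028, 0x0030, "DS", c(ct$spacing[2], ct$spacing[1])),
      el(0x0028, 0x0100, "US", 16),
      el(0x0028, 0x0101, "US", 16),
      el(0x0028, 0x0102, "US", 15),
      el(0x0028, 0x0103, "US", 1),              # signed
      el(0x0028, 0x1052, "DS", 0),              # intercept
      el(0x0028, 0x1053, "DS", 1),              # slope
      el(0x7FE0, 0x0010, "OW", raw_i16(slice))
    )
    paths[k] <- file.path(dir, sprintf("ct_%03d.dcm", k))
    write_dicom_file(paths[k], .SOP_CT, sop_uid, elems)
  }
  invisible(paths)
}

#' Read a DICOM CT series into a volume
#'
#' Slices are assembled in order of their z position (not filename);
#' rescale slope and intercept are applied. A directory holding more than
#' one series, or a non-uniform z grid (missing slices), is rejected.
#'
#' @param dir Directory holding exactly one CT series (`*.dcm`).
#' @return A [ct_volume()].
#' @export
read_ct_series <- function(dir) {
  files <- list.files(dir, pattern = "\\.dcm$", full.names = TRUE)
  if (!length(files)) stop("no DICOM files in ", dir, call. = FALSE)
  slices <- lapply(files, read_dicom_file)
  mods <- vapply(slices, function(s) s[["0008,0060"]][1], "")
  slices <- slices[mods == "CT"]
  if (!length(slices)) stop("no CT images in ", dir, call. = FALSE)
  series <- vapply(slices, function(s) s[["0020,000E"]][1], "")
  if (length(unique(series)) > 1L) {
    stop("directory holds more than one CT series", call. = FALSE)
  }
  z <- vapply(slices, function(s) s[["0020,0032"]][3], 0)
  ord <- order(z)
  slices <- slices[ord]; z <- z[ord]
  if (length(z) > 1L) {
    dz <- diff(z)
    if (any(abs(dz - dz[1]) > 1e-6 * max(abs(dz[1]), 1))) {
      stop("non-uniform slice spacing (missing slices?)", call. = FALSE)
    }
  }
  s1 <- slices[[1]]
  nx <- s1[["0028,0011"]]; ny <- s1[["0028,0010"]]
  ps <- s1[["0028,0030"]]  # (row = y, col = x)
  dz <- if (length(z) > 1L) diff(z)[1] else s1[["0018,0050"]]
  hu <- array(0, dim = c(nx, ny, length(slices)))
  for (k in seq_along(slices)) {
    s <- slices[[k]]
    slope <- if (!is.null(s[["0028,1053"]])) s[["0028,1053"]] else 1
    intercept <- if (!is.null(s[["0028,1052"]])) s[["0028,1052"]] else 0
    v <- rd_i16(s[["7FE0,0010"]])
    hu[, , k] <- array(v * slope + intercept, dim = c(nx, ny))
  }
  ct_volume(hu, spacing = c(ps[2], ps[1], dz),
            origin = s1[["0020,0032"]],
            orientation = s1[["0020,0037"]])
}

# ---- RT-dose ------------------------------------------------------------

#' Write a dose grid as a DICOM RT-dose object
#'
#' Dose is stored as unsigned 32-bit multiframe pixel data with a
#' dose-grid-scaling factor.
#'
#' @param dg A [dose_grid()].
#' @param path Output file.
#' @param scaling Dose grid scaling (Gy per stored unit). Default scales
#'   the maximum dose to near the top of the representable range.
#' @param id Identifier folded into generated UIDs.
#' @return `path`, invisibly.
#' @export
write_rt_dose <- function(dg, path, scaling = NULL, id = "1") {
  stopifnot(inherits(dg, "dose_grid"))
  d <- dim(dg$dose)
  maxd <- max(dg$dose)
  if (is.null(scaling)) {
    scaling <- if (maxd > 0) maxd / 2^30 else 1e-6
  }
  stored <- round(dg$dose / scaling)
  if (any(stored > 4294967295)) stop("dose exceeds stored range", call. = FALSE)
  sop_uid <- make_uid("8", id)
  elems <- list(
    el(0x0008, 0x0016, "UI", .SOP_RTDOSE),
    el(0x0008, 0x0018, "UI", sop_uid),
    el(0x0008, 0x0060, "CS", "RTDOSE"),
    el(0x0020, 0x000D, "UI", make_uid("7", id)),
    el(0x0020, 0x000E, "UI", make_uid("8", id, "1")),
    el(0x0020, 0x0032, "DS", dg$origin),
    el(0x0020, 0x0037, "DS", .IDENT_ORIENT),
    el(0x0028, 0x0002, "US", 1),
    el(0x0028, 0x0004, "CS", "MONOCHROME2"),
    el(0x0028, 0x0008, "IS", d[3]),
    el(0x0028, 0x0010, "US", d[2]),
    el(0x0028, 0x0011, "US", d[1]),
    el(0x0028, 0x0030, "DS", c(dg$spacing[2], dg$spacing[1])),
    el(0x0028, 0x0100, "US", 32),
    el(0x0028, 0x0101, "US", 32),
    el(0x0028, 0x0102, "US", 31),
    el(0x0028, 0x0103, "US", 0),
    el(0x3004, 0x0002, "CS", "GY"),
    el(0x3004, 0x0004, "CS", "PHYSICAL"),
    el(0x3004, 0x000A, "CS", "PLAN"),
    el(0x3004, 0x000C, "DS", (seq_len(d[3]) - 1) * dg$spacing[3]),
    el(0x3004, 0x000E, "DS", scaling),
    el(0x7FE0, 0x0010, "OW", raw_u32(as.vector(stored)))
  )
  write_dicom_file(path, .SOP_RTDOSE, sop_uid, elems)
  invisible(path)
}

#' Read a DICOM RT-dose object
#'
#' Stored values are multiplied by the dose-grid-scaling factor at read
#' time, giving Gy. A missing scaling attribute or a negative resulting
#' dose is an error.
#'
#' @param file Path to an RT-dose file.
#' @return A [dose_grid()].
#' @export
read_rt_dose <- function(file) {
  ds <- read_dicom_file(file)
  if (!identical(ds[["0008,0060"]][1], "RTDOSE")) {
    stop("not an RT-dose object: ", file, call. = FALSE)
  }
  scaling <- ds[["3004,000E"]]
  if (is.null(scaling)) {
    stop("RT-dose missing dose-grid-scaling attribute", call. = FALSE)
  }
  nx <- ds[["0028,0011"]]; ny <- ds[["0028,0010"]]
  nz <- ds[["0028,0008"]]
  offsets <- ds[["3004,000C"]]
  dz <- if (length(offsets) > 1L) {
    dd <- diff(offsets)
    if (any(abs(dd - dd[1]) > 1e-6)) {
      stop("non-uniform dose frame offsets", call. = FALSE)
    }
    dd[1]
  } else 1
  ps <- ds[["0028,0030"]]
  stored <- rd_u32(ds[["7FE0,0010"]])
  dose <- array(stored * scaling, dim = c(nx, ny, nz))
  if (any(dose < 0)) stop("negative dose in RT-dose object", call. = FALSE)
  dose_grid(dose, spacing = c(ps[2], ps[1], dz),
            origin = ds[["0020,0032"]],
            orientation = ds[["0020,0037"]])
}

# ---- RT-plan ------------------------------------------------------------

#' Write a DICOM RT-plan object
#'
#' @param beams Data frame with columns `label`, `dose` (Gy per beam) and
#'   isocenter columns `iso_x`, `iso_y`, `iso_z` (mm). May have zero rows
#'   when `target_prescription` carries the plan dose instead.
#' @param path Output file.
#' @param plan_label Plan label string.
#' @param target_prescription Optional total prescription (Gy) written to
#'   the dose-reference sequence (used as the fallback dose source by
#'   [read_rt_plan()] when beams carry no dose).
#' @param id Identifier folded into generated UIDs.
#' @return `path`, invisibly.
#' @export
write_rt_plan <- function(beams, path, plan_label = "PLAN",
                          target_prescription = NULL, id = "1") {
  beams <- as.data.frame(beams)
  sop_uid <- make_uid("9", id)
  nb <- nrow(beams)
  ref_items <- lapply(seq_len(nb), function(i) {
    encode_dataset(list(
      el(0x300A, 0x0084, "DS", beams$dose[i]),
      el(0x300C, 0x0006, "IS", i)
    ))
  })
  fg_item <- encode_dataset(list(
    el(0x300A, 0x0078, "IS", 1),
    el(0x300C, 0x0004, "SQ", ref_items)
  ))
  beam_items <- lapply(seq_len(nb), function(i) {
    cp_item <- encode_dataset(list(
      el(0x300A, 0x012C, "DS",
         c(beams$iso_x[i], beams$iso_y[i], beams$iso_z[i]))
    ))
    encode_dataset(list(
      el(0x300A, 0x00C0, "IS", i),
      el(0x300A, 0x00C2, "LO", beams$label[i]),
      el(0x300A, 0x0111, "SQ", list(cp_item))
    ))
  })
  elems <- list(
    el(0x0008, 0x0016, "UI", .SOP_RTPLAN),
    el(0x0008, 0x0018, "UI", sop_uid),
    el(0x0008, 0x0060, "CS", "RTPLAN"),
    el(0x0020, 0x000D, "UI", make_uid("7", id)),
    el(0x0020, 0x000E, "UI", make_uid("9", id, "1")),
    el(0x300A, 0x0002, "SH", plan_label)
  )
  if (!is.null(target_prescription)) {
    dr_item <- encode_dataset(list(
      el(0x300A, 0x0026, "DS", target_prescription)
    ))
    elems <- c(elems, list(el(0x300A, 0x0010, "SQ", list(dr_item))))
  }
  elems <- c(elems, list(el(0x300A, 0x0070, "SQ", list(fg_item))))
  if (nb > 0) {
    elems <- c(elems, list(el(0x300A, 0x00B0, "SQ", beam_items)))
  }
  write_dicom_file(path, .SOP_RTPLAN, sop_uid, elems)
  invisible(path)
}

#' Read a DICOM RT-plan object
#'
#' Extracts the per-beam prescribed dose from the fraction group's
#' referenced-beam sequence and each beam's isocenter from its first
#' control point. The total prescribed dose is the exact sum of the
#' per-beam doses. When no beam carries a dose attribute, the target
#' prescription dose from the dose-reference sequence is used instead and
#' the result is flagged (`dose_source = "dose_reference"`).
#'
#' @param file Path to an RT-plan file.
#' @return Object of class `plan_summary`: `beams` (data frame `label`,
#'   `prescribed_dose`, `iso_x`, `iso_y`, `iso_z`), `total_prescribed`,
#'   `plan_label`, `dose_source`.
#' @export
read_rt_plan <- function(file) {
  ds <- read_dicom_file(file)
  if (!identical(ds[["0008,0060"]][1], "RTPLAN")) {
    stop("not an RT-plan object: ", file, call. = FALSE)
  }
  plan_label <- if (!is.null(ds[["300A,0002"]])) ds[["300A,0002"]][1] else ""
  # beam metadata (names, isocenters) keyed by beam number
  beam_meta <- list()
  for (b in ds[["300A,00B0"]]) {
    num <- b[["300A,00C0"]]
    iso <- c(NA_real_, NA_real_, NA_real_)
    cps <- b[["300A,0111"]]
    if (length(cps) && !is.null(cps[[1]][["300A,012C"]])) {
      iso <- cps[[1]][["300A,012C"]]
    }
    beam_meta[[as.character(num)]] <-
      list(label = if (!is.null(b[["300A,00C2"]])) b[["300A,00C2"]][1] else
             paste0("beam", num), iso = iso)
  }
  beams <- data.frame(label = character(), prescribed_dose = numeric(),
                      iso_x = numeric(), iso_y = numeric(),
                      iso_z = numeric(), stringsAsFactors = FALSE)
  for (fg in ds[["300A,0070"]]) {
    for (rb in fg[["300C,0004"]]) {
      dose <- rb[["300A,0084"]]
      if (is.null(dose)) next
      num <- as.character(rb[["300C,0006"]])
      meta <- beam_meta[[num]]
      if (is.null(meta)) meta <- list(label = paste0("beam", num),
                                      iso = c(NA, NA, NA))
      beams[nrow(beams) + 1L, ] <- list(meta$label, dose, meta$iso[1],
                                        meta$iso[2], meta$iso[3])
    }
  }
  dose_source <- "beams"
  if (!nrow(beams)) {
    rx <- NULL
    for (dr in ds[["300A,0010"]]) {
      if (!is.null(dr[["300A,0026"]])) rx <- dr[["300A,0026"]]
    }
    if (is.null(rx)) {
      stop("RT-plan carries no dose attributes", call. = FALSE)
    }
    total <- rx
    dose_source <- "dose_reference"
  } else {
    total <- sum(beams$prescribed_dose)
  }
  structure(
    list(beams = beams, total_prescribed = total, plan_label = plan_label,
         dose_source = dose_source),
    class = "plan_summary"
  )
}

#' @export
print.plan_summary <- function(x, ...) {
  cat(sprintf("RT plan '%s': %d beam(s), total prescribed %.4g Gy (%s)\n",
              x$plan_label, nrow(x$beams), x$total_prescribed,
              x$dose_source))
  invisible(x)
}

# ---- record-completeness filter ----------------------------------------

#' Check plan dose against the recorded delivered dose
#'
#' The extracted total prescribed dose is compared against the delivered
#' dose recorded in the cohort database; a record whose absolute mismatch
#' exceeds 0.1 Gy is rejected as incomplete (a mismatch of exactly the
#' threshold is accepted). The direction of the mismatch is reported.
#'
#' @param plan A `plan_summary` from [read_rt_plan()].
#' @param chars A [patient_characteristics()] with
#'   `recorded_delivered_dose`.
#' @param threshold Mismatch tolerance in Gy.
#' @return List: `decision` (`"accept"`/`"reject"`), `mismatch` (Gy),
#'   `direction` (`"match"`, `"plan-low"`, `"plan-high"`, `"missing"`).
#' @export
check_dose_consistency <- function(plan, chars, threshold = 0.1) {
  stopifnot(inherits(plan, "plan_summary"))
  rec <- chars$recorded_delivered_dose
  if (is.null(rec) || is.na(rec)) {
    return(list(decision = "reject", mismatch = NA_real_,
                direction = "missing", reason = "missing record"))
  }
  mismatch <- abs(plan$total_prescribed - rec)
  direction <- if (plan$total_prescribed < rec - 1e-12) "plan-low"
    else if (plan$total_prescribed > rec + 1e-12) "plan-high"
    else "match"
  # strict-greater rule with a float grace so a mismatch of exactly the
  # threshold is accepted regardless of decimal representation error
  over <- mismatch > threshold + 1e-9
  list(
    decision = if (over) "reject" else "accept",
    mismatch = mismatch,
    direction = direction,
    reason = if (over) {
      sprintf("prescribed/recorded dose mismatch %.3g Gy", mismatch)
    } else NA_character_
  )
}

# ---- treatment-region categorization (configurable stub) ----------------

#' Default plan-label keyword map for treatment regions
#'
#' @return Named character vector: keyword (matched case-insensitively
#'   against the plan label, first hit wins) -> region label.
#' @export
default_region_keywords <- function() {
  c("pelvis" = "pelvic", "pelvic" = "pelvic", "prostate" = "pelvic",
    "breast" = "breast", "brain" = "intracranial",
    "cranial" = "intracranial", "spine" = "spine", "vertebra" = "spine",
    "head" = "head-and-neck", "neck" = "head-and-neck",
    "lung" = "thoracic", "chest" = "thoracic", "thorax" = "thoracic",
    "abdomen" = "abdominal", "abdominal" = "abdominal",
    "liver" = "abdominal", "femur" = "extremities", "arm" = "extremities",
    "leg" = "extremities", "hip" = "bone-pelvic", "rib" = "bone-thoracic")
}

#' Categorize the treatment region of a plan
#'
#' First keyword hit on the plan label wins; otherwise the isocenter z
#' position is banded as a fraction of the matched phantom's cranio-caudal
#' extent (0 = most inferior, 1 = most superior). A plan matching neither
#' is labelled `"uncategorized"`. This is a configurable classification
#' aid, not a clinical taxonomy.
#'
#' @param plan A `plan_summary`.
#' @param isocenter Length-3 mm isocenter (defaults to the first beam's).
#' @param keywords Named vector keyword -> region
#'   (see [default_region_keywords()]).
#' @param z_extent Optional length-2 mm range (inferior, superior) of the
#'   registered phantom skeleton along z; enables the positional fallback.
#' @param bands Data frame `lo`, `hi`, `region` of fractional z bands.
#' @return Region label (character scalar).
#' @export
categorize_treatment_region <- function(plan, isocenter = NULL,
                                        keywords = default_region_keywords(),
                                        z_extent = NULL,
                                        bands = default_region_bands()) {
  stopifnot(inherits(plan, "plan_summary"))
  label <- tolower(plan$plan_label)
  for (i in seq_along(keywords)) {
    if (grepl(names(keywords)[i], label, fixed = TRUE)) {
      return(unname(keywords[i]))
    }
  }
  if (is.null(isocenter) && nrow(plan$beams)) {
    isocenter <- c(plan$beams$iso_x[1], plan$beams$iso_y[1],
                   plan$beams$iso_z[1])
  }
  if (!is.null(isocenter) && !is.null(z_extent) &&
      all(is.finite(isocenter))) {
    frac <- (isocenter[3] - z_extent[1]) / diff(z_extent)
    if (is.finite(frac) && frac >= 0 && frac <= 1) {
      hit <- which(frac >= bands$lo & frac <= bands$hi)
      if (length(hit)) return(bands$region[hit[1]])
    }
  }
  "uncategorized"
}

#' Default fractional cranio-caudal bands for the positional fallback
#'
#' @return Data frame with columns `lo`, `hi` (fractions of the phantom
#'   extent measured from the inferior end) and `region`.
#' @export
default_region_bands <- function() {
  data.frame(
    lo = c(0.90, 0.80, 0.55, 0.42, 0.25, 0.00),
    hi = c(1.00, 0.90, 0.80, 0.55, 0.42, 0.25),
    region = c("intracranial", "head-and-neck", "thoracic", "abdominal",
               "pelvic", "extremities"),
    stringsAsFactors = FALSE
  )
}
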
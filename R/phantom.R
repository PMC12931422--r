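#' Tissue subtype codes used in phantom tissue rasters
#'
#' Integer codes: 0 none, 1 cortical bone, 2 trabecular spongiosa,
#' 3 medullary cavity.
#'
#' @return Named integer vector of the codes.
#' @export
tissue_codes <- function() {
  c(none = 0L, cortical = 1L, spongiosa = 2L, medullary_cavity = 3L)
}

#' Construct a labeled voxel phantom
#'
#' A phantom couples two co-registered integer rasters on the same grid:
#' `label_volume` assigns each voxel a bone-site id (0 = non-bone) and
#' `tissue_volume` a tissue subtype (0 none, 1 cortical, 2 spongiosa,
#' 3 medullary cavity). `site_map` names each site id with one of the 34
#' reference site names; body metadata (age, sex, height, weight) drives
#' phantom selection and the marrow-fraction lookup.
#'
#' @param label_volume 3-D integer array of bone-site ids (0 = non-bone).
#' @param tissue_volume 3-D integer array of tissue codes, same shape.
#' @param spacing mm per axis (length 3, positive).
#' @param origin mm coordinate of the center of voxel (1,1,1) in the
#'   phantom frame.
#' @param site_map Named integer vector mapping site name -> site id; the
#'   names must be reference site names (see [abm_site_names()]).
#' @param meta List with `age_years`, `sex` ("F"/"M"), `height_cm`,
#'   `weight_kg`, `id`.
#' @return An object of class `phantom`.
#' @export
phantom <- function(label_volume, tissue_volume, spacing, origin,
                    site_map, meta) {
  label_volume <- array(as.integer(label_volume), dim = dim(label_volume))
  tissue_volume <- array(as.integer(tissue_volume), dim = dim(tissue_volume))
  if (!identical(dim(label_volume), dim(tissue_volume))) {
    stop("label and tissue rasters differ in shape", call. = FALSE)
  }
  spacing <- as.numeric(spacing); origin <- as.numeric(origin)
  stopifnot(length(spacing) == 3L, length(origin) == 3L)
  if (any(spacing <= 0)) stop("spacing must be strictly positive", call. = FALSE)
  known <- tolower(abm_site_names())
  bad <- setdiff(tolower(names(site_map)), known)
  if (length(bad)) {
    stop("unknown bone site name(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  site_map <- stats::setNames(as.integer(site_map), names(site_map))
  if (anyDuplicated(site_map)) stop("duplicate site ids", call. = FALSE)
  used <- sort(unique(as.vector(label_volume[label_volume > 0L])))
  if (!all(used %in% site_map)) {
    stop("label raster contains ids missing from site_map", call. = FALSE)
  }
  # bone <-> tissue consistency: tissue != none iff site id > 0
  if (any((label_volume > 0L) != (tissue_volume > 0L))) {
    stop("bone-site labels and tissue subtypes disagree on bone voxels",
         call. = FALSE)
  }
  need <- c("age_years", "sex", "height_cm", "weight_kg", "id")
  miss <- setdiff(need, names(meta))
  if (length(miss)) {
    stop("phantom metadata missing: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  meta$sex <- match.arg(toupper(meta$sex), c("F", "M"))
  structure(
    list(label_volume = label_volume, tissue_volume = tissue_volume,
         spacing = spacing, origin = origin, site_map = site_map,
         meta = meta),
    class = "phantom"
  )
}

#' @export
print.phantom <- function(x, ...) {
  nb <- sum(x$label_volume > 0L)
  cat(sprintf("Voxel phantom '%s' (%s, %.3g y, %.3g cm, %.3g kg)\n",
              x$meta$id, x$meta$sex, x$meta$age_years,
              x$meta$height_cm, x$meta$weight_kg))
  cat(sprintf("  grid %s, spacing %s mm\n",
              paste(dim(x$label_volume), collapse = "x"),
              paste(format(x$spacing), collapse = "x")))
  cat(sprintf("  %d bone voxels over %d sites\n", nb, length(x$site_map)))
  invisible(x)
}

#' Write a phantom to its on-disk container
#'
#' The container is three sibling files: `<name>.labels.nrrd` and
#' `<name>.tissue.nrrd` (ascii-encoded rasters, x fastest) plus a
#' `<name>.meta.json` sidecar holding `age_years`, `sex`, `height_cm`,
#' `weight_kg`, `id` and `site_name_map`.
#'
#' @param ph A [phantom()].
#' @param path Base path without extension (e.g. `"dir/mini30M"`).
#' @return `path`, invisibly.
#' @export
save_phantom <- function(ph, path) {
  stopifnot(inherits(ph, "phantom"))
  write_nrrd(ph$label_volume, paste0(path, ".labels.nrrd"),
             ph$spacing, ph$origin)
  write_nrrd(ph$tissue_volume, paste0(path, ".tissue.nrrd"),
             ph$spacing, ph$origin)
  meta <- ph$meta
  meta$site_name_map <- as.list(ph$site_map)
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Load a phantom from its on-disk container
#'
#' @param path Base path of a container written by [save_phantom()]
#'   (without the `.labels.nrrd` etc. extensions).
#' @return A [phantom()].
#' @export
load_phantom <- function(path) {
  labf <- paste0(path, ".labels.nrrd")
  tisf <- paste0(path, ".tissue.nrrd")
  metf <- paste0(path, ".meta.json")
  for (f in c(labf, tisf, metf)) {
    if (!file.exists(f)) stop("missing container file: ", f, call. = FALSE)
  }
  lab <- read_nrrd(labf)
  tis <- read_nrrd(tisf)
  if (!identical(dim(lab$data), dim(tis$data))) {
    stop("label and tissue rasters differ in shape", call. = FALSE)
  }
  meta <- jsonlite::read_json(metf, simplifyVector = TRUE)
  if (is.null(meta$site_name_map)) {
    stop("metadata missing site_name_map", call. = FALSE)
  }
  site_map <- unlist(meta$site_name_map)
  meta$site_name_map <- NULL
  phantom(lab$data, tis$data, lab$spacing, lab$origin, site_map,
          meta = as.list(meta))
}

#' Patient characteristics record
#'
#' @param age Age in years at treatment (non-negative).
#' @param sex `"F"` or `"M"`.
#' @param height Height in cm (may be `NA`).
#' @param weight Weight in kg (may be `NA`).
#' @param recorded_delivered_dose Total delivered dose in Gy from the
#'   cohort record (may be `NA`; flagged downstream).
#' @return An object of class `patient_characteristics`.
#' @export
patient_characteristics <- function(age, sex, height = NA_real_,
                                    weight = NA_real_,
                                    recorded_delivered_dose = NA_real_) {
  stopifnot(is.numeric(age), length(age) == 1L)
  if (is.na(age) || age < 0) stop("age must be >= 0", call. = FALSE)
  sex <- match.arg(toupper(sex), c("F", "M"))
  if (!is.na(height) && height <= 0) stop("height must be > 0", call. = FALSE)
  if (!is.na(weight) && weight <= 0) stop("weight must be > 0", call. = FALSE)
  structure(
    list(age = as.numeric(age), sex = sex, height = as.numeric(height),
         weight = as.numeric(weight),
         recorded_delivered_dose = as.numeric(recorded_delivered_dose)),
    class = "patient_characteristics"
  )
}

#' Select the closest-matching phantom from a library
#'
#' Strict lexicographic match with priority age > sex > height > weight:
#' candidates minimising |age difference| are kept first; among those,
#' same-sex candidates are kept if any exists (otherwise selection
#' proceeds opposite-sex and is flagged); then |height difference|, then
#' |weight difference| are minimised in turn. Remaining ties go to the
#' smallest phantom id, making selection deterministic. A missing patient
#' height or weight skips that tier.
#'
#' @param chars A [patient_characteristics()].
#' @param library Data frame with columns `id`, `age`, `sex`, `height`,
#'   `weight` (one row per available phantom).
#' @return List with `id` (selected phantom id), `sex_mismatch` flag.
#' @export
select_phantom <- function(chars, library) {
  stopifnot(inherits(chars, "patient_characteristics"))
  library <- as.data.frame(library)
  if (!nrow(library)) stop("phantom library is empty", call. = FALSE)
  need <- c("id", "age", "sex", "height", "weight")
  miss <- setdiff(need, names(library))
  if (length(miss)) {
    stop("library missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  cand <- library
  d_age <- abs(cand$age - chars$age)
  cand <- cand[d_age == min(d_age), , drop = FALSE]
  sex_mismatch <- FALSE
  if (any(cand$sex == chars$sex)) {
    cand <- cand[cand$sex == chars$sex, , drop = FALSE]
  } else {
    sex_mismatch <- TRUE
  }
  if (!is.na(chars$height)) {
    d_h <- abs(cand$height - chars$height)
    cand <- cand[d_h == min(d_h), , drop = FALSE]
  }
  if (!is.na(chars$weight)) {
    d_w <- abs(cand$weight - chars$weight)
    cand <- cand[d_w == min(d_w), , drop = FALSE]
  }
  cand <- cand[order(cand$id), , drop = FALSE]
  list(id = cand$id[1], sex_mismatch = sex_mismatch)
}

#' Voxel indices belonging to one bone site
#'
#' @param ph A [phantom()].
#' @param site Site name (case-insensitive) or site id.
#' @param exclude_cortical If `TRUE`, return only trabecular-spongiosa and
#'   medullary-cavity voxels (the marrow-bearing subset).
#' @return Integer N x 3 matrix of 1-based voxel indices.
#' @export
bone_site_voxels <- function(ph, site, exclude_cortical = FALSE) {
  stopifnot(inherits(ph, "phantom"))
  id <- if (is.character(site)) {
    i <- match(tolower(site), tolower(names(ph$site_map)))
    if (is.na(i)) stop("site not present in phantom: ", site, call. = FALSE)
    ph$site_map[[i]]
  } else {
    site <- as.integer(site)
    if (!site %in% ph$site_map) {
      stop("site id not present in phantom: ", site, call. = FALSE)
    }
    site
  }
  keep <- ph$label_volume == id
  if (exclude_cortical) {
    keep <- keep & ph$tissue_volume != tissue_codes()[["cortical"]]
  }
  which(keep, arr.ind = TRUE, useNames = FALSE)
}

#' All bone voxels of a phantom as phantom-frame points
#'
#' Every voxel with a bone-site label (all tissue subtypes) is returned as
#' the mm coordinate of its center in the phantom frame.
#'
#' @param ph A [phantom()].
#' @return List of class `skeleton_points` with `points` (N x 3 mm),
#'   `voxel_index` (N x 3, 1-based) and `frame = "phantom"`.
#' @export
phantom_skeleton_points <- function(ph) {
  stopifnot(inherits(ph, "phantom"))
  idx <- which(ph$label_volume > 0L, arr.ind = TRUE, useNames = FALSE)
  if (!nrow(idx)) stop("phantom contains no bone voxels", call. = FALSE)
  skeleton_points(voxel_to_world(idx, ph$spacing, ph$origin),
                  voxel_index = idx, frame = "phantom")
}
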
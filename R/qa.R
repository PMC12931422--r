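#' Volume overlap fraction between patient and phantom skeletons
#'
#' VOF = |S_patient intersect S_phantom| / |S_patient| x 100, where
#' S_patient is the set of patient skeletal voxel indices and S_phantom
#' the set of patient-grid voxels hit by the registered phantom skeleton
#' (each transformed phantom point snapped to its nearest voxel center;
#' duplicate hits collapse to a set). The score is asymmetric: the
#' denominator is always the patient set. Higher is better; the score is
#' reported for review and cohort comparison, never used as an automatic
#' acceptance cutoff, because a low overlap does not necessarily imply a
#' poor dose estimate (thin bones misalign geometrically while remaining
#' close; in-field bones see near-uniform dose).
#'
#' @param patient_voxels N x 3 integer matrix of 1-based patient-grid
#'   voxel indices (e.g. `skeleton_points$voxel_index`).
#' @param phantom_points M x 3 mm points already transformed into the
#'   patient frame.
#' @param spacing,origin Patient CT grid geometry.
#' @param dim Optional grid dimension; phantom hits outside it (or any
#'   non-positive snapped index) fall outside every patient voxel and
#'   simply do not intersect.
#' @return VOF in percent (scalar in `[0, 100]`).
#' @export
compute_vof <- function(patient_voxels, phantom_points, spacing, origin,
                        dim = NULL) {
  if (is.null(nrow(patient_voxels)) || nrow(patient_voxels) == 0L) {
    stop("patient voxel set is empty", call. = FALSE)
  }
  patient_voxels <- matrix(as.integer(as.matrix(patient_voxels)), ncol = 3)
  idx <- round(world_to_voxel(phantom_points, spacing, origin))
  key <- function(m) paste(m[, 1], m[, 2], m[, 3])
  s_pat <- unique(key(patient_voxels))
  s_pha <- unique(key(idx))
  100 * length(intersect(s_pat, s_pha)) / length(s_pat)
}

#' Render a patient/phantom skeletal overlay image
#'
#' Writes a deterministic PNG with three orthographic projections
#' (axial, coronal, sagittal) of the two point clouds: patient skeleton in
#' purple, registered phantom skeleton in green, overlap additive. Fixed
#' canvas, no timestamps, so identical inputs give byte-identical files.
#'
#' @param patient_points N x 3 mm patient skeletal points.
#' @param phantom_points M x 3 mm phantom points in the patient frame.
#' @param out_path Output PNG path.
#' @param px Canvas edge length in pixels per panel.
#' @return `out_path`, invisibly.
#' @export
render_overlay <- function(patient_points, phantom_points, out_path,
                           px = 220L) {
  if (is.null(nrow(patient_points)) || nrow(patient_points) == 0L ||
      is.null(nrow(phantom_points)) || nrow(phantom_points) == 0L) {
    stop("both point sets must be non-empty", call. = FALSE)
  }
  pat <- as.matrix(patient_points); pha <- as.matrix(phantom_points)
  all_pts <- rbind(pat, pha)
  lo <- apply(all_pts, 2, min); hi <- apply(all_pts, 2, max)
  span <- pmax(hi - lo, 1e-6)
  # panel projections: axial (x,y), coronal (x,z), sagittal (y,z)
  proj <- list(c(1L, 2L), c(1L, 3L), c(2L, 3L))
  img <- array(1, dim = c(px, 3L * px, 3L))  # white canvas, RGB
  splat <- function(pts, panel, rgb_mask) {
    ax <- proj[[panel]]
    u <- pmin(px, pmax(1L, 1L + floor((pts[, ax[1]] - lo[ax[1]]) /
                                        span[ax[1]] * (px - 1L))))
    v <- pmin(px, pmax(1L, 1L + floor((pts[, ax[2]] - lo[ax[2]]) /
                                        span[ax[2]] * (px - 1L))))
    col_off <- (panel - 1L) * px
    for (ch in 1:3) {
      if (rgb_mask[ch] == 0) next
      # darken the suppressed channels at hit pixels
      lin <- cbind(px + 1L - v, col_off + u, ch)
      img[lin] <<- img[lin] * 0
    }
    invisible(NULL)
  }
  for (panel in 1:3) {
    splat(pat, panel, c(0, 1, 0))  # kill green  -> purple (R+B survive)
    splat(pha, panel, c(1, 0, 1))  # kill red+blue -> green
  }
  png::writePNG(img, out_path)
  invisible(out_path)
}

#' Record a two-evaluator registration review
#'
#' A registration is accepted only if both independent evaluators accept
#' it; a single rejection excludes the session. The VOF is stored
#' alongside for cohort comparison but carries no automatic cutoff.
#'
#' @param vof VOF in percent.
#' @param evaluator_1,evaluator_2 Logical review flags.
#' @param overlay_path Optional path of the reviewed overlay image.
#' @param session_id Optional session identifier.
#' @return Object of class `qa_record`: `vof`, `review_flags`, `accepted`,
#'   `overlay_path`, `session_id`.
#' @export
record_review <- function(vof, evaluator_1, evaluator_2,
                          overlay_path = NA_character_,
                          session_id = NA_character_) {
  stopifnot(is.numeric(vof), vof >= 0, vof <= 100,
            is.logical(evaluator_1), is.logical(evaluator_2))
  structure(
    list(vof = vof,
         review_flags = c(evaluator_1 = evaluator_1,
                          evaluator_2 = evaluator_2),
         accepted = evaluator_1 && evaluator_2,
         overlay_path = overlay_path, session_id = session_id),
    class = "qa_record"
  )
}

#' @export
print.qa_record <- function(x, ...) {
  cat(sprintf("QA record%s: VOF %.1f%%, evaluators (%s, %s) -> %s\n",
              if (is.na(x$session_id)) "" else paste0(" ", x$session_id),
              x$vof, x$review_flags[1], x$review_flags[2],
              if (x$accepted) "accepted" else "rejected"))
  invisible(x)
}

#' Rank correlation between VOF and patient characteristics
#'
#' Screens the accepted registrations for systematic bias: Spearman's
#' rank-order correlation (average ranks at ties) between the VOF score
#' and each patient characteristic, with a two-sided p value from the
#' large-sample t approximation. Sex is coded 0/1 (rank correlation
#' remains meaningful for binary covariates). A constant characteristic
#' has no defined correlation and is reported as missing.
#'
#' @param vof_scores Numeric vector of VOF scores (accepted sessions).
#' @param characteristics Data frame with columns among `age`, `sex`
#'   (`"F"`/`"M"` or 0/1), `height`, `weight`; one row per score.
#' @return Data frame: `characteristic`, `rho`, `p`, `n`.
#' @export
vof_association <- function(vof_scores, characteristics) {
  characteristics <- as.data.frame(characteristics)
  n <- length(vof_scores)
  if (n < 3L) stop("need at least 3 accepted records", call. = FALSE)
  stopifnot(nrow(characteristics) == n)
  res <- lapply(names(characteristics), function(nm) {
    x <- characteristics[[nm]]
    if (is.character(x) || is.factor(x)) {
      x <- as.numeric(factor(x, levels = sort(unique(as.character(x))))) - 1
    }
    ok <- is.finite(x) & is.finite(vof_scores)
    x <- x[ok]; y <- vof_scores[ok]
    m <- length(x)
    if (m < 3L || length(unique(x)) < 2L || length(unique(y)) < 2L) {
      return(data.frame(characteristic = nm, rho = NA_real_, p = NA_real_,
                        n = m))
    }
    rho <- stats::cor(rank(x), rank(y))
    tt <- rho * sqrt((m - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tt), df = m - 2)
    data.frame(characteristic = nm, rho = rho, p = p, n = m)
  })
  do.call(rbind, res)
}

#' Patient-level inclusion from per-session reviews
#'
#' A patient enters the analytical population only if every one of their
#' treatment sessions passed review; one rejected session excludes the
#' patient and drops all of their sessions.
#'
#' @param records List of `qa_record` objects (see [record_review()]).
#' @param patient_ids Character/numeric vector assigning each record to a
#'   patient.
#' @return Data frame: `patient_id`, `n_sessions`, `n_accepted`,
#'   `included`.
#' @export
session_acceptance_rollup <- function(records, patient_ids) {
  stopifnot(length(records) == length(patient_ids))
  acc <- vapply(records, function(r) r$accepted, NA)
  ids <- as.character(patient_ids)
  out <- lapply(unique(ids), function(p) {
    sel <- ids == p
    data.frame(patient_id = p, n_sessions = sum(sel),
               n_accepted = sum(acc[sel]), included = all(acc[sel]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Write per-session QA records as CSV
#'
#' @param records List of `qa_record` objects.
#' @param path Output CSV path.
#' @return The data frame written, invisibly.
#' @export
write_qa_csv <- function(records, path) {
  df <- do.call(rbind, lapply(records, function(r) {
    data.frame(session_id = r$session_id, vof_percent = r$vof,
               evaluator_1 = r$review_flags[[1]],
               evaluator_2 = r$review_flags[[2]],
               accepted = r$accepted, overlay_path = r$overlay_path,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
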
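#' Distribute active-marrow fractions over a phantom's bone voxels
#'
#' For each bone site present in the phantom, the site's marrow fraction
#' (looked up for the patient's age and sex) is divided homogeneously over
#' that site's non-cortical voxels (trabecular spongiosa and medullary
#' cavity); cortical voxels carry weight 0. Voxel positions are mapped
#' into the patient frame with the registration transform. Sites whose
#' marrow fraction is zero at the reference age contribute no weight and
#' are dropped from the sample.
#'
#' @param ph The registered [phantom()].
#' @param transform [rigid_transform()] from the accepted registration
#'   (phantom -> patient frame).
#' @param age,sex Patient age (years) and sex for the fraction lookup.
#' @return Object of class `abm_sample`: `points` (N x 3 mm, patient
#'   frame), `weight` (fraction of total active marrow per voxel), `site`,
#'   `voxel_index`, `dose` (NULL until [sample_dose()]), `phantom_id`,
#'   `total_fraction` (sum of site fractions represented).
#' @export
assign_voxel_weights <- function(ph, transform, age, sex) {
  stopifnot(inherits(ph, "phantom"), inherits(transform, "rigid_transform"))
  pts <- NULL; wts <- NULL; sites <- NULL; vox <- NULL
  total_fraction <- 0
  for (nm in names(ph$site_map)) {
    frac <- abm_fraction_lookup(nm, age, sex)
    if (frac == 0) next
    idx_all <- bone_site_voxels(ph, nm, exclude_cortical = FALSE)
    idx_marrow <- bone_site_voxels(ph, nm, exclude_cortical = TRUE)
    if (nrow(idx_marrow) == 0L) {
      stop("site '", nm, "' holds marrow fraction ", frac,
           " but has no non-cortical voxels", call. = FALSE)
    }
    total_fraction <- total_fraction + frac
    w_site <- numeric(nrow(idx_all))
    marrow_key <- paste(idx_marrow[, 1], idx_marrow[, 2], idx_marrow[, 3])
    all_key <- paste(idx_all[, 1], idx_all[, 2], idx_all[, 3])
    w_site[all_key %in% marrow_key] <- frac / nrow(idx_marrow)
    pts <- rbind(pts, voxel_to_world(idx_all, ph$spacing, ph$origin))
    wts <- c(wts, w_site)
    sites <- c(sites, rep(nm, nrow(idx_all)))
    vox <- rbind(vox, idx_all)
  }
  if (is.null(pts)) {
    stop("no site in this phantom holds active marrow at age ", age,
         call. = FALSE)
  }
  structure(
    list(points = apply_transform(transform, pts), weight = wts,
         site = sites, voxel_index = vox, dose = NULL,
         phantom_id = ph$meta$id, total_fraction = total_fraction),
    class = "abm_sample"
  )
}

#' @export
print.abm_sample <- function(x, ...) {
  cat(sprintf(
    "ABM sample: %d voxels over %d sites, total marrow fraction %.4f%s\n",
    length(x$weight), length(unique(x$site)), sum(x$weight),
    if (is.null(x$dose)) " (dose not yet sampled)" else ""))
  invisible(x)
}

#' Sample a dose grid at arbitrary points
#'
#' Trilinear interpolation between voxel centers inside the grid; points
#' outside the boundaries of the dose matrix are assigned exactly zero
#' dose. Values at grid nodes are reproduced exactly and results are
#' never negative.
#'
#' @param grid A [dose_grid()].
#' @param points N x 3 mm points in the patient frame, or an `abm_sample`
#'   (whose `dose` field is then filled in).
#' @return Numeric dose vector (Gy), or the updated `abm_sample`.
#' @export
sample_dose <- function(grid, points) {
  stopifnot(inherits(grid, "dose_grid"))
  if (inherits(points, "abm_sample")) {
    out <- points
    out$dose <- sample_dose(grid, points$points)
    return(out)
  }
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  f <- world_to_voxel(points, grid$spacing, grid$origin)
  d <- dim(grid$dose)
  inside <- f[, 1] >= 1 & f[, 1] <= d[1] &
            f[, 2] >= 1 & f[, 2] <= d[2] &
            f[, 3] >= 1 & f[, 3] <= d[3]
  dose <- numeric(nrow(f))
  if (any(inside)) {
    fi <- f[inside, , drop = FALSE]
    i0 <- pmin(pmax(floor(fi[, 1]), 1), d[1] - 1)
    j0 <- pmin(pmax(floor(fi[, 2]), 1), d[2] - 1)
    k0 <- pmin(pmax(floor(fi[, 3]), 1), d[3] - 1)
    if (d[1] == 1) i0 <- rep(1, nrow(fi))
    if (d[2] == 1) j0 <- rep(1, nrow(fi))
    if (d[3] == 1) k0 <- rep(1, nrow(fi))
    i1 <- pmin(i0 + 1, d[1]); j1 <- pmin(j0 + 1, d[2])
    k1 <- pmin(k0 + 1, d[3])
    tx <- fi[, 1] - i0; ty <- fi[, 2] - j0; tz <- fi[, 3] - k0
    g <- function(i, j, k) grid$dose[cbind(i, j, k)]
    v <-
      g(i0, j0, k0) * (1 - tx) * (1 - ty) * (1 - tz) +
      g(i1, j0, k0) * tx       * (1 - ty) * (1 - tz) +
      g(i0, j1, k0) * (1 - tx) * ty       * (1 - tz) +
      g(i1, j1, k0) * tx       * ty       * (1 - tz) +
      g(i0, j0, k1) * (1 - tx) * (1 - ty) * tz +
      g(i1, j0, k1) * tx       * (1 - ty) * tz +
      g(i0, j1, k1) * (1 - tx) * ty       * tz +
      g(i1, j1, k1) * tx       * ty       * tz
    dose[inside] <- pmax(v, 0)
  }
  dose
}

#' Marrow-weighted mean dose
#'
#' Mean dose over all sampled bone voxels weighted by their marrow
#' fractions: sum(w * d) / sum(w).
#'
#' @param sample An `abm_sample` with doses, or a numeric dose vector.
#' @param weights Weights when `sample` is a plain vector.
#' @return Mean active bone marrow dose in Gy.
#' @export
mean_abm_dose <- function(sample, weights = NULL) {
  if (inherits(sample, "abm_sample")) {
    if (is.null(sample$dose)) stop("dose not sampled yet", call. = FALSE)
    weights <- sample$weight
    sample <- sample$dose
  }
  if (sum(weights) <= 0) stop("all weights are zero", call. = FALSE)
  sum(weights * sample) / sum(weights)
}

#' Exact marrow-weighted cumulative dose-volume histogram
#'
#' The weighted empirical dose distribution is kept exactly (one atom per
#' distinct dose value, no binning): V(d) = 100 x sum(w_i : d_i >= d) /
#' sum(w_i). Percentile doses D# are the weighted quantiles of this
#' distribution with the lower-boundary convention at ties, i.e. D# is
#' the smallest dose whose cumulative weight reaches (100 - #)%. That
#' convention yields D50 = 0 whenever at least half of the marrow weight
#' is unirradiated, matching the median-dose semantics of the cumulative
#' curve.
#'
#' @param sample An `abm_sample` with doses, or a numeric dose vector.
#' @param weights Weights when `sample` is a plain vector.
#' @return Object of class `abm_dvh`: data frame `dose` (ascending
#'   distinct atoms, Gy), `prob` (weight share), `volume_pct`
#'   (V(d), % of ABM receiving at least that dose), with total weight as
#'   attribute `total_weight`.
#' @export
compute_dvh <- function(sample, weights = NULL) {
  if (inherits(sample, "abm_sample")) {
    if (is.null(sample$dose)) stop("dose not sampled yet", call. = FALSE)
    weights <- sample$weight
    sample <- sample$dose
  }
  stopifnot(length(sample) == length(weights))
  keep <- weights > 0
  sample <- sample[keep]; weights <- weights[keep]
  tw <- sum(weights)
  if (tw <= 0) stop("all weights are zero", call. = FALSE)
  agg <- rowsum(weights, group = sample)
  atoms <- as.numeric(rownames(agg))
  ord <- order(atoms)
  atoms <- atoms[ord]
  prob <- as.numeric(agg)[ord] / tw
  surv <- rev(cumsum(rev(prob)))  # P(D >= atom)
  out <- data.frame(dose = atoms, prob = prob, volume_pct = 100 * surv)
  attr(out, "total_weight") <- tw
  class(out) <- c("abm_dvh", "data.frame")
  out
}

#' Percentile dose D# from a DVH
#'
#' D# is the dose exceeded by #% of the marrow volume: the
#' (100 - #)th weighted percentile of the dose distribution
#' (lower boundary at probability ties).
#'
#' @param dvh An `abm_dvh`.
#' @param pct The # in D# (e.g. 50 for the median dose D50).
#' @return Dose in Gy.
#' @export
dose_percentile <- function(dvh, pct) {
  stopifnot(inherits(dvh, "abm_dvh"), pct > 0, pct <= 100)
  target <- 1 - pct / 100
  cdf <- cumsum(dvh$prob)
  dvh$dose[which(cdf >= target - 1e-12)[1]]
}

#' Volume percentage receiving at least a dose cutoff
#'
#' V# = percentage of the active marrow receiving at least `dose_gy` Gy.
#'
#' @param dvh An `abm_dvh`.
#' @param dose_gy Dose cutoff in Gy.
#' @return Percent of ABM volume (0-100).
#' @export
volume_at_least <- function(dvh, dose_gy) {
  stopifnot(inherits(dvh, "abm_dvh"))
  100 * sum(dvh$prob[dvh$dose >= dose_gy])
}

#' Mean dose as the exact integral of the cumulative DVH
#'
#' Integrates V(d)/100 over dose on the atom grid (exact for the
#' piecewise-constant survival curve), which equals the weighted mean
#' dose up to floating rounding.
#'
#' @param dvh An `abm_dvh`.
#' @return Mean dose in Gy.
#' @export
dvh_integral_mean <- function(dvh) {
  stopifnot(inherits(dvh, "abm_dvh"))
  d_prev <- c(0, dvh$dose[-length(dvh$dose)])
  sum((dvh$dose - pmax(d_prev, 0)) * dvh$volume_pct / 100)
}

#' Dose and dose-volume metrics for an ABM sample
#'
#' @param sample An `abm_sample` with doses.
#' @param total_prescribed Total prescribed dose of the session (Gy);
#'   normalises the mean dose to Gy per prescribed Gy. `NULL` or 0 leaves
#'   `mean_per_rx` missing.
#' @param sessions_included Identifiers of the sessions the sample
#'   represents.
#' @return Object of class `abm_dose_result` with `mean_dose`,
#'   `mean_per_rx`, `d_metrics` (D50, D10, D1), `v_metrics` (V5, V10,
#'   V20), `dvh`, `total_fraction`, `sessions_included`.
#' @export
dose_metrics <- function(sample, total_prescribed = NULL,
                         sessions_included = NA_character_) {
  dvh <- compute_dvh(sample)
  mean_dose <- mean_abm_dose(sample)
  mean_per_rx <- if (is.null(total_prescribed) ||
                     !isTRUE(total_prescribed > 0)) {
    NA_real_
  } else mean_dose / total_prescribed
  structure(
    list(
      mean_dose = mean_dose,
      mean_per_rx = mean_per_rx,
      d_metrics = c(D50 = dose_percentile(dvh, 50),
                    D10 = dose_percentile(dvh, 10),
                    D1  = dose_percentile(dvh, 1)),
      v_metrics = c(V5  = volume_at_least(dvh, 5),
                    V10 = volume_at_least(dvh, 10),
                    V20 = volume_at_least(dvh, 20)),
      dvh = dvh,
      total_fraction = if (inherits(sample, "abm_sample")) {
        sample$total_fraction
      } else NA_real_,
      sessions_included = sessions_included
    ),
    class = "abm_dose_result"
  )
}

#' @export
print.abm_dose_result <- function(x, ...) {
  cat("Active bone marrow dose reconstruction\n")
  cat(sprintf("  mean ABM dose : %.4g Gy%s\n", x$mean_dose,
              if (is.na(x$mean_per_rx)) "" else
                sprintf(" (%.4g Gy/Gy_Rx)", x$mean_per_rx)))
  cat(sprintf("  D50/D10/D1    : %.4g / %.4g / %.4g Gy\n",
              x$d_metrics[1], x$d_metrics[2], x$d_metrics[3]))
  cat(sprintf("  V5/V10/V20    : %.3g / %.3g / %.3g %%\n",
              x$v_metrics[1], x$v_metrics[2], x$v_metrics[3]))
  invisible(x)
}

#' @export
summary.abm_dose_result <- function(object, ...) {
  out <- c(mean_gy = object$mean_dose, mean_per_rx = object$mean_per_rx,
           object$d_metrics, object$v_metrics,
           marrow_fraction_covered = object$total_fraction)
  class(out) <- "summary.abm_dose_result"
  out
}

#' @export
print.summary.abm_dose_result <- function(x, ...) {
  print(round(unclass(x), 5))
  invisible(x)
}

#' @export
plot.abm_dose_result <- function(x, ...) {
  dvh <- x$dvh
  graphics::plot(c(0, dvh$dose, max(dvh$dose) * 1.05),
                 c(100, dvh$volume_pct, 0), type = "s",
                 xlab = "dose (Gy)", ylab = "% ABM volume >= dose",
                 main = "Cumulative ABM dose-volume histogram",
                 ylim = c(0, 100), ...)
  invisible(x)
}

#' Sum treatment sessions into a cumulative dose result
#'
#' All sessions of a patient must have been mapped onto the same phantom
#' (one shared voxel identity space, selected from the first session);
#' each session is registered independently, its dose sampled at that
#' session's registered voxel positions, and the per-voxel doses are then
#' summed. Weights are taken once from the shared phantom, so the
#' cumulative mean equals the sum of the per-session means.
#'
#' @param samples List of `abm_sample` objects with doses, one per
#'   session, all derived from the same phantom.
#' @param total_prescribed Optional summed prescription over sessions.
#' @param sessions_included Session identifiers.
#' @return An `abm_dose_result` for the summed dose distribution.
#' @export
accumulate_sessions <- function(samples, total_prescribed = NULL,
                                sessions_included = NULL) {
  stopifnot(length(samples) >= 1L)
  ids <- vapply(samples, function(s) s$phantom_id, "")
  if (length(unique(ids)) > 1L) {
    stop("sessions were mapped on different phantoms: ",
         paste(unique(ids), collapse = ", "), call. = FALSE)
  }
  n <- vapply(samples, function(s) length(s$weight), 0L)
  if (length(unique(n)) > 1L) {
    stop("sessions disagree on phantom voxel count", call. = FALSE)
  }
  acc <- samples[[1]]
  if (is.null(acc$dose)) stop("dose not sampled yet", call. = FALSE)
  for (s in samples[-1]) {
    if (is.null(s$dose)) stop("dose not sampled yet", call. = FALSE)
    acc$dose <- acc$dose + s$dose
  }
  if (is.null(sessions_included)) {
    sessions_included <- paste0("session", seq_along(samples))
  }
  dose_metrics(acc, total_prescribed = total_prescribed,
               sessions_included = sessions_included)
}

#' Export a DVH as two-column text
#'
#' Writes `dose_gy` and `volume_pct` (percent of ABM receiving at least
#' that dose) at every distinct dose atom.
#'
#' @param dvh An `abm_dvh`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_dvh <- function(dvh, path) {
  stopifnot(inherits(dvh, "abm_dvh"))
  utils::write.table(
    data.frame(dose_gy = dvh$dose, volume_pct = dvh$volume_pct),
    path, row.names = FALSE, quote = FALSE, sep = "\t")
  invisible(path)
}
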
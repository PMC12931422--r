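#' Skeletal point set
#'
#' @param points N x 3 numeric matrix of mm coordinates.
#' @param voxel_index Optional N x 3 integer matrix of source voxel
#'   indices (1-based).
#' @param frame `"patient"` or `"phantom"`.
#' @return Object of class `skeleton_points`.
#' @export
skeleton_points <- function(points, voxel_index = NULL,
                            frame = c("patient", "phantom")) {
  frame <- match.arg(frame)
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  points <- as.matrix(points)
  stopifnot(ncol(points) == 3L)
  if (nrow(points) < 1L) stop("point set is empty", call. = FALSE)
  if (!all(is.finite(points))) stop("non-finite coordinates", call. = FALSE)
  structure(
    list(points = points, voxel_index = voxel_index, frame = frame),
    class = "skeleton_points"
  )
}

#' @export
print.skeleton_points <- function(x, ...) {
  cat(sprintf("Skeleton point set: %d points in %s frame\n",
              nrow(x$points), x$frame))
  invisible(x)
}

#' Extract the patient skeleton from CT by HU thresholding
#'
#' One point is emitted per voxel whose Hounsfield value is at or above
#' the threshold, at the voxel-center position in the patient (LPS, mm)
#' frame. The default threshold of 200 HU is a conventional floor for
#' bone attenuation and is configurable.
#'
#' @param ct A `ct_volume` (see [read_ct_series()]).
#' @param hu_threshold Bone threshold in HU.
#' @return A [skeleton_points()] in the patient frame.
#' @export
extract_skeleton <- function(ct, hu_threshold = 200) {
  stopifnot(inherits(ct, "ct_volume"))
  idx <- which(ct$hu >= hu_threshold, arr.ind = TRUE, useNames = FALSE)
  if (!nrow(idx)) {
    stop("no voxel at or above ", hu_threshold,
         " HU; skeleton extraction failed", call. = FALSE)
  }
  skeleton_points(voxel_to_world(idx, ct$spacing, ct$origin),
                  voxel_index = idx, frame = "patient")
}

#' Centroid-matching initial alignment
#'
#' Translation-only initialisation for ICP: moves the source centroid onto
#' the target centroid (identity rotation, unit scale).
#'
#' @param source,target [skeleton_points()] objects.
#' @return A [rigid_transform()].
#' @export
initial_align <- function(source, target) {
  stopifnot(inherits(source, "skeleton_points"),
            inherits(target, "skeleton_points"))
  rigid_transform(diag(3),
                  colMeans(target$points) - colMeans(source$points))
}

#' ICP configuration
#'
#' @param max_iterations Maximum ICP iterations (>= 1).
#' @param convergence_tol Stop when the mean correspondence distance
#'   improves by less than this (mm).
#' @param subsample Maximum number of points used per side; larger sets
#'   are uniformly subsampled (seeded).
#' @param allow_scale Estimate an isotropic scale (Umeyama) in addition to
#'   rotation and translation. Off by default: phantoms are rigid and body
#'   size is handled by phantom selection.
#' @param seed Integer seed for the subsampling draw.
#' @return List of class `icp_config`.
#' @export
icp_config <- function(max_iterations = 100, convergence_tol = 0.01,
                       subsample = 5000, allow_scale = FALSE, seed = 1L) {
  stopifnot(max_iterations >= 1, convergence_tol > 0, subsample >= 3)
  structure(
    list(max_iterations = as.integer(max_iterations),
         convergence_tol = convergence_tol,
         subsample = as.integer(subsample),
         allow_scale = isTRUE(allow_scale), seed = as.integer(seed)),
    class = "icp_config"
  )
}

# chunked brute-force nearest neighbour: for each row of `query` return
# index into `ref` of the closest point and the distance
nearest_neighbour <- function(query, ref, chunk = 512L) {
  n <- nrow(query)
  idx <- integer(n); dst <- numeric(n)
  ref_sq <- rowSums(ref^2)
  for (s in seq(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    q <- query[s:e, , drop = FALSE]
    # squared distances via expansion; ref_sq broadcast over rows
    d2 <- outer(rowSums(q^2), ref_sq, "+") - 2 * (q %*% t(ref))
    j <- max.col(-d2, ties.method = "first")
    idx[s:e] <- j
    # recompute the winning distances directly: the expanded form above
    # suffers catastrophic cancellation near zero distance
    dst[s:e] <- sqrt(rowSums((q - ref[j, , drop = FALSE])^2))
  }
  list(index = idx, dist = dst)
}

# closed-form least-squares rigid fit (Kabsch; optional Umeyama scale)
# mapping src onto dst
kabsch_fit <- function(src, dst, allow_scale = FALSE) {
  mu_s <- colMeans(src); mu_d <- colMeans(dst)
  sc <- sweep(src, 2, mu_s); dc <- sweep(dst, 2, mu_d)
  h <- crossprod(sc, dc) / nrow(src)
  sv <- svd(h)
  if (min(sv$d) < .Machine$double.eps * max(sv$d, 1) &&
      sum(sv$d > .Machine$double.eps * max(sv$d, 1)) < 2) {
    stop("degenerate geometry: rank-deficient cross-covariance",
         call. = FALSE)
  }
  s_diag <- c(1, 1, sign(det(sv$v %*% t(sv$u))))
  r <- sv$v %*% diag(s_diag) %*% t(sv$u)
  scale <- if (allow_scale) {
    var_s <- sum(sc^2) / nrow(src)
    sum(sv$d * s_diag) / var_s
  } else 1
  rigid_transform(r, mu_d - scale * as.numeric(r %*% mu_s), scale)
}

#' Register two skeletal point sets with the iterative closest point
#' algorithm
#'
#' Point-to-point ICP with the closed-form SVD (Kabsch) rigid update and
#' optional isotropic (Umeyama) scale. The moving set is the phantom
#' skeleton and the fixed set the patient skeleton, so the returned
#' transform maps phantom-frame points into the DICOM patient frame.
#' Iterations alternate nearest-neighbour correspondence and the rigid
#' update; an update that fails to reduce the mean correspondence distance
#' is rejected and iteration stops, so the recorded history is
#' non-increasing. Unless an explicit initial transform is supplied, the
#' descent is started from the centroid alignment and from the four
#' proper principal-axes alignments, and the start reaching the lowest
#' final mean correspondence distance wins; this guards against the
#' lattice-shift local minima a single start can fall into on regular
#' voxel point clouds.
#'
#' @param source Moving [skeleton_points()] (phantom).
#' @param target Fixed [skeleton_points()] (patient).
#' @param cfg An [icp_config()].
#' @param init Optional initial [rigid_transform()]; defaults to
#'   [initial_align()].
#' @return Object of class `icp_fit`: `transform` (phantom -> patient),
#'   `history` (mean correspondence distance per iteration, mm),
#'   `converged`, `iterations`, `rms` (final RMS correspondence distance),
#'   `config`.
#' @export
#' @examples
#' pts <- matrix(rnorm(300), ncol = 3) * 40
#' src <- skeleton_points(pts, frame = "phantom")
#' tru <- rigid_transform(rotation_about_axis("z", 20), c(5, -3, 2))
#' tgt <- skeleton_points(apply_transform(tru, pts))
#' fit <- icp_register(src, tgt)
#' fit$converged
icp_register <- function(source, target, cfg = icp_config(), init = NULL) {
  stopifnot(inherits(source, "skeleton_points"),
            inherits(target, "skeleton_points"),
            inherits(cfg, "icp_config"))
  src <- source$points; tgt <- target$points
  if (nrow(src) < 3L || nrow(tgt) < 3L) {
    stop("need at least 3 points per side", call. = FALSE)
  }
  # seeded uniform subsampling for tractability on dense skeletons
  local_sample <- function(pts, n, seed_offset) {
    if (nrow(pts) <= n) return(pts)
    keep <- with_seed(cfg$seed + seed_offset, sample.int(nrow(pts), n))
    pts[keep, , drop = FALSE]
  }
  src_s <- local_sample(src, cfg$subsample, 0L)
  tgt_s <- local_sample(tgt, cfg$subsample, 1L)

  inits <- if (is.null(init)) {
    c(list(initial_align(skeleton_points(src_s, frame = source$frame),
                         skeleton_points(tgt_s, frame = target$frame))),
      pca_inits(src_s, tgt_s))
  } else list(init)
  runs <- lapply(inits, function(t0) icp_run(src_s, tgt_s, cfg, t0))
  finals <- vapply(runs, function(r) utils::tail(r$history, 1), 0)
  best <- runs[[which.min(finals)]]
  structure(
    list(transform = best$transform, history = best$history,
         converged = best$converged,
         iterations = length(best$history) - 1L,
         rms = best$rms, config = cfg),
    class = "icp_fit"
  )
}

# principal-axes initialisations: align sorted principal directions of
# the two clouds under the four proper sign disambiguations
pca_inits <- function(src, tgt) {
  proper <- function(u) { if (det(u) < 0) u[, 3] <- -u[, 3]; u }
  us <- proper(eigen(stats::cov(src), symmetric = TRUE)$vectors)
  ut <- proper(eigen(stats::cov(tgt), symmetric = TRUE)$vectors)
  mu_s <- colMeans(src); mu_t <- colMeans(tgt)
  lapply(list(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)),
         function(s) {
           r <- ut %*% diag(s) %*% t(us)
           rigid_transform(r, mu_t - as.numeric(r %*% mu_s))
         })
}

# one ICP descent from a given initial transform; the recorded history is
# non-increasing because a non-improving update is rejected
icp_run <- function(src_s, tgt_s, cfg, trans) {
  moved <- apply_transform(trans, src_s)
  nn <- nearest_neighbour(moved, tgt_s)
  best_mean <- mean(nn$dist)
  history <- best_mean
  converged <- FALSE
  for (it in seq_len(cfg$max_iterations)) {
    cand <- kabsch_fit(src_s, tgt_s[nn$index, , drop = FALSE],
                       allow_scale = cfg$allow_scale)
    moved_c <- apply_transform(cand, src_s)
    nn_c <- nearest_neighbour(moved_c, tgt_s)
    m <- mean(nn_c$dist)
    if (m > best_mean + 1e-12) break  # reject non-improving update
    trans <- cand; nn <- nn_c
    improvement <- best_mean - m
    best_mean <- m
    history <- c(history, m)
    if (improvement < cfg$convergence_tol) { converged <- TRUE; break }
  }
  list(transform = trans, history = history, converged = converged,
       rms = sqrt(mean(nn$dist^2)))
}

#' @export
print.icp_fit <- function(x, ...) {
  cat(sprintf(
    "ICP registration: %d iterations, mean correspondence %.4g mm (%s)\n",
    x$iterations, utils::tail(x$history, 1),
    if (x$converged) "converged" else "not converged"))
  print(x$transform)
  invisible(x)
}

#' @export
coef.icp_fit <- function(object, ...) {
  c(stats::setNames(as.vector(object$transform$rotation),
                    paste0("r", outer(1:3, 1:3, paste0))),
    tx = object$transform$translation[1],
    ty = object$transform$translation[2],
    tz = object$transform$translation[3],
    scale = object$transform$scale)
}

#' @export
predict.icp_fit <- function(object, newdata, ...) {
  pts <- if (inherits(newdata, "skeleton_points")) newdata$points else newdata
  apply_transform(object$transform, pts)
}

#' @export
plot.icp_fit <- function(x, ...) {
  graphics::plot(seq_along(x$history) - 1L, x$history, type = "b",
       xlab = "iteration", ylab = "mean correspondence distance (mm)",
       main = "ICP convergence", ...)
  invisible(x)
}

#' Write a registration report as JSON
#'
#' @param fit An `icp_fit`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_registration_report <- function(fit, path) {
  stopifnot(inherits(fit, "icp_fit"))
  jsonlite::write_json(
    list(
      transform = as.vector(t(transform_matrix(fit$transform))),
      history_mm = fit$history,
      converged = fit$converged,
      iterations = fit$iterations,
      rms_mm = fit$rms,
      seed = fit$config$seed
    ),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
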
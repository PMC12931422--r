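#' Construct a rigid (optionally scaled) transform
#'
#' A transform maps phantom-frame points into the DICOM patient frame as
#' `p' = scale * R %*% p + t`. All coordinates are millimetres in the LPS
#' patient coordinate system; voxel coordinates refer to voxel centers.
#'
#' @param rotation 3x3 orthonormal matrix with determinant +1.
#' @param translation Numeric length-3 translation in mm.
#' @param scale Positive isotropic scale factor (1 for pure rigid).
#' @return An object of class `rigid_transform`.
#' @export
#' @examples
#' t <- rigid_transform(diag(3), c(1, 2, 3))
#' apply_transform(t, matrix(0, 1, 3))
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0),
                            scale = 1) {
  rotation <- matrix(as.numeric(rotation), 3, 3)
  translation <- as.numeric(translation)
  stopifnot(length(translation) == 3L, is.numeric(scale), length(scale) == 1L)
  if (scale <= 0) stop("scale must be positive", call. = FALSE)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9) {
    stop("rotation must be orthonormal (R'R = I)", call. = FALSE)
  }
  if (abs(det(rotation) - 1) > 1e-9) {
    stop("rotation must be proper (det = +1)", call. = FALSE)
  }
  structure(
    list(rotation = rotation, translation = translation, scale = scale),
    class = "rigid_transform"
  )
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("Rigid transform (phantom -> patient frame)\n")
  cat("  rotation:\n")
  print(round(x$rotation, 6))
  cat("  translation (mm):", format(round(x$translation, 4)), "\n")
  cat("  scale:", format(x$scale), "\n")
  invisible(x)
}

#' Apply a rigid transform to a point matrix
#'
#' @param transform A [rigid_transform()].
#' @param points N x 3 numeric matrix of mm coordinates (a length-3 vector
#'   is treated as one point).
#' @return N x 3 matrix of transformed coordinates.
#' @export
apply_transform <- function(transform, points) {
  stopifnot(inherits(transform, "rigid_transform"))
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  points <- as.matrix(points)
  stopifnot(ncol(points) == 3L)
  out <- transform$scale * (points %*% t(transform$rotation))
  sweep(out, 2, transform$translation, "+")
}

#' Invert a rigid transform
#'
#' @param transform A [rigid_transform()].
#' @return The inverse transform: `invert_transform(t)` composed with `t`
#'   is the identity.
#' @export
invert_transform <- function(transform) {
  stopifnot(inherits(transform, "rigid_transform"))
  r_inv <- t(transform$rotation)
  s_inv <- 1 / transform$scale
  rigid_transform(
    rotation = r_inv,
    translation = -s_inv * as.numeric(r_inv %*% transform$translation),
    scale = s_inv
  )
}

#' Compose two rigid transforms
#'
#' `compose_transforms(a, b)` is the transform applying `b` first, then
#' `a`: `x -> a(b(x))`.
#'
#' @param a,b [rigid_transform()] objects.
#' @return The composed `rigid_transform`.
#' @export
compose_transforms <- function(a, b) {
  stopifnot(inherits(a, "rigid_transform"), inherits(b, "rigid_transform"))
  rigid_transform(
    rotation = a$rotation %*% b$rotation,
    translation = a$scale * as.numeric(a$rotation %*% b$translation) +
      a$translation,
    scale = a$scale * b$scale
  )
}

#' Rotation matrix about a coordinate axis
#'
#' @param axis `"x"`, `"y"` or `"z"`.
#' @param angle_deg Rotation angle in degrees (right-handed).
#' @return 3x3 rotation matrix.
#' @export
rotation_about_axis <- function(axis = c("x", "y", "z"), angle_deg) {
  axis <- match.arg(axis)
  a <- angle_deg * pi / 180
  c_ <- cos(a); s_ <- sin(a)
  switch(axis,
    x = matrix(c(1, 0, 0, 0, c_, s_, 0, -s_, c_), 3, 3),
    y = matrix(c(c_, 0, -s_, 0, 1, 0, s_, 0, c_), 3, 3),
    z = matrix(c(c_, s_, 0, -s_, c_, 0, 0, 0, 1), 3, 3)
  )
}

#' Homogeneous 4x4 matrix form of a transform
#'
#' @param transform A [rigid_transform()].
#' @return 4x4 homogeneous matrix (row-major export order is the matrix
#'   itself; R stores column-major but the matrix is what it is).
#' @export
transform_matrix <- function(transform) {
  m <- diag(4)
  m[1:3, 1:3] <- transform$scale * transform$rotation
  m[1:3, 4] <- transform$translation
  m
}

# ---- raster <-> world helpers ------------------------------------------

# A "grid geometry" is list(spacing = c(dx,dy,dz), origin = c(x0,y0,z0))
# with axis-aligned orientation; voxel (i,j,k), 1-based in R, has center
# origin + (c(i,j,k) - 1) * spacing.

#' Convert 1-based voxel indices to mm world coordinates
#'
#' @param idx N x 3 matrix of 1-based voxel indices.
#' @param spacing,origin Grid geometry (mm per voxel; center of the first
#'   voxel).
#' @return N x 3 matrix of voxel-center coordinates in mm.
#' @export
voxel_to_world <- function(idx, spacing, origin) {
  if (is.null(dim(idx))) idx <- matrix(idx, ncol = 3)
  sweep(sweep(as.matrix(idx) - 1, 2, spacing, "*"), 2, origin, "+")
}

#' Convert mm world coordinates to (fractional) 1-based voxel indices
#'
#' @param pts N x 3 matrix of mm coordinates.
#' @param spacing,origin Grid geometry.
#' @return N x 3 matrix of fractional voxel indices (1 = first voxel
#'   center); round to get the nearest voxel.
#' @export
world_to_voxel <- function(pts, spacing, origin) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 3)
  sweep(sweep(as.matrix(pts), 2, origin, "-"), 2, spacing, "/") + 1
}
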
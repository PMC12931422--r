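# Shared fixtures, built once per test run.

fix_phantom <- local({
  ph <- NULL
  function() {
    if (is.null(ph)) ph <<- make_phantom()
    ph
  }
})

fix_skeleton <- function() phantom_skeleton_points(fix_phantom())

# a tiny phantom carrying every reference site (4 voxels each, 2x2
# footprint, no cortical shell) for whole-body fraction accounting
fix_full_site_phantom <- local({
  ph <- NULL
  function() {
    if (is.null(ph)) {
      sites <- data.frame(site = abm_site_names(), n_voxels = 4L,
                          cortical_fraction = 0,
                          width_x = 2L, width_y = 2L,
                          off_x = 0L, off_y = 0L)
      ph <<- make_phantom(sites, meta = list(age_years = 30, sex = "M",
                                             height_cm = 176,
                                             weight_kg = 73,
                                             id = "full34"))
    }
    ph
  }
})

# random proper rotation from three seeded Euler angles (degrees)
random_rotation <- function(max_deg = 45) {
  a <- stats::runif(3, -max_deg, max_deg)
  rotation_about_axis("z", a[1]) %*% rotation_about_axis("y", a[2]) %*%
    rotation_about_axis("x", a[3])
}

# brute-force weighted dose metrics: sort-and-scan, independent of the
# abm_dvh code path
brute_metrics <- function(doses, weights) {
  ord <- order(doses)
  d <- doses[ord]; w <- weights[ord] / sum(weights)
  cw <- cumsum(w)
  dq <- function(pct) {
    target <- 1 - pct / 100
    for (i in seq_along(d)) if (cw[i] >= target - 1e-12) return(d[i])
    d[length(d)]
  }
  vq <- function(cut) 100 * sum(w[d >= cut])
  list(mean = sum(d * w),
       D50 = dq(50), D10 = dq(10), D1 = dq(1),
       V5 = vq(5), V10 = vq(10), V20 = vq(20))
}
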
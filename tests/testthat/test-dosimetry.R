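test_that("site fractions spread homogeneously over non-cortical voxels", {
  lab <- array(0L, dim = c(8, 3, 3))
  tis <- array(0L, dim = c(8, 3, 3))
  lab[1:8, 2, 2] <- 1L
  tis[1:8, 2, 2] <- tissue_codes()[["spongiosa"]]
  tis[1:4, 2, 2] <- tissue_codes()[["cortical"]]
  ph <- phantom(lab, tis, c(1, 1, 1), c(0, 0, 0), c("Sacrum" = 1L),
                list(age_years = 30, sex = "M", height_cm = 176,
                     weight_kg = 73, id = "t"))
  smp <- assign_voxel_weights(ph, rigid_transform(), 30, "M")
  frac <- abm_fraction_lookup("Sacrum", 30, "M")
  # cortical voxels carry weight zero; the 4 marrow voxels share equally
  expect_equal(sort(unique(smp$weight)), c(0, frac / 4))
  expect_equal(sum(smp$weight == 0), 4L)
  expect_equal(sum(smp$weight), frac)
  expect_equal(smp$total_fraction, frac)
})

test_that("a 4-voxel site holding fraction 0.10 gives 0.025 per voxel", {
  lab <- array(0L, dim = c(4, 2, 2)); tis <- lab
  lab[1:4, 1, 1] <- 1L
  tis[1:4, 1, 1] <- tissue_codes()[["medullary_cavity"]]
  ph <- phantom(lab, tis, c(1, 1, 1), c(0, 0, 0), c("Sternum" = 1L),
                list(age_years = 30, sex = "F", height_cm = 165,
                     weight_kg = 60, id = "t"))
  smp <- assign_voxel_weights(ph, rigid_transform(), 30, "F")
  frac <- abm_fraction_lookup("Sternum", 30, "F")
  expect_equal(unique(smp$weight), frac / 4)
})

test_that("a full-site phantom carries the whole marrow distribution", {
  ph <- fix_full_site_phantom()
  smp <- assign_voxel_weights(ph, rigid_transform(), 30, "M")
  col_sum <- sum(abm_fraction_table()$f30M)
  expect_equal(sum(smp$weight), col_sum, tolerance = 1e-12)
  expect_lt(abs(sum(smp$weight) - 1), 0.002)
  # weights transform with the registration: translation moves positions
  tr <- rigid_transform(diag(3), c(7, -2, 13))
  smp2 <- assign_voxel_weights(ph, tr, 30, "M")
  expect_equal(smp2$points, sweep(smp$points, 2, c(7, -2, 13), "+"))
  expect_equal(smp2$weight, smp$weight)
})

test_that("sites with marrow but no marrow-capable voxels are an error", {
  lab <- array(0L, dim = c(4, 2, 2)); tis <- lab
  lab[1:4, 1, 1] <- 1L
  tis[1:4, 1, 1] <- tissue_codes()[["cortical"]]  # cortical-only site
  ph <- phantom(lab, tis, c(1, 1, 1), c(0, 0, 0), c("Ribs" = 1L),
                list(age_years = 30, sex = "M", height_cm = 176,
                     weight_kg = 73, id = "t"))
  expect_error(assign_voxel_weights(ph, rigid_transform(), 30, "M"),
               "no non-cortical voxels")
})

test_that("dose sampling is node-exact, trilinear between nodes, zero outside", {
  dose <- array(0, dim = c(3, 3, 3))
  dose[2, 2, 2] <- 10
  dg <- dose_grid(dose, c(2, 2, 2), c(0, 0, 0))
  # node exactness at every grid node
  nodes <- as.matrix(expand.grid(i = 1:3, j = 1:3, k = 1:3))
  vals <- sample_dose(dg, voxel_to_world(nodes, dg$spacing, dg$origin))
  expect_equal(vals, as.vector(dose[nodes]))
  # midpoint between a 0 node and the 10 node
  mid <- (voxel_to_world(c(2, 2, 2), dg$spacing, dg$origin) +
            voxel_to_world(c(1, 2, 2), dg$spacing, dg$origin)) / 2
  expect_equal(sample_dose(dg, mid), 5)
  # far outside is exactly zero
  expect_identical(sample_dose(dg, c(1000, 0, 0)), 0)
  expect_identical(sample_dose(dg, c(0, 0, -1e6)), 0)
  expect_true(all(sample_dose(dg, matrix(runif(300, -10, 10),
                                         ncol = 3)) >= 0))
})

test_that("weighted mean dose follows the weights", {
  expect_equal(mean_abm_dose(c(2, 2, 2), c(0.2, 0.5, 0.3)), 2)
  expect_equal(mean_abm_dose(c(0, 10), c(0.5, 0.5)), 5)
  expect_equal(mean_abm_dose(c(0, 10), c(0.9, 0.1)), 1)
  expect_error(mean_abm_dose(c(1, 2), c(0, 0)), "zero")
})

test_that("the two-atom distribution yields the documented DVH metrics", {
  dvh <- compute_dvh(c(0, 10), c(0.5, 0.5))
  expect_equal(volume_at_least(dvh, 5), 50)
  expect_equal(dose_percentile(dvh, 50), 0)   # half the marrow unirradiated
  expect_equal(dose_percentile(dvh, 10), 10)
  expect_equal(volume_at_least(dvh, 0), 100)  # V(0) = 100 always

  uni <- compute_dvh(rep(2, 5), rep(0.2, 5))
  expect_equal(volume_at_least(uni, 1), 100)
  expect_equal(volume_at_least(uni, 3), 0)
  expect_equal(dose_percentile(uni, 50), 2)
})

test_that("DVH metrics equal a brute-force sort-and-scan oracle", {
  set.seed(61)
  for (trial in 1:12) {
    n <- sample(c(100, 5000, 1e5), 1)
    doses <- round(rexp(n, 1 / 10), sample(c(0, 1, 3), 1))  # forces ties
    weights <- runif(n)
    dvh <- compute_dvh(doses, weights)
    oracle <- brute_metrics(doses, weights)
    expect_equal(mean_abm_dose(doses, weights), oracle$mean,
                 tolerance = 1e-9)
    expect_equal(dose_percentile(dvh, 50), oracle$D50, tolerance = 1e-9)
    expect_equal(dose_percentile(dvh, 10), oracle$D10, tolerance = 1e-9)
    expect_equal(dose_percentile(dvh, 1), oracle$D1, tolerance = 1e-9)
    expect_equal(volume_at_least(dvh, 5), oracle$V5, tolerance = 1e-9)
    expect_equal(volume_at_least(dvh, 10), oracle$V10, tolerance = 1e-9)
    expect_equal(volume_at_least(dvh, 20), oracle$V20, tolerance = 1e-9)
    # ordering invariants
    expect_true(oracle$D50 <= oracle$D10 + 1e-12 &&
                  oracle$D10 <= oracle$D1 + 1e-12)
    expect_true(oracle$V5 >= oracle$V10 && oracle$V10 >= oracle$V20)
    # the cumulative curve starts at 100% and never increases
    expect_equal(dvh$volume_pct[1], 100 * sum(weights[doses >= dvh$dose[1]])
                 / sum(weights))
    expect_true(all(diff(dvh$volume_pct) <= 1e-12))
    expect_equal(volume_at_least(dvh, 0), 100)
  }
})

test_that("the mean equals the integral of the cumulative DVH", {
  set.seed(71)
  for (trial in 1:8) {
    n <- sample(c(50, 2000, 5e4), 1)
    doses <- rgamma(n, shape = 0.8, rate = 0.1) *
      rbinom(n, 1, 0.7)  # zero-inflated like out-of-field marrow
    weights <- runif(n)
    dvh <- compute_dvh(doses, weights)
    m <- mean_abm_dose(doses, weights)
    expect_equal(dvh_integral_mean(dvh), m,
                 tolerance = 1e-6 * max(m, 1e-12))
  }
})

test_that("metrics from the DVH agree with metrics from the raw sample", {
  set.seed(81)
  doses <- c(rep(0, 40), runif(60, 0, 55))
  weights <- runif(100)
  dvh <- compute_dvh(doses, weights)
  res <- dose_metrics(structure(list(dose = doses, weight = weights,
                                     total_fraction = 1,
                                     phantom_id = "x"),
                                class = "abm_sample"),
                      total_prescribed = 50)
  expect_equal(res$mean_dose, mean_abm_dose(doses, weights),
               tolerance = 1e-12)
  expect_equal(res$mean_per_rx, res$mean_dose / 50)
  expect_equal(unname(res$d_metrics),
               c(dose_percentile(dvh, 50), dose_percentile(dvh, 10),
                 dose_percentile(dvh, 1)))
  expect_equal(unname(res$v_metrics),
               c(volume_at_least(dvh, 5), volume_at_least(dvh, 10),
                 volume_at_least(dvh, 20)))
  # missing prescription leaves the normalised mean missing
  expect_true(is.na(dose_metrics(
    structure(list(dose = doses, weight = weights, total_fraction = 1,
                   phantom_id = "x"), class = "abm_sample"))$mean_per_rx))
})

test_that("zero-padding the dose grid changes no metric", {
  ph <- fix_phantom()
  smp <- assign_voxel_weights(ph, rigid_transform(), 30, "M")
  dg <- make_dose_grid("gaussian_beam", grid_dim = c(20, 20, 40),
                       spacing = c(4, 4, 4), origin = c(-10, -12, -8),
                       peak_gy = 30, sigma_mm = 25)
  a <- dose_metrics(sample_dose(dg, smp), total_prescribed = 50)
  # embed the same dose in a grid padded with zeros on every side
  pad <- c(6L, 5L, 7L)
  big <- array(0, dim = dim(dg$dose) + 2L * pad)
  big[pad[1] + seq_len(20), pad[2] + seq_len(20), pad[3] + seq_len(40)] <-
    dg$dose
  dg_big <- dose_grid(big, dg$spacing, dg$origin - pad * dg$spacing)
  b <- dose_metrics(sample_dose(dg_big, smp), total_prescribed = 50)
  expect_equal(b$mean_dose, a$mean_dose, tolerance = 1e-12)
  expect_equal(b$d_metrics, a$d_metrics, tolerance = 1e-12)
  expect_equal(b$v_metrics, a$v_metrics, tolerance = 1e-12)
})

test_that("session accumulation is linear in the per-session means", {
  ph <- fix_phantom()
  smp <- assign_voxel_weights(ph, rigid_transform(), 30, "M")
  s1 <- smp; s1$dose <- rep(1, length(smp$weight))
  s2 <- smp; s2$dose <- rep(1, length(smp$weight))
  cum <- accumulate_sessions(list(s1, s2), total_prescribed = 100)
  expect_equal(cum$mean_dose, 2)
  # single session is the identity
  one <- accumulate_sessions(list(s1), total_prescribed = 50)
  expect_equal(one$mean_dose, dose_metrics(s1, 50)$mean_dose)
  # general linearity: mean(sum) = sum(means)
  set.seed(91)
  s3 <- smp; s3$dose <- runif(length(smp$weight), 0, 30)
  s4 <- smp; s4$dose <- runif(length(smp$weight), 0, 10)
  m3 <- mean_abm_dose(s3); m4 <- mean_abm_dose(s4)
  both <- accumulate_sessions(list(s3, s4))
  expect_equal(both$mean_dose, m3 + m4, tolerance = 1e-9)
  # mismatched phantoms are refused
  s5 <- s4; s5$phantom_id <- "other"
  expect_error(accumulate_sessions(list(s3, s5)), "different phantoms")
})

test_that("DVH exports are two-column text over the dose atoms", {
  dvh <- compute_dvh(c(0, 5, 5, 12), c(0.25, 0.25, 0.25, 0.25))
  f <- file.path(withr::local_tempdir(), "dvh.tsv")
  export_dvh(dvh, f)
  re <- utils::read.table(f, header = TRUE)
  expect_identical(names(re), c("dose_gy", "volume_pct"))
  expect_equal(re$dose_gy, c(0, 5, 12))
  expect_equal(re$volume_pct, c(100, 75, 25))
})
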
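make_study <- function(peak_a, low_a = peak_a * 0, up_a = peak_a * 0,
                       peak_p = peak_a, low_p = low_a, up_p = up_a,
                       duration_s = 1) {
  planar_study(list(peak = peak_a, lower = low_a, upper = up_a),
               list(peak = peak_p, lower = low_p, upper = up_p),
               duration_s = duration_s, pixel_mm = 2.4, time_h = 24)
}

test_that("TEW correction: no scatter leaves the photopeak unchanged, floor applies", {
  peak <- matrix(c(1000, 10, 0, 500), 2, 2)
  s <- make_study(peak)
  out <- tew_scatter_correct(s)
  expect_equal(out$anterior, peak)
  expect_equal(out$posterior, peak)
  # saturating scatter floors at zero
  s2 <- make_study(matrix(10, 1, 1), matrix(1000, 1, 1), matrix(1000, 1, 1))
  expect_equal(tew_scatter_correct(s2)$anterior, matrix(0, 1, 1))
})

test_that("TEW estimator matches a hand evaluation with the Lu-177 window widths", {
  # widths: lower 170*0.15 = 25.5, peak 208*0.15 = 31.2, upper 240*0.10 = 24.0 keV
  s <- make_study(matrix(1000, 1, 1), matrix(100, 1, 1), matrix(50, 1, 1))
  expected <- 1000 - (100 / 25.5 + 50 / 24.0) * 31.2 / 2
  expect_equal(tew_scatter_correct(s)$anterior[1, 1], expected, tolerance = 1e-12)
})

test_that("TEW output is non-negative and never exceeds the photopeak total", {
  withr::with_seed(3, {
    peak <- matrix(rpois(64, 200), 8, 8)
    low <- matrix(rpois(64, 60), 8, 8)
    up <- matrix(rpois(64, 40), 8, 8)
    out <- tew_scatter_correct(make_study(peak, low, up))
    expect_true(all(out$anterior >= 0))
    expect_lte(sum(out$anterior), sum(peak))
  })
})

test_that("bilinear HU-mu calibration recovers generating segments and clamps", {
  mu_water <- 0.0095
  hu <- c(-600, -300, -100, 100, 500, 1100)
  mu <- ifelse(hu < 0, mu_water + 8e-6 * hu, mu_water + 5e-6 * hu)
  cal <- fit_mu_calibration(hu, mu)
  expect_equal(cal$mu0, mu_water, tolerance = 1e-10)
  expect_equal(cal$slope_neg, 8e-6, tolerance = 1e-10)
  expect_equal(cal$slope_pos, 5e-6, tolerance = 1e-10)
  # continuity at the joint and clamping beyond the calibrated range
  expect_equal(predict(cal, 0), mu_water)
  expect_equal(predict(cal, 2000), predict(cal, 1127))
  expect_equal(predict(cal, -5000), predict(cal, -688))
  expect_error(fit_mu_calibration(c(-10, 5, 10), c(0.009, 0.0096, 0.0097)),
               class = "mdose_calibration_error")
})

test_that("mu projection integrates a uniform slab and assigns segment defaults", {
  vol <- array(0.0095, c(4, 4, 40))  # 40 voxels x 5 mm = 200 mm water
  proj <- build_mu_projection(vol, voxel_depth_mm = 5)
  expect_equal(proj$optical_depth, matrix(1.9, 4, 4), tolerance = 1e-12)
  # uncovered pixels take their segment default
  vol2 <- array(NA_real_, c(2, 2, 3))
  vol2[1, 1, ] <- 0.01
  seg <- matrix("legs", 2, 2)
  proj2 <- build_mu_projection(vol2, 5, segment_map = seg,
                               segment_defaults = c(legs = 1.2))
  expect_equal(proj2$optical_depth[2, 2], 1.2)
  expect_equal(proj2$provenance[1, 1], "ct")
  expect_equal(proj2$provenance[2, 2], "default")
  expect_error(build_mu_projection(vol2, 5, segment_map = seg,
                                   segment_defaults = c(arms = 1)),
               class = "mdose_missing_segment")
})

test_that("Gaussian blur of a delta map matches the normalised kernel oracle", {
  sigma <- (11 / 2.355) / 2.4  # FWHM 11 mm at 2.4 mm pixels
  n <- 41
  m <- matrix(0, n, n)
  m[21, 21] <- 1
  out <- gaussian_blur(m, sigma)
  # independent oracle: outer product of the 1D normalised discrete Gaussian
  r <- ceiling(6 * sigma)
  k <- exp(-0.5 * (((-r):r) / sigma)^2)
  k <- k / sum(k)
  expected <- matrix(0, n, n)
  idx <- (21 - r):(21 + r)
  expected[idx, idx] <- outer(k, k)
  expect_lt(max(abs(out - expected)), 1e-6)
  expect_equal(sum(out), 1, tolerance = 1e-12)
})

test_that("conjugate view applies the analytic transmission correction", {
  ant <- matrix(400, 2, 2)
  zero_mu <- matrix(0, 2, 2)
  expect_equal(conjugate_view(ant, ant, zero_mu, 1), ant)
  # optical depth ln 4: transmission 1/4, correction factor 2
  od <- matrix(log(4), 2, 2)
  expect_equal(conjugate_view(ant, ant, od, 1), matrix(800, 2, 2))
  # geometric mean / duration with unequal views
  post <- matrix(100, 2, 2)
  expect_equal(conjugate_view(ant, post, zero_mu, 10), matrix(20, 2, 2))
  # swapping views leaves the result unchanged; zero counts map to zero
  withr::with_seed(5, {
    a <- matrix(runif(9, 0, 500), 3, 3)
    p <- matrix(runif(9, 0, 500), 3, 3)
    a[1, 1] <- 0
    mu <- matrix(runif(9, 0, 2), 3, 3)
    expect_equal(conjugate_view(a, p, mu, 2), conjugate_view(p, a, mu, 2))
    expect_equal(conjugate_view(a, p, mu, 2)[1, 1], 0)
  })
  expect_error(conjugate_view(ant, matrix(1, 3, 3), zero_mu, 1),
               class = "mdose_shape_error")
})

test_that("planar calibration factor is SPECT activity over planar rate", {
  expect_equal(calibrate_planar(2000, 1e6)$factor_bq_per_cps, 500)
  expect_equal(calibrate_planar(1, 1)$factor_bq_per_cps, 1)
  expect_error(calibrate_planar(0, 1e6), class = "mdose_calibration_error")
  expect_error(calibrate_planar(10, -1), class = "mdose_calibration_error")
})

test_that("percent isocontour selects by fraction of the regional maximum", {
  vol <- array(0, c(8, 8, 8))
  sphere <- array(FALSE, c(8, 8, 8))
  for (i in 1:8) for (j in 1:8) for (k in 1:8) {
    sphere[i, j, k] <- sum((c(i, j, k) - 4.5)^2) <= 9
  }
  vol[sphere] <- 100
  voi <- percent_isocontour_voi(vol, sphere, 0.4)
  expect_equal(sum(voi), sum(sphere))  # uniform region fully selected
  # Gaussian blob: voxel count equals a brute-force scan
  blob <- array(0, c(9, 9, 9))
  for (i in 1:9) for (j in 1:9) for (k in 1:9) {
    blob[i, j, k] <- exp(-sum((c(i, j, k) - 5)^2) / 6)
  }
  box <- array(TRUE, c(9, 9, 9))
  voi50 <- percent_isocontour_voi(blob, box, 0.5)
  brute <- sum(blob >= 0.5 * max(blob))
  expect_equal(sum(voi50), brute)
  # threshold just below the unique maximum selects exactly that voxel
  voi999 <- percent_isocontour_voi(blob, box, 0.999)
  expect_equal(sum(voi999), 1)
  expect_true(voi999[5, 5, 5])
  # monotone: raising the level never adds voxels
  prev <- sum(percent_isocontour_voi(blob, box, 0.1))
  for (p in c(0.3, 0.5, 0.7, 0.9)) {
    cur <- sum(percent_isocontour_voi(blob, box, p))
    expect_lte(cur, prev)
    prev <- cur
  }
  expect_error(percent_isocontour_voi(array(0, c(2, 2, 2)), array(TRUE, c(2, 2, 2)), 0.4),
               class = "mdose_empty_region")
})

test_that("VOI activity sums concentration times voxel volume", {
  vol <- array(0, c(5, 5, 5))
  voi <- array(FALSE, c(5, 5, 5))
  voi[1:2, 1:5, 1:5] <- TRUE
  vol[voi] <- 1000
  expect_equal(voi_activity(vol, voi, 0.1), sum(voi) * 1000 * 0.1)
  # organ minus fully-contained tumour equals the difference of totals
  tum <- array(FALSE, c(5, 5, 5))
  tum[1, 1:2, 1:2] <- TRUE
  expect_equal(voi_activity(vol, voi, 0.1, exclude = tum),
               voi_activity(vol, voi, 0.1) - voi_activity(vol, tum, 0.1))
  # random volume against a brute-force voxel loop
  withr::with_seed(9, {
    v <- array(runif(125, 0, 50), c(5, 5, 5))
    m <- array(runif(125) > 0.6, c(5, 5, 5))
    brute <- 0
    for (i in 1:5) for (j in 1:5) for (k in 1:5) {
      if (m[i, j, k]) brute <- brute + v[i, j, k] * 0.2
    }
    expect_equal(voi_activity(v, m, 0.2), brute)
  })
  expect_error(voi_activity(vol, array(FALSE, c(5, 5, 5)), 0.1),
               class = "mdose_empty_region")
})
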
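test_that("profiles match the closed-form Gaussian vessel and are rotation-equivariant", {
  # analytic Gaussian trough rendered on a fine grid
  nr <- 101; nc <- 101
  sigma_um <- 12; ps <- 2
  ys <- matrix(rep(0:(nr - 1), nc), nr, nc)
  img <- 1000 * (1 - 0.6 * exp(-((ys - 50)^2 * ps^2) / (2 * sigma_um^2)))
  pr <- vessel_probes("v1", y = 50, x = 50, normal_dy = 1, normal_dx = 0,
                      half_length_um = 60, type = "artery")
  prof <- extract_profile(img, pr, pixel_size = ps)
  expect_equal(prof$intensity,
               oracle_gaussian_profile(prof$s_um, 0.6, sigma_um),
               tolerance = 1e-3 * 1000)
  # rotating image and probe by 90 degrees gives the identical profile
  img90 <- t(img)[, nr:1]   # counter-clockwise rotation
  pr90 <- vessel_probes("v1", y = 50, x = 50, normal_dy = 0, normal_dx = 1,
                        half_length_um = 60, type = "artery")
  prof90 <- extract_profile(t(img), pr90, pixel_size = ps)
  expect_equal(prof90$intensity, prof$intensity, tolerance = 1e-6)
  expect_error(extract_profile(img, vessel_probes("v", 2, 2, 1, 0, 300, "artery"),
                               pixel_size = ps),
               "exits the image")
})

test_that("FWHM is exact for top-hat and analytic for Gaussian troughs", {
  # top-hat trough of width 20 samples at 1 um spacing -> 20 um
  prof <- rep(100, 101)
  prof[41:60] <- 40
  expect_equal(fwhm_diameter(prof, spacing_um = 1), 20, tolerance = 1.01)
  # Gaussian trough, sigma 10 um -> FWHM 2 sqrt(2 ln 2) * 10 = 23.55
  s <- seq(-60, 60, by = 0.5)
  g <- 1000 * (1 - 0.5 * exp(-s^2 / (2 * 10^2)))
  expect_equal(fwhm_diameter(g, spacing_um = 0.5), 2 * sqrt(2 * log(2)) * 10,
               tolerance = 0.1)
  # flat profile fails
  expect_true(is.na(fwhm_diameter(rep(7, 80), spacing_um = 1)))
  # extremum at the edge fails
  ramp <- seq(100, 10, length.out = 50)
  expect_true(is.na(fwhm_diameter(ramp, spacing_um = 1)))
})

test_that("FWHM is invariant to affine intensity transforms", {
  s <- seq(-50, 50, by = 0.5)
  g <- 1 - 0.4 * exp(-s^2 / (2 * 8^2))
  d0 <- fwhm_diameter(g, spacing_um = 0.5)
  for (gain in c(0.5, 3, 1000)) {
    for (off in c(-5, 0, 40)) {
      expect_equal(fwhm_diameter(gain * g + off, spacing_um = 0.5), d0,
                   tolerance = 1e-9)
    }
  }
})

test_that("bright-vessel polarity measures peaks instead of troughs", {
  s <- seq(-50, 50, by = 0.5)
  g <- 100 + 50 * exp(-s^2 / (2 * 6^2))
  expect_equal(fwhm_diameter(g, spacing_um = 0.5, polarity = "bright_vessel"),
               2 * sqrt(2 * log(2)) * 6, tolerance = 0.15)
  expect_true(is.na(fwhm_diameter(g, spacing_um = 0.5)))  # wrong polarity
})

test_that("percent dilation handles plateaus, missing frames and unit scaling", {
  par <- stimulus_paradigm("hypercapnia", onsets = 30, stim_duration = 40,
                           baseline_duration = 30)
  tt <- 0:99
  d <- rep(50, 100)
  expect_equal(percent_dilation(d, tt, par)$percent_change, 0)
  d2 <- d
  d2[tt >= 40 & tt < 60] <- 55
  pd <- percent_dilation(d2, tt, par, smooth = 1)
  expect_equal(pd$percent_change, 10)
  expect_equal(pd$baseline_um, 50)
  # unit invariance: px vs um scaling leaves the percent unchanged
  pd_px <- percent_dilation(d2 / 33.7, tt, par, smooth = 1)
  expect_equal(pd_px$percent_change, pd$percent_change, tolerance = 1e-12)
  # >20% missing in a window excludes the vessel
  d3 <- d2
  d3[sample(which(tt < 30), 8)] <- NA
  expect_true(is.na(percent_dilation(d3, tt, par)$percent_change))
})

test_that("synthetic vessels recover diameter and dilation truth", {
  v <- gen_vessel_frame_series(diameters_um = c(30, 54, 120),
                               dilation_pct = 8, snr = 10,
                               frame_rate = 0.5, seed = 45)
  recs <- vessel_records(v$stack, v$probes, v$paradigm)
  expect_equal(recs$baseline_diameter, v$truth$diameters_um, tolerance = 0.02)
  expect_equal(recs$percent_change, rep(8, 3), tolerance = 1)
})

test_that("median split classifies around the cohort median with ties to large", {
  recs <- tibble::tibble(vessel_id = letters[1:6],
                         vessel_type = c(rep("artery", 4), "vein", "vein"),
                         baseline_diameter = c(40, 60, 50, 50, 10, 200),
                         percent_change = rnorm(6))
  out <- median_split(recs)
  expect_equal(attr(out, "median_diameter"), 50)
  expect_equal(out$size_class[1:4], c("small", "large", "large", "large"))
  expect_true(all(is.na(out$size_class[5:6])))
  eqrecs <- tibble::tibble(vessel_type = "artery",
                           baseline_diameter = rep(54, 4))
  expect_warning(out2 <- median_split(eqrecs), "all in-scope")
  expect_true(all(out2$size_class == "large"))
  expect_error(median_split(recs[5:6, ]), "at least two")
})

test_that("lognormal cohort median split is balanced to within one vessel", {
  v <- gen_cohort(level = "vessel", n_per_group = 2,
                  n_vessels_per_session = 8, seed = 46)
  out <- median_split(v$table)
  n_small <- sum(out$size_class == "small", na.rm = TRUE)
  n_large <- sum(out$size_class == "large", na.rm = TRUE)
  expect_lte(abs(n_small - n_large), 1)
})
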
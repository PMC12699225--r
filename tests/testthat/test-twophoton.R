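test_that("printed in-plane resolution follows from the field-of-view geometry", {
  expect_equal(pixel_size_from_fov(1130, 512), 2.207)
})

test_that("volume preprocessing fixes constants and equalises depth bins", {
  cst <- two_photon_volume(array(5, c(8, 20, 20)))
  out <- preprocess_volume(cst)
  expect_equal(out$methoxy, cst$methoxy, tolerance = 1e-10)
  # intensity decaying x0.5 per depth bin is equalised to within 1%
  x <- array(0, c(8, 24, 24))
  bins <- cut(1:8, 4, labels = FALSE)
  for (z in 1:8) x[z, , ] <- 100 * 0.5^(bins[z] - 1)
  out2 <- preprocess_volume(two_photon_volume(x))
  bm <- vapply(1:4, function(b) mean(out2$methoxy[bins == b, , ]), numeric(1))
  expect_true(all(abs(bm / bm[1] - 1) < 0.01))
  expect_warning(preprocess_volume(two_photon_volume(array(1, c(1, 10, 10)))),
                 "single-slice")
})

test_that("the 3x3 median rejects salt-and-pepper impulses", {
  withr::local_seed(51)
  x <- array(100, c(3, 30, 30))
  idx <- sample(900, 20)
  sl <- x[2, , ]
  sl[idx] <- c(rep(0, 10), rep(1000, 10))
  x[2, , ] <- sl
  out <- preprocess_volume(two_photon_volume(x), sigma = 0, flat_sigma = 0,
                           n_depth_bins = 1)
  dev <- abs(out$methoxy[2, , ] - 100)
  expect_lt(max(dev[2:29, 2:29]), 3 * sd(sl))
})

test_that("CAA coverage follows the within-vessel mean + 1.5 SD rule", {
  # uniform vessel (SD 0): strict inequality gives 0%
  vol <- two_photon_volume(array(50, c(2, 10, 10)))
  outl <- matrix(0L, 10, 10); outl[, 3:6] <- 1L
  cc <- caa_coverage(vol, outl)
  expect_equal(cc$coverage, 0)
  # two vessels with coverages 10% and 30% and equal areas pool to 20%
  # (fractions kept below the point where a mean + 1.5 SD threshold would
  # swallow the bright mode itself)
  m <- array(100, c(1, 20, 20))
  o2 <- matrix(0L, 20, 20)
  o2[1:10, 1:4] <- 1L; o2[1:10, 11:14] <- 2L
  m[1, 1, 1:4] <- 1000                       # 4 of 40 px  -> 10%
  for (r in 1:3) m[1, r, 11:14] <- 1000      # 12 of 40 px -> 30%
  cc2 <- caa_coverage(two_photon_volume(m), o2)
  expect_equal(sort(cc2$per_vessel$coverage), c(10, 30))
  expect_equal(cc2$coverage, 20)
  expect_warning(caa_coverage(two_photon_volume(m),
                              list(o2 == 1, matrix(FALSE, 20, 20))),
                 "empty outline")
})

test_that("CAA coverage is invariant to gain rescaling", {
  g <- gen_twophoton_volume(seed = 52)
  pp <- preprocess_volume(g$volume)
  c1 <- caa_coverage(pp, g$outlines)$coverage
  pp2 <- pp
  pp2$methoxy <- pp$methoxy * 4.2
  c2 <- caa_coverage(pp2, g$outlines)$coverage
  expect_equal(c1, c2, tolerance = 1e-10)
})

test_that("plaque segmentation counts constructed components and sizes exactly", {
  # a 3x3x3 cube (27 voxels) on dim background: one plaque of 27 voxels
  x <- array(0.1, c(10, 12, 12))
  x[4:6, 4:6, 4:6] <- 1.0
  vol <- two_photon_volume(x, voxel_size = c(3, 2.207, 2.207))
  pv <- plaque_volume(vol)
  expect_equal(pv$n_plaques, 1L)
  expect_equal(pv$plaque_volume_um3, 27 * 3 * 2.207^2)
  # a blob of exactly 15 voxels is rejected (strictly greater than 15)
  y <- array(0.1, c(8, 10, 10))
  y[3:5, 3:7, 3] <- 1.0   # 3 x 5 x 1 = 15 voxels
  pv15 <- plaque_volume(two_photon_volume(y))
  expect_equal(pv15$n_plaques, 0L)
  expect_equal(pv15$plaque_volume_um3, 0)
  # 16 voxels passes
  y[3, 3, 4] <- 1.0
  pv16 <- plaque_volume(two_photon_volume(y))
  expect_equal(pv16$n_plaques, 1L)
  # all-zero volume
  z <- plaque_volume(two_photon_volume(array(0, c(4, 6, 6))))
  expect_equal(z$n_plaques, 0L)
  expect_equal(z$plaque_volume_um3, 0)
})

test_that("26- vs 6-connectivity changes diagonal linkage", {
  x <- array(0, c(6, 6, 6))
  x[2, 2, 2] <- 1; x[3, 3, 3] <- 1   # diagonal neighbours
  lab26 <- mesovasc:::label_components_3d(x > 0, 26L)
  lab6 <- mesovasc:::label_components_3d(x > 0, 6L)
  expect_equal(max(lab26), 1L)
  expect_equal(max(lab6), 2L)
})

test_that("raising the plaque threshold never increases plaque volume", {
  g <- gen_twophoton_volume(seed = 53)
  pp <- preprocess_volume(g$volume)
  cc <- caa_coverage(pp, g$outlines)
  vols <- vapply(seq(0.4, 0.8, by = 0.1), function(f) {
    plaque_volume(pp, cc$caa_mask, factor = f)$plaque_volume_um3
  }, numeric(1))
  expect_true(all(diff(vols) <= 1e-9))
})

test_that("session averaging pools images arithmetically", {
  one <- tibble::tibble(caa_coverage = 12, plaque_volume = 500)
  expect_equal(session_average(one)$caa_coverage, 12)
  two <- tibble::tibble(caa_coverage = c(10, 20), plaque_volume = c(100, 300))
  avg <- session_average(two)
  expect_equal(avg$caa_coverage, 15)
  expect_equal(avg$plaque_volume, 200)
  expect_equal(avg$n_images, 2L)
  expect_error(session_average(two[0, ]), "at least one")
})
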
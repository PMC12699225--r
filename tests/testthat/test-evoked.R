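make_step_stack <- function(nt = 80, nr = 8, nc = 9, base = 100, amp = 0.1,
                            onsets = c(20, 60) / 10, rate = 10) {
  tt <- (seq_len(nt) - 1) / rate
  fr <- array(base, c(nt, nr, nc))
  for (on in onsets) fr[tt >= on & tt < on + 2, , ] <- base * (1 + amp)
  channel_stack(fr, "gcamp470", frame_times = tt)
}

test_that("fractional change is exact for plateau steps and zero for constants", {
  par <- stimulus_paradigm("whisker", onsets = c(2, 6), stim_duration = 2)
  cst <- channel_stack(array(100, c(80, 8, 9)), "gcamp470")
  m0 <- trial_fractional_change(cst, par, response_window = 1)
  expect_true(all(abs(m0$dff) < 1e-12))

  st <- make_step_stack(amp = 0.10)
  m <- trial_fractional_change(st, par, response_window = 1)
  plateau <- m$dff[m$times >= 0.1 & m$times < 1.9, 4, 4]
  expect_equal(plateau, rep(0.10, length(plateau)))
})

test_that("dF/F0 is invariant to intensity rescaling", {
  withr::local_seed(31)
  par <- stimulus_paradigm("whisker", onsets = c(2, 6), stim_duration = 2)
  st <- make_step_stack(amp = 0.05)
  st$frames <- st$frames + array(rnorm(length(st$frames)), dim(st$frames))
  st2 <- st
  st2$frames <- st$frames * 3.7
  m1 <- trial_fractional_change(st, par)
  m2 <- trial_fractional_change(st2, par)
  expect_equal(m1$dff, m2$dff, tolerance = 1e-12)
})

test_that("pixels with non-positive baseline are flagged invalid", {
  par <- stimulus_paradigm("whisker", onsets = 2, stim_duration = 2)
  st <- make_step_stack(nt = 60, onsets = 2)
  st$frames[, 3, 3] <- 0
  m <- trial_fractional_change(st, par)
  expect_false(m$valid[3, 3])
  expect_true(all(is.na(m$dff[, 3, 3])))
  amap <- activation_map(m)
  expect_true(is.na(amap[3, 3]))
})

test_that("greedy ROI matches the priority-queue oracle on smooth random maps", {
  withr::local_seed(32)
  for (rep in 1:5) {
    map <- mesovasc:::gaussian_blur(matrix(rnorm(40 * 50), 40, 50), 3)
    roi <- extract_barrel_roi(map, k = 100)
    expect_identical(roi$grid, oracle_greedy_roi(map, 100))
    expect_equal(sum(roi$grid), 100L)
    # always contains the global maximum
    expect_true(roi$grid[which.max(map)])
  }
})

test_that("ROI construction honours unique blocks and seed dominance", {
  map <- matrix(0, 30, 30)
  map[11:20, 11:20] <- 1
  roi <- extract_barrel_roi(map, k = 100)
  expect_identical(which(roi$grid), which(map == 1))

  two <- matrix(0, 40, 40)
  two[2:13, 2:13] <- 1      # 144 px at value 1
  two[25:36, 25:36] <- 2    # 144 px at value 2
  roi2 <- extract_barrel_roi(two, k = 100)
  expect_true(all(two[roi2$grid] == 2))
})

test_that("ROI is 8-connected", {
  withr::local_seed(33)
  map <- mesovasc:::gaussian_blur(matrix(rnorm(30 * 30), 30, 30), 2)
  roi <- extract_barrel_roi(map, k = 60)
  lab <- mesovasc:::label_components_3d(array(roi$grid, c(1, 30, 30)), 26L)
  expect_equal(max(lab), 1L)
})

test_that("peak response is linear over trials and exact on plateaus", {
  # two noiseless trials with peaks 2% and 4% -> trial-averaged peak 3%
  nt <- 120; rate <- 10
  tt <- (seq_len(nt) - 1) / rate
  fr <- array(100, c(nt, 6, 6))
  fr[tt >= 2 & tt < 4, , ] <- 102
  fr[tt >= 8 & tt < 10, , ] <- 104
  st <- channel_stack(fr, "gcamp470", frame_times = tt)
  par <- stimulus_paradigm("whisker", onsets = c(2, 8), stim_duration = 2)
  m <- trial_fractional_change(st, par, response_window = 1)
  roi <- mask_image(matrix(TRUE, 6, 6), "barrel_roi")
  p <- peak_response(m, roi)
  expect_equal(p$peak, 3, tolerance = 1e-10)
  expect_error(peak_response(m, mask_image(matrix(FALSE, 6, 6), "barrel_roi")),
               "empty ROI")
})

test_that("ratio arithmetic and error path", {
  expect_equal(bold_gcamp_ratio(0.5, 1.0), 0.5)
  expect_equal(bold_gcamp_ratio(2.0, 2.0), 1.0)
  expect_error(bold_gcamp_ratio(1, 0), "undefined")
})

test_that("trial averaging reduces peak variance about 1/sqrt(n)", {
  withr::local_seed(34)
  peak_of <- function(n_trials) {
    par <- stimulus_paradigm("whisker",
                             onsets = 4 + 16 * (seq_len(n_trials) - 1),
                             stim_duration = 2)
    nt <- (max(par$onsets) + 14) * 10
    tt <- (seq_len(nt) - 1) / 10
    fr <- array(100 + rnorm(nt * 36, sd = 2), c(nt, 6, 6))
    st <- channel_stack(fr, "gcamp470", frame_times = tt)
    m <- trial_fractional_change(st, par, response_window = 2)
    mean(m$dff[10, , ], na.rm = TRUE)   # fixed epoch sample, null response
  }
  v1 <- var(replicate(40, peak_of(1)))
  v8 <- var(replicate(40, peak_of(8)))
  expect_lt(v8, v1 / 3)   # ~ 1/8 expected; generous Monte-Carlo margin
})
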
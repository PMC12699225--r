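test_that("balanced two-group fit reproduces the group-mean difference exactly", {
  withr::local_seed(61)
  d <- tibble::tibble(
    mouse_id = rep(sprintf("m%02d", 1:10), each = 4),
    genotype = rep(c("WT", "APP_PS1"), each = 20),
    y = rnorm(40)
  )
  fit <- fit_lme(d, y ~ genotype, group = "mouse_id")
  diff_hat <- tidy(fit)$estimate[tidy(fit)$term == "genotypeWT"]
  expect_equal(diff_hat,
               mean(d$y[d$genotype == "WT"]) - mean(d$y[d$genotype == "APP_PS1"]),
               tolerance = 1e-8)
})

test_that("one observation per mouse falls back to the OLS oracle", {
  withr::local_seed(62)
  d <- tibble::tibble(mouse_id = sprintf("m%02d", 1:30),
                      age = runif(30, 3, 20), y = rnorm(30))
  expect_warning(fit <- fit_lme(d, y ~ age), "inestimable")
  ols <- lm(y ~ age, data = d)
  expect_equal(tidy(fit)$estimate, unname(coef(ols)), tolerance = 1e-12)
  expect_equal(glance(fit)$engine, "lm")
})

test_that("rank-deficient designs are rejected by name", {
  d <- tibble::tibble(mouse_id = rep(c("a", "b"), 10),
                      x1 = rnorm(20))
  d$x2 <- 2 * d$x1
  d$y <- rnorm(20)
  expect_error(fit_lme(d, y ~ x1 + x2), "rank-deficient")
})

test_that("fixed effects agree with an independent lme4 fit", {
  co <- gen_cohort(betas = list(age = -0.05, age_genotypeAD = -0.08), seed = 63)
  fit <- fit_lme(co$table, outcome ~ age * genotype)
  lmer_fit <- lme4::lmer(outcome ~ age * genotype + (1 | mouse_id),
                         data = co$table, REML = TRUE)
  expect_equal(tidy(fit)$estimate, unname(lme4::fixef(lmer_fit)),
               tolerance = 1e-4)
  expect_equal(glance(fit)$sd_intercept,
               attr(lme4::VarCorr(lmer_fit)$mouse_id, "stddev")[[1]],
               tolerance = 1e-3)
})

test_that("simulated fixed effects fall inside their 95% CIs at the nominal rate", {
  withr::local_seed(64)
  hits <- 0L
  n_sim <- 60
  for (i in seq_len(n_sim)) {
    co <- gen_cohort(n_per_group = 4, betas = list(age = -0.1),
                     sd_intercept = 0, sd_resid = 1, seed = 6400 + i)
    fit <- fit_lme(co$table, outcome ~ age)
    row <- tidy(fit)[tidy(fit)$term == "age", ]
    if (row$conf_low <= -0.1 && -0.1 <= row$conf_high) hits <- hits + 1L
  }
  expect_gte(hits, ceiling(0.85 * n_sim))   # >= 93% expected; MC margin
})

test_that("Johnson-Neyman handles the no-interaction edge cases", {
  # b3 = 0, b1 significant: significant everywhere, no boundaries
  jn1 <- mesovasc:::jn_from_coefs(b1 = 2, b3 = 0, v11 = 0.04, v33 = 0,
                                  v13 = 0, t_crit = 2)
  expect_length(jn1$boundaries, 0)
  expect_true(all(jn1$significant))
  # b3 = 0, b1 not significant: never significant
  jn2 <- mesovasc:::jn_from_coefs(b1 = 0.1, b3 = 0, v11 = 0.04, v33 = 0,
                                  v13 = 0, t_crit = 2)
  expect_length(jn2$boundaries, 0)
  expect_false(any(jn2$significant))
})

test_that("Johnson-Neyman boundaries match the grid-search oracle", {
  # a fixed numeric case with correlated coefficient covariance
  jn <- mesovasc:::jn_from_coefs(b1 = 2, b3 = -0.2, v11 = 0.25, v33 = 0.01,
                                 v13 = -0.03, t_crit = 2)
  orc <- oracle_jn_grid(2, -0.2, 0.25, 0.01, -0.03, 2)
  expect_equal(jn$boundaries, orc, tolerance = 1e-4)
  # random draws with valid covariance structure
  withr::local_seed(65)
  for (i in 1:25) {
    L <- matrix(c(runif(1, 0.1, 1), 0, runif(2, -0.3, 0.3)), 2, 2)
    V <- L %*% t(L) + diag(1e-4, 2)
    b <- rnorm(2, sd = c(1, 0.3))
    jn <- mesovasc:::jn_from_coefs(b[1], b[2], V[1, 1], V[2, 2], V[1, 2],
                                   t_crit = 2.05)
    orc <- oracle_jn_grid(b[1], b[2], V[1, 1], V[2, 2], V[1, 2], 2.05)
    expect_equal(jn$boundaries, orc, tolerance = 1e-4)
  }
})

test_that("johnson_neyman extracts the interaction from a fitted model", {
  co <- gen_cohort(level = "vessel", jn_boundary_month = 11,
                   n_vessels_per_session = 6, seed = 66)
  fit <- fit_lme(co$table, percent_change ~ baseline_diameter * age)
  jn <- johnson_neyman(fit, "baseline_diameter", "age")
  expect_s3_class(jn, "vasc_jn")
  expect_true(length(jn$boundaries) >= 1)
  # the loss-of-significance boundary sits near the planted 11 months
  expect_equal(min(jn$boundaries), 11, tolerance = 2)
  expect_error(johnson_neyman(fit, "baseline_diameter", "nope"),
               "must contain")
})

test_that("Holm adjustment reproduces hand-computed step-down values", {
  expect_equal(holm_adjust(0.05), 0.05)
  expect_equal(holm_adjust(c(0.01, 0.03, 0.04)), c(0.03, 0.06, 0.06))
  expect_equal(holm_adjust(numeric(0)), numeric(0))
  withr::local_seed(67)
  for (i in 1:10) {
    p <- runif(sample(1:8, 1))
    adj <- holm_adjust(p)
    expect_equal(adj, oracle_holm(p))
    expect_true(all(adj >= p) && all(adj <= 1))
    expect_equal(order(adj[order(p)]), seq_along(p))  # monotone step-down
  }
  expect_error(holm_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("median-split contrasts detect a planted old-female small-vessel deficit", {
  withr::local_seed(68)
  detected <- 0L; null_fp <- 0L
  n_sim <- 25
  for (i in seq_len(n_sim)) {
    co <- gen_cohort(level = "vessel", n_per_group = 4,
                     n_vessels_per_session = 6,
                     betas = list(diameter = 0, age = 0, intercept = 20),
                     sd_intercept = 0.3, sd_resid = 2, seed = 6800 + i)
    tab <- median_split(co$table)
    # plant: old females' small vessels dilate 3 percentage points less
    hit <- tab$size_class == "small" & tab$sex == "F" & tab$age >= 11
    tab$percent_change[hit] <- tab$percent_change[hit] - 3
    ct <- split_contrasts(tab, age_cut = 11)
    row <- ct[ct$size_class == "small" & ct$sex == "F", ]
    if (!is.na(row$p_adjusted) && row$p_adjusted < 0.05 && row$estimate > 0) {
      detected <- detected + 1L
    }
    null_row <- ct[ct$size_class == "large" & ct$sex == "M", ]
    if (!is.na(null_row$p_adjusted) && null_row$p_adjusted < 0.05) {
      null_fp <- null_fp + 1L
    }
  }
  expect_gte(detected, ceiling(0.8 * n_sim))
  expect_lte(null_fp, ceiling(0.2 * n_sim))
})

test_that("contrast table reports cell counts and missing cells", {
  withr::local_seed(69)
  tab <- tibble::tibble(
    mouse_id = rep(c("a", "b", "c", "d"), each = 6),
    sex = rep(c("F", "M"), each = 12),
    age = rep(c(5, 15, 5), 8),
    size_class = rep(c("small", "large"), 12),
    percent_change = rnorm(24, 10)
  )
  ct <- split_contrasts(tab)
  expect_true(all(c("size_class", "sex", "estimate", "p_adjusted",
                    "n_young", "n_old") %in% names(ct)))
  expect_equal(nrow(ct), 4L)
  # empty old-male cell -> missing contrast
  tab2 <- tab[!(tab$sex == "M" & tab$age >= 11), ]
  ct2 <- split_contrasts(tab2)
  expect_true(all(is.na(ct2$estimate[ct2$sex == "M"])))
})
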
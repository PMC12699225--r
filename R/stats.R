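# Cohort-level inference: linear mixed-effects models with a mouse random
# intercept, Johnson-Neyman conditional-effect regions, Holm-adjusted
# median-split contrasts.

#' Fit a linear mixed-effects model with a mouse random intercept
#'
#' REML fit of `fixed` with a random intercept per grouping unit (the
#' mouse), via [nlme::lme()]. Per-term Type-III (marginal) F tests use the
#' between-within denominator-df convention; the convention is recorded in
#' the returned object. When the design has one observation per group the
#' random intercept is inestimable: a warning is raised and an ordinary
#' least-squares fit is returned instead (flagged in the metadata).
#'
#' @param data A long-format cohort table (data frame); one row per session
#'   or per vessel measurement.
#' @param fixed Fixed-effects formula, e.g. `peak_bold ~ age * genotype`.
#' @param group Name of the grouping column (default `"mouse_id"`).
#' @return A `vasc_lme` object: the underlying fit plus tidy fixed-effect
#'   and ANOVA tables.
#' @export
fit_lme <- function(data, fixed, group = "mouse_id") {
  fixed <- as.formula(fixed)
  if (!group %in% names(data)) abort(sprintf("column '%s' not found", group))
  vars <- all.vars(fixed)
  data <- as.data.frame(data)[stats::complete.cases(data[, c(vars, group)]),
                              , drop = FALSE]
  mm <- model.matrix(fixed, data)
  if (qr(mm)$rank < ncol(mm)) {
    abort(sprintf("rank-deficient fixed-effects design for %s",
                  deparse(fixed)))
  }
  n_groups <- length(unique(data[[group]]))
  if (n_groups < 2L) abort("need at least two groups")
  singleton <- nrow(data) == n_groups
  ranform <- as.formula(paste("~ 1 |", group))
  fit <- NULL
  if (!singleton) {
    fit <- tryCatch(
      nlme::lme(fixed, random = ranform, data = data, method = "REML"),
      error = function(e) NULL)
  }
  if (is.null(fit)) {
    if (singleton) {
      warn("one observation per group: random intercept inestimable, falling back to OLS")
    } else {
      warn("mixed-model fit failed: falling back to OLS")
    }
    ols <- lm(fixed, data = data)
    sm <- summary(ols)$coefficients
    ci <- confint(ols)
    fe <- tibble::tibble(term = rownames(sm), estimate = unname(sm[, 1L]),
                         std_error = unname(sm[, 2L]), df = ols$df.residual,
                         statistic = unname(sm[, 3L]),
                         p_value = unname(sm[, 4L]),
                         conf_low = unname(ci[, 1L]),
                         conf_high = unname(ci[, 2L]))
    dr <- stats::drop1(ols, scope = attr(terms(fixed), "term.labels"),
                       test = "F")
    an <- tibble::tibble(term = rownames(dr)[-1L],
                         num_df = dr$Df[-1L], den_df = ols$df.residual,
                         f_value = dr$`F value`[-1L],
                         p_value = dr$`Pr(>F)`[-1L])
    obj <- list(fit = ols, engine = "lm", fixed = fixed, group = group,
                fixed_effects = fe, anova = an, vcov = vcov(ols),
                sigma = sigma(ols), sd_intercept = 0,
                n_obs = nrow(data), n_groups = n_groups,
                resid_df = ols$df.residual,
                ddf_convention = "residual (OLS fallback)")
    return(structure(obj, class = "vasc_lme"))
  }
  sm <- summary(fit)$tTable
  ql <- qt(0.975, sm[, "DF"])
  fe <- tibble::tibble(term = rownames(sm), estimate = unname(sm[, "Value"]),
                       std_error = unname(sm[, "Std.Error"]),
                       df = unname(sm[, "DF"]),
                       statistic = unname(sm[, "t-value"]),
                       p_value = unname(sm[, "p-value"]),
                       conf_low = unname(sm[, "Value"] - ql * sm[, "Std.Error"]),
                       conf_high = unname(sm[, "Value"] + ql * sm[, "Std.Error"]))
  av <- stats::anova(fit, type = "marginal")
  an <- tibble::tibble(term = rownames(av), num_df = av$numDF,
                       den_df = av$denDF, f_value = av$`F-value`,
                       p_value = av$`p-value`)
  an <- an[an$term != "(Intercept)", , drop = FALSE]
  vc <- nlme::VarCorr(fit)
  obj <- list(fit = fit, engine = "nlme", fixed = fixed, group = group,
              fixed_effects = fe, anova = an, vcov = vcov(fit),
              sigma = fit$sigma,
              sd_intercept = suppressWarnings(as.numeric(vc["(Intercept)", "StdDev"])),
              n_obs = nrow(data), n_groups = n_groups,
              resid_df = min(sm[, "DF"]),
              ddf_convention = "between-within (nlme marginal/Type-III)")
  structure(obj, class = "vasc_lme")
}

#' @export
print.vasc_lme <- function(x, ...) {
  cat(sprintf("<vasc_lme: %s | random ~1|%s | %d obs, %d groups | df: %s>\n",
              deparse(x$fixed), x$group, x$n_obs, x$n_groups,
              x$ddf_convention))
  print(x$fixed_effects)
  invisible(x)
}

#' Tidy / glance methods for mixed-model fits
#'
#' `tidy()` returns the fixed-effect table (term, estimate, std_error, df,
#' statistic, p_value, conf_low, conf_high); `tidy(effects = "anova")` the
#' Type-III F table. `glance()` returns one row of fit summaries.
#'
#' @param x A `vasc_lme` object.
#' @param effects `"fixed"` or `"anova"`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy vasc_lme
#' @export
tidy.vasc_lme <- function(x, effects = c("fixed", "anova"), ...) {
  effects <- match.arg(effects)
  if (effects == "fixed") x$fixed_effects else x$anova
}

#' @rdname tidy.vasc_lme
#' @method glance vasc_lme
#' @export
glance.vasc_lme <- function(x, ...) {
  tibble::tibble(n_obs = x$n_obs, n_groups = x$n_groups,
                 sigma = x$sigma, sd_intercept = x$sd_intercept,
                 engine = x$engine, ddf = x$ddf_convention)
}

#' Johnson-Neyman region for a conditional slope
#'
#' For a model containing `x`, `m` and their interaction, the conditional
#' slope of `x` at moderator value `m` is `theta(m) = b_x + b_xm * m` with
#' variance `var(b_x) + m^2 var(b_xm) + 2 m cov(b_x, b_xm)`. The region
#' boundaries are the real roots of `theta(m)^2 = t_crit^2 var(theta(m))`
#' (a quadratic in `m`), with `t_crit` at the fit's fixed-effects residual
#' df and the given alpha. When no real root exists the slope is either
#' significant for every moderator value or for none.
#'
#' @param fit A `vasc_lme` containing `predictor`, `moderator` and their
#'   interaction.
#' @param predictor,moderator Term names as they appear in the model.
#' @param alpha Two-sided significance level, default 0.05.
#' @return A `vasc_jn` object: `boundaries` (0, 1 or 2 sorted values),
#'   `significant` (logical per interval), `intervals` tibble, plus the
#'   inputs needed to reconstruct `theta(m)`.
#' @export
johnson_neyman <- function(fit, predictor, moderator, alpha = 0.05) {
  stopifnot(inherits(fit, "vasc_lme"))
  V <- as.matrix(fit$vcov)
  cn <- colnames(V)
  inter <- intersect(c(paste0(predictor, ":", moderator),
                       paste0(moderator, ":", predictor)), cn)
  if (!predictor %in% cn || length(inter) == 0L) {
    abort("fit must contain the predictor and the predictor:moderator interaction")
  }
  inter <- inter[1L]
  b1 <- fit$fixed_effects$estimate[fit$fixed_effects$term == predictor]
  b3 <- fit$fixed_effects$estimate[fit$fixed_effects$term == inter]
  v11 <- V[predictor, predictor]
  v33 <- V[inter, inter]
  v13 <- V[predictor, inter]
  df <- fit$resid_df
  tc <- qt(1 - alpha / 2, df)
  jn_from_coefs(b1, b3, v11, v33, v13, tc, df = df, alpha = alpha,
                predictor = predictor, moderator = moderator)
}

# Core quadratic solver, exposed for direct use with known coefficients.
jn_from_coefs <- function(b1, b3, v11, v33, v13, t_crit, df = Inf,
                          alpha = 0.05, predictor = "x", moderator = "m") {
  A <- b3^2 - t_crit^2 * v33
  B <- 2 * (b1 * b3 - t_crit^2 * v13)
  C <- b1^2 - t_crit^2 * v11
  disc <- B^2 - 4 * A * C
  boundaries <- numeric(0)
  if (abs(A) < .Machine$double.eps^0.75) {
    if (abs(B) > .Machine$double.eps^0.5) boundaries <- -C / B
  } else if (disc > 0) {
    boundaries <- sort((-B + c(-1, 1) * sqrt(disc)) / (2 * A))
  } else if (disc == 0) {
    boundaries <- -B / (2 * A)
  }
  probe <- function(m) {
    th <- b1 + b3 * m
    se <- sqrt(v11 + m^2 * v33 + 2 * m * v13)
    abs(th) / se > t_crit
  }
  pts <- if (length(boundaries) == 0L) 0 else {
    mids <- c(min(boundaries) - 1,
              if (length(boundaries) == 2L) mean(boundaries),
              max(boundaries) + 1)
    mids
  }
  significant <- vapply(pts, probe, logical(1))
  intervals <- tibble::tibble(
    lower = c(-Inf, boundaries),
    upper = c(boundaries, Inf),
    significant = significant
  )
  structure(list(boundaries = boundaries, significant = significant,
                 intervals = intervals, b1 = b1, b3 = b3,
                 v11 = v11, v33 = v33, v13 = v13,
                 t_crit = t_crit, df = df, alpha = alpha,
                 predictor = predictor, moderator = moderator),
            class = "vasc_jn")
}

#' @export
print.vasc_jn <- function(x, ...) {
  cat(sprintf("<Johnson-Neyman: slope of %s vs %s, alpha = %g>\n",
              x$predictor, x$moderator, x$alpha))
  print(x$intervals)
  invisible(x)
}

#' @method tidy vasc_jn
#' @export
tidy.vasc_jn <- function(x, ...) x$intervals

#' Holm step-down adjustment
#'
#' Step-down Holm adjustment of a vector of p-values (monotone, each
#' adjusted value at least the raw one, capped at 1).
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in the input order.
#' @export
holm_adjust <- function(pvalues) {
  if (length(pvalues) == 0L) return(numeric(0))
  if (any(!is.na(pvalues) & (pvalues < 0 | pvalues > 1))) {
    abort("p-values must lie in [0, 1]")
  }
  p.adjust(pvalues, method = "holm")
}

#' Median-split group contrasts with Holm adjustment
#'
#' Within each vessel size class (from [median_split()]), fits a mixed
#' model of percent dilation on the sex-by-age-bin group factor (ages binned
#' at `age_cut` months) with a mouse random intercept, then tests the young
#' vs old contrast within each sex via [emmeans::emmeans()]. The whole
#' contrast family (both sexes x both size classes) is Holm-adjusted
#' together. Empty cells skip their contrast (reported as missing).
#'
#' @param records Vessel records with `size_class`, `percent_change`,
#'   `sex`, `age`, `mouse_id`.
#' @param age_cut Age bin boundary in months (default 11; `old` is
#'   `>= age_cut`).
#' @param alpha Significance level recorded alongside.
#' @return A tibble: size_class, sex, estimate (young - old), std_error,
#'   df, p_value, p_adjusted, n_young, n_old.
#' @export
split_contrasts <- function(records, age_cut = 11, alpha = 0.05) {
  need <- c("size_class", "percent_change", "sex", "age", "mouse_id")
  if (!all(need %in% names(records))) {
    abort(paste("records must contain", paste(need, collapse = ", ")))
  }
  records <- records[!is.na(records$size_class) &
                       !is.na(records$percent_change), , drop = FALSE]
  records$age_bin <- ifelse(records$age < age_cut, "young", "old")
  records$grp <- factor(paste(records$sex, records$age_bin, sep = "."))
  rows <- list()
  for (sc in sort(unique(records$size_class))) {
    sub <- records[records$size_class == sc, , drop = FALSE]
    sub$grp <- droplevels(sub$grp)
    fit <- tryCatch(
      nlme::lme(percent_change ~ 0 + grp, random = ~ 1 | mouse_id,
                data = sub, method = "REML"),
      error = function(e) NULL)
    if (is.null(fit)) {
      # degenerate designs (e.g. one vessel per cell): plain fixed-effects fit
      fit <- lm(percent_change ~ 0 + grp, data = sub)
    }
    emm <- tryCatch(emmeans::emmeans(fit, ~ grp), error = function(e) NULL)
    for (sx in sort(unique(records$sex))) {
      gy <- paste(sx, "young", sep = ".")
      go <- paste(sx, "old", sep = ".")
      ny <- sum(sub$grp == gy); no <- sum(sub$grp == go)
      if (ny == 0L || no == 0L || is.null(emm)) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          size_class = sc, sex = sx, estimate = NA_real_,
          std_error = NA_real_, df = NA_real_, p_value = NA_real_,
          n_young = ny, n_old = no)
        next
      }
      lv <- as.character(summary(emm)$grp)
      w <- as.numeric(lv == gy) - as.numeric(lv == go)
      ct <- summary(emmeans::contrast(emm, method = list(young_vs_old = w)))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        size_class = sc, sex = sx, estimate = ct$estimate,
        std_error = ct$SE, df = ct$df, p_value = ct$p.value,
        n_young = ny, n_old = no)
    }
  }
  out <- dplyr::bind_rows(rows)
  out$p_adjusted <- NA_real_
  ok <- !is.na(out$p_value)
  out$p_adjusted[ok] <- holm_adjust(out$p_value[ok])
  attr(out, "alpha") <- alpha
  attr(out, "age_cut") <- age_cut
  out
}
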
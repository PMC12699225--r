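# Scaled-down end-to-end run: synthesize hypercapnia sessions whose planted
# BOLD reactivity declines with age in APP/PS1 mice, push every session
# through the imaging pipeline, and fit the cohort model on the measured
# peaks. Returns the estimated age x genotype interaction (% / month).
run_reactivity_cohort <- function(run_seed, n_per_cell = 4, n_sessions = 3,
                                  b_ga = -0.0004, nr = 32, nc = 44,
                                  frame_rate = 0.1, snr = 5) {
  set.seed(run_seed)
  mice <- expand.grid(g = c("WT", "APP_PS1"), s = c("F", "M"),
                      i = seq_len(n_per_cell), stringsAsFactors = FALSE)
  mice$id <- sprintf("m%02d", seq_len(nrow(mice)))
  u <- rnorm(nrow(mice), 0, 0.001)
  rows <- list()
  k <- 0
  for (m in seq_len(nrow(mice))) {
    ages <- sort(runif(n_sessions, 3, 18))
    for (a in ages) {
      k <- k + 1
      amp <- 0.02 + b_ga * a * (mice$g[m] == "APP_PS1") + u[m] +
        rnorm(1, 0, 0.0008)
      s <- gen_widefield_session("hypercapnia", nr = nr, nc = nc,
                                 frame_rate = frame_rate, snr = snr,
                                 drift_amp = 0.02, amp_bold = amp,
                                 amp_cbv = amp * 1.3,
                                 seed = run_seed * 1000 + k)
      bold <- intensity_correct(s$stacks$bold620, s$skull)
      cbv <- intensity_correct(s$stacks$cbv570, s$skull)
      res <- suppressWarnings(
        hypercapnia_analysis(bold, cbv, s$brain, s$paradigm))
      rows[[k]] <- tibble::tibble(mouse_id = mice$id[m],
                                  genotype = mice$g[m], sex = mice$s[m],
                                  age = a, peak_bold = res$peak_bold)
    }
  }
  tab <- dplyr::bind_rows(rows)
  tab$genotype <- factor(tab$genotype, levels = c("WT", "APP_PS1"))
  fit <- suppressWarnings(fit_lme(tab, peak_bold ~ age * genotype))
  fe <- tidy(fit)
  fe$estimate[fe$term == "age:genotypeAPP_PS1"]
}
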
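# Synthetic widefield sessions, vessel movies, two-photon volumes and
# longitudinal cohorts with recorded ground truth. Every generator is
# deterministic given its seed; every generated observable ships its truth.

gamma_kernel <- function(t, t_peak, shape = 3) {
  # gamma-variate normalised to peak 1 at t_peak; 0 for t < 0
  b <- t_peak / shape
  k <- ifelse(t <= 0, 0, (t / t_peak)^shape * exp(-(t - t_peak) / b))
  k
}

# Sum-of-line-segments vesselness map: dark Gaussian tubes across the canvas.
render_vessel_texture <- function(nr, nc, n_vessels = 6, width_px = 2.5,
                                  depth = 0.5) {
  v <- matrix(0, nr, nc)
  ys <- matrix(rep(seq_len(nr) - 1, nc), nr, nc)
  xs <- matrix(rep(seq_len(nc) - 1, each = nr), nr, nc)
  for (i in seq_len(n_vessels)) {
    th <- runif(1, 0, pi)
    cy <- runif(1, 0.1, 0.9) * (nr - 1)
    cx <- runif(1, 0.1, 0.9) * (nc - 1)
    d <- -(ys - cy) * sin(th) + (xs - cx) * cos(th)   # distance to the line
    v <- pmax(v, exp(-d^2 / (2 * width_px^2)))
  }
  depth * v
}

ellipse_mask <- function(nr, nc, fy = 0.38, fx = 0.38) {
  ys <- (seq_len(nr) - (nr + 1) / 2) / (fy * nr)
  xs <- (seq_len(nc) - (nc + 1) / 2) / (fx * nc)
  outer(ys^2, xs^2, `+`) <= 1
}

#' Generate a synthetic widefield imaging session
#'
#' Emulates one awake-mouse widefield session: three channel stacks (GCaMP
#' 470, OIS-CBV 570, OIS-BOLD 620) on a canvas with vascular texture,
#' brain-ROI and skull-control masks, a stimulus paradigm, plus ground
#' truth. Whisker mode injects a barrel-localised fast GCaMP response
#' (gamma kernel, 0.5-s peak) and a slower, smaller hemodynamic response
#' (1.5-s peak); hypercapnia mode injects tissue-wide dR/R0 plateaus
#' (positive at 620 nm, negative at 570 nm) across the CO2 window. Shared
#' multiplicative illumination drift is written into every pixel including
#' the skull-control region; optional rigid motion follows a sub-pixel
#' random walk; white noise is scaled so that `snr` equals the peak
#' fractional response amplitude divided by the per-pixel per-frame
#' fractional noise SD.
#'
#' @param kind `"whisker"` or `"hypercapnia"`.
#' @param nr,nc Canvas size (default 130 x 174, the binned camera grid).
#' @param frame_rate Per-channel frame rate (Hz), default 10.
#' @param n_trials Whisker trials (default 8) at `isi`-second spacing.
#' @param isi Whisker inter-stimulus interval (s), default 16.
#' @param stim_duration Stimulus length (s): 2 (whisker) or 90 (hypercapnia).
#' @param baseline_duration Pre-onset baseline (s): 2 or 30.
#' @param recovery_duration Hypercapnia recovery per repeat (s), default 270.
#' @param n_repeats Hypercapnia repeats, default 2.
#' @param amp_gcamp,amp_bold,amp_cbv Peak fractional response amplitudes
#'   (e.g. 0.03 = 3% dF/F0). `amp_cbv` is the magnitude of the 570 nm
#'   reflectance drop.
#' @param snr Amplitude-to-noise ratio (see above); `Inf` for noiseless.
#' @param drift_amp Peak-to-peak multiplicative drift amplitude.
#' @param motion_amp Random-walk step SD in px (0 disables motion).
#' @param vessel_fraction Target fraction of the brain ROI covered by dark
#'   vessels (570 nm texture), default 0.2.
#' @param pixel_size um/pixel (default 33.7, the binned resolution).
#' @param seed RNG seed.
#' @return A list: `stacks` (list of three `channel_stack`s), `paradigm`,
#'   `brain`, `skull` (mask_images), `truth`.
#' @export
gen_widefield_session <- function(kind = c("whisker", "hypercapnia"),
                                  nr = 130L, nc = 174L, frame_rate = 10,
                                  n_trials = 8L, isi = 16,
                                  stim_duration = NULL,
                                  baseline_duration = NULL,
                                  recovery_duration = 270, n_repeats = 2L,
                                  amp_gcamp = 0.03, amp_bold = 0.015,
                                  amp_cbv = 0.02, snr = 10,
                                  drift_amp = 0.02, motion_amp = 0,
                                  vessel_fraction = 0.2, pixel_size = 33.7,
                                  seed = 1L) {
  kind <- match.arg(kind)
  withr::with_seed(seed, {
    stim_duration <- stim_duration %||% switch(kind, whisker = 2, hypercapnia = 90)
    baseline_duration <- baseline_duration %||% switch(kind, whisker = 2, hypercapnia = 30)
    if (kind == "whisker") {
      if (baseline_duration + stim_duration + 8 > isi + 6) {
        abort("infeasible config: response window exceeds the inter-stimulus interval")
      }
      onsets <- 2 + baseline_duration + isi * (seq_len(n_trials) - 1)
      total_t <- max(onsets) + isi
    } else {
      cycle <- baseline_duration + stim_duration + recovery_duration
      onsets <- baseline_duration + cycle * (seq_len(n_repeats) - 1)
      total_t <- cycle * n_repeats
    }
    paradigm <- stimulus_paradigm(kind, onsets, stim_duration, baseline_duration)
    nt <- floor(total_t * frame_rate)
    tt <- (seq_len(nt) - 1) / frame_rate

    brain <- ellipse_mask(nr, nc)
    ring <- ellipse_mask(nr, nc, 0.48, 0.48) & !ellipse_mask(nr, nc, 0.44, 0.44)
    skull <- ring
    # vascular texture calibrated to the requested coverage of the brain ROI
    vt <- render_vessel_texture(nr, nc, n_vessels = 8, width_px = 2.5,
                                depth = 1)
    vessel_mask <- matrix(FALSE, nr, nc)
    if (vessel_fraction > 0) {
      thr <- quantile(vt[brain], 1 - vessel_fraction)
      vessel_mask <- vt >= thr & brain
    }
    smooth_bg <- gaussian_blur(matrix(rnorm(nr * nc), nr, nc), 6)
    smooth_bg <- 1 + 0.15 * smooth_bg / max(abs(smooth_bg))
    base <- list(
      gcamp470 = 1500 * smooth_bg * (1 - 0.15 * (vessel_mask * 1)),
      cbv570   = 2500 * smooth_bg * (1 - 0.45 * (vessel_mask * 1)),
      bold620  = 3000 * smooth_bg * (1 - 0.10 * (vessel_mask * 1))
    )

    # temporal response courses, peak amplitude 1
    resp <- list(gcamp470 = numeric(nt), cbv570 = numeric(nt),
                 bold620 = numeric(nt))
    if (kind == "whisker") {
      for (on in onsets) {
        rel <- tt - on
        resp$gcamp470 <- resp$gcamp470 +
          gamma_kernel(rel, 0.5) * as.numeric(rel <= stim_duration + 8)
        hemo <- gamma_kernel(rel, 1.5, shape = 4)
        resp$bold620 <- resp$bold620 + hemo
        resp$cbv570 <- resp$cbv570 + hemo
      }
      for (ch in names(resp)) resp[[ch]] <- pmin(resp[[ch]], 1)
    } else {
      plateau <- numeric(nt)
      for (on in onsets) {
        rel <- tt - on
        ramp <- pmin(pmax(rel / 20, 0), 1) * exp(-pmax(rel - stim_duration, 0) / 20)
        plateau <- pmax(plateau, ramp)
      }
      resp$bold620 <- plateau
      resp$cbv570 <- plateau
      resp$gcamp470 <- numeric(nt)
    }

    # spatial weights: barrel blob for whisker, brain tissue for hypercapnia
    if (kind == "whisker") {
      by <- round(nr * 0.45); bx <- round(nc * 0.6)
      ys <- matrix(rep(seq_len(nr), nc), nr, nc)
      xs <- matrix(rep(seq_len(nc), each = nr), nr, nc)
      # flat-top (super-Gaussian) blob: near-1 across > 150 px so the top-100
      # ROI mean matches the planted amplitude
      r0 <- max(9, 0.07 * min(nr, nc))
      rr <- sqrt((ys - by)^2 + (xs - bx)^2)
      blob <- exp(-(rr / r0)^10)
      w <- blob * brain
      barrel_center <- c(by, bx)
    } else {
      w <- brain * 1
      barrel_center <- NULL
    }

    amps <- list(gcamp470 = amp_gcamp, cbv570 = -amp_cbv, bold620 = amp_bold)
    drift <- drift_amp / 2 * sin(2 * pi * tt / max(total_t / 1.5, 20)) +
      drift_amp / 4 * (tt / max(tt, 1))
    shifts <- matrix(0, nt, 2L)
    if (motion_amp > 0) {
      shifts <- apply(matrix(rnorm(nt * 2, sd = motion_amp), nt, 2L), 2L, cumsum)
      shifts <- shifts - matrix(shifts[1L, ], nt, 2L, byrow = TRUE)
      shifts <- pmin(pmax(shifts, -5), 5)
    }

    stacks <- list()
    for (ch in names(base)) {
      bb <- as.vector(base[[ch]])
      ww <- as.vector(w)
      a <- amps[[ch]]
      # time x pixel: base * (1 + drift) * (1 + a * resp * w) + noise
      Y <- outer(1 + drift, bb)
      if (a != 0) Y <- Y * (1 + a * outer(resp[[ch]], ww))
      if (is.finite(snr)) {
        amag <- max(abs(a), amp_gcamp, 1e-3)
        Y <- Y + matrix(rnorm(nt * nr * nc, sd = amag / snr * mean(bb)),
                        nt, nr * nc)
      }
      fr <- array(Y, c(nt, nr, nc))
      if (motion_amp > 0) {
        for (i in seq_len(nt)) {
          if (any(shifts[i, ] != 0)) {
            fr[i, , ] <- fourier_shift_2d(fr[i, , ], shifts[i, 1L], shifts[i, 2L])
          }
        }
      }
      stacks[[ch]] <- channel_stack(fr, channel = ch, frame_times = tt,
                                    pixel_size = pixel_size)
    }

    truth <- list(
      kind = kind, seed = seed,
      amp_gcamp_pct = 100 * amp_gcamp, amp_bold_pct = 100 * amp_bold,
      amp_cbv_pct = 100 * amp_cbv,
      barrel_center = barrel_center, vessel_mask = vessel_mask,
      tissue_fraction = 1 - sum(vessel_mask & brain) / sum(brain),
      shifts = shifts, drift = drift, snr = snr
    )
    list(stacks = stacks, paradigm = paradigm,
         brain = mask_image(brain, "brain_roi"),
         skull = mask_image(skull, "skull_control"),
         truth = truth)
  })
}

#' Interleave per-channel stacks into a raw LED-multiplexed sequence
#'
#' Inverse of [demux_channels()]: used to emulate the camera's raw output.
#'
#' @param stacks Named list of three `channel_stack`s.
#' @param layout LED cycle order.
#' @return Numeric array `time x row x col`.
#' @export
interleave_channels <- function(stacks, layout = CHANNELS) {
  nt <- min(vapply(stacks, function(s) dim(s$frames)[1L], integer(1)))
  d <- dim(stacks[[1L]]$frames)
  raw <- array(0, c(3L * nt, d[2L], d[3L]))
  for (p in 1:3) {
    raw[p + 3L * (seq_len(nt) - 1L), , ] <-
      stacks[[layout[p]]]$frames[seq_len(nt), , , drop = FALSE]
  }
  raw
}

render_vessel_frame <- function(nr, nc, centers_px, angles, widths_px,
                                profile = "gaussian", depth = 0.6, bg = 1000,
                                edge_px = 2) {
  img <- matrix(bg, nr, nc)
  ys <- matrix(rep(seq_len(nr) - 1, nc), nr, nc)
  xs <- matrix(rep(seq_len(nc) - 1, each = nr), nr, nc)
  att <- matrix(0, nr, nc)
  for (i in seq_along(widths_px)) {
    th <- angles[i]
    d <- -(ys - centers_px[i, 1L]) * sin(th) + (xs - centers_px[i, 2L]) * cos(th)
    a <- if (profile == "gaussian") {
      s <- widths_px[i] / (2 * sqrt(2 * log(2)))
      exp(-d^2 / (2 * s^2))
    } else {
      # top-hat with a linear edge ramp (PSF-blurred blood column); the half
      # level sits at the true radius irrespective of grid phase or angle
      pmin(pmax((widths_px[i] / 2 - abs(d)) / edge_px + 0.5, 0), 1)
    }
    att <- pmax(att, a)
  }
  img * (1 - depth * att)
}

#' Generate a synthetic vessel movie with known diameters and dilations
#'
#' Dark vessels on bright tissue; each vessel's diameter follows the CO2
#' epoch (smooth ramp to `+dilation_pct`% during the stimulus window and
#' recovery afterwards). Probes (centre, unit normal, half-length, type)
#' and full ground truth are returned. Diameters default to a lognormal
#' draw with median 54 um, matching the arterial diameter distribution of
#' the cohort.
#'
#' @param n_vessels Number of (parallel-placed, randomly oriented) vessels.
#' @param diameters_um Baseline diameters; default lognormal (median 54 um,
#'   sdlog 0.4), clipped to 10-150 um.
#' @param dilation_pct Peak dilation (%), recycled per vessel.
#' @param types Vessel types, recycled (default `"artery"`).
#' @param profile Cross-section shape: `"tophat"` (default; dark blood
#'   column with a 1-px anti-aliased edge, as surface vessels appear at
#'   570 nm) or `"gaussian"`.
#' @param pixel_size um/pixel; the default 2 um/px is a zoomed single-vessel
#'   field where profiles are well sampled.
#' @param frame_rate Frames per second, default 1 (diametry does not need
#'   the full 10 Hz).
#' @param paradigm A hypercapnia `stimulus_paradigm`; default 30 s baseline,
#'   90 s CO2, 60 s recovery, one repeat.
#' @param snr Vessel-contrast-to-noise ratio; `Inf` for noiseless.
#' @param seed RNG seed.
#' @return A list: `stack` (570 nm `channel_stack`), `probes`, `paradigm`,
#'   `truth` (per-vessel baseline diameters and dilations).
#' @export
gen_vessel_frame_series <- function(n_vessels = 6L, diameters_um = NULL,
                                    dilation_pct = 8, types = "artery",
                                    profile = c("tophat", "gaussian"),
                                    pixel_size = 2, frame_rate = 1,
                                    paradigm = NULL, snr = 20, seed = 1L) {
  profile <- match.arg(profile)
  withr::with_seed(seed, {
    if (is.null(diameters_um)) {
      diameters_um <- pmin(pmax(rlnorm(n_vessels, log(54), 0.4), 10), 150)
    }
    n_vessels <- length(diameters_um)
    if (any(diameters_um < 10 | diameters_um > 150)) {
      abort("diameters must lie within 10-150 um")
    }
    dilation_pct <- rep_len(dilation_pct, n_vessels)
    types <- rep_len(types, n_vessels)
    paradigm <- paradigm %||%
      stimulus_paradigm("hypercapnia", onsets = 30, stim_duration = 90,
                        baseline_duration = 30)
    total_t <- max(paradigm$onsets) + paradigm$stim_duration + 60
    nt <- floor(total_t * frame_rate)
    tt <- (seq_len(nt) - 1) / frame_rate

    # canvas: near-vertical vessels in separate column lanes (axis direction
    # (cos a, sin a), normal (-sin a, cos a)); lanes wide enough that every
    # probe segment stays inside the image
    half_len_um <- pmin(pmax(diameters_um * 2.2, 60), 200)
    lane_um <- 2 * max(half_len_um) + 60
    nc <- max(64L, ceiling(lane_um * n_vessels / pixel_size))
    nr <- max(64L, ceiling((1.4 * max(half_len_um) + 60) / pixel_size))
    angles <- runif(n_vessels, -pi / 6, pi / 6)
    centers <- cbind(rep(nr / 2, n_vessels),
                     (seq_len(n_vessels) - 0.5) * lane_um / pixel_size)

    course <- numeric(nt)
    for (on in paradigm$onsets) {
      rel <- tt - on
      ramp <- pmin(pmax(rel / 20, 0), 1) *
        exp(-pmax(rel - paradigm$stim_duration, 0) / 20)
      course <- pmax(course, ramp)
    }

    bg <- 1000
    depth <- 0.6
    frames <- array(0, c(nt, nr, nc))
    for (i in seq_len(nt)) {
      w <- diameters_um * (1 + dilation_pct / 100 * course[i]) / pixel_size
      frames[i, , ] <- render_vessel_frame(nr, nc, centers, angles, w,
                                           profile = profile, depth = depth,
                                           bg = bg)
    }
    if (is.finite(snr)) {
      frames <- frames + rnorm(length(frames), sd = depth * bg / snr)
      frames <- pmax(frames, 0)
    }
    probes <- vessel_probes(
      vessel_id = sprintf("v%02d", seq_len(n_vessels)),
      y = centers[, 1L], x = centers[, 2L],
      normal_dy = -sin(angles), normal_dx = cos(angles),
      half_length_um = half_len_um,
      type = types
    )
    truth <- list(seed = seed, diameters_um = diameters_um,
                  dilation_pct = dilation_pct, types = types,
                  course = course, profile = profile)
    list(stack = channel_stack(frames, "cbv570", frame_times = tt,
                               pixel_size = pixel_size),
         probes = probes, paradigm = paradigm, truth = truth)
  })
}

#' Generate a synthetic two-photon volume with known CAA and plaques
#'
#' SR101 channel holds tubular vessels (vertical strips through z); the
#' methoxy channel holds CAA bands covering a known fraction of each
#' vessel's MIP footprint plus spherical plaques of known voxel counts away
#' from the vessels. Exponential depth decay and white noise are applied;
#' plaque positions avoid vessel strips (retrying up to a limit).
#'
#' @param nz,ny,nx Volume size (default 16 x 96 x 96).
#' @param n_vessels Number of vessel strips.
#' @param caa_fraction Fraction of each vessel's footprint covered by CAA.
#' @param plaque_radii_vox Radii (voxels) of spherical plaques; can be
#'   empty.
#' @param depth_decay Per-slice multiplicative decay (e.g. 0.95).
#' @param snr CAA-contrast-to-noise ratio; `Inf` for noiseless.
#' @param voxel_size um per voxel (z, y, x).
#' @param seed RNG seed.
#' @return A list: `volume` (`two_photon_volume`), `outlines` (label
#'   matrix), `truth` (true coverage, per-plaque voxel counts, true volume).
#' @export
gen_twophoton_volume <- function(nz = 16L, ny = 96L, nx = 96L,
                                 n_vessels = 3L, caa_fraction = 0.25,
                                 plaque_radii_vox = c(4, 5),
                                 depth_decay = 0.97, snr = 15,
                                 voxel_size = c(3, 2.207, 2.207),
                                 seed = 1L) {
  withr::with_seed(seed, {
    tissue_mu <- 100
    band_mu <- 220                   # CAA band intensity (contrast 120)
    noise_sd <- if (is.finite(snr)) (band_mu - tissue_mu) / snr else 0

    methoxy <- array(tissue_mu, c(nz, ny, nx))
    sr101 <- array(50, c(nz, ny, nx))
    outlines <- matrix(0L, ny, nx)
    strip_w <- 6L
    gap <- floor(nx / (n_vessels + 1))
    caa_map <- matrix(FALSE, ny, nx)
    for (v in seq_len(n_vessels)) {
      x0 <- v * gap - strip_w %/% 2L
      xs <- x0:(x0 + strip_w - 1L)
      outlines[, xs] <- v
      for (z in seq_len(nz)) sr101[z, , xs] <- 800
      # CAA bands: contiguous runs of rows covering caa_fraction of the strip
      n_rows <- round(caa_fraction * ny)
      if (n_rows > 0) {
        start <- sample.int(ny - n_rows + 1L, 1L)
        rows <- start:(start + n_rows - 1L)
        for (z in seq_len(nz)) methoxy[z, rows, xs] <- band_mu
      }
    }
    # plaques: spheres away from strips
    plaque_counts <- integer(0)
    centers <- list()
    for (r in plaque_radii_vox) {
      placed <- FALSE
      for (try in 1:50) {
        cz <- runif(1, r + 1, nz - r - 1)
        cy <- runif(1, r + 1, ny - r - 1)
        cx <- runif(1, r + 1, nx - r - 1)
        xr <- max(1, floor(cx - r - 2)):min(nx, ceiling(cx + r + 2))
        if (any(outlines[, xr] > 0)) next
        zi <- seq_len(nz); yi <- seq_len(ny); xi <- seq_len(nx)
        dz2 <- (zi - cz)^2; dy2 <- (yi - cy)^2; dx2 <- (xi - cx)^2
        inside <- outer(outer(dz2, dy2, `+`), dx2, `+`) <= r^2
        if (!any(inside)) next
        methoxy[inside] <- band_mu * 2   # plaques well above 0.6 x max of the bands
        plaque_counts <- c(plaque_counts, sum(inside))
        centers[[length(centers) + 1L]] <- c(cz, cy, cx)
        placed <- TRUE
        break
      }
      if (!placed && length(plaque_radii_vox) > 0) {
        abort("could not place a plaque away from the CAA vessels")
      }
    }
    decay <- depth_decay^(seq_len(nz) - 1L)
    for (z in seq_len(nz)) {
      methoxy[z, , ] <- methoxy[z, , ] * decay[z]
      sr101[z, , ] <- sr101[z, , ] * decay[z]
    }
    if (noise_sd > 0) {
      methoxy <- pmax(methoxy + rnorm(length(methoxy), sd = noise_sd), 0)
    }
    vol <- two_photon_volume(methoxy, sr101, voxel_size)
    truth <- list(seed = seed, caa_fraction = caa_fraction,
                  plaque_voxels = plaque_counts,
                  plaque_volume_um3 = sum(plaque_counts[plaque_counts > 15]) *
                    prod(voxel_size),
                  n_plaques_detectable = sum(plaque_counts > 15),
                  centers = centers)
    list(volume = vol, outlines = outlines, truth = truth)
  })
}

#' Generate a longitudinal synthetic cohort with known fixed effects
#'
#' Emulates the study design: four groups (APP/PS1 and WT, each 8 M + 8 F),
#' longitudinal sessions from about 3 to 20 months with per-mouse visit
#' counts drawn around 5.4 +/- 3.1 and inter-visit intervals around
#' 1.52 +/- 0.5 months, outcomes from a linear mixed model with a mouse
#' random intercept. `level = "session"` yields one outcome row per session
#' (for reactivity-style outcomes); `level = "vessel"` yields vessel-level
#' dilation records with a lognormal baseline-diameter distribution (median
#' 54 um) and a dilation ~ diameter * age fixed-effect surface, optionally
#' calibrated so the true Johnson-Neyman boundary sits at
#' `jn_boundary_month`.
#'
#' @param n_per_group Mice per genotype x sex cell (default 8).
#' @param level `"session"` or `"vessel"`.
#' @param betas Named fixed effects. Session level uses any of `intercept`,
#'   `age`, `sexM`, `genotypeAD`, `age_genotypeAD`, `age_sexM`. Vessel level
#'   uses `intercept`, `diameter`, `age`, `diameter_age`.
#' @param sd_intercept Random-intercept SD (default 0.5).
#' @param sd_resid Residual SD (default 1).
#' @param n_vessels_per_session Vessels per session (vessel level).
#' @param jn_boundary_month If non-NULL (vessel level), overrides
#'   `betas["diameter"]` so that the conditional diameter slope loses
#'   significance (alpha 0.05) exactly at this age under the realized
#'   design.
#' @param outcome Name for the outcome column (default `"outcome"`).
#' @param seed RNG seed.
#' @return A list: `table` (long tibble), `truth` (betas actually used,
#'   variance components, seed).
#' @export
gen_cohort <- function(n_per_group = 8L, level = c("session", "vessel"),
                       betas = NULL, sd_intercept = 0.5, sd_resid = 1,
                       n_vessels_per_session = 10L,
                       jn_boundary_month = NULL, outcome = "outcome",
                       seed = 1L) {
  level <- match.arg(level)
  withr::with_seed(seed, {
    groups <- expand.grid(genotype = c("APP_PS1", "WT"), sex = c("M", "F"),
                          i = seq_len(n_per_group),
                          stringsAsFactors = FALSE)
    mice <- tibble::tibble(
      mouse_id = sprintf("m%02d", seq_len(nrow(groups))),
      genotype = groups$genotype, sex = groups$sex
    )
    sessions <- list()
    for (m in seq_len(nrow(mice))) {
      nv <- max(1L, min(12L, round(rnorm(1, 5.4, 3.1))))
      gaps <- pmax(rnorm(nv - 1, 1.52, 0.5), 0.5)
      ages <- pmin(3 + runif(1, 0, 1.5) + c(0, cumsum(gaps)), 20)
      sessions[[m]] <- tibble::tibble(
        mouse_id = mice$mouse_id[m], genotype = mice$genotype[m],
        sex = mice$sex[m], age = ages,
        session_index = seq_along(ages))
    }
    tab <- dplyr::bind_rows(sessions)
    tab$genotype <- factor(tab$genotype, levels = c("WT", "APP_PS1"))
    tab$sex <- factor(tab$sex, levels = c("F", "M"))
    u <- setNames(rnorm(nrow(mice), 0, sd_intercept), mice$mouse_id)

    if (level == "session") {
      b <- list(intercept = 2, age = 0, sexM = 0, genotypeAD = 0,
                age_genotypeAD = 0, age_sexM = 0)
      b[names(betas)] <- betas
      mu <- b$intercept + b$age * tab$age +
        b$sexM * (tab$sex == "M") +
        b$genotypeAD * (tab$genotype == "APP_PS1") +
        b$age_genotypeAD * tab$age * (tab$genotype == "APP_PS1") +
        b$age_sexM * tab$age * (tab$sex == "M")
      tab[[outcome]] <- mu + u[tab$mouse_id] + rnorm(nrow(tab), 0, sd_resid)
      truth <- list(betas = b, sd_intercept = sd_intercept,
                    sd_resid = sd_resid, seed = seed)
      return(list(table = tab, truth = truth))
    }

    # vessel level
    tab <- tab[rep(seq_len(nrow(tab)), each = n_vessels_per_session), ]
    tab$vessel_id <- sprintf("%s.s%d.v%02d", tab$mouse_id, tab$session_index,
                             seq_len(n_vessels_per_session))
    tab$vessel_type <- "artery"
    tab$baseline_diameter <- pmin(pmax(rlnorm(nrow(tab), log(54), 0.4), 10), 150)
    b <- list(intercept = 20, diameter = -0.15, age = -0.29,
              diameter_age = 0)
    b[names(betas)] <- betas
    if (!is.null(jn_boundary_month)) {
      # choose the diameter main effect so that, for the realized design,
      # the conditional slope theta(m) = b_d + b_da m satisfies
      # |theta(m*)| = t_crit * SE(theta(m*)) at m* = jn_boundary_month.
      X <- model.matrix(~ baseline_diameter * age, tab)
      XtXi <- solve(crossprod(X))
      Vd <- sd_resid^2 * XtXi
      m <- jn_boundary_month
      se_m <- sqrt(Vd["baseline_diameter", "baseline_diameter"] +
                     m^2 * Vd["baseline_diameter:age", "baseline_diameter:age"] +
                     2 * m * Vd["baseline_diameter", "baseline_diameter:age"])
      tc <- qt(0.975, nrow(tab) - ncol(X))
      # negative slope at young ages relaxing toward zero with age
      if (is.null(betas$diameter_age)) b$diameter_age <- abs(b$diameter) / 40
      b$diameter <- -(tc * se_m) - b$diameter_age * m
    }
    mu <- b$intercept + b$diameter * tab$baseline_diameter +
      b$age * tab$age + b$diameter_age * tab$baseline_diameter * tab$age
    tab$percent_change <- mu + u[tab$mouse_id] + rnorm(nrow(tab), 0, sd_resid)
    truth <- list(betas = b, sd_intercept = sd_intercept, sd_resid = sd_resid,
                  jn_boundary_month = jn_boundary_month, seed = seed)
    list(table = tibble::as_tibble(tab), truth = truth)
  })
}
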
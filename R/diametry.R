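# Single-vessel FWHM diametry and percent dilation across the CO2 paradigm.

#' Vessel probe set
#'
#' Probes are manual annotations: a centreline point, the unit normal to the
#' local vessel axis, the half-length of the sampling segment and the vessel
#' type. `y`/`x` are 0-based pixel-centre coordinates.
#'
#' @param vessel_id Identifiers.
#' @param y,x Centre coordinates (0-based pixels).
#' @param normal_dy,normal_dx Normal direction (normalised internally).
#' @param half_length_um Probe half-length in um.
#' @param type `"artery"` or `"vein"`.
#' @return A tibble of probes.
#' @export
vessel_probes <- function(vessel_id, y, x, normal_dy, normal_dx,
                          half_length_um, type) {
  nrm <- sqrt(normal_dy^2 + normal_dx^2)
  if (any(nrm == 0)) abort("zero-length normal vector")
  if (any(half_length_um <= 0)) abort("`half_length_um` must be positive")
  if (!all(type %in% c("artery", "vein"))) abort("type must be artery or vein")
  tibble::tibble(vessel_id = as.character(vessel_id), y = y, x = x,
                 normal_dy = normal_dy / nrm, normal_dx = normal_dx / nrm,
                 half_length_um = half_length_um, type = type)
}

#' Read probe annotations from CSV
#'
#' Columns: vessel_id, y, x, normal_dy, normal_dx, half_length_um, type.
#' @param path CSV path.
#' @return A probe tibble (normals normalised).
#' @export
read_probes <- function(path) {
  p <- readr::read_csv(path, show_col_types = FALSE)
  vessel_probes(p$vessel_id, p$y, p$x, p$normal_dy, p$normal_dx,
                p$half_length_um, p$type)
}

bilinear_sample <- function(img, ys, xs) {
  # ys, xs: 0-based pixel-centre coordinates
  nr <- nrow(img); nc <- ncol(img)
  y0 <- floor(ys); x0 <- floor(xs)
  fy <- ys - y0; fx <- xs - x0
  y0 <- pmin(pmax(y0, 0), nr - 1L); x0 <- pmin(pmax(x0, 0), nc - 1L)
  y1 <- pmin(y0 + 1, nr - 1L); x1 <- pmin(x0 + 1, nc - 1L)
  v00 <- img[cbind(y0 + 1L, x0 + 1L)]
  v01 <- img[cbind(y0 + 1L, x1 + 1L)]
  v10 <- img[cbind(y1 + 1L, x0 + 1L)]
  v11 <- img[cbind(y1 + 1L, x1 + 1L)]
  (1 - fy) * ((1 - fx) * v00 + fx * v01) + fy * ((1 - fx) * v10 + fx * v11)
}

#' Sample a vessel cross-sectional intensity profile
#'
#' Bilinear interpolation at uniform steps along the probe segment
#' (centre +/- half-length along the normal).
#'
#' @param frame 2-D image (matrix).
#' @param probe One probe row (see [vessel_probes()]).
#' @param pixel_size um/pixel of `frame`.
#' @param step_frac Sampling step as a fraction of the pixel size (default
#'   0.25).
#' @return A list: `intensity`, `s_um` (signed distance from the centre in
#'   um), `spacing_um`.
#' @export
extract_profile <- function(frame, probe, pixel_size, step_frac = 0.25) {
  stopifnot(is.matrix(frame))
  assert_scalar_pos(pixel_size, "pixel_size")
  step_um <- step_frac * pixel_size
  s <- seq(-probe$half_length_um, probe$half_length_um, by = step_um)
  ys <- probe$y + probe$normal_dy * s / pixel_size
  xs <- probe$x + probe$normal_dx * s / pixel_size
  if (min(ys) < 0 || max(ys) > nrow(frame) - 1 ||
      min(xs) < 0 || max(xs) > ncol(frame) - 1) {
    abort("probe segment exits the image")
  }
  list(intensity = bilinear_sample(frame, ys, xs), s_um = s, spacing_um = step_um)
}

#' Vessel diameter as FWHM of a cross-sectional profile
#'
#' The profile is lightly smoothed (moving average, width 3), the local
#' baseline is the median of the outer 20% of samples at each end (so
#' neighbouring vessels do not bias the half level), the half level is
#' baseline + 0.5 x (extremum - baseline), and the two crossings flanking
#' the extremum are located by linear interpolation. Fails (returns NA) when
#' the extremum sits at the profile edge, fewer than two crossings bracket
#' it, or the contrast is below the noise floor.
#'
#' @param profile Numeric intensity profile (or the list returned by
#'   [extract_profile()]).
#' @param spacing_um Sample spacing in um (taken from the list input if
#'   omitted).
#' @param polarity `"dark_vessel"` (absorption trough; the 570 nm default)
#'   or `"bright_vessel"`.
#' @param smooth Moving-average width (samples), default 3.
#' @param noise_k Contrast must exceed `noise_k` x SD of the outer samples.
#' @return Diameter in um, or `NA_real_` on measurement failure.
#' @export
fwhm_diameter <- function(profile, spacing_um = NULL,
                          polarity = c("dark_vessel", "bright_vessel"),
                          smooth = 3L, noise_k = 3) {
  polarity <- match.arg(polarity)
  if (is.list(profile)) {
    spacing_um <- spacing_um %||% profile$spacing_um
    profile <- profile$intensity
  }
  assert_scalar_pos(spacing_um, "spacing_um")
  n <- length(profile)
  if (n < 5L) return(NA_real_)
  y <- moving_average(profile, smooth)
  if (polarity == "dark_vessel") y <- -y
  m <- max(2L, ceiling(0.2 * n))
  outer_vals <- c(y[seq_len(m)], y[(n - m + 1L):n])
  baseline <- median(outer_vals)
  ipk <- which.max(y)
  # extremum level from a +/-2-sample window around the argmax: using the
  # raw maximum would take the largest noise excursion and bias the half
  # level (hence the width) low on noisy profiles
  pk <- mean(y[max(1L, ipk - 2L):min(n, ipk + 2L)])
  contrast <- pk - baseline
  noise <- sd(outer_vals)
  if (ipk <= 1L || ipk >= n) return(NA_real_)
  if (!is.finite(contrast) || contrast <= 0 || contrast <= noise_k * noise) {
    return(NA_real_)
  }
  half <- baseline + 0.5 * contrast
  # left crossing: last index < ipk with y < half
  left <- NA_real_
  for (i in (ipk - 1L):1L) {
    if (y[i] < half) {
      left <- i + (half - y[i]) / (y[i + 1L] - y[i])
      break
    }
  }
  right <- NA_real_
  for (i in (ipk + 1L):n) {
    if (y[i] < half) {
      right <- i - (half - y[i]) / (y[i - 1L] - y[i])
      break
    }
  }
  if (is.na(left) || is.na(right)) return(NA_real_)
  (right - left) * spacing_um
}

#' Per-frame vessel diameters across a stack
#'
#' Measures each probe's FWHM diameter on every frame of a (570 nm) stack.
#'
#' @param stack A `channel_stack`.
#' @param probes Probe tibble from [vessel_probes()].
#' @param polarity See [fwhm_diameter()].
#' @param step_frac See [extract_profile()].
#' @return A tibble: vessel_id, frame, time, diameter_um (NA where the
#'   measurement failed).
#' @export
measure_diameters <- function(stack, probes, polarity = "dark_vessel",
                              step_frac = 0.25) {
  stopifnot(inherits(stack, "channel_stack"))
  nt <- dim(stack$frames)[1L]
  res <- vector("list", nrow(probes))
  for (v in seq_len(nrow(probes))) {
    pr <- probes[v, ]
    dia <- numeric(nt)
    for (i in seq_len(nt)) {
      prof <- extract_profile(stack$frames[i, , ], pr, stack$pixel_size,
                              step_frac)
      dia[i] <- fwhm_diameter(prof, polarity = polarity)
    }
    res[[v]] <- tibble::tibble(vessel_id = pr$vessel_id, frame = seq_len(nt),
                               time = stack$frame_times, diameter_um = dia)
  }
  dplyr::bind_rows(res)
}

#' Percent dilation of a vessel across the CO2 paradigm
#'
#' Baseline diameter D0 is the mean over the baseline epoch preceding the
#' first onset; the dilation is 100 x max over the stimulus window of
#' |D(t) - D0| / D0, with the sign of the extremal deviation attached.
#' Diameters are lightly smoothed in time (moving average, width 3) before
#' peak detection so a single-frame noise excursion cannot set the peak.
#' Vessels with more than `max_missing` failed frames in either window are
#' excluded (NA).
#'
#' @param diameters Diameter series in um (NA = failed frame).
#' @param times Frame times (s), same length.
#' @param paradigm Hypercapnia `stimulus_paradigm`.
#' @param max_missing Maximum tolerated fraction of failed frames (0.2).
#' @param smooth Temporal moving-average width.
#' @return A list: `percent_change` (signed, %), `baseline_um`; both NA if
#'   excluded.
#' @export
percent_dilation <- function(diameters, times, paradigm, max_missing = 0.2,
                             smooth = 3L) {
  stopifnot(length(diameters) == length(times))
  excluded <- list(percent_change = NA_real_, baseline_um = NA_real_)
  epochs_pc <- numeric(0)
  base_all <- numeric(0)
  dsm <- moving_average(diameters, smooth)
  for (on in paradigm$onsets) {
    bsel <- times >= on - paradigm$baseline_duration & times < on
    ssel <- times >= on & times <= on + paradigm$stim_duration
    if (!any(bsel) || !any(ssel)) return(excluded)
    if (mean(is.na(diameters[bsel])) > max_missing ||
        mean(is.na(diameters[ssel])) > max_missing) {
      return(excluded)
    }
    d0 <- mean(dsm[bsel], na.rm = TRUE)
    dev <- (dsm[ssel] - d0) / d0
    ipk <- which.max(abs(dev))
    epochs_pc <- c(epochs_pc, 100 * dev[ipk])
    base_all <- c(base_all, d0)
  }
  list(percent_change = mean(epochs_pc), baseline_um = mean(base_all))
}

#' Vessel records for a session
#'
#' Combines per-frame diametry and percent dilation into per-vessel records.
#'
#' @param stack Preprocessed 570 nm `channel_stack`.
#' @param probes Probe tibble.
#' @param paradigm Hypercapnia `stimulus_paradigm`.
#' @param session Optional one-row tibble from [session_meta()], bound to
#'   every record.
#' @inheritParams percent_dilation
#' @return A tibble: vessel_id, vessel_type, baseline_diameter,
#'   percent_change (NA rows = excluded vessels), plus session columns.
#' @export
vessel_records <- function(stack, probes, paradigm, session = NULL,
                           max_missing = 0.2) {
  dia <- measure_diameters(stack, probes)
  out <- dplyr::group_modify(
    dplyr::group_by(dia, .data$vessel_id),
    function(df, key) {
      pd <- percent_dilation(df$diameter_um, df$time, paradigm, max_missing)
      tibble::tibble(baseline_diameter = pd$baseline_um,
                     percent_change = pd$percent_change)
    }
  )
  out <- dplyr::ungroup(out)
  out <- dplyr::left_join(out,
                          dplyr::select(probes, "vessel_id", vessel_type = "type"),
                          by = "vessel_id")
  out <- dplyr::relocate(out, "vessel_id", "vessel_type")
  if (!is.null(session)) out <- dplyr::bind_cols(out, session[rep(1L, nrow(out)), ])
  out
}

#' Median split of arterial baseline diameters
#'
#' The cohort median of arterial baseline diameters classifies vessels as
#' small (`< median`) or large (`>= median`); the median itself is an output
#' of the cohort, never an input. Ties at the median go to `large`; if all
#' diameters are equal a warning is raised (everything is `large`).
#'
#' @param records Vessel-record tibble with `vessel_type` and
#'   `baseline_diameter`.
#' @param scope Vessel type defining the split population (default
#'   `"artery"`).
#' @return The records with a `size_class` column added for in-scope rows
#'   (NA elsewhere); the split value is attached as attribute
#'   `median_diameter`.
#' @export
median_split <- function(records, scope = "artery") {
  sel <- records$vessel_type == scope & !is.na(records$baseline_diameter)
  if (sum(sel) < 2L) abort("need at least two in-scope records for a median split")
  med <- median(records$baseline_diameter[sel])
  if (all(records$baseline_diameter[sel] == med)) {
    warn("all in-scope diameters equal: every vessel classified 'large'")
  }
  records$size_class <- NA_character_
  records$size_class[sel] <-
    ifelse(records$baseline_diameter[sel] < med, "small", "large")
  attr(records, "median_diameter") <- med
  records
}
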
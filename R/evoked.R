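# Whisker-evoked neurovascular coupling: trial-averaged fractional-change
# movies, greedy top-k barrel ROI, peak responses, BOLD:GCaMP ratio.

#' Trial-averaged fractional-change movie
#'
#' For each stimulus onset, F0 is the per-pixel mean over the
#' `baseline_window` seconds preceding the onset and the trial epoch runs
#' from onset to onset + stimulus duration + `response_window`. Per-trial
#' (F - F0)/F0 movies are averaged across trials. Pixels with F0 <= 0 in any
#' trial are flagged invalid (NA in the average) and excluded from later ROI
#' search. Frames listed in `bad_frames` (e.g. registration shift > 5 px)
#' are dropped from both baselines and epoch averages.
#'
#' @param stack A `channel_stack`.
#' @param paradigm A `stimulus_paradigm`.
#' @param baseline_window Baseline length in seconds (default 2 s).
#' @param response_window Post-offset window (s) kept in the epoch, default
#'   8 s, long enough for the slower hemodynamic peak within the shortest ISI.
#' @param bad_frames Integer indices of frames to exclude.
#' @return A list of class `dff_movie`: `dff` (epoch_time x row x col trial
#'   average), `times` (s relative to onset), `n_trials`, `valid` (logical
#'   matrix of usable pixels).
#' @export
trial_fractional_change <- function(stack, paradigm, baseline_window = 2,
                                    response_window = 8, bad_frames = NULL) {
  stopifnot(inherits(stack, "channel_stack"),
            inherits(paradigm, "stimulus_paradigm"))
  tt <- stack$frame_times
  d <- dim(stack$frames)
  epoch_len <- paradigm$stim_duration + response_window
  use <- rep(TRUE, d[1L])
  if (!is.null(bad_frames)) use[bad_frames] <- FALSE

  # common relative-index grid: offsets from the first frame at/after onset
  first_idx <- vapply(paradigm$onsets, function(on) {
    i <- which(tt >= on)[1L]
    if (is.na(i)) abort("onset beyond end of recording") else i
  }, integer(1))
  n_ep <- vapply(seq_along(first_idx), function(k) {
    sum(tt >= paradigm$onsets[k] & tt <= paradigm$onsets[k] + epoch_len)
  }, integer(1))
  L <- min(n_ep)
  if (L < 1L) abort("epoch window contains no frames")

  npx <- d[2L] * d[3L]
  acc <- matrix(0, L, npx)
  cnt <- matrix(0, L, npx)
  valid <- rep(TRUE, npx)
  Y <- matrix(stack$frames, nrow = d[1L])
  for (k in seq_along(paradigm$onsets)) {
    on <- paradigm$onsets[k]
    bidx <- which(tt >= on - baseline_window & tt < on & use)
    if (length(bidx) < 1L) abort("onset lacks a full baseline window")
    f0 <- colMeans(Y[bidx, , drop = FALSE])
    valid <- valid & (f0 > 0)
    eidx <- first_idx[k] + seq_len(L) - 1L
    keep <- use[eidx]
    dff <- sweep(Y[eidx, , drop = FALSE], 2L, f0, `/`) - 1
    acc[keep, ] <- acc[keep, ] + dff[keep, , drop = FALSE]
    cnt[keep, ] <- cnt[keep, ] + 1
  }
  avg <- acc / cnt
  avg[, !valid] <- NA_real_
  structure(
    list(dff = array(avg, c(L, d[2L], d[3L])),
         times = tt[first_idx[1L] + seq_len(L) - 1L] - paradigm$onsets[1L],
         n_trials = length(paradigm$onsets),
         valid = matrix(valid, d[2L], d[3L]),
         stim_duration = paradigm$stim_duration),
    class = "dff_movie"
  )
}

#' Per-pixel activation map from a trial-averaged movie
#'
#' @param movie A `dff_movie` from [trial_fractional_change()].
#' @param reduction `"peak_over_stim"` (per-pixel maximum over the stimulus
#'   epoch; default, used for ROI selection) or `"mean_over_stim"`.
#' @return A matrix of fractional change with attribute `reduction`; invalid
#'   pixels are NA.
#' @export
activation_map <- function(movie, reduction = c("peak_over_stim", "mean_over_stim")) {
  reduction <- match.arg(reduction)
  stopifnot(inherits(movie, "dff_movie"))
  idx <- which(movie$times >= 0 & movie$times <= movie$stim_duration)
  if (length(idx) == 0L) idx <- seq_along(movie$times)
  sub <- movie$dff[idx, , , drop = FALSE]
  f <- if (reduction == "peak_over_stim") {
    function(v) if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE)
  } else {
    function(v) mean(v)
  }
  out <- apply(sub, c(2L, 3L), f)
  attr(out, "reduction") <- reduction
  out
}

neighbours_8 <- function(i, j, nr, nc) {
  dr <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
  dc <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  r <- i + dr; c <- j + dc
  ok <- r >= 1L & r <= nr & c >= 1L & c <= nc
  cbind(r[ok], c[ok])
}

neighbours_4 <- function(i, j, nr, nc) {
  dr <- c(-1L, 0L, 0L, 1L)
  dc <- c(0L, -1L, 1L, 0L)
  r <- i + dr; c <- j + dc
  ok <- r >= 1L & r <= nr & c >= 1L & c <= nc
  cbind(r[ok], c[ok])
}

#' Extract the barrel ROI as the top-k connected activated pixels
#'
#' Greedy connected region growth: seed at the global-maximum pixel of the
#' activation map, then repeatedly add the highest-valued pixel 8-connected
#' to the current region until the region holds `k` pixels (the "top 100
#' connected pixels with the highest activation"). An alternative
#' construction (threshold at the k-th highest value, keep the component
#' containing the maximum) is available for sensitivity checks.
#'
#' @param map Activation matrix (NA = invalid pixel).
#' @param k Region size in pixels (default 100; capped at the number of
#'   valid pixels).
#' @param connectivity 8 (default) or 4.
#' @param method `"greedy"` (default) or `"threshold"`.
#' @return A `mask_image` with label `barrel_roi`.
#' @export
extract_barrel_roi <- function(map, k = 100L, connectivity = 8L,
                               method = c("greedy", "threshold")) {
  method <- match.arg(method)
  stopifnot(is.matrix(map))
  nr <- nrow(map); nc <- ncol(map)
  nvalid <- sum(!is.na(map))
  if (nvalid == 0L) abort("no valid pixels: no activation to segment")
  k <- min(as.integer(k), nvalid)
  nb <- if (connectivity == 8L) neighbours_8 else neighbours_4
  seed <- arrayInd(which.max(map), dim(map))
  roi <- matrix(FALSE, nr, nc)
  if (method == "greedy") {
    roi[seed] <- TRUE
    frontier <- rep(NA_real_, nr * nc)   # candidate values indexed linearly
    add_neighbours <- function(i, j) {
      for (q in seq_len(nrow(nbs <- nb(i, j, nr, nc)))) {
        r <- nbs[q, 1L]; c <- nbs[q, 2L]
        if (!roi[r, c] && !is.na(map[r, c])) frontier[(c - 1L) * nr + r] <<- map[r, c]
      }
    }
    add_neighbours(seed[1L], seed[2L])
    while (sum(roi) < k) {
      if (all(is.na(frontier))) break      # region exhausted its component
      best <- which.max(frontier)
      frontier[best] <- NA_real_
      i <- (best - 1L) %% nr + 1L
      j <- (best - 1L) %/% nr + 1L
      roi[i, j] <- TRUE
      add_neighbours(i, j)
    }
  } else {
    thr <- sort(map[!is.na(map)], decreasing = TRUE)[k]
    cand <- !is.na(map) & map >= thr
    # component containing the global maximum
    queue <- list(seed)
    roi[seed] <- TRUE
    while (length(queue) > 0L) {
      p <- queue[[length(queue)]]
      queue[[length(queue)]] <- NULL
      nbs <- nb(p[1L], p[2L], nr, nc)
      for (q in seq_len(nrow(nbs))) {
        r <- nbs[q, 1L]; c <- nbs[q, 2L]
        if (cand[r, c] && !roi[r, c]) {
          roi[r, c] <- TRUE
          queue[[length(queue) + 1L]] <- c(r, c)
        }
      }
    }
  }
  mask_image(roi, label = "barrel_roi")
}

#' Peak evoked response within an ROI
#'
#' ROI-mean trace of the trial-averaged fractional-change movie; the peak is
#' the signed extremum of largest magnitude between onset and
#' onset + stimulus + response window, reported in per cent. The 620 nm dR/R0
#' is reported as-is (reflectance rise = BOLD-like positive).
#'
#' @param movie A `dff_movie`.
#' @param roi A `mask_image` (any label) within the frame grid.
#' @return A list: `peak` (%), `time_to_peak` (s), `trace` (tibble).
#' @export
peak_response <- function(movie, roi) {
  stopifnot(inherits(movie, "dff_movie"), inherits(roi, "mask_image"))
  sel <- as.vector(roi$grid)
  if (!any(sel)) abort("empty ROI")
  Y <- matrix(movie$dff, nrow = dim(movie$dff)[1L])
  trace <- rowMeans(Y[, sel, drop = FALSE], na.rm = TRUE)
  ipk <- which.max(abs(trace))
  list(peak = 100 * trace[ipk],
       time_to_peak = movie$times[ipk],
       trace = tibble::tibble(time = movie$times, dff = trace))
}

#' OIS-BOLD to GCaMP peak ratio
#'
#' @param peak_bold Peak OIS-BOLD dR/R0 (%).
#' @param peak_gcamp Peak GCaMP dF/F0 (%), non-zero.
#' @return `peak_bold / peak_gcamp` (dimensionless).
#' @export
bold_gcamp_ratio <- function(peak_bold, peak_gcamp) {
  if (any(peak_gcamp == 0)) abort("undefined ratio: peak_gcamp is zero")
  peak_bold / peak_gcamp
}

#' Whisker-session neurovascular coupling summary
#'
#' Runs the evoked chain on already-preprocessed GCaMP and OIS-BOLD stacks:
#' trial averaging, activation map on GCaMP, greedy top-k barrel ROI, peak
#' responses in both channels and their ratio.
#'
#' @param gcamp,bold Preprocessed `channel_stack`s (470 and 620 nm).
#' @param paradigm Whisker `stimulus_paradigm`.
#' @param k ROI size in pixels.
#' @param baseline_window,response_window Seconds, see
#'   [trial_fractional_change()].
#' @param bad_frames Frames to exclude (per channel list or shared vector).
#' @return A one-row tibble: `peak_gcamp`, `peak_bold`, `bold_gcamp_ratio`,
#'   `roi_size`, plus the ROI mask as an attribute `roi`.
#' @export
evoked_analysis <- function(gcamp, bold, paradigm, k = 100L,
                            baseline_window = 2, response_window = 8,
                            bad_frames = NULL) {
  mg <- trial_fractional_change(gcamp, paradigm, baseline_window,
                                response_window, bad_frames)
  mb <- trial_fractional_change(bold, paradigm, baseline_window,
                                response_window, bad_frames)
  amap <- activation_map(mg)
  roi <- extract_barrel_roi(amap, k = k)
  pg <- peak_response(mg, roi)
  pb <- peak_response(mb, roi)
  out <- tibble::tibble(
    peak_gcamp = pg$peak, peak_bold = pb$peak,
    bold_gcamp_ratio = bold_gcamp_ratio(pb$peak, pg$peak),
    roi_size = sum(roi$grid)
  )
  attr(out, "roi") <- roi
  out
}
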
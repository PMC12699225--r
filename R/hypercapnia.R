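# Global CO2 reactivity: K-means large-vessel removal, tissue dR/R0 time
# series, peak reactivity over the CO2 epoch.

# Exact 1-D two-class k-means: every optimal 2-partition of 1-D data is a
# threshold partition, so scan all n-1 split points of the sorted values.
kmeans_1d_2 <- function(x) {
  xs <- sort(x)
  n <- length(xs)
  cs <- cumsum(xs); css <- cumsum(xs^2)
  i <- seq_len(n - 1L)
  ss_lo <- css[i] - cs[i]^2 / i
  ss_hi <- (css[n] - css[i]) - (cs[n] - cs[i])^2 / (n - i)
  best <- which.min(ss_lo + ss_hi)
  thr <- (xs[best] + xs[best + 1L]) / 2
  list(threshold = thr,
       centers = c(mean(xs[1:best]), mean(xs[(best + 1L):n])))
}

#' Remove large vessels from the brain ROI by K-means segmentation
#'
#' The mean 570 nm image within the brain ROI is divided by a heavy Gaussian
#' blur of itself (flattening low-frequency illumination inhomogeneity), then
#' two-class K-means on the flattened pixel intensity separates
#' haemoglobin-dark vessel pixels from tissue; the lower-reflectance cluster
#' is removed. If the two clusters are not meaningfully separated
#' (simplified silhouette below `min_silhouette`) a warning is raised and no
#' pixels are removed.
#'
#' @param mean_frame Mean 570 nm image (matrix).
#' @param brain A `mask_image` with label `brain_roi`.
#' @param sigma Flattening blur SD in (binned) pixels, default 20.
#' @param min_silhouette Minimum mean simplified silhouette to accept the
#'   vessel/tissue split, default 0.1.
#' @param min_contrast Minimum relative separation of the cluster centres
#'   (on the flattened-intensity scale) to accept the split, default 0.05:
#'   vessels at 570 nm are tens of per cent darker than tissue, whereas a
#'   single-mode histogram splits its own noise with centres only a few
#'   noise SDs apart.
#' @return A list: `tissue` (`mask_image`), `tissue_fraction`, `threshold`
#'   (on flattened intensity), `silhouette`.
#' @export
remove_large_vessels <- function(mean_frame, brain, sigma = 20,
                                 min_silhouette = 0.1, min_contrast = 0.05) {
  stopifnot(is.matrix(mean_frame), inherits(brain, "mask_image"))
  if (!any(brain$grid)) abort("empty brain ROI")
  flatfield <- gaussian_blur(mean_frame, sigma)
  flat <- mean_frame / pmax(flatfield, .Machine$double.eps)
  v <- flat[brain$grid]
  km <- kmeans_1d_2(v)
  lab <- as.integer(v > km$threshold) + 1L       # 1 = dark (vessel) cluster
  a <- abs(v - km$centers[lab])
  b <- abs(v - km$centers[3L - lab])
  sil <- mean((b - a) / pmax(a, b))
  grid <- brain$grid
  rel_sep <- (km$centers[2L] - km$centers[1L]) / km$centers[2L]
  if (!is.finite(sil) || sil < min_silhouette || rel_sep < min_contrast ||
      length(unique(lab)) < 2L) {
    warn("vessel/tissue clusters not separated: no pixels removed")
    tissue <- grid
  } else {
    tissue <- grid
    tissue[grid][lab == 1L] <- FALSE
  }
  list(tissue = mask_image(tissue, label = "brain_roi"),
       tissue_fraction = sum(tissue) / sum(grid),
       threshold = km$threshold, silhouette = sil)
}

#' Tissue fractional-change time series
#'
#' Per-frame mean over tissue pixels, expressed as fractional change
#' relative to the mean over the baseline epoch preceding the first CO2
#' onset.
#'
#' @param stack A preprocessed `channel_stack`.
#' @param tissue A non-empty `mask_image`.
#' @param paradigm Hypercapnia `stimulus_paradigm`.
#' @return A tibble with `time` (s) and `frac` (dR/R0, dimensionless);
#'   attribute `raw` holds the uncorrected mean trace.
#' @export
tissue_timeseries <- function(stack, tissue, paradigm) {
  stopifnot(inherits(stack, "channel_stack"), inherits(tissue, "mask_image"))
  sel <- as.vector(tissue$grid)
  if (!any(sel)) abort("empty tissue mask")
  Y <- matrix(stack$frames, nrow = dim(stack$frames)[1L])
  raw <- rowMeans(Y[, sel, drop = FALSE])
  on <- paradigm$onsets[1L]
  bidx <- stack$frame_times >= on - paradigm$baseline_duration &
    stack$frame_times < on
  if (!any(bidx)) abort("baseline epoch missing from recording")
  b0 <- mean(raw[bidx])
  out <- tibble::tibble(time = stack$frame_times, frac = raw / b0 - 1)
  attr(out, "raw") <- raw
  out
}

#' Peak CO2 reactivity from a tissue trace
#'
#' Each repeat's epoch is re-baselined to the mean over the
#' `baseline_duration` seconds preceding its own onset, epochs are averaged
#' at the epoch level (the paradigm is repeated twice per session), and the
#' peak is the signed extremum of largest magnitude within the stimulus
#' window, in per cent. For the 570 nm channel set `negate = TRUE` so that a
#' CBV (absorption) rise is reported positive.
#'
#' @param trace Tibble with `time` and `frac` (or attribute `raw`), as
#'   returned by [tissue_timeseries()].
#' @param paradigm Hypercapnia `stimulus_paradigm`.
#' @param negate Negate the sign before reporting (570 nm convention).
#' @return A list: `peak` (%), `time_to_peak` (s into the epoch), `epoch`
#'   (tibble of the repeat-averaged trace).
#' @export
peak_reactivity <- function(trace, paradigm, negate = FALSE) {
  stopifnot(is.data.frame(trace), inherits(paradigm, "stimulus_paradigm"))
  raw <- attr(trace, "raw") %||% (trace$frac + 1)
  tt <- trace$time
  first_idx <- vapply(paradigm$onsets, function(on) {
    i <- which(tt >= on)[1L]
    if (is.na(i)) abort("onset beyond end of recording") else i
  }, integer(1))
  n_ep <- vapply(seq_along(first_idx), function(k) {
    sum(tt >= paradigm$onsets[k] & tt <= paradigm$onsets[k] + paradigm$stim_duration)
  }, integer(1))
  L <- min(n_ep)
  if (L < 1L) abort("stimulus epoch contains no frames")
  acc <- numeric(L)
  for (k in seq_along(paradigm$onsets)) {
    on <- paradigm$onsets[k]
    bidx <- tt >= on - paradigm$baseline_duration & tt < on
    if (!any(bidx)) abort("repeat lacks a full baseline epoch")
    b0 <- mean(raw[bidx])
    eidx <- first_idx[k] + seq_len(L) - 1L
    acc <- acc + (raw[eidx] / b0 - 1)
  }
  avg <- acc / length(paradigm$onsets)
  if (negate) avg <- -avg
  ipk <- which.max(abs(avg))
  etime <- tt[first_idx[1L] + seq_len(L) - 1L] - paradigm$onsets[1L]
  list(peak = 100 * avg[ipk], time_to_peak = etime[ipk],
       epoch = tibble::tibble(time = etime, frac = avg))
}

#' Hypercapnia-session reactivity summary
#'
#' Full CO2-reactivity chain on preprocessed 620 nm (OIS-BOLD) and 570 nm
#' (OIS-CBV) stacks: large-vessel removal on the mean 570 nm image, tissue
#' time series per channel, repeat-averaged peak dR/R0. The 570 nm peak is
#' negated so a CBV increase is positive.
#'
#' @param bold,cbv Preprocessed `channel_stack`s (620 and 570 nm).
#' @param brain A `mask_image` with label `brain_roi`.
#' @param paradigm Hypercapnia `stimulus_paradigm`.
#' @param sigma Flattening blur SD, see [remove_large_vessels()].
#' @return A one-row tibble: `peak_bold`, `peak_cbv` (%), `tissue_fraction`;
#'   attribute `tissue` holds the tissue mask.
#' @export
hypercapnia_analysis <- function(bold, cbv, brain, paradigm, sigma = 20) {
  mean570 <- apply(cbv$frames, c(2L, 3L), mean)
  seg <- remove_large_vessels(mean570, brain, sigma = sigma)
  tb <- tissue_timeseries(bold, seg$tissue, paradigm)
  tc <- tissue_timeseries(cbv, seg$tissue, paradigm)
  pb <- peak_reactivity(tb, paradigm, negate = FALSE)
  pc <- peak_reactivity(tc, paradigm, negate = TRUE)
  out <- tibble::tibble(peak_bold = pb$peak, peak_cbv = pc$peak,
                        tissue_fraction = seg$tissue_fraction)
  attr(out, "tissue") <- seg$tissue
  out
}
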
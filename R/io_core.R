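# Stacks, paradigms, masks: constructors and file round-trips.

CHANNELS <- c("gcamp470", "cbv570", "bold620")

#' Construct a single-channel imaging stack
#'
#' A `channel_stack` holds one wavelength channel of a widefield movie as a
#' `time x row x col` array together with per-frame acquisition times (s) and
#' the in-plane pixel size (um/pixel, isotropic).
#'
#' @param frames Numeric array, `time x row x col`; all values finite.
#' @param channel One of `"gcamp470"` (GCaMP fluorescence), `"cbv570"`
#'   (total-haemoglobin OIS at the isosbestic point) or `"bold620"`
#'   (deoxyhaemoglobin-weighted OIS).
#' @param frame_times Strictly increasing acquisition times in seconds, one
#'   per frame.
#' @param pixel_size In-plane pixel size in um/pixel.
#' @return An object of class `channel_stack`.
#' @export
channel_stack <- function(frames, channel = CHANNELS, frame_times = NULL,
                          pixel_size = 16.9) {
  channel <- match.arg(channel)
  if (!is.array(frames) || length(dim(frames)) != 3L) {
    abort("`frames` must be a 3-D array (time x row x col)")
  }
  nt <- dim(frames)[1L]
  if (nt < 1L) abort("`frames` must contain at least one time point")
  if (!all(is.finite(frames))) abort("`frames` must be finite")
  if (is.null(frame_times)) frame_times <- (seq_len(nt) - 1) / 10
  if (length(frame_times) != nt) {
    abort("`frame_times` length must equal the number of frames")
  }
  if (nt > 1L && any(diff(frame_times) <= 0)) {
    abort("`frame_times` must be strictly increasing")
  }
  assert_scalar_pos(pixel_size, "pixel_size")
  structure(
    list(frames = frames, channel = channel,
         frame_times = as.numeric(frame_times), pixel_size = pixel_size),
    class = "channel_stack"
  )
}

#' @export
print.channel_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<channel_stack %s: %d frames of %d x %d px, %.3g um/px, %.3g-%.3g s>\n",
              x$channel, d[1], d[2], d[3], x$pixel_size,
              min(x$frame_times), max(x$frame_times)))
  invisible(x)
}

#' @export
dim.channel_stack <- function(x) dim(x$frames)

#' Stimulus paradigm descriptor
#'
#' Onsets and window durations for the whisker-puff and hypercapnia
#' paradigms. The defaults mirror the acquisition protocols: 2-s whisker
#' stimulation trains, and a hypercapnia block of 30 s baseline, 90 s CO2 and
#' 270 s recovery repeated twice.
#'
#' @param kind `"whisker"` or `"hypercapnia"`.
#' @param onsets Stimulus onset times (s), strictly increasing.
#' @param stim_duration Stimulus duration (s).
#' @param baseline_duration Pre-onset baseline window (s): 2 s for whisker,
#'   30 s for hypercapnia.
#' @return A `stimulus_paradigm` object.
#' @export
stimulus_paradigm <- function(kind = c("whisker", "hypercapnia"), onsets,
                              stim_duration = NULL, baseline_duration = NULL) {
  kind <- match.arg(kind)
  stim_duration <- stim_duration %||% switch(kind, whisker = 2, hypercapnia = 90)
  baseline_duration <- baseline_duration %||% switch(kind, whisker = 2, hypercapnia = 30)
  if (length(onsets) < 1L || (length(onsets) > 1L && any(diff(onsets) <= 0))) {
    abort("`onsets` must be non-empty and strictly increasing")
  }
  assert_scalar_pos(stim_duration, "stim_duration")
  assert_scalar_pos(baseline_duration, "baseline_duration")
  if (length(onsets) > 1L && any(diff(onsets) < stim_duration)) {
    abort("inter-onset gaps must be at least `stim_duration`")
  }
  structure(
    list(kind = kind, onsets = as.numeric(onsets),
         stim_duration = stim_duration, baseline_duration = baseline_duration,
         n_repeats = length(onsets)),
    class = "stimulus_paradigm"
  )
}

#' Binary mask aligned to a stack's spatial grid
#'
#' @param grid Logical matrix (row x col).
#' @param label Semantic label: brain ROI, skull/head-bar control region,
#'   large-vessel mask, barrel ROI or two-photon vessel outline.
#' @return A `mask_image` object.
#' @export
mask_image <- function(grid, label = c("brain_roi", "skull_control",
                                       "vessel_large", "barrel_roi",
                                       "vessel_outline")) {
  label <- match.arg(label)
  if (!is.matrix(grid)) abort("`grid` must be a matrix")
  grid <- grid > 0
  if (label %in% c("skull_control", "brain_roi") && !any(grid)) {
    abort(sprintf("'%s' mask must contain at least one pixel", label))
  }
  structure(list(grid = grid, label = label), class = "mask_image")
}

#' Session metadata record
#'
#' @param mouse_id Non-empty identifier.
#' @param genotype `"APP_PS1"` or `"WT"`.
#' @param sex `"M"` or `"F"`.
#' @param age Age in months, positive.
#' @param session_index Session counter within mouse.
#' @return A one-row tibble.
#' @export
session_meta <- function(mouse_id, genotype = c("APP_PS1", "WT"),
                         sex = c("M", "F"), age, session_index = 1L) {
  genotype <- match.arg(genotype)
  sex <- match.arg(sex)
  if (!nzchar(mouse_id)) abort("`mouse_id` must be non-empty")
  assert_scalar_pos(age, "age")
  tibble::tibble(mouse_id = as.character(mouse_id), genotype = genotype,
                 sex = sex, age = as.numeric(age),
                 session_index = as.integer(session_index))
}

#' Read a multi-page TIFF stack
#'
#' Reads all pages of a multi-page TIFF in acquisition order. Integer TIFFs
#' are returned at their native integer scale (`as.is`), so a write/read
#' round-trip of integer pixel data is bit-identical.
#'
#' @param path Path to a readable multi-page TIFF.
#' @return Numeric array `time x row x col` with attribute `n_pages`.
#' @export
read_stack <- function(path) {
  if (!file.exists(path)) abort(sprintf("cannot read '%s': no such file", path))
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                    error = function(e) abort(sprintf("failed to read '%s': %s",
                                                      path, conditionMessage(e))))
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) == 0L) abort(sprintf("'%s' contains zero pages", path))
  d <- dim(pages[[1L]])
  raw <- array(0, c(length(pages), d[1L], d[2L]))
  for (i in seq_along(pages)) raw[i, , ] <- pages[[i]]
  attr(raw, "n_pages") <- length(pages)
  raw
}

#' Write a frame sequence as a multi-page TIFF
#'
#' @param raw Numeric array `time x row x col` of nonnegative integers (or a
#'   `channel_stack`, whose frames are used).
#' @param path Output path.
#' @param bits Bits per sample (8 or 16).
#' @return `path`, invisibly.
#' @export
write_stack <- function(raw, path, bits = 16L) {
  if (inherits(raw, "channel_stack")) raw <- raw$frames
  stopifnot(is.array(raw), length(dim(raw)) == 3L)
  if (!bits %in% c(8L, 16L)) abort("`bits` must be 8 or 16")
  top <- 2^bits - 1
  if (min(raw) < 0 || max(raw) > top) {
    abort(sprintf("pixel values must lie in [0, %d] for %d-bit output", top, bits))
  }
  pages <- lapply(seq_len(dim(raw)[1L]), function(i) round(raw[i, , ]) / top)
  ok <- tryCatch(tiff::writeTIFF(pages, path, bits.per.sample = bits),
                 error = function(e) abort(sprintf("failed to write '%s': %s",
                                                   path, conditionMessage(e))))
  invisible(path)
}

#' Demultiplex interleaved LED frames into per-channel stacks
#'
#' The widefield camera acquires the three LED channels sequentially
#' interleaved at 30 Hz (10 Hz per LED). This splits a raw frame sequence by
#' cycle position; a trailing partial cycle is dropped (acquisition routinely
#' ends mid-cycle) and a message reports the count. Per-channel frame times
#' are the acquisition times of that channel's own frames.
#'
#' @param raw Numeric array `time x row x col` of interleaved frames.
#' @param layout Character vector naming the LED cycle order, a permutation
#'   of `c("gcamp470", "cbv570", "bold620")`.
#' @param acquisition_rate Camera frame rate in Hz (total across LEDs).
#' @param pixel_size um/pixel of the raw frames.
#' @return Named list of three `channel_stack` objects.
#' @export
demux_channels <- function(raw, layout = CHANNELS, acquisition_rate = 30,
                           pixel_size = 16.9) {
  stopifnot(is.array(raw), length(dim(raw)) == 3L)
  if (!setequal(layout, CHANNELS) || length(layout) != 3L) {
    abort("`layout` must be a permutation of gcamp470, cbv570, bold620")
  }
  nt <- dim(raw)[1L]
  ncyc <- nt %/% 3L
  if (ncyc < 1L) abort("fewer frames than one full LED cycle")
  dropped <- nt - 3L * ncyc
  if (dropped > 0L) {
    message(sprintf("dropping %d trailing frame(s) not completing an LED cycle", dropped))
  }
  all_times <- (seq_len(nt) - 1) / acquisition_rate
  out <- list()
  for (p in 1:3) {
    idx <- p + 3L * (seq_len(ncyc) - 1L)
    out[[layout[p]]] <- channel_stack(raw[idx, , , drop = FALSE],
                                      channel = layout[p],
                                      frame_times = all_times[idx],
                                      pixel_size = pixel_size)
  }
  out[CHANNELS]
}

#' Write a session-metrics table to CSV
#'
#' Non-finite metric values are written as empty cells; a warning reports how
#' many were blanked.
#'
#' @param records Non-empty data frame of session metrics.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_results <- function(records, path) {
  if (!is.data.frame(records) || nrow(records) == 0L) {
    abort("`records` must be a non-empty data frame")
  }
  records <- tibble::as_tibble(records)
  n_bad <- 0L
  for (col in names(records)) {
    if (is.numeric(records[[col]])) {
      bad <- is.nan(records[[col]]) | is.infinite(records[[col]])
      n_bad <- n_bad + sum(bad)
      records[[col]][bad] <- NA
    }
  }
  if (n_bad > 0L) warn(sprintf("%d non-finite value(s) written as empty cells", n_bad))
  readr::write_csv(records, path, na = "")
  invisible(path)
}

#' Read a session-metrics table written by [write_results()]
#'
#' @param path CSV path.
#' @return A tibble.
#' @export
read_results <- function(path) {
  if (!file.exists(path)) abort(sprintf("cannot read '%s': no such file", path))
  readr::read_csv(path, show_col_types = FALSE, na = c("", "NA"))
}

#' Read / write a binary mask as PNG
#'
#' @param path PNG path.
#' @param label Mask label, see [mask_image()].
#' @return For `read_mask`, a `mask_image`; for `write_mask`, `path`.
#' @export
read_mask <- function(path, label = "brain_roi") {
  if (!file.exists(path)) abort(sprintf("cannot read '%s': no such file", path))
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  mask_image(img > 0.5, label = label)
}

#' @rdname read_mask
#' @param mask A `mask_image` or logical matrix.
#' @export
write_mask <- function(mask, path) {
  grid <- if (inherits(mask, "mask_image")) mask$grid else mask > 0
  png::writePNG(grid * 1, path)
  invisible(path)
}
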
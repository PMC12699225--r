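# Spatial binning, Fourier sub-pixel rigid registration, illumination
# regression. All three act on channel_stack objects and run before any
# quantification.

#' Spatially bin a stack
#'
#' Each output pixel is the mean of a `factor x factor` block; trailing rows
#' and columns that do not fill a block are discarded and the pixel size is
#' multiplied by the factor. The camera frames are binned by a factor of 2
#' before analysis in the standard chain.
#'
#' @param stack A `channel_stack`.
#' @param factor Integer binning factor, >= 1.
#' @return A binned `channel_stack`.
#' @export
spatial_bin <- function(stack, factor = 2L) {
  stopifnot(inherits(stack, "channel_stack"))
  factor <- as.integer(factor)
  d <- dim(stack$frames)
  if (factor < 1L) abort("`factor` must be >= 1")
  if (factor > d[2L] || factor > d[3L]) abort("`factor` exceeds image size")
  if (factor == 1L) return(stack)
  nr <- d[2L] %/% factor
  nc <- d[3L] %/% factor
  x <- stack$frames[, seq_len(nr * factor), seq_len(nc * factor), drop = FALSE]
  # average over the two block dimensions by reshaping
  dim(x) <- c(d[1L], factor, nr, factor, nc)
  out <- apply(x, c(1L, 3L, 5L), mean)
  channel_stack(out, channel = stack$channel, frame_times = stack$frame_times,
                pixel_size = stack$pixel_size * factor)
}

fft2 <- function(x) fft(x)
ifft2 <- function(x) fft(x, inverse = TRUE) / length(x)

fft_freq_idx <- function(n) {
  # unshifted integer frequencies 0,1,...,-1 as used by the DFT
  c(0:(ceiling(n / 2) - 1L), -(floor(n / 2):1))
}

# Translate an image by (dy, dx) pixels (positive = toward larger indices)
# using the Fourier shift theorem; content wraps at the edges.
fourier_shift_2d <- function(img, dy, dx) {
  nr <- nrow(img); nc <- ncol(img)
  ky <- fft_freq_idx(nr) / nr
  kx <- fft_freq_idx(nc) / nc
  ph <- exp(-2i * pi * outer(ky * dy, kx * dx, `+`))
  Re(ifft2(fft2(img) * ph))
}

# Evaluate the cross-correlation surface at sub-pixel lags near (dy0, dx0)
# by direct DFT evaluation of the cross-power spectrum.
refine_peak <- function(cp, dy0, dx0, upsample = 20L, halfwidth = 0.75) {
  nr <- nrow(cp); nc <- ncol(cp)
  gy <- dy0 + seq(-halfwidth, halfwidth, by = 1 / upsample)
  gx <- dx0 + seq(-halfwidth, halfwidth, by = 1 / upsample)
  ky <- fft_freq_idx(nr)
  kx <- fft_freq_idx(nc)
  Er <- exp(2i * pi * outer(gy, ky) / nr)        # |gy| x nr
  Ec <- exp(2i * pi * outer(kx, gx) / nc)        # nc x |gx|
  cc <- Re(Er %*% cp %*% Ec)
  pk <- arrayInd(which.max(cc), dim(cc))
  c(gy[pk[1L]], gx[pk[2L]])
}

#' Estimate and correct rigid translation by Fourier cross-correlation
#'
#' 2-D Fourier-based sub-pixel rigid registration against a reference frame
#' (the first frame by default). Per-frame translations are estimated from
#' the phase-correlation peak and refined by direct evaluation of the
#' cross-correlation surface on an upsampled grid; frames are resampled by
#' the inverse shift via the Fourier shift theorem. Wrapped edges are
#' replaced by replicating the nearest interior pixels over a 2-px border.
#'
#' @param stack A `channel_stack` with at least 1 frame.
#' @param reference Reference frame (matrix); defaults to frame 1.
#' @param upsample Sub-pixel upsampling factor (>= 10 recommended).
#' @param max_shift Estimates beyond this magnitude (px) are clipped to it.
#' @param shifts Optionally, a precomputed two-column matrix of (dy, dx) per
#'   frame to apply instead of estimating (used to propagate shifts estimated
#'   on the 570 nm channel to the other channels).
#' @return A list with `stack` (registered) and `shifts` (tibble with
#'   frame, dy, dx).
#' @export
register_rigid <- function(stack, reference = NULL, upsample = 20L,
                           max_shift = 10, shifts = NULL) {
  stopifnot(inherits(stack, "channel_stack"))
  nt <- dim(stack$frames)[1L]
  reference <- reference %||% stack$frames[1L, , ]
  est <- is.null(shifts)
  if (est) {
    shifts <- matrix(0, nt, 2L)
    if (sd(reference) == 0) {
      warn("constant reference frame: registration unreliable, shifts set to 0")
      est <- FALSE
    }
  } else {
    shifts <- as.matrix(shifts[, c("dy", "dx")])
    stopifnot(nrow(shifts) == nt)
  }
  out <- stack$frames
  if (est) {
    fr <- Conj(fft2(reference))
    nr <- nrow(reference); nc <- ncol(reference)
    for (i in seq_len(nt)) {
      img <- stack$frames[i, , ]
      cp <- fr * fft2(img)
      cc <- Re(ifft2(cp))
      pk <- arrayInd(which.max(cc), dim(cc))
      d0 <- c(pk[1L] - 1L, pk[2L] - 1L)
      if (d0[1L] > nr / 2) d0[1L] <- d0[1L] - nr
      if (d0[2L] > nc / 2) d0[2L] <- d0[2L] - nc
      d <- refine_peak(cp, d0[1L], d0[2L], upsample = upsample)
      d <- pmin(pmax(d, -max_shift), max_shift)
      shifts[i, ] <- d
    }
    shifts[1L, ] <- 0
  }
  for (i in seq_len(nt)) {
    if (any(shifts[i, ] != 0)) {
      sh <- fourier_shift_2d(stack$frames[i, , ], -shifts[i, 1L], -shifts[i, 2L])
      out[i, , ] <- replicate_border(sh, 2L)
    }
  }
  list(
    stack = channel_stack(out, channel = stack$channel,
                          frame_times = stack$frame_times,
                          pixel_size = stack$pixel_size),
    shifts = tibble::tibble(frame = seq_len(nt),
                            dy = shifts[, 1L], dx = shifts[, 2L])
  )
}

replicate_border <- function(img, w = 2L) {
  n <- nrow(img); m <- ncol(img)
  if (n > 2 * w) {
    img[seq_len(w), ] <- img[rep(w + 1L, w), ]
    img[(n - w + 1L):n, ] <- img[rep(n - w, w), ]
  }
  if (m > 2 * w) {
    img[, seq_len(w)] <- img[, rep(w + 1L, w)]
    img[, (m - w + 1L):m] <- img[, rep(m - w, w)]
  }
  img
}

#' Regress illumination drift out of a stack
#'
#' Removes, from every pixel's time series, its least-squares projection onto
#' the mean time series of a control region over the skull bone or head bar
#' (plus an intercept), then adds the pixel's temporal mean back so baseline
#' levels stay physically meaningful for later ratio metrics (dF/F0, dR/R0).
#' The operation is idempotent to numerical precision.
#'
#' @param stack A `channel_stack`.
#' @param control A `mask_image` with label `skull_control` (non-empty).
#' @return A corrected `channel_stack`.
#' @export
intensity_correct <- function(stack, control) {
  stopifnot(inherits(stack, "channel_stack"), inherits(control, "mask_image"))
  d <- dim(stack$frames)
  if (!identical(dim(control$grid), d[2:3])) {
    abort("control mask shape does not match stack frames")
  }
  nt <- d[1L]
  Y <- matrix(stack$frames, nrow = nt)          # time x pixels
  ctrl <- rowMeans(Y[, as.vector(control$grid), drop = FALSE])
  cc <- ctrl - mean(ctrl)
  s2 <- sum(cc^2)
  if (s2 < .Machine$double.eps * nt) {
    warn("constant control trace: intensity correction skipped")
    return(stack)
  }
  beta <- crossprod(Y, cc) / s2                 # pixels x 1
  Y <- Y - tcrossprod(cc, beta)                 # removes slope, keeps mean
  out <- array(Y, d)
  channel_stack(out, channel = stack$channel, frame_times = stack$frame_times,
                pixel_size = stack$pixel_size)
}
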
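# Two-photon CAA coverage and tissue plaque volume quantification.

#' In-plane pixel size from field of view
#'
#' @param fov_um Field of view in um (default 1130, the maximum two-photon
#'   field of view).
#' @param n_pixels Pixels across the field (default 512).
#' @param digits Rounding for reporting (3 -> 2.207 um/pixel).
#' @return Pixel size in um/pixel.
#' @export
pixel_size_from_fov <- function(fov_um = 1130, n_pixels = 512, digits = 3) {
  assert_scalar_pos(fov_um, "fov_um")
  assert_scalar_pos(n_pixels, "n_pixels")
  round(fov_um / n_pixels, digits)
}

#' Construct a two-photon volume
#'
#' @param methoxy Methoxy-X04 (amyloid) voxel grid, `z x y x x`.
#' @param sr101 SR101 (vessel) voxel grid, congruent shape.
#' @param voxel_size `(z, y, x)` voxel size in um; default `c(3, 2.207,
#'   2.207)` (3-um z steps, 2.207 um/pixel in plane).
#' @return A `two_photon_volume` object.
#' @export
two_photon_volume <- function(methoxy, sr101 = NULL,
                              voxel_size = c(3, 2.207, 2.207)) {
  stopifnot(is.array(methoxy), length(dim(methoxy)) == 3L)
  if (!is.null(sr101) && !identical(dim(sr101), dim(methoxy))) {
    abort("channel shapes must be congruent")
  }
  if (any(voxel_size <= 0) || length(voxel_size) != 3L) {
    abort("`voxel_size` must be three positive values (z, y, x)")
  }
  structure(list(methoxy = methoxy, sr101 = sr101,
                 voxel_size = as.numeric(voxel_size)),
            class = "two_photon_volume")
}

#' Preprocess a two-photon volume
#'
#' Per slice: 3x3 median filter, then Gaussian smoothing (sigma 0.4 px);
#' low-frequency intensity fluctuations are removed by dividing each slice
#' by a heavy Gaussian blur (sigma `flat_sigma`) of the z-mean image;
#' finally the z-extent is split into `n_depth_bins` equal-depth bins and
#' each bin is rescaled so its mean intensity matches the shallowest bin
#' (depth attenuation correction). Single-slice volumes skip the depth
#' correction with a warning.
#'
#' @param vol A `two_photon_volume`.
#' @param sigma In-plane smoothing SD (px), default 0.4 (0 = skip).
#' @param flat_sigma Flat-field blur SD (px), default 50 (0 = skip the
#'   flat-field division).
#' @param n_depth_bins Number of equal-depth z bins, default 4.
#' @return A preprocessed `two_photon_volume` (methoxy channel processed;
#'   sr101 passed through).
#' @export
preprocess_volume <- function(vol, sigma = 0.4, flat_sigma = 50,
                              n_depth_bins = 4L) {
  stopifnot(inherits(vol, "two_photon_volume"))
  x <- vol$methoxy
  nz <- dim(x)[1L]
  for (z in seq_len(nz)) {
    sl <- median_filter_3x3(x[z, , ])
    x[z, , ] <- gaussian_blur(sl, sigma)
  }
  if (flat_sigma > 0) {
    zmean <- apply(x, c(2L, 3L), mean)
    field <- gaussian_blur(zmean, flat_sigma)
    field <- field / mean(field)
    field <- pmax(field, .Machine$double.eps)
    for (z in seq_len(nz)) x[z, , ] <- x[z, , ] / field
  }
  if (nz < 2L) {
    warn("single-slice volume: depth correction skipped")
  } else if (n_depth_bins >= 2L) {
    q <- min(n_depth_bins, nz)
    bins <- cut(seq_len(nz), breaks = q, labels = FALSE)
    ref <- mean(x[bins == 1L, , ])
    for (b in seq_len(q)[-1L]) {
      mb <- mean(x[bins == b, , ])
      if (mb > 0) x[bins == b, , ] <- x[bins == b, , ] * (ref / mb)
    }
  }
  two_photon_volume(x, vol$sr101, vol$voxel_size)
}

#' CAA vessel coverage from the methoxy MIP
#'
#' On the maximum-intensity projection of the methoxy channel, each
#' manually-outlined vessel gets its own threshold: mean + `thresh_sd` x SD
#' of the MIP intensity within that outline. CAA pixels are those strictly
#' above the threshold; coverage is pooled over all vessels as
#' 100 x CAA pixels / total outline pixels. Empty outlines are skipped with
#' a warning.
#'
#' @param vol A (preprocessed) `two_photon_volume`.
#' @param outlines Integer label matrix (0 = background, v = vessel v) on
#'   the MIP grid, or a list of logical masks.
#' @param thresh_sd Threshold in SDs above the within-vessel mean (1.5).
#' @return A list: `coverage` (%), `caa_mask` (logical MIP-grid matrix),
#'   `per_vessel` tibble.
#' @export
caa_coverage <- function(vol, outlines, thresh_sd = 1.5) {
  stopifnot(inherits(vol, "two_photon_volume"))
  mip <- apply(vol$methoxy, c(2L, 3L), max)
  if (is.matrix(outlines)) {
    ids <- setdiff(sort(unique(as.vector(outlines))), 0)
    masks <- lapply(ids, function(v) outlines == v)
  } else {
    masks <- outlines
    ids <- seq_along(masks)
  }
  if (length(masks) == 0L) abort("no vessel outlines supplied")
  caa <- matrix(FALSE, nrow(mip), ncol(mip))
  rows <- list()
  for (i in seq_along(masks)) {
    m <- masks[[i]]
    if (!identical(dim(m), dim(mip))) abort("outline shape does not match MIP")
    if (!any(m)) {
      warn(sprintf("vessel %s: empty outline skipped", ids[i]))
      next
    }
    v <- mip[m]
    thr <- mean(v) + thresh_sd * sd(v)
    if (!is.finite(thr)) thr <- mean(v)   # single-pixel outline: SD undefined
    hit <- m & mip > thr
    caa <- caa | hit
    rows[[length(rows) + 1L]] <- tibble::tibble(
      vessel = ids[i], area_px = sum(m), caa_px = sum(hit),
      coverage = 100 * sum(hit) / sum(m))
  }
  per_vessel <- dplyr::bind_rows(rows)
  if (nrow(per_vessel) == 0L) abort("all outlines empty")
  list(coverage = 100 * sum(per_vessel$caa_px) / sum(per_vessel$area_px),
       caa_mask = caa, per_vessel = per_vessel)
}

#' Tissue plaque volume after CAA removal
#'
#' The MIP-derived CAA pixel mask is extruded through z and those voxels
#' zeroed; candidate plaque voxels are strictly above `factor` x the volume
#' maximum (computed after preprocessing and CAA removal, per image);
#' 26-connected components are retained only when strictly larger than
#' `min_voxels` voxels.
#'
#' @param vol A preprocessed `two_photon_volume`.
#' @param caa_mask Logical MIP-grid matrix from [caa_coverage()] (optional).
#' @param factor Threshold as a fraction of the volume maximum (0.6).
#' @param min_voxels Components must exceed this size (15).
#' @param connectivity 26 (default) or 6.
#' @return A list: `plaque_volume_um3`, `n_plaques`, `labels` (integer
#'   array), `component_sizes`.
#' @export
plaque_volume <- function(vol, caa_mask = NULL, factor = 0.6,
                          min_voxels = 15L, connectivity = 26L) {
  stopifnot(inherits(vol, "two_photon_volume"))
  x <- vol$methoxy
  if (!is.null(caa_mask)) {
    stopifnot(identical(dim(caa_mask), dim(x)[2:3]))
    for (z in seq_len(dim(x)[1L])) {
      sl <- x[z, , ]
      sl[caa_mask] <- 0
      x[z, , ] <- sl
    }
  }
  mx <- max(x)
  if (mx <= 0) {
    return(list(plaque_volume_um3 = 0, n_plaques = 0L,
                labels = array(0L, dim(x)), component_sizes = integer(0)))
  }
  cand <- x > factor * mx
  labels <- label_components_3d(cand, connectivity)
  sizes <- tabulate(labels[labels > 0L])
  keep <- which(sizes > min_voxels)
  labels[!(labels %in% keep)] <- 0L
  vox_um3 <- prod(vol$voxel_size)
  list(plaque_volume_um3 = sum(sizes[keep]) * vox_um3,
       n_plaques = length(keep),
       labels = labels,
       component_sizes = sizes)
}

#' Pathology summary for one image
#'
#' Runs preprocessing, CAA coverage and plaque segmentation on one
#' two-photon image.
#'
#' @param vol A raw `two_photon_volume`.
#' @param outlines Vessel outlines, see [caa_coverage()].
#' @param ... Passed to [preprocess_volume()], [caa_coverage()] and
#'   [plaque_volume()] by name.
#' @return A one-row tibble: `caa_coverage`, `plaque_volume`, `n_plaques`.
#' @export
pathology_analysis <- function(vol, outlines, ...) {
  args <- list(...)
  pp <- do.call(preprocess_volume,
                c(list(vol), args[names(args) %in%
                                    names(formals(preprocess_volume))[-1]]))
  cc <- do.call(caa_coverage,
                c(list(pp, outlines), args[names(args) %in% "thresh_sd"]))
  pv <- do.call(plaque_volume,
                c(list(pp, cc$caa_mask),
                  args[names(args) %in% c("factor", "min_voxels", "connectivity")]))
  tibble::tibble(caa_coverage = cc$coverage,
                 plaque_volume = pv$plaque_volume_um3,
                 n_plaques = pv$n_plaques)
}

#' Session-level pathology average
#'
#' Arithmetic mean of CAA coverage and plaque volume across a session's
#' images (2-4 per session), giving one global value per mouse per time
#' point.
#'
#' @param results Tibble with `caa_coverage` and `plaque_volume`, one row
#'   per image.
#' @return A one-row tibble: means plus `n_images`.
#' @export
session_average <- function(results) {
  if (nrow(results) < 1L) abort("need at least one image result")
  tibble::tibble(caa_coverage = mean(results$caa_coverage),
                 plaque_volume = mean(results$plaque_volume),
                 n_images = nrow(results))
}
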
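# Internal numerical primitives shared across modules.

# Separable Gaussian blur with replicated (clamped) edges. Works for kernels
# wider than the image: the kernel radius is what it is, samples beyond the
# border read the border value.
gaussian_blur <- function(x, sigma) {
  stopifnot(is.matrix(x), sigma >= 0)
  if (sigma == 0) return(x)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  x <- blur_1d(x, k, r)          # along rows (dim 1)
  t(blur_1d(t(x), k, r))         # along cols
}

blur_1d <- function(x, k, r) {
  n <- nrow(x)
  # clamp indices to [1, n]
  idx <- pmin(pmax(outer(seq_len(n), -r:r, `+`), 1L), n)
  out <- matrix(0, n, ncol(x))
  for (j in seq_along(k)) out <- out + k[j] * x[idx[, j], , drop = FALSE]
  out
}

# Exact 3x3 median with replicated edges.
median_filter_3x3 <- function(x) {
  stopifnot(is.matrix(x))
  n <- nrow(x); m <- ncol(x)
  ri <- function(d) pmin(pmax(seq_len(n) + d, 1L), n)
  ci <- function(d) pmin(pmax(seq_len(m) + d, 1L), m)
  nb <- matrix(0, n * m, 9L)
  p <- 1L
  for (dr in -1:1) for (dc in -1:1) {
    nb[, p] <- as.vector(x[ri(dr), ci(dc)])
    p <- p + 1L
  }
  # median of 9 = 5th order statistic, vectorised via row sort
  nb <- matrix(nb[order(row(nb), nb)], nrow = n * m, byrow = TRUE)
  matrix(nb[, 5L], n, m)
}

# Linear index neighbours for 3-D connected components.
neighbour_offsets_3d <- function(connectivity = 26L) {
  offs <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
  offs <- offs[!(offs$dz == 0 & offs$dy == 0 & offs$dx == 0), ]
  if (connectivity == 6L) {
    offs <- offs[abs(offs$dz) + abs(offs$dy) + abs(offs$dx) == 1L, ]
  } else if (connectivity != 26L) {
    abort("connectivity must be 6 or 26")
  }
  as.matrix(offs)
}

# Label 26- (or 6-) connected components of a logical 3-D array.
# Returns an integer array of the same shape (0 = background).
label_components_3d <- function(mask, connectivity = 26L) {
  stopifnot(is.array(mask), length(dim(mask)) == 3L)
  d <- dim(mask)
  offs <- neighbour_offsets_3d(connectivity)
  labels <- array(0L, d)
  cand <- which(mask)
  if (length(cand) == 0L) return(labels)
  in_set <- array(FALSE, d)
  in_set[cand] <- TRUE
  nz <- d[1L]; ny <- d[2L]; nx <- d[3L]
  current <- 0L
  for (seed in cand) {
    if (labels[seed] != 0L) next
    current <- current + 1L
    queue <- seed
    labels[seed] <- current
    while (length(queue) > 0L) {
      v <- queue[length(queue)]
      queue <- queue[-length(queue)]
      v0 <- v - 1L
      z <- v0 %% nz
      y <- (v0 %/% nz) %% ny
      x <- v0 %/% (nz * ny)
      for (i in seq_len(nrow(offs))) {
        zz <- z + offs[i, 1L]; yy <- y + offs[i, 2L]; xx <- x + offs[i, 3L]
        if (zz < 0L || zz >= nz || yy < 0L || yy >= ny || xx < 0L || xx >= nx) next
        w <- zz + nz * (yy + ny * xx) + 1L
        if (in_set[w] && labels[w] == 0L) {
          labels[w] <- current
          queue <- c(queue, w)
        }
      }
    }
  }
  labels
}

# Centered moving average of odd width; ends use shrinking windows.
moving_average <- function(x, width = 3L) {
  if (width <= 1L) return(x)
  n <- length(x)
  r <- (width - 1L) %/% 2L
  out <- numeric(n)
  for (i in seq_len(n)) {
    j <- max(1L, i - r):min(n, i + r)
    out[i] <- mean(x[j], na.rm = TRUE)
  }
  out[is.nan(out)] <- NA_real_
  out
}

assert_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    abort(sprintf("`%s` must be a positive finite scalar", name))
  }
  invisible(x)
}
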
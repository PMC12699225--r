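# Independent reference implementations used as oracles. These deliberately
# use different algorithms/data structures from the package code paths.

# Block mean by explicit loops.
oracle_block_mean <- function(img, f) {
  nr <- nrow(img) %/% f
  nc <- ncol(img) %/% f
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      acc <- 0
      for (a in seq_len(f)) for (b in seq_len(f)) {
        acc <- acc + img[(i - 1) * f + a, (j - 1) * f + b]
      }
      out[i, j] <- acc / f^2
    }
  }
  out
}

# Greedy top-k connected region via an explicit priority queue (sorted
# insertion into a frontier list).
oracle_greedy_roi <- function(map, k, connectivity = 8) {
  nr <- nrow(map); nc <- ncol(map)
  offs <- if (connectivity == 8) {
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else {
    cbind(c(-1, 0, 0, 1), c(0, -1, 1, 0))
  }
  in_roi <- matrix(FALSE, nr, nc)
  in_pq <- matrix(FALSE, nr, nc)
  seed <- arrayInd(which.max(map), dim(map))
  pq_val <- numeric(0); pq_pos <- matrix(0L, 0L, 2L)
  push <- function(i, j) {
    if (in_pq[i, j] || in_roi[i, j] || is.na(map[i, j])) return(invisible())
    v <- map[i, j]
    ins <- findInterval(-v, -pq_val) + 1L   # descending order
    pq_val <<- append(pq_val, v, after = ins - 1L)
    pq_pos <<- rbind(pq_pos[seq_len(ins - 1L), , drop = FALSE],
                     c(i, j),
                     pq_pos[seq(ins, length.out = nrow(pq_pos) - ins + 1L),
                            , drop = FALSE])
    in_pq[i, j] <<- TRUE
  }
  add <- function(i, j) {
    in_roi[i, j] <<- TRUE
    for (q in seq_len(nrow(offs))) {
      r <- i + offs[q, 1]; c <- j + offs[q, 2]
      if (r >= 1 && r <= nr && c >= 1 && c <= nc) push(r, c)
    }
  }
  add(seed[1], seed[2])
  while (sum(in_roi) < k && length(pq_val) > 0) {
    p <- pq_pos[1L, ]
    pq_val <- pq_val[-1L]
    pq_pos <- pq_pos[-1L, , drop = FALSE]
    in_pq[p[1], p[2]] <- FALSE
    add(p[1], p[2])
  }
  in_roi
}

# Brute-force 1-D two-class k-means: try every split of the sorted data and
# minimise total within-cluster sum of squares computed by plain loops.
oracle_kmeans1d_threshold <- function(x) {
  xs <- sort(unique(x))
  best_ss <- Inf; best_thr <- NA_real_
  for (i in seq_len(length(xs) - 1)) {
    thr <- (xs[i] + xs[i + 1]) / 2
    lo <- x[x <= thr]; hi <- x[x > thr]
    ss <- sum((lo - mean(lo))^2) + sum((hi - mean(hi))^2)
    if (ss < best_ss) {
      best_ss <- ss; best_thr <- thr
    }
  }
  best_thr
}

# Johnson-Neyman boundaries by dense grid search + uniroot refinement of
# |theta(m)| / se(m) - t_crit.
oracle_jn_grid <- function(b1, b3, v11, v33, v13, t_crit,
                           m_range = c(-1e4, 1e4), n_grid = 400001) {
  g <- function(m) {
    th <- b1 + b3 * m
    se <- sqrt(v11 + m^2 * v33 + 2 * m * v13)
    abs(th) / se - t_crit
  }
  ms <- seq(m_range[1], m_range[2], length.out = n_grid)
  gv <- g(ms)
  roots <- numeric(0)
  sgn <- sign(gv)
  flips <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  for (i in flips) {
    roots <- c(roots, stats::uniroot(g, c(ms[i], ms[i + 1]),
                                     tol = 1e-10)$root)
  }
  sort(roots)
}

# Hand-rolled Holm step-down.
oracle_holm <- function(p) {
  k <- length(p)
  o <- order(p)
  adj <- numeric(k)
  running <- 0
  for (i in seq_len(k)) {
    running <- max(running, min(1, (k - i + 1) * p[o[i]]))
    adj[o[i]] <- running
  }
  adj
}

# Closed-form Gaussian trough profile evaluated analytically.
oracle_gaussian_profile <- function(s_um, depth, sigma_um, bg = 1000) {
  bg * (1 - depth * exp(-s_um^2 / (2 * sigma_um^2)))
}

# Small textured image for registration tests.
make_texture <- function(nr, nc, sigma = 3, seed = 1) {
  withr::with_seed(seed, {
    mesovasc:::gaussian_blur(matrix(rnorm(nr * nc), nr, nc), sigma)
  })
}
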
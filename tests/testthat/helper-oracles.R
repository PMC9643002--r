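# Independent oracle implementations, deliberately written with different
# machinery than the package internals.

# Real even-order SH basis built from pracma::legendre (which includes the
# Condon-Shortley phase; cancelled here so conventions match).
oracle_sh_basis <- function(dirs, lmax) {
  dirs <- matrix(dirs, ncol = 3)
  n <- nrow(dirs)
  ct <- dirs[, 3]
  phi <- atan2(dirs[, 2], dirs[, 1])
  nc <- (lmax + 1) * (lmax + 2) / 2
  B <- matrix(0, n, nc)
  idx <- 0L
  for (l in seq(0, lmax, by = 2)) {
    P <- pracma::legendre(l, ct) # (l+1) x n, rows m = 0..l, with CS phase
    if (l == 0) P <- matrix(P, nrow = 1)
    for (m in -l:l) {
      idx <- idx + 1L
      am <- abs(m)
      N <- sqrt((2 * l + 1) / (4 * pi) *
                  exp(lgamma(l - am + 1) - lgamma(l + am + 1)))
      p <- P[am + 1, ] * (-1)^am # cancel Condon-Shortley
      B[, idx] <- if (m == 0) N * p
      else if (m > 0) sqrt(2) * N * p * cos(am * phi)
      else sqrt(2) * N * p * sin(am * phi)
    }
  }
  B
}

# Dense-quadrature projection of a lobe sum onto the SH basis:
# Gauss-Legendre in cos(theta) x trapezoid in phi.
oracle_project_lobes <- function(populations, kappa, lmax, n_theta = 64,
                                 n_phi = 128) {
  gl <- pracma::gaussLegendre(n_theta, -1, 1)
  phi <- seq(0, 2 * pi, length.out = n_phi + 1)[-(n_phi + 1)]
  ct <- rep(gl$x, each = n_phi)
  ph <- rep(phi, times = n_theta)
  st <- sqrt(pmax(0, 1 - ct^2))
  dirs <- cbind(st * cos(ph), st * sin(ph), ct)
  wq <- rep(gl$w, each = n_phi) * (2 * pi / n_phi)
  f <- numeric(nrow(dirs))
  for (pop in populations) {
    u <- pop$direction
    f <- f + pop$density * exp(kappa * (drop(dirs %*% u)^2 - 1))
  }
  B <- oracle_sh_basis(dirs, lmax)
  drop(t(B) %*% (wq * f))
}

# Independent trilinear interpolation (8-corner loop, zero outside).
oracle_trilinear <- function(vol4d, u) {
  dm <- dim(vol4d)
  out <- matrix(0, nrow(u), dm[4])
  for (r in seq_len(nrow(u))) {
    i0 <- floor(u[r, ])
    f <- u[r, ] - i0
    for (di in 0:1) for (dj in 0:1) for (dk in 0:1) {
      i <- i0 + c(di, dj, dk)
      if (any(i < 0) || any(i >= dm[1:3])) next
      wgt <- prod(ifelse(c(di, dj, dk) == 1, f, 1 - f))
      out[r, ] <- out[r, ] + wgt * vol4d[i[1] + 1, i[2] + 1, i[3] + 1, ]
    }
  }
  out
}

# Brute-force gm/wm interface scan over all voxels.
oracle_gmwmi <- function(t5) {
  d <- t5$data
  gm <- d[, , , 1] + d[, , , 2] >= 0.5
  wm <- d[, , , 3] >= 0.5
  dm <- dim(gm)
  out <- array(FALSE, dm)
  for (i in 1:dm[1]) for (j in 1:dm[2]) for (k in 1:dm[3]) {
    nb <- rbind(c(i - 1, j, k), c(i + 1, j, k), c(i, j - 1, k),
                c(i, j + 1, k), c(i, j, k - 1), c(i, j, k + 1))
    nb <- nb[nb[, 1] >= 1 & nb[, 1] <= dm[1] & nb[, 2] >= 1 &
               nb[, 2] <= dm[2] & nb[, 3] >= 1 & nb[, 3] <= dm[3], ,
             drop = FALSE]
    if (gm[i, j, k] && any(wm[nb])) out[i, j, k] <- TRUE
    if (wm[i, j, k] && any(gm[nb])) out[i, j, k] <- TRUE
  }
  out
}

# Exact segment-cube intersection length by slab clipping (Liang-Barsky).
segment_in_cube <- function(p0, p1, lo, hi) {
  d <- p1 - p0
  t0 <- 0
  t1 <- 1
  for (k in 1:3) {
    if (d[k] == 0) {
      if (p0[k] < lo[k] || p0[k] >= hi[k]) return(0)
    } else {
      ta <- (lo[k] - p0[k]) / d[k]
      tb <- (hi[k] - p0[k]) / d[k]
      if (ta > tb) { tmp <- ta; ta <- tb; tb <- tmp }
      t0 <- max(t0, ta)
      t1 <- min(t1, tb)
      if (t0 >= t1) return(0)
    }
  }
  (t1 - t0) * sqrt(sum(d^2))
}

# Brute-force TDI: distinct-streamline count per voxel via exact clipping
# over the full grid bounding box of each segment.
oracle_tdi <- function(tractogram, grid, weights = NULL) {
  inv <- solve(grid$affine)
  out <- array(0, grid$shape)
  n <- length(tractogram$streamlines)
  w <- if (is.null(weights)) rep(1, n) else weights
  for (s in seq_len(n)) {
    pts <- tractogram$streamlines[[s]]
    u <- t(inv[1:3, 1:3] %*% t(pts) + inv[1:3, 4]) + 0.5 # voxel v: [v, v+1)
    touched <- new.env(parent = emptyenv())
    for (i in seq_len(nrow(u) - 1)) {
      p0 <- u[i, ]
      p1 <- u[i + 1, ]
      lo <- pmax(floor(pmin(p0, p1)), 0)
      hi <- pmin(floor(pmax(p0, p1)), grid$shape - 1)
      if (any(lo > hi)) next
      for (vx in lo[1]:hi[1]) for (vy in lo[2]:hi[2]) for (vz in lo[3]:hi[3]) {
        len <- segment_in_cube(p0, p1, c(vx, vy, vz), c(vx, vy, vz) + 1)
        if (len > 0)
          assign(paste(vx, vy, vz), TRUE, envir = touched)
      }
    }
    for (key in ls(touched)) {
      v <- as.integer(strsplit(key, " ")[[1]])
      out[v[1] + 1, v[2] + 1, v[3] + 1] <-
        out[v[1] + 1, v[2] + 1, v[3] + 1] + w[s]
    }
  }
  out
}

# Dense point-sampling estimate of per-voxel traversal lengths of one
# streamline (n_samp points per segment).
oracle_voxel_lengths <- function(pts, grid, n_samp = 10000) {
  inv <- solve(grid$affine)
  acc <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(pts) - 1)) {
    p0 <- pts[i, ]
    p1 <- pts[i + 1, ]
    seglen <- sqrt(sum((p1 - p0)^2))
    tt <- (seq_len(n_samp) - 0.5) / n_samp
    sp <- outer(tt, p1 - p0) + matrix(p0, n_samp, 3, byrow = TRUE)
    u <- t(inv[1:3, 1:3] %*% t(sp) + inv[1:3, 4])
    v <- floor(u + 0.5)
    key <- paste(v[, 1], v[, 2], v[, 3])
    tab <- table(key)
    for (k in names(tab)) {
      prev <- if (!is.null(acc[[k]])) acc[[k]] else 0
      assign(k, prev + tab[[k]] * seglen / n_samp, envir = acc)
    }
  }
  keys <- ls(acc)
  list(voxel = do.call(rbind, lapply(strsplit(keys, " "), as.integer)),
       length = vapply(keys, function(k) acc[[k]], numeric(1)))
}
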
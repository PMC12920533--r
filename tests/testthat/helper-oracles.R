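# Independent oracles and small fixtures used across the suite. These
# deliberately avoid the package's internal code paths: gradients are formed
# by direct per-voxel finite differences, eigenvalues by base eigen(), and
# connected components by a plain BFS flood fill.

small_config <- function(n = 16L, phases = 3L, seed = 1L, ...) {
  phantom_config(grid_shape = c(n, n, n), n_phases = phases, seed = seed, ...)
}

interior3 <- function(n) {
  m <- array(FALSE, c(n, n, n))
  m[2:(n - 1), 2:(n - 1), 2:(n - 1)] <- TRUE
  m
}

# Direct velocity-gradient tensor at one voxel by central differences over
# the full grid (no mask handling; call only at interior voxels).
oracle_gradient_at <- function(field, i, j, k, phase) {
  h <- field$spacing_mm
  J <- matrix(0, 3, 3)
  for (ic in 1:3) {
    v <- field$values[, , , ic, phase]
    J[ic, 1] <- (v[i + 1, j, k] - v[i - 1, j, k]) / (2 * h) * 10
    J[ic, 2] <- (v[i, j + 1, k] - v[i, j - 1, k]) / (2 * h) * 10
    J[ic, 3] <- (v[i, j, k + 1] - v[i, j, k - 1]) / (2 * h) * 10
  }
  J
}

oracle_vorticity_at <- function(field, i, j, k, phase) {
  J <- oracle_gradient_at(field, i, j, k, phase)
  c(J[3, 2] - J[2, 3], J[1, 3] - J[3, 1], J[2, 1] - J[1, 2])
}

oracle_lambda2_at <- function(field, i, j, k, phase) {
  J <- oracle_gradient_at(field, i, j, k, phase)
  S <- (J + t(J)) / 2
  O <- (J - t(J)) / 2
  sort(eigen(S %*% S + O %*% O, symmetric = TRUE, only.values = TRUE)$values)[2]
}

helper_coords <- function(shape, h) {
  nx <- shape[1]; ny <- shape[2]; nz <- shape[3]
  x <- (seq_len(nx) - (nx + 1) / 2) * h
  y <- (seq_len(ny) - (ny + 1) / 2) * h
  z <- (seq_len(nz) - 0.5) * h
  list(x = array(rep(x, times = ny * nz), dim = shape),
       y = array(rep(rep(y, each = nx), times = nz), dim = shape),
       z = array(rep(z, each = nx * ny), dim = shape))
}

# A smooth divergence-rich random field: sums of low-frequency sinusoids.
random_smooth_field <- function(config, seed = 1) {
  g <- helper_coords(config$grid_shape, config$spacing_mm)
  withr::with_seed(seed, {
    mk <- function() {
      a <- stats::runif(3, -20, 20)
      f <- stats::runif(3, 0.02, 0.08)
      p <- stats::runif(3, 0, 2 * pi)
      a[1] * sin(f[1] * g$x + p[1]) + a[2] * cos(f[2] * g$y + p[2]) +
        a[3] * sin(f[3] * g$z + p[3])
    }
    d <- config$grid_shape
    vals <- array(0, c(d, 3L, config$n_phases))
    vx <- mk(); vy <- mk(); vz <- mk()
    for (t in seq_len(config$n_phases)) {
      vals[, , , 1, t] <- vx; vals[, , , 2, t] <- vy; vals[, , , 3, t] <- vz
    }
    velocity_field(vals, config$spacing_mm, config$venc_cm_s)
  })
}

# BFS flood fill with 26-connectivity over a logical 3-D array.
oracle_flood_fill_26 <- function(sel) {
  d <- dim(sel)
  lab <- array(0L, d)
  nxt <- 0L
  idx <- which(sel)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  for (start in idx) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      p <- arrayInd(cur, d)
      for (r in seq_len(nrow(offs))) {
        q <- p + offs[r, ]
        if (any(q < 1) || any(q > d)) next
        qi <- q[1] + (q[2] - 1) * d[1] + (q[3] - 1) * d[1] * d[2]
        if (sel[qi] && lab[qi] == 0L) {
          lab[qi] <- nxt
          queue <- c(queue, qi)
        }
      }
    }
  }
  lab
}

# Pairwise-slope Theil-Sen by explicit double loop (oracle).
oracle_theil_sen <- function(t, y) {
  ok <- !is.na(t) & !is.na(y)
  t <- t[ok]; y <- y[ok]
  s <- c()
  n <- length(t)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (t[j] != t[i]) s <- c(s, (y[j] - y[i]) / (t[j] - t[i]))
  }
  median(s)
}

# Rotate a phantom dataset by 90 degrees counterclockwise about the grid
# z-axis: voxel (i,j,k) -> (n-j+1, i, k); vectors (vx,vy) -> (-vy, vx).
# Requires a square x/y grid.
rotate_phantom_90 <- function(ph) {
  rot3 <- function(a) {
    d <- dim(a)
    aperm(a[, d[2]:1, , drop = FALSE], c(2, 1, 3))
  }
  d <- dim(ph$field$values)
  vals <- array(0, d)
  for (t in seq_len(d[5])) {
    vx <- ph$field$values[, , , 1, t]; dim(vx) <- d[1:3]
    vy <- ph$field$values[, , , 2, t]; dim(vy) <- d[1:3]
    vz <- ph$field$values[, , , 3, t]; dim(vz) <- d[1:3]
    vals[, , , 1, t] <- -rot3(vy)
    vals[, , , 2, t] <- rot3(vx)
    vals[, , , 3, t] <- rot3(vz)
  }
  mrot <- array(FALSE, dim(ph$mask$values))
  grot <- array(0, dim(ph$magnitude$values))
  for (t in seq_len(dim(ph$mask$values)[4])) {
    mrot[, , , t] <- rot3(ph$mask$values[, , , t])
    grot[, , , t] <- rot3(ph$magnitude$values[, , , t])
  }
  list(field = velocity_field(vals, ph$field$spacing_mm, ph$field$venc_cm_s),
       magnitude = magnitude_image(grot, ph$magnitude$spacing_mm),
       mask = blood_pool_mask(mrot, ph$mask$spacing_mm))
}
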
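# Internal 3-D array helpers shared by the gradient, unwrap and phantom code.
# All fields live on a regular grid with isotropic spacing (mm); the LV long
# axis is the grid z-axis with the base at low z.

# Shift a 3-D array by one voxel along `axis` (+1 pulls the value of the
# next-index neighbour into each voxel); vacated voxels become NA.
shift3 <- function(a, axis, by) {
  stopifnot(length(dim(a)) == 3L, by %in% c(-1L, 1L))
  d <- dim(a)
  out <- array(NA_real_, d)
  idx_src <- idx_dst <- lapply(d, seq_len)
  n <- d[axis]
  if (n < 2L) return(out)
  if (by == 1L) {
    idx_dst[[axis]] <- 1:(n - 1L)
    idx_src[[axis]] <- 2:n
  } else {
    idx_dst[[axis]] <- 2:n
    idx_src[[axis]] <- 1:(n - 1L)
  }
  out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
    a[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
  out
}

# Voxel-centre coordinates in mm. x and y are centred on the grid axis
# (x = y = 0 on the long axis), z runs from the basal face (z > 0, apex at
# high z).
grid_coords <- function(grid_shape, spacing_mm) {
  nx <- grid_shape[1]; ny <- grid_shape[2]; nz <- grid_shape[3]
  x <- (seq_len(nx) - (nx + 1) / 2) * spacing_mm
  y <- (seq_len(ny) - (ny + 1) / 2) * spacing_mm
  z <- (seq_len(nz) - 0.5) * spacing_mm
  list(
    x = array(rep(x, times = ny * nz), dim = grid_shape),
    y = array(rep(rep(y, each = nx), times = nz), dim = grid_shape),
    z = array(rep(z, each = nx * ny), dim = grid_shape)
  )
}

z_slice_mm <- function(k, spacing_mm) (k - 0.5) * spacing_mm

# Mask-aware partial derivative along one axis: central difference where both
# neighbours are in-mask, one-sided where only one is, NA where neither is.
# `a` and `mask` are 3-D; values outside the mask are never read.
masked_partial <- function(a, mask, axis, h) {
  a_in <- a
  a_in[!mask] <- NA_real_
  fwd <- shift3(a_in, axis, 1L)
  bwd <- shift3(a_in, axis, -1L)
  has_f <- !is.na(fwd)
  has_b <- !is.na(bwd)
  out <- array(NA_real_, dim(a))
  both <- has_f & has_b
  out[both] <- (fwd[both] - bwd[both]) / (2 * h)
  fo <- has_f & !has_b
  out[fo] <- (fwd[fo] - a_in[fo]) / h
  bo <- has_b & !has_f
  out[bo] <- (a_in[bo] - bwd[bo]) / h
  out[!mask] <- NA_real_
  out
}

# Median over the 6-neighbourhood of every voxel, ignoring out-of-grid and
# out-of-mask neighbours. Vectorised via a compare-exchange sorting network
# over the six neighbour planes (apply() would be far too slow per voxel).
neighbour_median6 <- function(a, mask = NULL) {
  d <- dim(a)
  a_in <- a
  if (!is.null(mask)) a_in[!mask] <- NA_real_
  cols <- matrix(NA_real_, nrow = prod(d), ncol = 6L)
  j <- 0L
  for (axis in 1:3) for (by in c(-1L, 1L)) {
    j <- j + 1L
    cols[, j] <- as.vector(shift3(a_in, axis, by))
  }
  k <- rowSums(!is.na(cols))
  cols[is.na(cols)] <- Inf  # push missing neighbours past the valid ones
  # bubble sorting network on 6 columns
  for (pass in 1:5) for (i in 1:(6 - pass)) {
    lo <- pmin(cols[, i], cols[, i + 1])
    hi <- pmax(cols[, i], cols[, i + 1])
    cols[, i] <- lo
    cols[, i + 1] <- hi
  }
  n <- nrow(cols)
  med <- rep(NA_real_, n)
  has <- k > 0L
  i_lo <- (k + 1L) %/% 2L
  i_hi <- k %/% 2L + 1L
  rows <- seq_len(n)[has]
  med[has] <- (cols[cbind(rows, i_lo[has])] + cols[cbind(rows, i_hi[has])]) / 2
  array(med, d)
}
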
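# Velocity-data corrections applied before any flow quantification:
# anti-aliasing (phase unwrap), noise masking, eddy-current correction, and
# PC-MRA generation.

#' Correct velocity aliasing (anti-aliasing / phase unwrap)
#'
#' Velocities beyond the encoding limit VENC alias by multiples of 2*VENC.
#' For every voxel, phase and component, the value is compared with the
#' median of its spatial 6-neighbourhood; if it differs by more than VENC,
#' the multiple of 2*VENC that minimises the difference is added. A single
#' spatial pass corrects single-wrap aliasing, the regime relevant at
#' VENC = 150 cm/s in the LV.
#'
#' @param field A [velocity_field].
#' @param mask Optional [blood_pool_mask] (or logical array); only in-mask
#'   neighbours contribute to the median, and voxels with no in-mask
#'   neighbour pass through unchanged.
#' @return A corrected [velocity_field].
#' @export
unwrap_velocity <- function(field, mask = NULL) {
  if (is.null(field$venc_cm_s)) stop("field lacks VENC metadata")
  venc <- field$venc_cm_s
  d <- dim(field$values)
  for (t in seq_len(d[5])) {
    m3 <- if (is.null(mask)) NULL else mask_at_phase(mask, t)
    for (ic in 1:3) {
      v <- field$values[, , , ic, t]
      dim(v) <- d[1:3]
      med <- neighbour_median6(v, m3)
      diffv <- v - med
      wraps <- round(diffv / (2 * venc))
      fix <- !is.na(diffv) & abs(diffv) > venc & wraps != 0
      if (!is.null(m3)) fix <- fix & m3
      if (any(fix)) {
        v[fix] <- v[fix] - 2 * venc * wraps[fix]
        field$values[, , , ic, t] <- v
      }
    }
  }
  field
}

#' First-order eddy-current correction
#'
#' Residual eddy-current fields add a slowly varying spatial offset to the
#' measured velocities. Static tissue is identified as voxels whose
#' time-averaged magnitude exceeds a quantile threshold and whose temporal
#' velocity SD falls below a quantile threshold; per phase and per component
#' a first-order polynomial in (x, y, z) is fitted to the static-tissue
#' velocities and subtracted everywhere. After correction the mean residual
#' velocity over static tissue is zero to numerical precision.
#'
#' @param field A [velocity_field].
#' @param magnitude A [magnitude_image] on the same grid.
#' @param mag_quantile Magnitude quantile above which a voxel may count as
#'   static tissue (default 0.5).
#' @param sd_quantile Temporal-velocity-SD quantile below which a voxel may
#'   count as static (default 0.1).
#' @param min_static Minimum number of static voxels required; below this a
#'   warning is emitted and the input is returned unchanged (default 100).
#' @return A corrected [velocity_field].
#' @export
correct_eddy_currents <- function(field, magnitude, mag_quantile = 0.5,
                                  sd_quantile = 0.1, min_static = 100L) {
  d <- dim(field$values)
  stopifnot(all(dim(magnitude$values)[1:3] == d[1:3]))
  nvox <- prod(d[1:3])
  nt <- d[5]
  mag_avg <- array(rowMeans(matrix(magnitude$values, nrow = nvox)), d[1:3])
  # temporal variance of velocity per voxel, averaged over components
  row_var <- function(M) rowSums((M - rowMeans(M))^2) / max(1L, ncol(M) - 1L)
  vvar <- 0
  for (ic in 1:3) {
    vvar <- vvar + row_var(matrix(field$values[, , , ic, ], nrow = nvox))
  }
  vsd <- array(sqrt(vvar / 3), d[1:3])
  static <- (mag_avg >= quantile(mag_avg, mag_quantile)) &
    (vsd <= quantile(vsd, sd_quantile))
  if (sum(static) < min_static) {
    warning(sprintf(
      "only %d static-tissue voxels found (< %d); skipping eddy-current correction",
      sum(static), min_static))
    return(field)
  }
  g <- grid_coords(d[1:3], field$spacing_mm)
  X <- cbind(1, g$x[static], g$y[static], g$z[static])
  Xall <- cbind(1, as.vector(g$x), as.vector(g$y), as.vector(g$z))
  XtX_inv <- solve(crossprod(X))
  for (t in seq_len(d[5])) for (ic in 1:3) {
    v <- field$values[, , , ic, t]
    beta <- XtX_inv %*% crossprod(X, v[static])
    v <- v - array(Xall %*% beta, d[1:3])
    field$values[, , , ic, t] <- v
  }
  field
}

#' Zero velocities in low-signal (noise) voxels
#'
#' Voxels whose time-averaged magnitude falls below a fraction of the
#' maximum time-averaged magnitude carry no reliable phase information;
#' their velocities are set to zero.
#'
#' @param field A [velocity_field].
#' @param magnitude A [magnitude_image] on the same grid.
#' @param threshold_frac Fraction of the maximum time-averaged magnitude in
#'   \[0, 1); default 0.1.
#' @return A [velocity_field] with noise-voxel velocities zeroed.
#' @export
apply_noise_mask <- function(field, magnitude, threshold_frac = 0.1) {
  if (threshold_frac < 0 || threshold_frac >= 1) {
    stop("threshold_frac must lie in [0, 1)")
  }
  if (threshold_frac == 0) return(field)
  d3 <- dim(magnitude$values)[1:3]
  mag_avg <- array(rowMeans(matrix(magnitude$values, nrow = prod(d3))), d3)
  noise <- mag_avg < threshold_frac * max(mag_avg)
  if (any(noise)) {
    d <- dim(field$values)
    for (t in seq_len(d[5])) for (ic in 1:3) {
      v <- field$values[, , , ic, t]
      v[noise] <- 0
      field$values[, , , ic, t] <- v
    }
  }
  field
}

#' Phase-contrast MR angiography (PC-MRA) volume
#'
#' A 3-D angiography-like contrast volume: the time average over cardiac
#' phases of magnitude times speed. Vessels and chambers with coherent flow
#' appear bright; static or signal-free voxels appear dark.
#'
#' @param field A [velocity_field].
#' @param magnitude A [magnitude_image] on the same grid.
#' @return A 3-D numeric array (non-negative).
#' @export
compute_pcmra <- function(field, magnitude) {
  d <- dim(field$values)
  stopifnot(all(dim(magnitude$values)[1:3] == d[1:3]))
  acc <- array(0, d[1:3])
  for (t in seq_len(d[5])) {
    sp <- sqrt(field$values[, , , 1, t]^2 + field$values[, , , 2, t]^2 +
                 field$values[, , , 3, t]^2)
    acc <- acc + magnitude$values[, , , t] * sp
  }
  acc / d[5]
}
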
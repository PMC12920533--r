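#' Phantom acquisition configuration
#'
#' Describes the synthetic 4D flow acquisition the phantom generator
#' emulates: a 2.0 mm isotropic grid with 25 phases per cardiac cycle and a
#' velocity-encoding limit of 150 cm/s, matching a typical left-ventricular
#' 4D flow protocol.
#'
#' @param grid_shape Integer length-3 voxel counts per axis; all must be >= 8.
#' @param spacing_mm Isotropic voxel edge (mm), default 2.0.
#' @param n_phases Cardiac phases per cycle (>= 2), default 25.
#' @param venc_cm_s Velocity-encoding limit (cm/s), default 150.
#' @param cycle_s Cardiac-cycle duration in seconds, default 0.8.
#' @param seed Integer RNG seed for the measurement-noise generator.
#' @param noise_sd_cm_s SD of additive Gaussian velocity noise inside the
#'   blood pool (cm/s), default 1.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(grid_shape = c(48L, 48L, 48L), spacing_mm = 2.0,
                           n_phases = 25L, venc_cm_s = 150, cycle_s = 0.8,
                           seed = 1L, noise_sd_cm_s = 1.0) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 8L)) {
    stop("grid_shape must be three integers, all >= 8")
  }
  if (n_phases < 2L) stop("n_phases must be >= 2")
  if (venc_cm_s <= 0) stop("venc_cm_s must be positive")
  if (spacing_mm <= 0) stop("spacing_mm must be positive")
  structure(list(grid_shape = grid_shape, spacing_mm = spacing_mm,
                 n_phases = as.integer(n_phases), venc_cm_s = venc_cm_s,
                 cycle_s = cycle_s, seed = as.integer(seed),
                 noise_sd_cm_s = noise_sd_cm_s),
            class = "phantom_config")
}

#' Phantom ground-truth manifest
#'
#' The known quantities embedded in a generated LV phantom, against which the
#' downstream pipeline is validated: the tilt (polar angle to the long axis)
#' and azimuth of the helical vortex-tube axis, the prescribed E/A peak
#' inflow ratio, and the vortex-tube circulation and core radius.
#'
#' @param vvc_polar_deg Angle between the vortex-tube axis and the LV long
#'   axis, degrees in \[0, 90\].
#' @param vvc_azimuth_deg Azimuth of the tube axis about the long axis,
#'   degrees counterclockwise from +x.
#' @param ea_ratio_true Prescribed E-peak/A-peak flow-rate ratio (> 0).
#' @param circulation_m2_s Vortex-tube circulation (m^2/s).
#' @param core_radius_mm Lamb-Oseen core radius of the tube (mm, > 0).
#' @param omega_rad_s Solid-body angular speed, only meaningful for the
#'   analytic solid-body phantom.
#' @return An object of class `phantom_truth`.
#' @export
phantom_truth <- function(vvc_polar_deg = 20, vvc_azimuth_deg = 0,
                          ea_ratio_true = 1.5, circulation_m2_s = 0.015,
                          core_radius_mm = 6, omega_rad_s = NA_real_) {
  if (vvc_polar_deg < 0 || vvc_polar_deg > 90) {
    stop("vvc_polar_deg must lie in [0, 90]")
  }
  if (ea_ratio_true <= 0) stop("ea_ratio_true must be positive")
  if (core_radius_mm <= 0) stop("core_radius_mm must be positive")
  structure(list(vvc_polar_deg = vvc_polar_deg,
                 vvc_azimuth_deg = vvc_azimuth_deg,
                 ea_ratio_true = ea_ratio_true,
                 circulation_m2_s = circulation_m2_s,
                 core_radius_mm = core_radius_mm,
                 omega_rad_s = omega_rad_s),
            class = "phantom_truth")
}

#' Solid-body rotation field (analytic vorticity oracle)
#'
#' Velocity `v = omega x r` about the grid-centre long axis, identical at
#' every phase. The curl of a solid-body rotation is exactly `2 omega`
#' everywhere, and its Lambda2 value is `-omega^2` (strain tensor S = 0,
#' eigenvalues of Omega^2 are \{-omega^2, -omega^2, 0\}), making this field
#' an exact analytic oracle for the gradient-based operators: central
#' differences are exact on linear fields.
#'
#' @param omega_rad_s Angular speed (rad/s), finite.
#' @param config A [phantom_config()].
#' @return A list with `field` ([velocity_field]), `magnitude`
#'   ([magnitude_image], uniform), `mask` (`NULL`: whole grid),
#'   `config`, and `truth` recording `omega_rad_s`.
#' @export
make_solid_body_field <- function(omega_rad_s, config = phantom_config()) {
  stopifnot(is.finite(omega_rad_s))
  g <- grid_coords(config$grid_shape, config$spacing_mm)
  # v (cm/s) = omega (1/s) x r (cm); coordinates are mm
  vx <- -omega_rad_s * g$y / 10
  vy <- omega_rad_s * g$x / 10
  vz <- array(0, config$grid_shape)
  field <- replicate_phases(vx, vy, vz, config)
  list(field = field,
       magnitude = uniform_magnitude(config),
       mask = NULL, config = config,
       truth = phantom_truth(omega_rad_s = omega_rad_s))
}

#' Planar pure-shear field (negative control for vortex detection)
#'
#' Velocity `v = (gamma * y, 0, 0)`: vorticity magnitude is `gamma` but
#' `S^2 + Omega^2` vanishes identically, so Lambda2 is exactly zero and no
#' vortex core may be detected. Distinguishes rotation-driven from
#' shear-driven vorticity.
#'
#' @param gamma_s Shear rate (1/s), finite.
#' @inheritParams make_solid_body_field
#' @return Same structure as [make_solid_body_field()].
#' @export
make_shear_field <- function(gamma_s, config = phantom_config()) {
  stopifnot(is.finite(gamma_s))
  g <- grid_coords(config$grid_shape, config$spacing_mm)
  vx <- gamma_s * g$y / 10
  zero <- array(0, config$grid_shape)
  field <- replicate_phases(vx, zero, zero, config)
  list(field = field, magnitude = uniform_magnitude(config),
       mask = NULL, config = config, truth = phantom_truth())
}

replicate_phases <- function(vx, vy, vz, config) {
  d <- config$grid_shape
  nt <- config$n_phases
  vals <- array(0, c(d, 3L, nt))
  for (t in seq_len(nt)) {
    vals[, , , 1, t] <- vx
    vals[, , , 2, t] <- vy
    vals[, , , 3, t] <- vz
  }
  velocity_field(vals, config$spacing_mm, config$venc_cm_s)
}

uniform_magnitude <- function(config, value = 100) {
  magnitude_image(array(value, c(config$grid_shape, config$n_phases)),
                  config$spacing_mm)
}

# Phase indices of the E and A inflow peaks and the diastolic window for a
# given phase count; at the default 25 phases these are E = 15, A = 23,
# window 13..25.
phantom_wave_phases <- function(n_phases) {
  list(e_phase = as.integer(round(0.60 * n_phases)),
       a_phase = as.integer(round(0.92 * n_phases)),
       width = 1.5 * n_phases / 25,
       window = c(as.integer(round(0.52 * n_phases)), as.integer(n_phases)))
}

# Biphasic transmitral waveform sampled at integer phases: two Gaussians in
# phase index whose peak amplitudes have ratio ea (E over A).
phantom_waveform <- function(n_phases, ea_ratio, peak_cm_s = 30) {
  w <- phantom_wave_phases(n_phases)
  t <- seq_len(n_phases)
  a_amp <- peak_cm_s
  e_amp <- peak_cm_s * ea_ratio
  e_amp * exp(-(t - w$e_phase)^2 / (2 * w$width^2)) +
    a_amp * exp(-(t - w$a_phase)^2 / (2 * w$width^2))
}

# Tangential Lamb-Oseen speed profile in cm/s; r in mm, circulation in m^2/s.
lamb_oseen_speed <- function(r_mm, circulation_m2_s, core_radius_mm) {
  r_m <- r_mm / 1000
  rc_m <- core_radius_mm / 1000
  v <- ifelse(r_m < 1e-9, 0,
              circulation_m2_s / (2 * pi * pmax(r_m, 1e-9)) *
                (1 - exp(-(r_m / rc_m)^2)))
  v * 100
}

#' Synthetic left-ventricular 4D flow phantom
#'
#' Builds a complete synthetic acquisition with known ground truth. The
#' blood pool is a half prolate spheroid (long axis along z, base at low z).
#' The velocity field superposes: (a) a transmitral jet through a basal disc
#' with a biphasic (E/A) waveform whose peak-flow ratio equals
#' `truth$ea_ratio_true`; (b) a Lamb-Oseen vortex tube through the cavity
#' centre at polar angle `truth$vvc_polar_deg` and azimuth
#' `truth$vvc_azimuth_deg`, emulating the helical filling-flow core; and
#' (c) a thin-core vortex ring at the basal plane emulating the mitral-valve
#' vortex ring. Seeded Gaussian noise is added inside the pool; all velocity
#' is zero outside the mask and the magnitude image is high inside the pool
#' and low outside.
#'
#' @param config A [phantom_config()].
#' @param truth A [phantom_truth()]; the returned object echoes it.
#' @param wrap_venc If `TRUE`, velocity aliasing at the VENC limit is
#'   simulated on the returned field (see [simulate_venc_wrap()]).
#' @return A list of class `lv_phantom` with elements `field`, `magnitude`,
#'   `mask`, `truth`, `config`, and `geometry` (cavity centre, semi-axes,
#'   basal disc and ring parameters, per-phase jet waveform in cm/s).
#' @export
make_lv_phantom <- function(config = phantom_config(),
                            truth = phantom_truth(),
                            wrap_venc = FALSE) {
  stopifnot(inherits(config, "phantom_config"), inherits(truth, "phantom_truth"))
  h <- config$spacing_mm
  d <- config$grid_shape
  g <- grid_coords(d, h)

  # cavity geometry: half prolate spheroid, base at low z
  z_base <- 2 * h
  c_mm <- 0.80 * (d[3] * h - z_base)           # long semi-axis
  a_mm <- 0.55 * (d[1] * h / 2)                # short semi-axis
  mask3 <- (g$z >= z_base) &
    ((g$x^2 + g$y^2) / a_mm^2 + ((g$z - z_base) / c_mm)^2 <= 1)
  centre <- c(0, 0, z_base + 0.45 * c_mm)

  # vortex-tube axis and guard: the tube must stay inside the cavity while
  # spanning the basal-to-apical thirds (it has to cross the mid-plane)
  th <- truth$vvc_polar_deg * pi / 180
  ph <- truth$vvc_azimuth_deg * pi / 180
  dvec <- c(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
  for (zq in z_base + c(1, 2) / 3 * c_mm) {
    if (dvec[3] < 1e-9) stop("vortex-tube axis may not be perpendicular to the long axis")
    s <- (zq - centre[3]) / dvec[3]
    p <- centre + s * dvec
    r_loc <- a_mm * sqrt(max(0, 1 - ((zq - z_base) / c_mm)^2))
    if (sqrt(p[1]^2 + p[2]^2) >= r_loc) {
      stop("vortex-tube axis exits the blood pool before spanning the basal-to-apical thirds")
    }
  }

  # (b) Lamb-Oseen tube about the tilted axis (phase-constant)
  rx <- g$x - centre[1]; ry <- g$y - centre[2]; rz <- g$z - centre[3]
  ax <- rx * dvec[1] + ry * dvec[2] + rz * dvec[3]
  px <- rx - ax * dvec[1]; py <- ry - ax * dvec[2]; pz <- rz - ax * dvec[3]
  rperp <- sqrt(px^2 + py^2 + pz^2)
  # swirl direction = d x (perp / |perp|)
  sx <- dvec[2] * pz - dvec[3] * py
  sy <- dvec[3] * px - dvec[1] * pz
  sz <- dvec[1] * py - dvec[2] * px
  sn <- pmax(rperp, 1e-9)
  vth <- lamb_oseen_speed(rperp, truth$circulation_m2_s, truth$core_radius_mm)
  tube_x <- vth * sx / sn; tube_y <- vth * sy / sn; tube_z <- vth * sz / sn

  # (c) thin-core ring at the basal plane (MV vortex ring analogue)
  z_ring <- z_base + 0.25 * c_mm
  r_ring_loc <- a_mm * sqrt(max(0, 1 - ((z_ring - z_base) / c_mm)^2))
  ring_R <- 0.62 * r_ring_loc
  ring_rc <- 3
  ring_gamma <- -0.008   # sign: ring pumps fluid base-to-apex through its centre
  phi <- atan2(g$y, g$x)
  qx <- ring_R * cos(phi); qy <- ring_R * sin(phi)
  dx <- g$x - qx; dy <- g$y - qy; dz <- g$z - z_ring
  rho <- sqrt(dx^2 + dy^2 + dz^2)
  # swirl about the ring tangent t = (-sin phi, cos phi, 0)
  tx <- -sin(phi); ty <- cos(phi)
  # u = t x (d / |d|)
  un <- pmax(rho, 1e-9)
  ux <- ty * dz / un
  uy <- -tx * dz / un
  uz <- (tx * dy - ty * dx) / un
  vring <- lamb_oseen_speed(rho, ring_gamma, ring_rc)
  ring_x <- vring * ux; ring_y <- vring * uy; ring_z <- vring * uz

  # (a) transmitral jet: uniform axial velocity in a basal cylinder
  r_jet <- 8
  jet_zone <- mask3 & (g$x^2 + g$y^2 <= r_jet^2) &
    (g$z <= z_base + 0.35 * c_mm)
  wave <- phantom_waveform(config$n_phases, truth$ea_ratio_true)
  wp <- phantom_wave_phases(config$n_phases)
  # all diastolic flow structures wax and wane with the filling waveform, so
  # the net flux through any basal section stays proportional to it and the
  # E/A ratio of the flow-rate curve equals the prescribed ratio
  envelope <- wave / wave[wp$e_phase]

  nt <- config$n_phases
  vals <- array(0, c(d, 3L, nt))
  base_x <- (tube_x + ring_x) * mask3
  base_y <- (tube_y + ring_y) * mask3
  base_z <- (tube_z + ring_z) * mask3
  withr::with_seed(config$seed, {
    for (t in seq_len(nt)) {
      jz <- array(0, d)
      jz[jet_zone] <- wave[t]
      n_in <- sum(mask3)
      nx_ <- ny_ <- nz_ <- array(0, d)
      nx_[mask3] <- rnorm(n_in, 0, config$noise_sd_cm_s)
      ny_[mask3] <- rnorm(n_in, 0, config$noise_sd_cm_s)
      nz_[mask3] <- rnorm(n_in, 0, config$noise_sd_cm_s)
      vals[, , , 1, t] <- base_x * envelope[t] + nx_
      vals[, , , 2, t] <- base_y * envelope[t] + ny_
      vals[, , , 3, t] <- (base_z * envelope[t] + jz * mask3) + nz_
    }
  })
  if (max(abs(vals)) > config$venc_cm_s) {
    stop("phantom velocities exceed the VENC limit; reduce amplitudes")
  }

  mag <- array(5, c(d, nt))
  for (t in seq_len(nt)) mag[, , , t][mask3] <- 100

  field <- velocity_field(vals, h, config$venc_cm_s)
  if (wrap_venc) field <- simulate_venc_wrap(field)

  structure(list(
    field = field,
    magnitude = magnitude_image(mag, h),
    mask = blood_pool_mask(array(rep(mask3, nt), c(d, nt)), h),
    truth = truth, config = config,
    geometry = list(centre = centre, semi_axis_short_mm = a_mm,
                    semi_axis_long_mm = c_mm, z_base_mm = z_base,
                    z_ring_mm = z_ring, ring_radius_mm = ring_R,
                    jet_radius_mm = r_jet, waveform_cm_s = wave)
  ), class = "lv_phantom")
}

#' Simulate velocity aliasing at the VENC limit
#'
#' Maps every velocity component to `((v + VENC) mod 2 VENC) - VENC`,
#' reproducing the phase-wrap a scanner records when true velocity exceeds
#' the encoding limit. Used to exercise the anti-aliasing correction.
#'
#' @param field A [velocity_field].
#' @return A [velocity_field] with wrapped values.
#' @export
simulate_venc_wrap <- function(field) {
  v <- field$venc_cm_s
  field$values <- ((field$values + v) %% (2 * v)) - v
  field
}

#' Synthetic linear-trend time series
#'
#' Generates `y_i = intercept + slope_true * t_i + e_i` with iid Gaussian
#' noise, as a parameter-recovery fixture for the trend estimators.
#'
#' @param slope_true True per-week rate.
#' @param intercept Intercept at week 0.
#' @param times_weeks Numeric grid of at least 3 distinct times (weeks).
#' @param sigma Noise SD (>= 0).
#' @param seed Integer RNG seed.
#' @return A tibble with columns `time_weeks`, `value`, and attribute
#'   `truth` holding the generating parameters.
#' @export
make_trend_series <- function(slope_true, intercept, times_weeks, sigma,
                              seed = 1L) {
  if (length(unique(times_weeks)) < 3L) {
    stop("times_weeks must contain at least 3 distinct times")
  }
  if (sigma < 0) stop("sigma must be non-negative")
  y <- withr::with_seed(seed, {
    intercept + slope_true * times_weeks + rnorm(length(times_weeks), 0, sigma)
  })
  out <- tibble::tibble(time_weeks = as.numeric(times_weeks), value = y)
  attr(out, "truth") <- list(slope_true = slope_true, intercept = intercept,
                             sigma = sigma, seed = seed)
  out
}
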
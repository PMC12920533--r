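#' Time-resolved three-component velocity field
#'
#' The central container of the flow pipeline: one velocity vector (cm/s) per
#' voxel per cardiac phase on a regular isotropic grid, together with the
#' acquisition metadata needed downstream (voxel spacing and the
#' velocity-encoding limit VENC beyond which measured velocities alias).
#'
#' @param values Numeric array of dimension `c(nx, ny, nz, 3, n_phases)`;
#'   component order is (x, y, z), units cm/s.
#' @param spacing_mm Isotropic voxel edge length in mm.
#' @param venc_cm_s Velocity-encoding limit in cm/s (must be positive).
#' @param phase_labels Integer 1-based phase indices; defaults to
#'   `1:n_phases`.
#'
#' @return An object of class `velocity_field`.
#' @export
velocity_field <- function(values, spacing_mm, venc_cm_s,
                           phase_labels = NULL) {
  stopifnot(is.array(values), length(dim(values)) == 5L, dim(values)[4] == 3L)
  stopifnot(is.numeric(spacing_mm), spacing_mm > 0)
  stopifnot(is.numeric(venc_cm_s), venc_cm_s > 0)
  nt <- dim(values)[5]
  if (is.null(phase_labels)) phase_labels <- seq_len(nt)
  phase_labels <- as.integer(phase_labels)
  if (length(phase_labels) != nt || any(diff(phase_labels) <= 0) ||
      phase_labels[1] < 1L) {
    stop("phase_labels must be strictly increasing 1-based indices, one per phase")
  }
  structure(
    list(values = values, spacing_mm = spacing_mm, venc_cm_s = venc_cm_s,
         phase_labels = phase_labels),
    class = "velocity_field"
  )
}

#' @export
print.velocity_field <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "<velocity_field> %dx%dx%d voxels, %d phases, %.2f mm spacing, VENC %g cm/s\n",
    d[1], d[2], d[3], d[5], x$spacing_mm, x$venc_cm_s))
  invisible(x)
}

#' Magnitude image accompanying a velocity field
#'
#' Scalar MR signal per voxel per phase (arbitrary units, non-negative), on
#' the same grid as the velocity data. Used for noise masking, static-tissue
#' detection and PC-MRA generation.
#'
#' @param values Numeric array `c(nx, ny, nz, n_phases)`, non-negative.
#' @param spacing_mm Isotropic voxel edge in mm.
#' @return An object of class `magnitude_image`.
#' @export
magnitude_image <- function(values, spacing_mm) {
  stopifnot(is.array(values), length(dim(values)) == 4L)
  if (any(values < 0, na.rm = TRUE)) stop("magnitude values must be non-negative")
  structure(list(values = values, spacing_mm = spacing_mm),
            class = "magnitude_image")
}

#' Per-phase binary left-ventricular blood-pool mask
#'
#' @param values Logical array `c(nx, ny, nz, n_phases)`; `TRUE` marks cavity
#'   (fluid-domain) voxels.
#' @param spacing_mm Isotropic voxel edge in mm.
#' @param phase_labels Integer phase indices, defaults to `1:n_phases`.
#' @return An object of class `blood_pool_mask`.
#' @export
blood_pool_mask <- function(values, spacing_mm, phase_labels = NULL) {
  stopifnot(is.array(values), length(dim(values)) == 4L)
  storage.mode(values) <- "logical"
  nt <- dim(values)[4]
  if (is.null(phase_labels)) phase_labels <- seq_len(nt)
  structure(list(values = values, spacing_mm = spacing_mm,
                 phase_labels = as.integer(phase_labels)),
            class = "blood_pool_mask")
}

# 3-D mask slice at one phase; accepts a blood_pool_mask, a 4-D or a 3-D
# logical array, or NULL (whole grid of shape `shape`).
mask_at_phase <- function(mask, phase = 1L, shape = NULL) {
  if (is.null(mask)) {
    stopifnot(!is.null(shape))
    return(array(TRUE, shape))
  }
  if (inherits(mask, "blood_pool_mask")) mask <- mask$values
  if (length(dim(mask)) == 4L) {
    m <- mask[, , , phase]
    dim(m) <- dim(mask)[1:3]
    return(m)
  }
  mask
}

#' Line in space (vortex or anatomical axis)
#'
#' @param anchor Numeric length-3 point on the line (mm).
#' @param direction Numeric length-3 direction; normalised internally.
#' @param extent Optional parameter range (mm) along the direction.
#' @return An object of class `centerline`.
#' @export
centerline <- function(anchor, direction, extent = NULL) {
  stopifnot(length(anchor) == 3L, length(direction) == 3L)
  nrm <- sqrt(sum(direction^2))
  if (nrm < 1e-12) stop("direction must be non-zero")
  structure(list(anchor = as.numeric(anchor),
                 direction = as.numeric(direction) / nrm,
                 extent = extent),
            class = "centerline")
}

#' @export
print.centerline <- function(x, ...) {
  cat(sprintf("<centerline> anchor (%.1f, %.1f, %.1f) mm, direction (%.3f, %.3f, %.3f)\n",
              x$anchor[1], x$anchor[2], x$anchor[3],
              x$direction[1], x$direction[2], x$direction[3]))
  invisible(x)
}

#' Write phantom or derived volumes to NIfTI
#'
#' Writes one 4-D NIfTI file per velocity component plus magnitude and mask
#' volumes, with the voxel spacing recorded in the header, and a JSON
#' manifest holding the generator configuration and ground truth. This is the
#' on-disk interchange format; the analysis functions operate on the
#' in-memory containers.
#'
#' @param phantom A phantom dataset as returned by [make_lv_phantom()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_flow_nifti <- function(phantom, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sp <- phantom$field$spacing_mm
  comp <- c("vx", "vy", "vz")
  paths <- character(0)
  for (i in 1:3) {
    v <- phantom$field$values[, , , i, , drop = TRUE]
    p <- file.path(dir, paste0(comp[i], ".nii"))
    RNifti::writeNifti(RNifti::asNifti(v, pixdim = c(sp, sp, sp, 1)), p)
    paths[comp[i]] <- p
  }
  p <- file.path(dir, "magnitude.nii")
  RNifti::writeNifti(RNifti::asNifti(phantom$magnitude$values,
                                     pixdim = c(sp, sp, sp, 1)), p)
  paths["magnitude"] <- p
  p <- file.path(dir, "mask.nii")
  RNifti::writeNifti(RNifti::asNifti(phantom$mask$values * 1L,
                                     pixdim = c(sp, sp, sp, 1)), p)
  paths["mask"] <- p
  manifest <- list(config = unclass(phantom$config),
                   truth = unclass(phantom$truth),
                   venc_cm_s = phantom$field$venc_cm_s)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  paths["manifest"] <- file.path(dir, "manifest.json")
  invisible(paths)
}

#' Read a phantom dataset written by [write_flow_nifti()]
#'
#' @param dir Directory containing the NIfTI files and `manifest.json`.
#' @return A list with `field`, `magnitude`, `mask`, `config`, `truth`.
#' @export
read_flow_nifti <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  comp <- lapply(c("vx", "vy", "vz"), function(cn) {
    as.array(RNifti::readNifti(file.path(dir, paste0(cn, ".nii"))))
  })
  d <- dim(comp[[1]])
  vals <- array(0, c(d[1:3], 3L, d[4]))
  for (i in 1:3) vals[, , , i, ] <- comp[[i]]
  sp <- manifest$config$spacing_mm
  mag <- as.array(RNifti::readNifti(file.path(dir, "magnitude.nii")))
  msk <- as.array(RNifti::readNifti(file.path(dir, "mask.nii"))) > 0.5
  list(
    field = velocity_field(vals, sp, manifest$venc_cm_s),
    magnitude = magnitude_image(mag, sp),
    mask = blood_pool_mask(msk, sp),
    config = manifest$config,
    truth = manifest$truth
  )
}
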
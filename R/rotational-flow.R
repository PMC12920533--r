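# Voxel-wise vorticity and Lambda2, vortex-component extraction and
# classification (mitral-valve ring vs vertical vortex core), VVC centerline
# fitting, and the angle/orientation of the VVC relative to the anatomical
# centerline.

# The nine partial derivatives dv_i/dx_j (1/s) at one phase. Velocities are
# cm/s and spacing is mm, so each difference quotient is scaled by 10.
velocity_gradient <- function(field, m3, phase) {
  d <- dim(field$values)[1:3]
  h <- field$spacing_mm
  J <- vector("list", 9L)
  dim(J) <- c(3L, 3L)
  for (ic in 1:3) {
    v <- field$values[, , , ic, phase]
    dim(v) <- d
    for (ax in 1:3) {
      J[[ic, ax]] <- masked_partial(v, m3, ax, h) * 10
    }
  }
  J
}

#' Voxel-wise vorticity (curl of the velocity field)
#'
#' Computes the curl by central differences on in-mask voxels (one-sided at
#' mask borders where only one neighbour exists), in 1/s. Voxels lacking a
#' valid neighbour pair along some required axis are excluded from
#' `valid_mask`.
#'
#' @param field A [velocity_field] (cm/s, mm spacing).
#' @param mask Optional [blood_pool_mask]; `NULL` treats the whole grid as
#'   valid.
#' @param phases Integer phases to process (default all).
#' @return A list of class `vorticity_field`: `vector` (array
#'   `c(nx,ny,nz,3,length(phases))`, 1/s), `magnitude`
#'   (`c(nx,ny,nz,length(phases))`), `valid_mask` (logical, same shape as
#'   magnitude), `phases`.
#' @export
compute_vorticity <- function(field, mask = NULL, phases = NULL) {
  d <- dim(field$values)[1:3]
  if (is.null(phases)) phases <- seq_len(dim(field$values)[5])
  nt <- length(phases)
  vec <- array(NA_real_, c(d, 3L, nt))
  mag <- array(NA_real_, c(d, nt))
  valid <- array(FALSE, c(d, nt))
  for (it in seq_len(nt)) {
    t <- phases[it]
    m3 <- mask_at_phase(mask, t, shape = d)
    J <- velocity_gradient(field, m3, t)
    wx <- J[[3, 2]] - J[[2, 3]]   # dvz/dy - dvy/dz
    wy <- J[[1, 3]] - J[[3, 1]]   # dvx/dz - dvz/dx
    wz <- J[[2, 1]] - J[[1, 2]]   # dvy/dx - dvx/dy
    ok <- !is.na(wx) & !is.na(wy) & !is.na(wz)
    vec[, , , 1, it] <- wx; vec[, , , 2, it] <- wy; vec[, , , 3, it] <- wz
    mg <- sqrt(wx^2 + wy^2 + wz^2)
    mg[!ok] <- NA_real_
    mag[, , , it] <- mg
    valid[, , , it][ok] <- TRUE
  }
  structure(list(vector = vec, magnitude = mag, valid_mask = valid,
                 phases = as.integer(phases), spacing_mm = field$spacing_mm),
            class = "vorticity_field")
}

# Middle eigenvalue of a field of symmetric 3x3 matrices, vectorised
# closed-form (trigonometric) solution. Entries are arrays of identical
# shape. Exact for diagonal and zero matrices, which covers the analytic
# solid-body and pure-shear oracles.
sym3_middle_eigenvalue <- function(a11, a22, a33, a12, a13, a23) {
  q <- (a11 + a22 + a33) / 3
  p2 <- (a11 - q)^2 + (a22 - q)^2 + (a33 - q)^2 +
    2 * (a12^2 + a13^2 + a23^2)
  p <- sqrt(pmax(p2, 0) / 6)
  b11 <- a11 - q; b22 <- a22 - q; b33 <- a33 - q
  detB <- b11 * (b22 * b33 - a23^2) -
    a12 * (a12 * b33 - a23 * a13) +
    a13 * (a12 * a23 - b22 * a13)
  degenerate <- !is.na(p) & p < 1e-300
  p_safe <- ifelse(degenerate, 1, p)
  r <- detB / (2 * p_safe^3)
  r <- pmin(pmax(r, -1), 1)
  phi <- acos(r) / 3
  e1 <- q + 2 * p * cos(phi)
  e3 <- q + 2 * p * cos(phi + 2 * pi / 3)
  e2 <- 3 * q - e1 - e3
  e2[degenerate] <- q[degenerate]
  e2
}

#' Voxel-wise Lambda2 vortex criterion
#'
#' For each voxel, builds the velocity-gradient tensor J (same difference
#' stencils as [compute_vorticity()]), splits it into the strain tensor
#' `S = (J + J')/2` and the spin tensor `Omega = (J - J')/2`, and returns
#' the middle eigenvalue (ascending order) of the symmetric matrix
#' `S^2 + Omega^2`, in 1/s^2. Negative Lambda2 marks vortex cores while
#' irrotational shear yields exactly zero.
#'
#' @inheritParams compute_vorticity
#' @return A list of class `lambda2_field`: `lambda2` (array
#'   `c(nx,ny,nz,length(phases))`), `valid_mask`, `phases`, `spacing_mm`.
#' @export
compute_lambda2 <- function(field, mask = NULL, phases = NULL) {
  d <- dim(field$values)[1:3]
  if (is.null(phases)) phases <- seq_len(dim(field$values)[5])
  nt <- length(phases)
  l2 <- array(NA_real_, c(d, nt))
  valid <- array(FALSE, c(d, nt))
  for (it in seq_len(nt)) {
    t <- phases[it]
    m3 <- mask_at_phase(mask, t, shape = d)
    J <- velocity_gradient(field, m3, t)
    ok <- Reduce(`&`, lapply(J, function(a) !is.na(a)))
    for (k in 1:9) J[[k]][!ok] <- 0
    S <- O <- vector("list", 9L); dim(S) <- dim(O) <- c(3L, 3L)
    for (i in 1:3) for (j in 1:3) {
      S[[i, j]] <- (J[[i, j]] + J[[j, i]]) / 2
      O[[i, j]] <- (J[[i, j]] - J[[j, i]]) / 2
    }
    # A = S^2 + Omega^2 (symmetric); A_ij = sum_k S_ik S_kj + O_ik O_kj
    Aent <- function(i, j) {
      out <- 0
      for (k in 1:3) out <- out + S[[i, k]] * S[[k, j]] + O[[i, k]] * O[[k, j]]
      out
    }
    lam <- sym3_middle_eigenvalue(Aent(1, 1), Aent(2, 2), Aent(3, 3),
                                  Aent(1, 2), Aent(1, 3), Aent(2, 3))
    lam[!ok] <- NA_real_
    l2[, , , it] <- lam
    valid[, , , it][ok] <- TRUE
  }
  structure(list(lambda2 = l2, valid_mask = valid,
                 phases = as.integer(phases), spacing_mm = field$spacing_mm),
            class = "lambda2_field")
}

#' Regional vorticity averages
#'
#' Arithmetic mean of vorticity magnitude per (plane level, region class)
#' over the diastolic phase window. The blood pool is divided into basal,
#' mid and apical level slabs by [segment_blood_pool()]; each of the 16
#' segments carries a class (infarct/adjacent/remote) and voxels are pooled
#' by class within each level slab.
#'
#' @param vort A `vorticity_field` from [compute_vorticity()].
#' @param regions A `region_map` from [segment_blood_pool()].
#' @param region_class Character vector of length 16 mapping segment to
#'   class (e.g. from [classify_segment_regions()]). Defaults to all
#'   `"remote"`.
#' @param phase_window Inclusive 1-based phase-label range to average over;
#'   default `c(13, 25)` (early to end diastole at 25 phases).
#' @return A tibble with columns `plane`, `region`, `mean_vorticity`,
#'   `n_voxels`; region/plane combinations with no valid voxel are reported
#'   with `NA` mean.
#' @export
regional_vorticity <- function(vort, regions,
                               region_class = rep("remote", 16),
                               phase_window = c(13, 25)) {
  stopifnot(length(region_class) == 16L)
  in_window <- vort$phases >= phase_window[1] & vort$phases <= phase_window[2]
  if (!any(in_window)) stop("phase window contains no analyzed phases")
  lv_names <- c("basal", "mid", "apical")
  seg <- regions$segment_id
  lev <- regions$level
  cls_of_voxel <- array("", dim(seg))
  inpool <- seg > 0
  cls_of_voxel[inpool] <- region_class[seg[inpool]]
  out <- list()
  for (lv in 1:3) for (cl in c("infarct", "adjacent", "remote")) {
    sel3 <- inpool & lev == lv & cls_of_voxel == cl
    if (!any(sel3)) {
      if (cl %in% region_class[
        regions$segment_table$level == lv_names[lv]]) {
        out[[length(out) + 1L]] <- tibble::tibble(
          plane = lv_names[lv], region = cl,
          mean_vorticity = NA_real_, n_voxels = 0L)
      }
      next
    }
    vals <- c()
    n_valid <- 0L
    for (it in which(in_window)) {
      mg <- vort$magnitude[, , , it]
      v <- mg[sel3]
      v <- v[!is.na(v)]
      vals <- c(vals, sum(v))
      n_valid <- n_valid + length(v)
    }
    out[[length(out) + 1L]] <- tibble::tibble(
      plane = lv_names[lv], region = cl,
      mean_vorticity = if (n_valid > 0) sum(vals) / n_valid else NA_real_,
      n_voxels = n_valid)
  }
  dplyr::bind_rows(out)
}

# 26-connectivity component labelling over a set of selected voxels, via
# igraph on the neighbour-pair graph.
label_components_26 <- function(sel3) {
  d <- dim(sel3)
  idx <- which(sel3)
  if (length(idx) == 0L) return(list(labels = integer(0), idx = idx))
  pos <- arrayInd(idx, d)
  key <- (pos[, 3] - 1) * d[1] * d[2] + (pos[, 2] - 1) * d[1] + pos[, 1]
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0 & (offs[, 1] > 0 |
           (offs[, 1] == 0 & offs[, 2] > 0) |
           (offs[, 1] == 0 & offs[, 2] == 0 & offs[, 3] > 0)), , drop = FALSE]
  edges <- list()
  for (r in seq_len(nrow(offs))) {
    np <- cbind(pos[, 1] + offs[r, 1], pos[, 2] + offs[r, 2],
                pos[, 3] + offs[r, 3])
    inb <- np[, 1] >= 1 & np[, 1] <= d[1] & np[, 2] >= 1 & np[, 2] <= d[2] &
      np[, 3] >= 1 & np[, 3] <= d[3]
    nkey <- (np[, 3] - 1) * d[1] * d[2] + (np[, 2] - 1) * d[1] + np[, 1]
    m <- match(nkey, key)
    pair <- which(inb & !is.na(m))
    if (length(pair)) edges[[length(edges) + 1L]] <- cbind(pair, m[pair])
  }
  n <- length(idx)
  if (length(edges) == 0L) {
    comp <- seq_len(n)
  } else {
    ed <- do.call(rbind, edges)
    gr <- igraph::graph_from_edgelist(ed, directed = FALSE)
    gr <- igraph::add_vertices(gr, max(0L, n - igraph::vcount(gr)))
    comp <- igraph::components(gr)$membership[seq_len(n)]
  }
  list(labels = as.integer(comp), idx = idx, pos = pos)
}

#' Extract vortex components from a Lambda2 field
#'
#' Thresholds the Lambda2 field at a fraction of its most negative in-mask
#' value at the chosen phase, labels the sub-threshold voxels by
#' 26-connectivity, discards components smaller than `min_voxels`, and
#' returns them sorted by size (largest first). Each component carries its
#' voxel positions, Lambda2 values, centroid (mm), principal axis (leading
#' eigenvector of the voxel-coordinate covariance) and long-axis span.
#'
#' @param l2 A `lambda2_field` from [compute_lambda2()].
#' @param phase Phase label to analyse (must be among `l2$phases`).
#' @param threshold_frac Fraction in (0, 1\] of the most negative Lambda2
#'   used as threshold; default 0.1.
#' @param min_voxels Minimum component size in voxels; default 20.
#' @return A list of `vortex_component` objects (possibly empty).
#' @export
extract_vortex_components <- function(l2, phase = NULL, threshold_frac = 0.1,
                                      min_voxels = 20L) {
  if (threshold_frac <= 0 || threshold_frac > 1) {
    stop("threshold_frac must lie in (0, 1]")
  }
  it <- if (is.null(phase)) 1L else match(phase, l2$phases)
  if (is.na(it)) stop("requested phase was not analysed in the lambda2 field")
  lam <- l2$lambda2[, , , it]
  dim(lam) <- dim(l2$lambda2)[1:3]
  lmin <- suppressWarnings(min(lam, na.rm = TRUE))
  if (!is.finite(lmin) || lmin >= 0) return(list())
  tau <- threshold_frac * lmin
  sel <- !is.na(lam) & lam < tau
  if (!any(sel)) return(list())
  lab <- label_components_26(sel)
  d <- dim(sel)
  h <- l2$spacing_mm
  comps <- list()
  for (cid in unique(lab$labels)) {
    rows <- lab$labels == cid
    if (sum(rows) < min_voxels) next
    pos <- lab$pos[rows, , drop = FALSE]
    lamv <- lam[lab$idx[rows]]
    mm <- cbind((pos[, 1] - (d[1] + 1) / 2) * h,
                (pos[, 2] - (d[2] + 1) / 2) * h,
                z_slice_mm(pos[, 3], h))
    ctr <- colMeans(mm)
    cv <- stats::cov(mm)
    ev <- eigen(cv, symmetric = TRUE)
    pax <- ev$vectors[, 1]
    if (pax[3] < 0) pax <- -pax
    comps[[length(comps) + 1L]] <- structure(list(
      voxels = pos, coords_mm = mm, lambda2 = lamv, size = nrow(pos),
      centroid_mm = ctr, principal_axis = pax,
      z_range_mm = range(mm[, 3]), type = "OTHER",
      phase = l2$phases[it], spacing_mm = h), class = "vortex_component")
  }
  comps[order(vapply(comps, function(cc) -cc$size, numeric(1)))]
}

#' Classify vortex components as MV ring, VVC or other
#'
#' The vertical vortex core (VVC) is the largest component whose principal
#' axis makes less than `vvc_max_angle_deg` with the anatomical direction
#' and whose voxels cross the mid-plane. The mitral-valve vortex ring is a
#' component whose centroid lies within `ring_max_dist_slices` slice
#' thicknesses of the basal plane and whose principal axis is at least 45
#' degrees off the long axis (a torus's leading axis lies in-plane).
#'
#' @param components List from [extract_vortex_components()].
#' @param anatomical The anatomical [centerline].
#' @param basal,mid Plane specifications from [define_analysis_planes()].
#' @param vvc_max_angle_deg Maximum principal-axis angle to the anatomical
#'   direction for VVC (default 45).
#' @param ring_max_dist_slices Maximum centroid distance to the basal plane
#'   in slice thicknesses for the ring (default 1.5).
#' @return The component list with `type` set; attribute `vvc_present`
#'   indicates whether a VVC was found.
#' @export
classify_vortex_components <- function(components, anatomical, basal, mid,
                                       vvc_max_angle_deg = 45,
                                       ring_max_dist_slices = 1.5) {
  if (length(components) == 0L) {
    attr(components, "vvc_present") <- FALSE
    return(components)
  }
  dv <- anatomical$direction
  h <- components[[1]]$spacing_mm
  z_mid <- mid$z_mm
  z_basal <- basal$z_mm
  vvc_idx <- NA_integer_
  for (i in seq_along(components)) {
    cc <- components[[i]]
    ang <- angle_between_deg(cc$principal_axis, dv)
    crosses_mid <- cc$z_range_mm[1] <= z_mid && cc$z_range_mm[2] >= z_mid
    if (is.na(vvc_idx) && ang < vvc_max_angle_deg && crosses_mid) {
      vvc_idx <- i
      components[[i]]$type <- "VVC"
      next
    }
    near_base <- abs(cc$centroid_mm[3] - z_basal) <= ring_max_dist_slices * h
    if (near_base && ang >= 45) {
      components[[i]]$type <- "MV_RING"
    } else {
      components[[i]]$type <- "OTHER"
    }
  }
  attr(components, "vvc_present") <- !is.na(vvc_idx)
  components
}

angle_between_deg <- function(a, b) {
  ca <- abs(sum(a * b)) / (sqrt(sum(a^2)) * sqrt(sum(b^2)))
  acos(pmin(pmax(ca, 0), 1)) * 180 / pi
}

#' Fit the VVC centerline
#'
#' Computes per-slice |Lambda2|-weighted centroids of the component along
#' the long axis, then fits a total-least-squares (principal-component)
#' line through the centroids. The direction is oriented base to apex.
#'
#' @param vvc A `vortex_component` (needs at least 3 occupied z-slices).
#' @return A [centerline].
#' @export
fit_vvc_centerline <- function(vvc) {
  zs <- sort(unique(vvc$voxels[, 3]))
  if (length(zs) < 3L) stop("VVC component occupies fewer than 3 z-slices")
  w <- abs(vvc$lambda2)
  cents <- t(vapply(zs, function(k) {
    rows <- vvc$voxels[, 3] == k
    ww <- w[rows]
    if (sum(ww) <= 0) ww <- rep(1, sum(rows))
    c(sum(vvc$coords_mm[rows, 1] * ww) / sum(ww),
      sum(vvc$coords_mm[rows, 2] * ww) / sum(ww),
      vvc$coords_mm[rows, 3][1])
  }, numeric(3)))
  ctr <- colMeans(cents)
  sv <- svd(sweep(cents, 2, ctr))
  dirv <- sv$v[, 1]
  if (dirv[3] < 0) dirv <- -dirv
  centerline(anchor = ctr, direction = dirv,
             extent = range((cents %*% dirv) - sum(ctr * dirv)))
}

#' Angle and orientation of the VVC relative to the anatomical centerline
#'
#' The angle is `acos(|d_vvc . d_anat|)` in degrees. The orientation
#' azimuth locates the VVC's mid-plane crossing relative to the anatomical
#' centerline's mid-plane point, measured counterclockwise from a reference
#' azimuth. For radial plotting the angle (radians) is capped at pi/6.
#'
#' @param vvc_line The fitted VVC [centerline].
#' @param anatomical The anatomical [centerline].
#' @param mid Mid-plane specification from [define_analysis_planes()].
#' @param reference_azimuth_deg Reference azimuth (degrees CCW from +x),
#'   default 0.
#' @param phase_used Cardiac phase at which the VVC was assessed (recorded
#'   in the result).
#' @return A list of class `angle_result` with `angle_deg`,
#'   `orientation_azimuth_deg` (NA when the VVC line is parallel to the
#'   mid-plane), `crossing_offset_mm`, `radial_plot_radius` (radians, capped
#'   at pi/6) and `phase_used`.
#' @export
vvc_angle <- function(vvc_line, anatomical, mid, reference_azimuth_deg = 0,
                      phase_used = NA_integer_) {
  ang <- angle_between_deg(vvc_line$direction, anatomical$direction)
  cross_at_z <- function(line, z) {
    if (abs(line$direction[3]) < 1e-12) return(NULL)
    s <- (z - line$anchor[3]) / line$direction[3]
    line$anchor + s * line$direction
  }
  pv <- cross_at_z(vvc_line, mid$z_mm)
  pa <- cross_at_z(anatomical, mid$z_mm)
  if (is.null(pv) || is.null(pa)) {
    azim <- NA_real_
    off <- c(NA_real_, NA_real_)
  } else {
    off <- (pv - pa)[1:2]
    azim <- if (sqrt(sum(off^2)) < 1e-9) 0 else
      (atan2(off[2], off[1]) * 180 / pi - reference_azimuth_deg) %% 360
  }
  structure(list(angle_deg = ang,
                 orientation_azimuth_deg = azim,
                 crossing_offset_mm = off,
                 radial_plot_radius = min(ang * pi / 180, pi / 6),
                 phase_used = phase_used),
            class = "angle_result")
}

#' Select the cardiac phase for VVC assessment
#'
#' Uses the E-wave peak phase when a VVC of sufficient size exists there;
#' otherwise the earliest later diastolic phase with a qualifying VVC; if
#' none exists the VVC is reported absent.
#'
#' @param components_by_phase Named list mapping phase label (as character)
#'   to a classified component list from [classify_vortex_components()].
#' @param e_phase E-wave peak phase label.
#' @param min_voxels Minimum VVC size (default 20).
#' @return The selected phase label (integer), or `NA` when no VVC was
#'   found at any candidate phase.
#' @export
select_vvc_phase <- function(components_by_phase, e_phase, min_voxels = 20L) {
  has_vvc <- function(comps) {
    any(vapply(comps, function(cc) cc$type == "VVC" && cc$size >= min_voxels,
               logical(1)))
  }
  phases <- as.integer(names(components_by_phase))
  ord <- order(phases)
  for (i in ord) {
    if (phases[i] < e_phase) next
    if (has_vvc(components_by_phase[[i]])) return(phases[i])
  }
  NA_integer_
}
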
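# Analysis planes, centerlines, AHA-style segmentation of the blood pool,
# and the tissue metrics (LGE extent, ECV) derived from segmentation inputs.

#' Define basal, mid and apical analysis planes
#'
#' Places the three analysis planes at fixed fractions of the occupied
#' long-axis extent of the blood pool, rounded to the nearest slice. The
#' basal plane doubles as the transvalvular flow-rate plane.
#'
#' @param mask A [blood_pool_mask], or a 3-D logical array at the reference
#'   phase.
#' @param fractions Long-axis fractions for (basal, mid, apical); default
#'   `c(0.25, 0.50, 0.75)`.
#' @param phase Reference phase used when `mask` is 4-D (default 1).
#' @return A named list of three plane specifications (`basal`, `mid`,
#'   `apical`), each with `level`, `slice_index`, `z_mm` and unit `normal`
#'   (the long axis, base to apex).
#' @export
define_analysis_planes <- function(mask, fractions = c(0.25, 0.50, 0.75),
                                   phase = 1L) {
  spacing <- if (inherits(mask, "blood_pool_mask")) mask$spacing_mm else NA_real_
  m3 <- mask_at_phase(mask, phase)
  occ <- which(apply(m3, 3, any))
  if (length(occ) == 0L) stop("blood-pool mask is empty at the reference phase")
  z0 <- min(occ); z1 <- max(occ)
  n_slices <- z1 - z0 + 1L
  if (n_slices < 4L) stop("occupied long-axis extent is fewer than 4 slices")
  levels <- c("basal", "mid", "apical")
  planes <- lapply(seq_along(levels), function(i) {
    k <- z0 + as.integer(round(fractions[i] * n_slices))
    k <- min(max(k, z0), z1)
    list(level = levels[i], slice_index = k,
         z_mm = if (is.na(spacing)) NA_real_ else z_slice_mm(k, spacing),
         normal = c(0, 0, 1))
  })
  names(planes) <- levels
  if (!(planes$basal$slice_index < planes$mid$slice_index &&
        planes$mid$slice_index < planes$apical$slice_index)) {
    stop("plane ordering basal < mid < apical violated; check fractions")
  }
  planes
}

#' Anatomical centerline of the left ventricle
#'
#' The line joining the in-mask centroids of the basal and apical slices,
#' oriented base to apex. This geometric reference is insensitive to
#' mid-ventricular wall deformation.
#'
#' @param mask A [blood_pool_mask] (or 3-D logical array).
#' @param basal,apical Plane specifications from [define_analysis_planes()].
#' @param phase Cardiac phase at which to evaluate the mask (default 1).
#' @return A [centerline].
#' @export
anatomical_centerline <- function(mask, basal, apical, phase = 1L) {
  spacing <- if (inherits(mask, "blood_pool_mask")) mask$spacing_mm else 1
  m3 <- mask_at_phase(mask, phase)
  cent <- function(k, lvl) {
    sl <- m3[, , k]
    if (!any(sl)) stop(sprintf("blood-pool mask empty on the %s slice (z index %d)", lvl, k))
    idx <- which(sl, arr.ind = TRUE)
    nx <- dim(m3)[1]; ny <- dim(m3)[2]
    c((mean(idx[, 1]) - (nx + 1) / 2) * spacing,
      (mean(idx[, 2]) - (ny + 1) / 2) * spacing,
      z_slice_mm(k, spacing))
  }
  p_base <- cent(basal$slice_index, "basal")
  p_apex <- cent(apical$slice_index, "apical")
  centerline(anchor = p_base, direction = p_apex - p_base,
             extent = c(0, sqrt(sum((p_apex - p_base)^2))))
}

# Slab (level) index 1/2/3 for every z slice: occupied extent split into
# basal, mid, apical thirds.
level_slabs <- function(m3) {
  occ <- which(apply(m3, 3, any))
  z0 <- min(occ); z1 <- max(occ)
  n <- z1 - z0 + 1L
  cut1 <- z0 + ceiling(n / 3) - 1L
  cut2 <- z0 + ceiling(2 * n / 3) - 1L
  list(z0 = z0, z1 = z1, cut1 = cut1, cut2 = cut2)
}

#' AHA-style segmentation of the LV blood pool
#'
#' Divides the blood pool into 16 segments analogous to the AHA myocardial
#' scheme: the occupied long-axis extent is split into basal, mid and apical
#' thirds; the basal and mid thirds are divided into 6 azimuthal sectors
#' each and the apical third into 4, numbered counterclockwise from a
#' reference azimuth about each slab's in-mask centroid. Segments 1-6 are
#' basal, 7-12 mid, 13-16 apical.
#'
#' @param mask A [blood_pool_mask] (or 3-D logical array).
#' @param planes Planes from [define_analysis_planes()] (used for level
#'   bookkeeping; the slabs are thirds of the occupied extent).
#' @param reference_azimuth_deg Azimuth (degrees counterclockwise from +x)
#'   at which sector 1 of each ring starts; default 0.
#' @param phase Cardiac phase of the mask (default 1).
#' @return A list of class `region_map`: `segment_id` (3-D integer array, 0
#'   outside the pool), `level` (3-D integer array, 1 basal / 2 mid /
#'   3 apical), `n_segments = 16`, and `segment_table` (tibble of segment,
#'   level, sector).
#' @export
segment_blood_pool <- function(mask, planes = NULL, reference_azimuth_deg = 0,
                               phase = 1L) {
  spacing <- if (inherits(mask, "blood_pool_mask")) mask$spacing_mm else 1
  m3 <- mask_at_phase(mask, phase)
  d <- dim(m3)
  sl <- level_slabs(m3)
  zidx <- rep(seq_len(d[3]), each = d[1] * d[2])
  level <- array(0L, d)
  level[m3 & array(zidx <= sl$cut1, d)] <- 1L
  level[m3 & array(zidx > sl$cut1 & zidx <= sl$cut2, d)] <- 2L
  level[m3 & array(zidx > sl$cut2, d)] <- 3L

  g <- grid_coords(d, spacing)
  seg <- array(0L, d)
  n_sector <- c(6L, 6L, 4L)
  offset <- c(0L, 6L, 12L)
  for (lv in 1:3) {
    in_lv <- level == lv
    if (!any(in_lv)) next
    cx <- mean(g$x[in_lv]); cy <- mean(g$y[in_lv])
    az <- (atan2(g$y[in_lv] - cy, g$x[in_lv] - cx) * 180 / pi -
             reference_azimuth_deg) %% 360
    sector <- pmin(floor(az / (360 / n_sector[lv])) + 1L, n_sector[lv])
    seg[in_lv] <- offset[lv] + as.integer(sector)
  }
  seg_table <- tibble::tibble(
    segment = 1:16,
    level = c(rep("basal", 6), rep("mid", 6), rep("apical", 4)),
    sector = c(1:6, 1:6, 1:4)
  )
  structure(list(segment_id = seg, level = level, n_segments = 16L,
                 reference_azimuth_deg = reference_azimuth_deg,
                 segment_table = seg_table, spacing_mm = spacing),
            class = "region_map")
}

#' Late-gadolinium-enhancement extent
#'
#' Percentage of enhanced myocardial volume relative to total myocardial
#' volume.
#'
#' @param enhanced_mask Logical array of enhanced voxels (must be a subset
#'   of `myocardium_mask`).
#' @param myocardium_mask Logical array of myocardial voxels (non-empty).
#' @return Extent in percent.
#' @export
lge_extent <- function(enhanced_mask, myocardium_mask) {
  n_myo <- sum(myocardium_mask)
  if (n_myo == 0L) stop("myocardium mask is empty")
  if (any(enhanced_mask & !myocardium_mask)) {
    stop("enhanced mask must be a subset of the myocardium mask")
  }
  100 * sum(enhanced_mask) / n_myo
}

# Adjacency graph of the 16-segment scheme: cyclic within each ring; basal
# sector i touches mid sector i; mid and apical sectors touch where their
# azimuthal spans overlap or share an edge.
segment_adjacency <- function() {
  edges <- list()
  add <- function(a, b) edges[[length(edges) + 1L]] <<- c(a, b)
  for (i in 1:6) add(i, i %% 6 + 1)               # basal ring
  for (i in 1:6) add(6 + i, 6 + i %% 6 + 1)       # mid ring
  for (i in 1:4) add(12 + i, 12 + i %% 4 + 1)     # apical ring
  for (i in 1:6) add(i, 6 + i)                    # basal <-> mid, aligned
  for (i in 1:6) {                                 # mid <-> apical, overlap
    mid_span <- c((i - 1) * 60, i * 60)
    for (k in 1:4) {
      ap_span <- c((k - 1) * 90, k * 90)
      if (mid_span[1] <= ap_span[2] && ap_span[1] <= mid_span[2]) {
        add(6 + i, 12 + k)
      }
    }
  }
  do.call(rbind, edges)
}

#' Classify segments as infarct, adjacent or remote
#'
#' A segment is infarcted when its LGE extent strictly exceeds 25%;
#' segments sharing a sector border or level adjacency with an infarcted
#' segment are adjacent; all others are remote.
#'
#' @param lge_percent Numeric vector of 16 per-segment LGE extents in
#'   \[0, 100\].
#' @return Character vector of length 16 with values `"infarct"`,
#'   `"adjacent"` or `"remote"`.
#' @export
classify_segment_regions <- function(lge_percent) {
  stopifnot(length(lge_percent) == 16L,
            all(lge_percent >= 0 & lge_percent <= 100, na.rm = TRUE))
  infarct <- !is.na(lge_percent) & lge_percent > 25
  cls <- rep("remote", 16L)
  cls[infarct] <- "infarct"
  if (any(infarct)) {
    ed <- segment_adjacency()
    nb <- unique(c(ed[ed[, 1] %in% which(infarct), 2],
                   ed[ed[, 2] %in% which(infarct), 1]))
    cls[setdiff(nb, which(infarct))] <- "adjacent"
  }
  cls
}

#' Extracellular volume fraction from pre/post-contrast T1
#'
#' `ECV = 100 * (1 - Hct) * dR1_myo / dR1_blood` with
#' `dR1 = 1/T1_post - 1/T1_pre` for myocardium and blood respectively.
#' Invariant to expressing T1 in ms or s.
#'
#' @param t1_myo_pre,t1_myo_post Pre-/post-contrast myocardial T1 (> 0).
#' @param t1_blood_pre,t1_blood_post Pre-/post-contrast blood T1 (> 0).
#' @param hct Hematocrit fraction in (0, 1).
#' @return ECV in percent.
#' @export
compute_ecv <- function(t1_myo_pre, t1_myo_post, t1_blood_pre, t1_blood_post,
                        hct) {
  stopifnot(t1_myo_pre > 0, t1_myo_post > 0, t1_blood_pre > 0,
            t1_blood_post > 0, hct > 0, hct < 1)
  if (t1_myo_post > t1_myo_pre || t1_blood_post >= t1_blood_pre) {
    stop("post-contrast T1 must not exceed pre-contrast T1")
  }
  dr1_myo <- 1 / t1_myo_post - 1 / t1_myo_pre
  dr1_blood <- 1 / t1_blood_post - 1 / t1_blood_pre
  if (abs(dr1_blood) < .Machine$double.eps) {
    stop("blood delta-R1 is zero; ECV undefined")
  }
  100 * (1 - hct) * dr1_myo / dr1_blood
}
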
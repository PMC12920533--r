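# Transvalvular inflow: flow-rate curve at the basal plane and E/A metrics.

#' Flow-rate curve through an analysis plane
#'
#' Sums, over the in-mask voxels of the plane slice, the velocity component
#' along the plane normal times the voxel face area. With velocity in cm/s
#' and spacing in mm the result is in mL/s; positive flow is directed into
#' the ventricle (base to apex).
#'
#' @param field A [velocity_field].
#' @param mask A [blood_pool_mask] (per-phase) or 3-D logical array.
#' @param plane A plane specification from [define_analysis_planes()].
#' @return A tibble of class `flow_curve` with columns `phase` and `q`
#'   (mL/s; `NA` where the in-mask plane is empty), and attribute `plane`.
#' @export
flow_rate_curve <- function(field, mask, plane) {
  d <- dim(field$values)
  k <- plane$slice_index
  if (k < 1 || k > d[3]) stop("plane slice lies outside the grid")
  area_cm2 <- (field$spacing_mm / 10)^2
  nrm <- plane$normal
  q <- vapply(seq_len(d[5]), function(t) {
    m3 <- mask_at_phase(mask, t, shape = d[1:3])
    sl <- m3[, , k]
    if (!any(sl)) return(NA_real_)
    vn <- field$values[, , k, 1, t] * nrm[1] +
      field$values[, , k, 2, t] * nrm[2] +
      field$values[, , k, 3, t] * nrm[3]
    sum(vn[sl]) * area_cm2
  }, numeric(1))
  out <- tibble::tibble(phase = field$phase_labels, q = q)
  attr(out, "plane") <- plane
  class(out) <- c("flow_curve", class(out))
  out
}

#' E-wave, A-wave and E/A ratio from a flow-rate curve
#'
#' Splits the diastolic window into an early (E) and a late (A) part and
#' takes the peak flow rate in each. The split phase defaults to the
#' minimum of the curve strictly between the two largest local maxima in
#' the window; when fewer than two local maxima exist it falls back to a
#' fixed fraction of the cycle (phase 19 of 25).
#'
#' @param curve A `flow_curve` from [flow_rate_curve()].
#' @param window Inclusive diastolic phase-label range; default
#'   `c(13, 25)` scaled to the curve's phase count.
#' @param split Optional split phase; computed as described when `NULL`.
#' @return A list of class `ea_result` with `e_peak`, `a_peak` (mL/s),
#'   `ea_ratio`, `e_phase`, `a_phase`, `split_phase` and `flag`
#'   (`"ok"` or `"a_peak_nonpositive"`).
#' @export
detect_ea <- function(curve, window = NULL, split = NULL) {
  n <- max(curve$phase)
  if (is.null(window)) {
    window <- if (n == 25L) c(13L, 25L) else
      c(as.integer(round(0.52 * n)), as.integer(n))
  }
  in_win <- curve$phase >= window[1] & curve$phase <= window[2]
  if (!any(in_win)) stop("diastolic window contains no phases of the curve")
  ph <- curve$phase[in_win]
  qv <- curve$q[in_win]
  if (is.null(split)) {
    # local maxima within the window
    locmax <- which(diff(sign(diff(c(-Inf, qv, -Inf)))) == -2)
    if (length(locmax) >= 2L) {
      top2 <- sort(locmax[order(qv[locmax], decreasing = TRUE)][1:2])
      between <- (top2[1] + 1):(top2[2] - 1)
      split <- if (length(between) > 0) ph[between[which.min(qv[between])]] else
        ph[top2[1]]
    } else {
      split <- if (n == 25L) 19L else as.integer(round(0.76 * n))
    }
  }
  if (split <= window[1] || split >= window[2]) {
    split <- as.integer(round(mean(window)))
  }
  e_sel <- ph >= window[1] & ph <= split
  a_sel <- ph > split & ph <= window[2]
  e_peak <- max(qv[e_sel], na.rm = TRUE)
  a_peak <- max(qv[a_sel], na.rm = TRUE)
  flag <- "ok"
  ea <- if (is.finite(a_peak) && a_peak > 0) e_peak / a_peak else {
    flag <- "a_peak_nonpositive"
    NA_real_
  }
  structure(list(
    e_peak = e_peak, a_peak = a_peak, ea_ratio = ea,
    e_phase = ph[e_sel][which.max(qv[e_sel])],
    a_phase = ph[a_sel][which.max(qv[a_sel])],
    split_phase = as.integer(split), flag = flag
  ), class = "ea_result")
}
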
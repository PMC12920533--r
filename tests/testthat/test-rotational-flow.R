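test_that("vorticity matches a per-voxel finite-difference oracle", {
  cfg <- small_config()
  f <- random_smooth_field(cfg, seed = 7)
  vo <- compute_vorticity(f, phases = 1)
  set.seed(1)
  for (r in 1:20) {
    ijk <- sample(2:15, 3, replace = TRUE)
    expect_equal(vo$vector[ijk[1], ijk[2], ijk[3], , 1],
                 oracle_vorticity_at(f, ijk[1], ijk[2], ijk[3], 1),
                 tolerance = 1e-9)
  }
  expect_equal(vo$magnitude[, , , 1],
               sqrt(vo$vector[, , , 1, 1]^2 + vo$vector[, , , 2, 1]^2 +
                      vo$vector[, , , 3, 1]^2),
               tolerance = 1e-9)
})

test_that("lambda2 matches an independent eigen decomposition", {
  cfg <- small_config()
  f <- random_smooth_field(cfg, seed = 3)
  l2 <- compute_lambda2(f, phases = 1)
  set.seed(2)
  for (r in 1:20) {
    ijk <- sample(2:15, 3, replace = TRUE)
    want <- oracle_lambda2_at(f, ijk[1], ijk[2], ijk[3], 1)
    got <- l2$lambda2[ijk[1], ijk[2], ijk[3], 1]
    expect_equal(got, want, tolerance = 1e-7 * max(1, abs(want)))
  }
})

test_that("lambda2 is Galilean invariant", {
  cfg <- small_config(n = 12)
  f <- random_smooth_field(cfg, seed = 5)
  g <- f
  g$values[, , , 1, ] <- g$values[, , , 1, ] + 40
  g$values[, , , 3, ] <- g$values[, , , 3, ] - 25
  expect_equal(compute_lambda2(f, phases = 1)$lambda2,
               compute_lambda2(g, phases = 1)$lambda2, tolerance = 1e-12)
})

test_that("mask-aware stencils fall back to one-sided differences", {
  cfg <- small_config(n = 10, phases = 2)
  g <- helper_coords(cfg$grid_shape, cfg$spacing_mm)
  vals <- array(0, c(cfg$grid_shape, 3L, 1L))
  vals[, , , 1, 1] <- 2 * g$y / 10   # linear: one-sided == central == exact
  f <- velocity_field(vals, cfg$spacing_mm, 150)
  m <- array(FALSE, cfg$grid_shape)
  m[3:8, 3:8, 3:8] <- TRUE
  vo <- compute_vorticity(f, blood_pool_mask(array(m, c(dim(m), 1)), 2),
                          phases = 1)
  expect_equal(max(abs(vo$magnitude[, , , 1][m] - 2)), 0, tolerance = 1e-9)
  expect_true(all(is.na(vo$magnitude[, , , 1][!m])))
  expect_true(all(vo$valid_mask[, , , 1][m]))
})

test_that("component extraction matches a BFS flood-fill oracle", {
  # two separated solid-body blobs produce exactly two components
  cfg <- small_config(n = 24, phases = 2)
  g <- helper_coords(cfg$grid_shape, cfg$spacing_mm)
  blob <- function(cx, cy, cz, r) (g$x - cx)^2 + (g$y - cy)^2 + (g$z - cz)^2 < r^2
  b1 <- blob(-10, 0, 14, 8); b2 <- blob(12, 0, 34, 8)
  vals <- array(0, c(cfg$grid_shape, 3L, 1L))
  vx <- -1 * g$y / 10; vy <- 1 * g$x / 10      # omega = 1 about local axes
  vx2 <- -1.5 * (g$y - 0) / 10; vy2 <- 1.5 * (g$x - 12) / 10
  vals[, , , 1, 1] <- vx * b1 + vx2 * b2
  vals[, , , 2, 1] <- vy * b1 + vy2 * b2
  f <- velocity_field(vals, cfg$spacing_mm, 150)
  l2 <- compute_lambda2(f, phases = 1)
  comps <- extract_vortex_components(l2, phase = 1, threshold_frac = 0.1,
                                     min_voxels = 10)
  expect_length(comps, 2)
  expect_true(comps[[1]]$size >= comps[[2]]$size)
  # oracle: flood-fill the same thresholded voxel set
  lam <- l2$lambda2[, , , 1]
  tau <- 0.1 * min(lam, na.rm = TRUE)
  sel <- !is.na(lam) & lam < tau
  lab <- oracle_flood_fill_26(sel)
  sizes <- sort(as.integer(table(lab[lab > 0])), decreasing = TRUE)
  sizes <- sizes[sizes >= 10]
  expect_identical(vapply(comps, function(cc) cc$size, integer(1)), sizes)
  # the two component voxel sets coincide with the oracle labelling
  for (cc in comps) {
    ids <- lab[cbind(cc$voxels[, 1], cc$voxels[, 2], cc$voxels[, 3])]
    expect_equal(length(unique(ids)), 1L)
  }
})

test_that("phantom yields an MV-ring and a VVC component", {
  ph <- make_lv_phantom(phantom_config(seed = 6),
                        phantom_truth(vvc_polar_deg = 20,
                                      vvc_azimuth_deg = 90))
  pl <- define_analysis_planes(ph$mask)
  anat <- anatomical_centerline(ph$mask, pl$basal, pl$apical)
  wp <- lvflow:::phantom_wave_phases(25)
  l2 <- compute_lambda2(ph$field, ph$mask, phases = wp$e_phase)
  comps <- extract_vortex_components(l2, phase = wp$e_phase,
                                     threshold_frac = 0.1, min_voxels = 20)
  expect_gte(length(comps), 2)
  comps <- classify_vortex_components(comps, anat, pl$basal, pl$mid)
  types <- vapply(comps, function(cc) cc$type, character(1))
  expect_true("VVC" %in% types)
  expect_true("MV_RING" %in% types)
  expect_true(attr(comps, "vvc_present"))
})

test_that("VVC centerline fitting recovers exact and perturbed lines", {
  # voxels exactly on a 20-degree line
  t <- seq(-20, 20, by = 2)
  dirv <- c(sin(20 * pi / 180), 0, cos(20 * pi / 180))
  pts <- t(vapply(t, function(s) c(24, 24, 40) + s * dirv, numeric(3)))
  vox <- round(cbind(pts[, 1] / 2 + 12.25, pts[, 2] / 2 + 12.25,
                     pts[, 3] / 2 + 0.5))
  comp <- structure(list(
    voxels = vox,
    coords_mm = cbind((vox[, 1] - 12.25) * 2, (vox[, 2] - 12.25) * 2,
                      (vox[, 3] - 0.5) * 2),
    lambda2 = rep(-1, nrow(vox)), size = nrow(vox),
    spacing_mm = 2), class = "vortex_component")
  # use the exact continuous coordinates to avoid voxelisation error here
  comp$coords_mm <- pts
  comp$voxels[, 3] <- seq_len(nrow(pts))   # distinct slices
  line <- fit_vvc_centerline(comp)
  expect_lt(acos(min(1, abs(sum(line$direction * dirv)))) * 180 / pi, 0.5)
  # symmetric perturbation about the line leaves the direction unchanged
  n_perp <- c(cos(20 * pi / 180), 0, -sin(20 * pi / 180))
  comp2 <- comp
  comp2$coords_mm <- rbind(pts + rep(n_perp, each = nrow(pts)) * 1.5,
                           pts - rep(n_perp, each = nrow(pts)) * 1.5)
  comp2$voxels <- rbind(comp$voxels, comp$voxels)
  comp2$lambda2 <- rep(-1, nrow(comp2$coords_mm))
  line2 <- fit_vvc_centerline(comp2)
  expect_lt(acos(min(1, abs(sum(line2$direction * dirv)))) * 180 / pi, 1)
  expect_error(fit_vvc_centerline(structure(list(
    voxels = vox[1:2, , drop = FALSE], coords_mm = pts[1:2, , drop = FALSE],
    lambda2 = c(-1, -1), spacing_mm = 2), class = "vortex_component")),
    "fewer than 3")
})

test_that("angle between centerlines follows the closed form", {
  anat <- centerline(c(0, 0, 0), c(0, 0, 1))
  mid <- list(level = "mid", slice_index = 10L, z_mm = 20, normal = c(0, 0, 1))
  same <- vvc_angle(centerline(c(0, 0, 5), c(0, 0, 1)), anat, mid)
  expect_equal(same$angle_deg, 0)
  expect_equal(sum(abs(same$crossing_offset_mm)), 0)
  orth <- vvc_angle(centerline(c(0, 0, 20), c(1, 0, 0)), anat, mid)
  expect_equal(orth$angle_deg, 90)
  expect_true(is.na(orth$orientation_azimuth_deg))
  tilt <- vvc_angle(centerline(c(0, 0, 20),
                               c(sin(20 * pi / 180), 0, cos(20 * pi / 180))),
                    anat, mid)
  expect_equal(tilt$angle_deg, 20, tolerance = 1e-9)
  expect_equal(tilt$orientation_azimuth_deg, 0)
  expect_equal(tilt$radial_plot_radius, 20 * pi / 180)
  # radial-plot radius caps at pi/6 (30 degrees)
  steep <- vvc_angle(centerline(c(0, 0, 20),
                                c(sin(40 * pi / 180), 0, cos(40 * pi / 180))),
                     anat, mid)
  expect_equal(steep$radial_plot_radius, pi / 6)
})

test_that("VVC phase selection prefers the E-wave and falls back later", {
  mk <- function(type, size = 50) {
    structure(list(type = type, size = size), class = "vortex_component")
  }
  by_phase <- list(`15` = list(mk("MV_RING")), `16` = list(),
                   `18` = list(mk("VVC")), `20` = list(mk("VVC")))
  expect_identical(select_vvc_phase(by_phase, e_phase = 15), 18L)
  by_phase2 <- list(`15` = list(mk("VVC")), `18` = list(mk("VVC")))
  expect_identical(select_vvc_phase(by_phase2, e_phase = 15), 15L)
  by_phase3 <- list(`15` = list(mk("VVC", size = 5)), `18` = list())
  expect_true(is.na(select_vvc_phase(by_phase3, e_phase = 15)))
})

test_that("regional vorticity averages match hand enumeration", {
  # two-segment toy: constant magnitudes per region
  ph <- make_lv_phantom(small_config(n = 20, phases = 3, seed = 2))
  m3 <- ph$mask$values[, , , 1]
  pl <- define_analysis_planes(m3)
  rm <- segment_blood_pool(ph$mask, pl)
  vo <- compute_vorticity(ph$field, ph$mask, phases = 2)
  cls <- rep(c("infarct", "remote"), 8)
  out <- regional_vorticity(vo, rm, region_class = cls,
                            phase_window = c(2, 2))
  # oracle: direct mean over the same voxels
  for (i in seq_len(nrow(out))) {
    lv <- match(out$plane[i], c("basal", "mid", "apical"))
    sel <- rm$level == lv & rm$segment_id > 0 &
      cls[pmax(rm$segment_id, 1)] == out$region[i]
    v <- vo$magnitude[, , , 1][sel]
    expect_equal(out$mean_vorticity[i], mean(v, na.rm = TRUE),
                 tolerance = 1e-12)
  }
  # uniform field: every region mean equals the uniform magnitude
  cfg <- small_config(n = 16, phases = 2)
  sb <- make_solid_body_field(2.5, cfg)
  mask_all <- blood_pool_mask(array(TRUE, c(cfg$grid_shape, 1L)),
                              cfg$spacing_mm)
  vo2 <- compute_vorticity(sb$field, mask_all, phases = 1)
  pl2 <- define_analysis_planes(array(TRUE, cfg$grid_shape))
  rm2 <- segment_blood_pool(mask_all, pl2)
  out2 <- regional_vorticity(vo2, rm2, phase_window = c(1, 1))
  expect_equal(out2$mean_vorticity, rep(5, nrow(out2)), tolerance = 1e-9)
})

test_that("angle and orientation are equivariant under 90-degree rotation", {
  ph <- make_lv_phantom(phantom_config(seed = 13),
                        phantom_truth(vvc_polar_deg = 20,
                                      vvc_azimuth_deg = 30))
  run <- function(p) {
    res <- analyze_session(p$field, p$magnitude, p$mask,
                           study_params(unwrap = FALSE))
    c(res$metrics$angle_deg, res$metrics$orientation_azimuth_deg)
  }
  a <- run(ph)
  b <- run(rotate_phantom_90(ph))
  expect_lt(abs(a[1] - b[1]), 0.5)
  dphi <- (b[2] - a[2]) %% 360
  expect_lt(min(abs(dphi - 90), abs(dphi - 90 - 360)), 2)
})
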
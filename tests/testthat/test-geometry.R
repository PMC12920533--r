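make_slab_mask <- function(d, z_lo, z_hi, radius = 10, dx_mm = 0, apex_dx_mm = 0) {
  g <- helper_coords(d, 2)
  m <- array(FALSE, d)
  for (k in z_lo:z_hi) {
    frac <- (k - z_lo) / max(1, z_hi - z_lo)
    cx <- dx_mm + frac * apex_dx_mm
    m[, , k] <- (g$x[, , k] - cx)^2 + g$y[, , k]^2 <= radius^2
  }
  m
}

test_that("analysis planes sit at the stated long-axis fractions", {
  d <- c(24L, 24L, 64L)
  m <- make_slab_mask(d, 10, 49)
  pl <- define_analysis_planes(m)
  expect_equal(pl$basal$slice_index, 20L)
  expect_equal(pl$mid$slice_index, 30L)
  expect_equal(pl$apical$slice_index, 40L)
  expect_error(define_analysis_planes(make_slab_mask(d, 10, 12)),
               "fewer than 4")
  # half-spheroid cavity: mid-plane area exceeds apical area
  ph <- make_lv_phantom(small_config(n = 24, phases = 3))
  m3 <- ph$mask$values[, , , 1]
  pp <- define_analysis_planes(m3)
  expect_gt(sum(m3[, , pp$mid$slice_index]), sum(m3[, , pp$apical$slice_index]))
})

test_that("anatomical centerline is the base-to-apex centroid line", {
  d <- c(32L, 32L, 40L)
  m <- make_slab_mask(d, 5, 35)
  pl <- define_analysis_planes(m)
  cl <- anatomical_centerline(blood_pool_mask(array(m, c(d, 1L)), 2),
                              pl$basal, pl$apical)
  expect_lt(acos(min(1, abs(cl$direction[3]))) * 180 / pi, 1)
  # translation equivariance: shift mask 5 voxels (10 mm) in x
  m2 <- array(FALSE, d)
  m2[6:d[1], , ] <- m[1:(d[1] - 5), , ]
  cl2 <- anatomical_centerline(blood_pool_mask(array(m2, c(d, 1L)), 2),
                               pl$basal, pl$apical)
  expect_equal(cl2$anchor - cl$anchor, c(10, 0, 0), tolerance = 1e-6)
  expect_equal(cl2$direction, cl$direction, tolerance = 1e-6)
  # sheared mask: apex centroid offset 5 mm over the basal-apical distance
  m3 <- make_slab_mask(d, 5, 35, apex_dx_mm = 5 / ((pl$apical$slice_index -
    pl$basal$slice_index) / (35 - 5)))
  cl3 <- anatomical_centerline(blood_pool_mask(array(m3, c(d, 1L)), 2),
                               pl$basal, pl$apical)
  dz_mm <- (pl$apical$slice_index - pl$basal$slice_index) * 2
  want <- atan(5 / dz_mm) * 180 / pi
  got <- acos(min(1, cl3$direction[3])) * 180 / pi
  expect_lt(abs(got - want), 0.5)
  # empty slice errors with the slice named
  m4 <- m; m4[, , pl$apical$slice_index] <- FALSE
  expect_error(anatomical_centerline(blood_pool_mask(array(m4, c(d, 1L)), 2),
                                     pl$basal, pl$apical), "apical")
})

test_that("blood-pool segmentation partitions the pool into 16 sectors", {
  ph <- make_lv_phantom(small_config(n = 24, phases = 3))
  m3 <- ph$mask$values[, , , 1]
  pl <- define_analysis_planes(m3)
  rm0 <- segment_blood_pool(blood_pool_mask(ph$mask$values, 2), pl)
  # every in-pool voxel gets exactly one segment; none outside
  expect_identical(sum(rm0$segment_id > 0), sum(m3))
  expect_true(all(rm0$segment_id[!m3] == 0L))
  expect_setequal(unique(rm0$segment_id[m3]), 1:16)
  # rotating the reference azimuth by 60 deg permutes basal ids cyclically
  rm60 <- segment_blood_pool(blood_pool_mask(ph$mask$values, 2), pl,
                             reference_azimuth_deg = 60)
  basal <- rm0$level == 1L & m3
  expect_identical(((rm0$segment_id[basal] - 1L - 1L) %% 6L) + 1L,
                   rm60$segment_id[basal])
})

test_that("segment assignment matches an independent atan2 binning oracle", {
  for (seed in 1:5) {
    ph <- make_lv_phantom(small_config(n = 20, phases = 3, seed = seed),
                          phantom_truth(vvc_polar_deg = 5 * seed %% 25))
    m3 <- ph$mask$values[, , , 1]
    pl <- define_analysis_planes(m3)
    rm <- segment_blood_pool(blood_pool_mask(ph$mask$values, 2), pl,
                             reference_azimuth_deg = 30)
    g <- helper_coords(dim(m3), 2)
    occ <- which(apply(m3, 3, any))
    z0 <- min(occ); z1 <- max(occ); n <- z1 - z0 + 1
    cut1 <- z0 + ceiling(n / 3) - 1; cut2 <- z0 + ceiling(2 * n / 3) - 1
    idx <- which(m3)
    pos <- arrayInd(idx, dim(m3))
    lev <- ifelse(pos[, 3] <= cut1, 1L, ifelse(pos[, 3] <= cut2, 2L, 3L))
    nsec <- c(6, 6, 4)[lev]
    off <- c(0, 6, 12)[lev]
    want <- integer(length(idx))
    for (lv in 1:3) {
      sel <- lev == lv
      vox <- idx[sel]
      cx <- mean(g$x[vox]); cy <- mean(g$y[vox])
      az <- (atan2(g$y[vox] - cy, g$x[vox] - cx) * 180 / pi - 30) %% 360
      want[sel] <- c(0, 6, 12)[lv] +
        pmin(floor(az / (360 / c(6, 6, 4)[lv])) + 1, c(6, 6, 4)[lv])
    }
    expect_identical(rm$segment_id[idx], as.integer(want))
  }
})

test_that("LGE extent is a volume percentage with subset guard", {
  myo <- array(FALSE, c(10, 10, 5)); myo[2:9, 2:9, ] <- TRUE
  enh <- array(FALSE, c(10, 10, 5)); enh[2:5, 2:6, 1] <- TRUE
  expect_equal(lge_extent(enh, myo), 100 * sum(enh) / sum(myo))
  expect_equal(lge_extent(myo, myo), 100)
  # scale invariance: doubling the volume preserves the percentage
  expect_equal(lge_extent(enh, myo),
               lge_extent(array(enh, c(10, 10, 5, 2))[, , , ],
                          array(myo, c(10, 10, 5, 2))[, , , ]))
  bad <- enh; bad[1, 1, 1] <- TRUE
  expect_error(lge_extent(bad, myo), "subset")
  expect_error(lge_extent(enh, array(FALSE, c(10, 10, 5))), "empty")
})

test_that("region classes follow the strict >25% rule and graph adjacency", {
  expect_equal(classify_segment_regions(rep(0, 16)), rep("remote", 16))
  v <- rep(0, 16); v[2] <- 25.0
  expect_equal(classify_segment_regions(v), rep("remote", 16))
  v[2] <- 25.1
  cls <- classify_segment_regions(v)
  expect_equal(which(cls == "infarct"), 2L)
  expect_setequal(which(cls == "adjacent"), c(1L, 3L, 8L))
  expect_true(all(cls[-c(1, 2, 3, 8)] == "remote"))
  # classes are exhaustive and mutually exclusive for random inputs
  withr::with_seed(4, {
    for (r in 1:20) {
      lge <- runif(16, 0, 100)
      cls <- classify_segment_regions(lge)
      expect_true(all(cls %in% c("infarct", "adjacent", "remote")))
      expect_identical(which(cls == "infarct"), which(lge > 25))
    }
  })
})

test_that("ECV follows the two-compartment delta-R1 formula", {
  # equal relaxivity change in myocardium and blood leaves 100*(1-Hct)
  expect_equal(compute_ecv(1000, 500, 1600, 1 / (0.001 + 1 / 1600),
                           hct = 0.40), 60)
  expect_equal(compute_ecv(1000, 1000, 1600, 300, hct = 0.40), 0)
  # hand-evaluated oracle with the baseline infarct-region myocardial T1
  want <- 100 * (1 - 0.40) * (1 / 500 - 1 / 1079) / (1 / 300 - 1 / 1600)
  expect_equal(compute_ecv(1079, 500, 1600, 300, hct = 0.40), want)
  # invariant to ms vs s
  expect_equal(compute_ecv(1.079, 0.5, 1.6, 0.3, hct = 0.40), want)
  expect_error(compute_ecv(1000, 1100, 1600, 300, hct = 0.4), "exceed")
  expect_error(compute_ecv(1000, 500, 1600, 300, hct = 1.2), "hct")
})
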
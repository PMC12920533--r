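test_that("unwrap restores isolated single-wrap voxels exactly", {
  # a smooth constant patch near 155 cm/s with one voxel stored wrapped
  cfg <- small_config(n = 12, phases = 2)
  d <- cfg$grid_shape
  vals <- array(0, c(d, 3L, 1L))
  vals[, , , 3, 1] <- 155
  truth <- vals
  truth[6, 6, 6, 3, 1] <- 160
  wrapped <- truth
  wrapped[6, 6, 6, 3, 1] <- 160 - 2 * 150   # scanner stores -140
  f <- velocity_field(wrapped, cfg$spacing_mm, venc_cm_s = 150)
  out <- unwrap_velocity(f)
  expect_equal(out$values, truth, tolerance = 1e-12)
})

test_that("unwrap is the identity on fields within VENC", {
  ph <- make_lv_phantom(small_config(n = 20, phases = 4, seed = 2))
  out <- unwrap_velocity(ph$field, ph$mask)
  expect_identical(out$values, ph$field$values)
})

test_that("wrap-simulation round-trips through unwrap on the phantom", {
  # boost sparse jet voxels past VENC so the stored field aliases exactly
  # there; the spatial-median pass must restore the boosted values
  n_bad <- 10L
  errs <- vapply(1:20, function(seed) {
    cfg <- phantom_config(grid_shape = c(32, 32, 32), n_phases = 5,
                          seed = seed)
    ph <- make_lv_phantom(cfg, phantom_truth(ea_ratio_true = 2))
    ep <- 3L  # E peak for a 5-phase cycle
    vz <- ph$field$values[, , , 3, ep]
    dim(vz) <- cfg$grid_shape
    # deep-jet voxels: all six neighbours also carry the jet velocity, so
    # the neighbourhood median stays near the true value after aliasing
    injet <- vz > 50
    deep <- injet
    d3 <- dim(injet)
    deep[c(1, d3[1]), , ] <- deep[, c(1, d3[2]), ] <- deep[, , c(1, d3[3])] <- FALSE
    idx <- which(deep)
    pos <- arrayInd(idx, d3)
    for (ax in 1:3) for (s in c(-1, 1)) {
      p <- pos; p[, ax] <- p[, ax] + s
      deep[idx[!injet[p]]] <- FALSE
    }
    # pick isolated voxels (pairwise Chebyshev distance > 1) so each keeps an
    # unwrapped neighbourhood
    set.seed(seed + 1000)
    cand <- sample(which(deep))
    bad <- integer(0)
    for (v in cand) {
      pv <- arrayInd(v, d3)
      if (length(bad) == 0L ||
          all(apply(abs(arrayInd(bad, d3) -
                          matrix(pv, length(bad), 3, byrow = TRUE)), 1, max) > 1)) {
        bad <- c(bad, v)
      }
      if (length(bad) == n_bad) break
    }
    truth <- ph$field
    v3 <- truth$values[, , , 3, ep]
    v3[bad] <- 160 + runif(length(bad), 0, 20)
    truth$values[, , , 3, ep] <- v3
    stored <- simulate_venc_wrap(truth)
    restored <- unwrap_velocity(stored, ph$mask)
    max(abs(restored$values - truth$values))
  }, numeric(1))
  expect_lt(max(errs), 1e-6)
})

test_that("eddy-current correction removes an injected first-order offset", {
  cfg <- small_config(n = 14, phases = 3)
  d <- cfg$grid_shape
  g <- helper_coords(d, cfg$spacing_mm)
  vals <- array(0, c(d, 3L, 3L))
  # moving blood in a central blob; static tissue elsewhere
  blob <- g$x^2 + g$y^2 + (g$z - 14)^2 < 8^2
  for (t in 1:3) {
    v <- array(0, d); v[blob] <- 10 * t
    vals[, , , 3, t] <- v
  }
  mag <- array(100, c(d, 3L))
  clean <- velocity_field(vals, cfg$spacing_mm, cfg$venc_cm_s)
  polluted <- clean
  plane <- 0.5 + 0.03 * g$x + 0.02 * g$y   # eddy-current offset model
  for (t in 1:3) for (ic in 1:3) {
    polluted$values[, , , ic, t] <- polluted$values[, , , ic, t] + plane
  }
  fixed <- correct_eddy_currents(polluted, magnitude_image(mag, cfg$spacing_mm))
  expect_equal(fixed$values, clean$values, tolerance = 1e-6)
  # offset-free input passes through essentially unchanged
  fixed2 <- correct_eddy_currents(clean, magnitude_image(mag, cfg$spacing_mm))
  expect_lt(max(abs(fixed2$values - clean$values)), 1e-9)
})

test_that("eddy-current correction is skipped when static tissue is scarce", {
  d <- c(4L, 4L, 4L)  # 64 voxels total: below any sensible static minimum
  vals <- array(1, c(d, 3L, 2L))
  mag <- array(100, c(d, 2L))
  f <- velocity_field(vals, 2, 150)
  expect_warning(out <- correct_eddy_currents(f, magnitude_image(mag, 2)),
                 "skipping")
  expect_identical(out$values, f$values)
})

test_that("noise masking zeroes low-signal voxels and only those", {
  cfg <- small_config(n = 20, phases = 4, seed = 5)
  ph <- make_lv_phantom(cfg)
  noisy <- ph$field
  m3 <- ph$mask$values[, , , 1]
  withr::with_seed(99, {
    for (t in 1:4) for (ic in 1:3) {
      v <- noisy$values[, , , ic, t]
      v[!m3] <- rnorm(sum(!m3), 0, 3)
      noisy$values[, , , ic, t] <- v
    }
  })
  out <- apply_noise_mask(noisy, ph$magnitude, threshold_frac = 0.1)
  for (t in 1:4) for (ic in 1:3) {
    expect_true(all(out$values[, , , ic, t][!m3] == 0))
    expect_identical(out$values[, , , ic, t][m3],
                     noisy$values[, , , ic, t][m3])
  }
  expect_identical(apply_noise_mask(noisy, ph$magnitude, 0)$values,
                   noisy$values)
})

test_that("PC-MRA equals magnitude times speed and contrasts the pool", {
  cfg <- small_config(n = 12, phases = 2)
  d <- cfg$grid_shape
  vals <- array(0, c(d, 3L, 2L))
  vals[, , , 1, ] <- 3; vals[, , , 2, ] <- 4   # speed 5 everywhere
  f <- velocity_field(vals, 2, 150)
  mag <- magnitude_image(array(7, c(d, 2L)), 2)
  expect_equal(unique(as.vector(compute_pcmra(f, mag))), 35)
  zero <- velocity_field(array(0, c(d, 3L, 2L)), 2, 150)
  expect_true(all(compute_pcmra(zero, mag) == 0))
  ph <- make_lv_phantom(small_config(n = 20, phases = 6, seed = 4))
  pcmra <- compute_pcmra(ph$field, ph$magnitude)
  m3 <- ph$mask$values[, , , 1]
  expect_gt(mean(pcmra[m3]), 5 * mean(pcmra[!m3]))
})

test_that("corrections preserve grid shape and are idempotent on clean data", {
  ph <- make_lv_phantom(small_config(n = 16, phases = 3, seed = 8))
  once <- apply_noise_mask(unwrap_velocity(ph$field, ph$mask), ph$magnitude)
  twice <- apply_noise_mask(unwrap_velocity(once, ph$mask), ph$magnitude)
  expect_identical(dim(once$values), dim(ph$field$values))
  expect_lt(max(abs(twice$values - once$values)), 1e-9)
})
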
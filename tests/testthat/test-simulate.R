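test_that("noiseless homogeneous slab renders the closed-form folded ramp", {
  for (brc in c(1.1, 3.0, 5.4)) {
    fx <- slab_volume(brc)
    pair <- fx$volume[[1]]
    phase <- compute_retardation(pair)
    j <- default_center_ascan(fx$tissue, fx$params)
    oracle <- folded_ramp_oracle(fx$tissue, fx$params,
                                 psoct:::lateral_positions(fx$tissue, fx$params)[j])
    measured <- phase$values[oracle$below, j]
    expect_lt(max(abs(measured - oracle$delta[oracle$below])), 1e-10)
    # the pi/2 wrap: everything in [0, pi/2]
    expect_true(all(phase$values >= 0 & phase$values <= pi / 2 + 1e-12))
  }
})

test_that("isotropic tissue reads zero retardation below the surface", {
  # the double-passed QWP sample arm returns all light in one channel for an
  # isotropic sample, so the folded retardation is 0 (see methods vignette)
  fx <- slab_volume(0)
  phase <- compute_retardation(fx$volume[[1]])
  oracle <- folded_ramp_oracle(fx$tissue, fx$params, 0.5)
  expect_true(all(phase$values[oracle$below, ] < 1e-12))
})

test_that("noiseless energy is the backscatter profile, independent of retardance", {
  fx0 <- slab_volume(0)
  fx5 <- slab_volume(5.4)
  i0 <- compute_reflectivity(fx0$volume[[1]])$values
  i5 <- compute_reflectivity(fx5$volume[[1]])$values
  # retarders are unitary: Av^2 + Ah^2 is unchanged by the birefringence
  expect_equal(i5, i0, tolerance = 1e-12)
})

test_that("simulation is deterministic under fixed seeds", {
  tissue <- make_tissue(grade_presets(config = "XZ_indented", grade = "G0"), seed = 3)
  p <- acq_scaled()
  a <- simulate_ascan(tissue, 5.75, p, seed = 21)
  b <- simulate_ascan(tissue, 5.75, p, seed = 21)
  expect_identical(a, b)
  c <- simulate_ascan(tissue, 5.75, p, seed = 22)
  expect_false(identical(a$Av, c$Av))
  va <- simulate_volume(tissue, p, n_bscans = 2, seed = 5)
  vb <- simulate_volume(tissue, p, n_bscans = 2, seed = 5)
  expect_identical(va, vb)
})

test_that("volumes have the requested size and co-registered shapes", {
  tissue <- make_tissue(grade_presets(config = "XZ_nonindented", grade = "G1"), seed = 1)
  p <- acq_scaled()
  v <- simulate_volume(tissue, p, n_bscans = 5, seed = 1)
  expect_length(v, 5)
  shapes <- unique(lapply(v, function(b) dim(b$Av)))
  expect_length(shapes, 1)
  expect_equal(shapes[[1]], c(p$n_depth, p$n_ascans))
  v1 <- simulate_volume(tissue, p, n_bscans = 1, seed = 1)
  expect_length(v1, 1)
  expect_error(simulate_volume(tissue, p, n_bscans = 0), class = "psoct_invalid_params")
  # adjacent B-scans of a laterally uniform tissue differ only by noise:
  # same underlying noiseless render, different realisations
  expect_false(identical(v[[1]]$Av, v[[2]]$Av))
  noiseless <- simulate_bscan(tissue, acq_scaled(noise_sigma = 0), seed = 1)
  expect_gt(stats::cor(as.vector(v[[1]]$Av), as.vector(noiseless$Av)), 0.8)
})

test_that("speckle is multiplicative with unit mean: A-scan averages converge", {
  tissue <- make_tissue(fixed_preset(2), seed = 4)
  pn <- acq_scaled(noise_sigma = 0.4, image_width = 1)
  p0 <- acq_scaled(noise_sigma = 0, image_width = 1)
  clean <- simulate_ascan(tissue, 5, p0, seed = 1)
  n_rep <- 400
  acc <- rep(0, pn$n_depth)
  for (s in seq_len(n_rep)) acc <- acc + simulate_ascan(tissue, 5, pn, seed = s)$Av
  avg <- acc / n_rep
  below <- clean$Av > 1e-6
  # relative error of the mean scales like sigma_speckle / sqrt(N)
  rel <- abs(avg[below] - clean$Av[below]) / clean$Av[below]
  expect_lt(stats::median(rel), 5 * 0.21 / sqrt(n_rep))
})

test_that("out-of-block lateral positions are rejected", {
  tissue <- make_tissue(grade_presets(config = "XY", grade = "G0"), seed = 1)
  expect_error(simulate_ascan(tissue, 10.7, acq_scaled()), class = "psoct_range_error")
})
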
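test_that("identical inputs give bit-identical tissue models", {
  p <- grade_presets(config = "XZ_indented", grade = "G1")
  a <- make_tissue(p, sample_index = 3, seed = 11)
  b <- make_tissue(p, sample_index = 3, seed = 11)
  expect_identical(a, b)
  c <- make_tissue(p, sample_index = 4, seed = 11)
  expect_false(identical(a$truth_brc, c$truth_brc))
})

test_that("zero between-sample SD makes every truth equal the preset mean", {
  p <- fixed_preset(2.4, config = "XZ_indented")
  truths <- sapply(1:5, function(i) make_tissue(p, sample_index = i, seed = 1)$truth_brc)
  expect_equal(truths, rep(2.4, 5))
})

test_that("truth draws follow the truncated normal of the preset", {
  # closed-form moments of Normal(1.8, 0.7) truncated below at 0:
  # mean = mu + sigma*lambda, var = sigma^2*(1 - lambda*(lambda - alpha)),
  # alpha = -mu/sigma, lambda = dnorm(alpha)/(1 - pnorm(alpha))
  mu <- 1.8; sigma <- 0.7
  alpha <- -mu / sigma
  lambda <- dnorm(alpha) / (1 - pnorm(alpha))
  m_exp <- mu + sigma * lambda            # 1.8103
  s_exp <- sigma * sqrt(1 - lambda * (lambda - alpha))  # 0.6866
  p <- grade_presets(config = "XZ_indented", grade = "G2")
  withr::with_seed(42, {
    draws <- psoct:::rtruncnorm0(10000, p$brc_mean, p$brc_sd)
  })
  expect_true(all(draws >= 0))
  expect_equal(mean(draws), m_exp, tolerance = 0.02)
  expect_equal(sd(draws), s_exp, tolerance = 0.03)
  # and the same draw path through make_tissue
  truths <- sapply(1:400, function(i) {
    make_tissue(p, sample_index = i, seed = 5, n_depth = 2L, n_lateral = 2L)$truth_brc
  })
  expect_equal(mean(truths), m_exp, tolerance = 3 * s_exp / sqrt(400))
})

test_that("indented models carry a bulge and asymmetric birefringence; uniform ones do not", {
  ind <- make_tissue(grade_presets(config = "XZ_indented", grade = "G0"), seed = 2)
  flat <- make_tissue(grade_presets(config = "XZ_nonindented", grade = "G0"), seed = 2)
  # surface rises (smaller depth) at the block centre
  centre <- which.min(abs(ind$lateral_grid - 5))
  expect_lt(ind$surface_height[centre], ind$surface_height[50])
  expect_true(all(diff(flat$surface_height) == 0))
  # dn laterally asymmetric for indented, uniform otherwise
  expect_false(isTRUE(all.equal(ind$dn_map[1, 50], ind$dn_map[1, 450])))
  expect_true(all(ind$dn_map >= 0))
  expect_equal(max(abs(diff(flat$dn_map[1, ]))), 0)
  # at the default analysis position the local dn encodes the truth exactly
  # nearest lateral grid node to the analysis position (grid step 20 um)
  x_eval <- psoct:::shoulder_position(ind$geometry, 5)
  j <- which.min(abs(ind$lateral_grid - x_eval))
  expect_equal(brc_for_dn(ind$dn_map[1, j]), ind$truth_brc, tolerance = 1e-3)
})

test_that("invalid geometry is rejected", {
  p <- grade_presets(config = "XZ_indented", grade = "G0")
  expect_error(make_tissue(p, thickness = 0), class = "psoct_invalid_geometry")
  expect_error(make_tissue(p, n_depth = 1), class = "psoct_invalid_geometry")
  expect_error(indentation_geometry(strain = 1.2), class = "psoct_invalid_geometry")
  expect_error(indentation_geometry(channel_gap = 0), class = "psoct_invalid_geometry")
})

test_that("dn_for_brc and brc_for_dn are exact inverses and handle edge cases", {
  expect_equal(dn_for_brc(0), 0)
  for (x in c(0.5, 3.0, 5.4)) {
    expect_equal(brc_for_dn(dn_for_brc(x)), x, tolerance = 1e-12)
  }
  expect_error(dn_for_brc(-1), class = "psoct_domain_error")
  # direct evaluation of the convention: dn = 3.13e-4 at 1310 nm -> ~3.0 rad/mm
  expect_equal(brc_for_dn(3.13e-4, 1310), 3.0025, tolerance = 1e-4)
  expect_equal(brc_for_dn(2 * 3.13e-4), 2 * brc_for_dn(3.13e-4))
})
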
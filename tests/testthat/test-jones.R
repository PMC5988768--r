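test_that("retarder matrices are unitary and compose as expected", {
  expect_equal(retarder_matrix(0, 0.7), diag(2) + 0i)
  withr::with_seed(1, {
    for (i in 1:20) {
      m <- retarder_matrix(runif(1, 0, 2 * pi - 1e-9), runif(1, 0, pi - 1e-9))
      det2 <- m[1, 1] * m[2, 2] - m[1, 2] * m[2, 1]
      expect_equal(Mod(det2), 1, tolerance = 1e-12)
      expect_equal(Conj(t(m)) %*% m, diag(2) + 0i, tolerance = 1e-12)
    }
  })
  # two identical quarter-wave elements = one half-wave element at the same axis
  q <- retarder_matrix(pi / 2, 0.3)
  expect_equal(q %*% q, retarder_matrix(pi, 0.3), tolerance = 1e-12)
  expect_error(retarder_matrix(-0.1), class = "psoct_domain_error")
  expect_error(retarder_matrix(1, axis = pi), class = "psoct_domain_error")
})

test_that("closed-form channel amplitudes agree with explicit Jones products", {
  withr::with_seed(7, {
    for (i in 1:25) {
      delta <- runif(1, 0, 3 * pi)
      axis <- runif(1, 0, pi - 1e-9)
      fast <- channel_amplitudes(delta, axis)
      # one-way layer stack of the same total retardance at the same axis;
      # the double pass is built by explicit matrix products
      k <- sample(1:4, 1)
      parts <- diff(c(0, sort(runif(k - 1, 0, delta %% (2 * pi))), delta %% (2 * pi)))
      # each one-way layer carries half its measured retardation; the return
      # pass doubles it, so layers summing to delta match channel_amplitudes
      slow <- psoct:::jones_round_trip(
        lapply(parts, function(r) list(retardance = r, axis = axis))
      )
      expect_equal(fast$Av, slow$Av, tolerance = 1e-10)
      expect_equal(fast$Ah, slow$Ah, tolerance = 1e-10)
      # unitarity: unit channel energy
      expect_equal(fast$Av^2 + fast$Ah^2, 1, tolerance = 1e-12)
    }
  })
})

test_that("noiseless Berek sweep reproduces the identity theory line on the full grid", {
  fold_deg <- function(s) pmin(s %% 180, 180 - s %% 180)
  grid <- expand.grid(set = seq(0, 180, by = 10), axis = seq(0, 180, by = 10))
  meas <- berek_measure(grid$set, grid$axis)
  expect_true(all(meas >= 0 & meas <= 90))
  expect_lt(max(abs(meas - fold_deg(grid$set))), 1e-9)
  # axis-independence of the circular-incidence design at 45 deg set retardation
  meas45 <- berek_measure(45, seq(0, 180, by = 10))
  expect_lt(max(abs(meas45 - 45)), 1e-9)
  expect_equal(berek_measure(90, 20), 90)
  expect_equal(berek_measure(0, 137), 0)
})

test_that("Berek noise path is seeded and folded back into range", {
  a <- berek_measure(rep(45, 50), 10, noise_sd = 3, seed = 9)
  b <- berek_measure(rep(45, 50), 10, noise_sd = 3, seed = 9)
  expect_identical(a, b)
  expect_true(all(a >= 0 & a <= 90))
  expect_gt(sd(a), 0)
  expect_error(berek_measure(190, 0), class = "psoct_domain_error")
  expect_error(berek_measure(90, -5), class = "psoct_domain_error")
})
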
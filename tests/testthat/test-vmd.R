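test_that("configuration defaults and validation", {
  cfg <- vmd_config()
  expect_equal(cfg$n_modes, 5L)
  expect_equal(cfg$alpha, 2000)
  expect_equal(cfg$tau, 0)
  expect_error(vmd_config(n_modes = 0))
  expect_error(vmd_config(alpha = -1))
  expect_error(vmd_config(eps_r = Inf, eps_a = Inf))
  om <- vmdeeg:::initial_omegas(vmd_config(n_modes = 5))
  expect_true(all(om > 0 & om < 0.5))
  expect_equal(diff(om), rep(om[1], 4))
})

test_that("mirror extension and cropping invert exactly", {
  expect_equal(extend_signal(c(1, 2, 3, 4)), c(2, 1, 1, 2, 3, 4, 4, 3))
  for (n in c(2, 5, 8, 101)) {
    x <- rnorm(n)
    ext <- extend_signal(x)
    expect_length(ext, 2 * n)
    expect_identical(crop_to_original(ext, n), x)
  }
  expect_equal(extend_signal(rep(7, 6)), rep(7, 12))
  expect_error(extend_signal(1))
})

test_that("convergence criterion follows the relative/absolute sums", {
  m <- matrix(rnorm(6), 2, 3)
  expect_true(vmd_check_convergence(m, m, 1e-7, Inf))
  # rel sum = 1, abs sum = 1, both at tolerance 0.5 -> not converged
  expect_false(vmd_check_convergence(matrix(c(1, 0), 1),
                                     matrix(c(1, 1), 1), 0.5, 0.5))
  # rel sum = 0.01/1 < 0.02 -> converged via the relative rule
  expect_true(vmd_check_convergence(matrix(c(1, 0), 1),
                                    matrix(c(1, 0.1), 1), 0.02, 1e-9))
  # zero-norm previous mode feeds only the absolute criterion
  expect_false(vmd_check_convergence(matrix(0, 1, 2),
                                     matrix(c(1, 1), 1), 1e7, 1))
  expect_true(vmd_check_convergence(matrix(0, 1, 2),
                                    matrix(c(0.1, 0), 1), Inf, 0.5))
  expect_error(vmd_check_convergence(matrix(0, 1, 2), matrix(0, 2, 2),
                                     1, 1))
})

test_that("zero input yields zero modes with zero residual", {
  ms <- vmd_decompose(rep(0, 64), vmd_config(n_modes = 2))
  expect_equal(ms$modes, matrix(0, 2, 64))
  expect_equal(ms$residual_energy, 0)
  expect_true(ms$converged)
})

test_that("input validation errors", {
  expect_error(vmd_decompose(c(1, NA, 3, 4, 5, 6, 7, 8), vmd_config()),
               "non-finite")
  expect_error(vmd_decompose(rnorm(8), vmd_config(n_modes = 5)),
               "half the signal length")
  expect_error(vmd_decompose(rnorm(4), vmd_config(n_modes = 1)))
})

test_that("a single mode locks onto a pure tone (FFT-peak oracle)", {
  x <- cos(2 * pi * 0.05 * (0:1023))
  oracle <- fft_peak(x)
  ms <- vmd_decompose(x, vmd_config(n_modes = 1))
  expect_true(ms$converged)
  expect_lt(abs(ms$omegas - oracle) / oracle, 0.01)
  # the mode reproduces an ideal narrow-band filtrate of the input
  ideal <- ideal_narrowband(x, oracle)
  expect_gt(cor(ms$modes[1, ], ideal), 0.99)
})

test_that("two well-separated tones are recovered as a bijection", {
  n <- 0:2047
  t1 <- cos(2 * pi * 0.02 * n)
  t2 <- cos(2 * pi * 0.20 * n)
  ms <- vmd_decompose(t1 + t2, vmd_config(n_modes = 2))
  # oracle: FFT peak locations of the isolated tones
  peaks <- sort(c(fft_peak(t1), fft_peak(t2)))
  expect_true(ms$converged)
  expect_lt(abs(ms$omegas[1] - peaks[1]) / peaks[1], 0.05)
  expect_lt(abs(ms$omegas[2] - peaks[2]) / peaks[2], 0.05)
  expect_gt(cor(ms$modes[1, ], t1), 0.95)
  expect_gt(cor(ms$modes[2, ], t2), 0.95)
  # partition: each tone's peak falls in exactly one mode's dominant band
  claimed <- vapply(peaks, function(p)
    which.min(abs(ms$omegas - p)), 0L)
  expect_equal(sort(claimed), c(1L, 2L))
})

test_that("three-tone mixtures reconstruct within 5% relative error", {
  x <- generate_tone_mixture(c(5, 20, 60), c(1, 0.8, 0.6), fs = 256,
                             duration_s = 8, seed = 2)
  ms <- vmd_decompose(x, vmd_config(n_modes = 3))
  recon <- vmd_reconstruct(ms)
  expect_length(recon, length(x))
  expect_lt(sqrt(sum((recon - x)^2) / sum(x^2)), 0.05)
  expect_equal(recon, colSums(ms$modes))
})

test_that("reconstruction utility sums modes and rejects empty input", {
  expect_equal(vmd_reconstruct(matrix(c(1, 1, 2, 2), 2, byrow = TRUE)),
               c(3, 3))
  m <- matrix(rnorm(10), 1)
  expect_equal(vmd_reconstruct(m), as.numeric(m))
  expect_error(vmd_reconstruct(matrix(0, 0, 5)), "empty")
})

test_that("spectral localization: power centroid matches reported omega", {
  battery <- list(c(0.03, 0.22), c(0.05, 0.31), c(0.10, 0.40))
  for (fr in battery) {
    n <- 0:2047
    x <- cos(2 * pi * fr[1] * n) + cos(2 * pi * fr[2] * n)
    ms <- vmd_decompose(x, vmd_config(n_modes = 2))
    for (k in 1:2) {
      sp <- Mod(fft(ms$modes[k, ]))[1:1024]^2
      f <- (0:1023) / 2048
      centroid <- sum(f * sp) / sum(sp)
      expect_lt(abs(centroid - ms$omegas[k]), 0.05) # 10% of Nyquist
    }
  }
})

test_that("iteration refines: converged runs need more than one sweep", {
  x <- generate_tone_mixture(c(8, 40), fs = 256, duration_s = 4,
                             noise_sd = 0.1, seed = 7)
  ms <- vmd_decompose(x, vmd_config(n_modes = 2))
  expect_true(ms$converged)
  expect_gt(ms$n_iter, 1)
  # the same run truncated to one sweep has not met the tolerance
  ms1 <- vmd_decompose(x, vmd_config(n_modes = 2, max_iter = 1))
  expect_false(ms1$converged)
})

test_that("decomposition is deterministic given config and seed", {
  x <- generate_tone_mixture(c(6, 30), fs = 128, duration_s = 4,
                             noise_sd = 0.2, seed = 11)
  cfg <- vmd_config(n_modes = 3, omega_init = "random", random_seed = 5)
  expect_identical(vmd_decompose(x, cfg), vmd_decompose(x, cfg))
  cfg2 <- vmd_config(n_modes = 3)
  expect_identical(vmd_decompose(x, cfg2), vmd_decompose(x, cfg2))
})

test_that("omegas are returned sorted and within [0, 0.5]", {
  x <- generate_tone_mixture(c(3, 17, 50, 90), fs = 256, duration_s = 4,
                             noise_sd = 0.3, seed = 3)
  ms <- vmd_decompose(x, vmd_config(n_modes = 4))
  expect_false(is.unsorted(ms$omegas))
  expect_true(all(ms$omegas >= 0 & ms$omegas <= 0.5))
})

test_that("dc_mode pins the first mode at zero frequency", {
  x <- 5 + cos(2 * pi * 0.1 * (0:511))
  ms <- vmd_decompose(x, vmd_config(n_modes = 2, dc_mode = TRUE))
  expect_equal(ms$omegas[1], 0)
  expect_gt(mean(ms$modes[1, ]), 2) # carries the offset
})

test_that("dual ascent (tau > 0) tightens reconstruction", {
  x <- generate_tone_mixture(c(10, 45), fs = 256, duration_s = 4,
                             noise_sd = 0, seed = 9)
  loose <- vmd_decompose(x, vmd_config(n_modes = 2, tau = 0))
  tight <- vmd_decompose(x, vmd_config(n_modes = 2, tau = 1))
  expect_lte(tight$residual_energy, loose$residual_energy + 1e-10)
  expect_lt(tight$residual_energy, 0.01)
})
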
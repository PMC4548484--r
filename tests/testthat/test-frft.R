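test_that("kernel matrix handles the analytic boundary branches", {
  expect_equal(frft_kernel_matrix(8, 0), diag(8) + 0i)
  P <- frft_kernel_matrix(8, pi)
  expect_equal(Re(P), diag(8)[, c(1, 8:2)])
  x <- rand_signal(8)
  expect_equal(as.vector(P %*% x), x[c(1, 8:2)])
  # 2*pi wraps back to the identity, 3*pi to the reversal
  expect_equal(frft_kernel_matrix(6, 2 * pi), diag(6) + 0i)
  expect_equal(frft_kernel_matrix(6, 3 * pi), frft_kernel_matrix(6, pi))
})

test_that("sampled kernel quadrature is unitary", {
  for (al in c(0.1, 0.3, 0.5, 0.8) * pi) {
    K <- frft_kernel_matrix(64, al)
    expect_lt(max(Mod(Conj(t(K)) %*% K - diag(64))), 1e-6)
  }
})

test_that("fast transform matches the kernel-matrix oracle", {
  for (n in c(32, 128)) {
    x <- rand_signal(n, seed = n)
    for (al in c(0.15, 0.5, 0.85) * pi) {
      expect_lt(rel_l2(frft(x, al), frft_kernel_matrix(n, al) %*% x), 1e-3)
    }
  }
})

test_that("fast transform preserves the L2 norm on random inputs", {
  x <- rand_signal(64, seed = 7)
  for (al in c(0.1, 0.5, 0.9) * pi) {
    y <- frft(x, al)
    expect_lt(abs(sqrt(sum(Mod(y)^2)) / sqrt(sum(Mod(x)^2)) - 1), 1e-6)
  }
})

test_that("boundary orders reduce to identity, reversal and the DFT", {
  x <- rand_signal(64, seed = 3)
  expect_equal(frft(x, 0), x)
  expect_equal(frft(x, pi), x[c(1, 64:2)])
  # centered unitary DFT magnitude = fftshifted |fft|/sqrt(n)
  m <- Mod(frft(x, pi / 2))
  ref <- Mod(stats::fft(x))[c(33:64, 1:32)] / sqrt(64)
  expect_lt(max(abs(m - ref)), 1e-6)
})

test_that("grid-aware composition restores order additivity", {
  x <- gauss_pulse(128, 0.25 * pi)
  y <- frft_compose(x, c(0.25 * pi, 0.35 * pi))
  expect_lt(rel_l2(y, frft(x, 0.6 * pi)), 1e-3)
  # a modulated pulse as a second, less symmetric case
  x2 <- gauss_pulse(128, 0.4 * pi) * cos(1.3 * frft_grid(128, 0.4 * pi))
  y2 <- frft_compose(x2, c(0.4 * pi, 0.3 * pi))
  expect_lt(rel_l2(y2, frft(x2, 0.7 * pi)), 1e-3)
})

test_that("naive index-space composition is only approximately additive", {
  # the sampling-type discrete FrFT ties each order to its own grid; composing
  # without regridding incurs a dilation error that frft_compose removes
  x <- gauss_pulse(128, 0.25 * pi)
  naive <- frft(frft(x, 0.25 * pi), 0.35 * pi)
  err_naive <- rel_l2(naive, frft(x, 0.6 * pi))
  err_aware <- rel_l2(frft_compose(x, c(0.25 * pi, 0.35 * pi)), frft(x, 0.6 * pi))
  expect_lt(err_naive, 0.25)
  expect_lt(err_aware, 1e-6 * err_naive)
})

test_that("invalid transform inputs are rejected", {
  expect_error(frft(numeric(0), 0.3 * pi), class = "frcc_invalid_input")
  expect_error(frft(c(1, NA, 2), 0.3 * pi), class = "frcc_invalid_input")
  expect_error(frft(1:8, Inf), class = "frcc_invalid_parameter")
  expect_error(frft_kernel_matrix(1, 0.3 * pi), class = "frcc_invalid_parameter")
  expect_error(frft_order(alpha = 0.3, p = 0.2), class = "frcc_invalid_parameter")
  expect_equal(frft_order(p = 1)$alpha, pi / 2)
})

test_that("fractional magnitude spectra retain the cosine phase offset", {
  omega0 <- 2 * pi * 38 / 256  # bin-aligned tone: leakage confined to 3 bins
  d_ft <- phase_demo_spread(cosine_phase_demo(omega0, c(0, pi / 4), pi / 2, n = 256))
  d_fr <- phase_demo_spread(cosine_phase_demo(omega0, c(0, pi / 4), 0.4 * pi, n = 256))
  expect_lt(d_ft, 1e-6)          # ordinary Fourier magnitude is phase-blind
  expect_gt(d_fr, 10 * max(d_ft, 1e-6))  # fractional magnitude is not
})

test_that("phase demo respects 2*pi periodicity and validates parameters", {
  for (al in c(0.3, 0.5, 0.7) * pi) {
    d <- phase_demo_spread(cosine_phase_demo(0.3 * pi, c(0, 2 * pi), al))
    expect_lt(d, 1e-10)
  }
  expect_error(cosine_phase_demo(pi, 0, 0.4 * pi), class = "frcc_invalid_parameter")
  expect_error(cosine_phase_demo(0.3 * pi, 0, pi), class = "frcc_invalid_parameter")
  p <- autoplot(cosine_phase_demo(0.3 * pi, c(0, 1), 0.4 * pi, n = 64))
  expect_s3_class(p, "ggplot")
})
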
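test_that("framing follows the 20 ms / 10 ms geometry", {
  p <- frame_params()
  f <- frame_signal(rnorm(8000), p)
  expect_equal(dim(f), c(99, 160))
  expect_equal(nrow(frame_signal(rnorm(160), p)), 1)
  expect_error(frame_signal(rnorm(159), p), class = "frcc_short_input")
  expect_error(frame_signal(rnorm(159), p), "160")  # names the required minimum
  # window is applied: a constant signal shows the taper
  g <- frame_signal(rep(1, 160), p)
  expect_equal(drop(g), 0.54 - 0.46 * cos(2 * pi * (0:159) / 159))
})

test_that("mel mapping matches its closed form and is monotone", {
  expect_equal(mel_of(0), 0)
  expect_equal(mel_of(700), 1125 * log(2))
  u <- seq(0, 4000, length.out = 200)
  expect_true(all(diff(mel_of(u)) > 0))
  expect_error(mel_of(-1), class = "frcc_invalid_parameter")
})

test_that("fractional filterbank reduces to the Mel bank and is sin-symmetric", {
  std <- mel_filterbank(24, 128, 8000)
  frac <- fractional_filterbank(frcc_config(alpha = pi / 2), 128, 8000)
  expect_lt(max(abs(frac - std)), 1e-12)
  b1 <- fractional_filterbank(frcc_config(alpha = pi / 6), 128, 8000)
  b2 <- fractional_filterbank(frcc_config(alpha = 5 * pi / 6), 128, 8000)
  expect_identical(b1, b2)
  expect_error(frcc_config(alpha = 0), class = "frcc_degenerate_order")
})

test_that("filters are nonnegative with unit peaks and overlapping supports", {
  for (al in c(0.2, 0.5, 0.9) * pi) {
    H <- fractional_filterbank(frcc_config(alpha = al), 128, 8000)
    expect_true(all(H >= 0))
    expect_equal(unname(apply(H, 1, max)), rep(1, 24))
    for (m in 1:23) {  # adjacent filters share support
      expect_true(any(H[m, ] > 0 & H[m + 1, ] > 0))
    }
  }
})

test_that("FrCC at alpha = pi/2 equals the MFCC reference path", {
  cfg <- frcc_config(alpha = pi / 2)
  withr::with_seed(11, {
    frames <- matrix(rnorm(20 * 160), 20, 160)
  })
  expect_lt(max(abs(frcc:::.frcc_from_frames(frames, cfg, 8000) -
                      mfcc_frames(frames, cfg, 8000))), 1e-8)
  vf <- frame_signal(vowel(150), frame_params())
  expect_lt(max(abs(frcc:::.frcc_from_frames(vf, cfg, 8000) -
                      mfcc_frames(vf, cfg, 8000))), 1e-8)
})

test_that("cepstra are scale-invariant and a zero frame hits the log floor", {
  cfg <- frcc_config(alpha = 0.37 * pi)
  fr <- withr::with_seed(5, rnorm(160))
  c1 <- frcc_frame(fr, cfg, 8000)
  c2 <- frcc_frame(2 * fr, cfg, 8000)
  expect_lt(max(abs(c1 - c2)), 1e-8)   # log shift cancels for n >= 1
  cz <- frcc_frame(rep(0, 160), cfg, 8000)
  expect_lt(max(abs(cz)), 1e-8)        # DCT of a constant log-energy vector
  expect_error(frcc_frame(c(fr[-1], NaN), cfg, 8000), class = "frcc_invalid_input")
})

test_that("delta regression has the documented closed forms", {
  expect_equal(delta_features(matrix(3, 10, 4), 2), matrix(0, 10, 4))
  ramp <- matrix(0.5 * (1:20), ncol = 1)
  d <- delta_features(ramp, 2)
  expect_equal(drop(d[3:18, ]), rep(0.5, 16))  # interior frames see the slope
  expect_equal(delta_features(matrix(1:4, 1, 4), 2), matrix(0, 1, 4))
})

test_that("feature extraction has the stated shape and is deterministic", {
  u <- list(samples = vowel(180, duration = 1), sample_rate = 8000,
            id = "v", label = "normal")
  cfg <- frcc_config(alpha = 0.42 * pi)
  f1 <- extract_features(u, cfg)
  expect_equal(dim(f1$features), c(99, 24))
  f2 <- extract_features(u, cfg)
  expect_identical(f1$features, f2$features)
  # at pi/2 the first 12 columns are the MFCC reference
  fpi <- extract_features(u, frcc_config(alpha = pi / 2))
  p <- frame_params()
  s <- u$samples
  s <- c(s[1], s[-1] - p$preemphasis * s[-length(s)])
  ref <- mfcc_frames(frame_signal(s, p), frcc_config(alpha = pi / 2), 8000)
  expect_lt(max(abs(f1$features[, 1:12] * 0 + fpi$features[, 1:12] - ref)), 1e-8)
  tb <- tibble::as_tibble(fpi)
  expect_equal(nrow(tb), 99)
  expect_equal(ncol(tb), 4 + 24)
})
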
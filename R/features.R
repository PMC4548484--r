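#' Short-time analysis parameters
#'
#' Frame geometry and conditioning for short-time speech analysis.  Defaults
#' follow the recording protocol the package emulates: 8 kHz sampling with
#' 20 ms frames overlapped by 10 ms.  Pre-emphasis and the Hamming taper are
#' the conventional MFCC front-end choices, so that the `alpha = pi/2` branch
#' of the feature extractor is a standard MFCC.
#'
#' @param sample_rate sampling rate in Hz.
#' @param frame_len frame length in seconds.
#' @param hop hop (frame advance) in seconds; the overlap is
#'   `frame_len - hop`.
#' @param window taper name: `"hamming"`, `"hann"` or `"rectangular"`.
#' @param preemphasis first-order pre-emphasis coefficient (0 disables).
#' @return A list of class `frame_params`.
#' @export
frame_params <- function(sample_rate = 8000, frame_len = 0.020, hop = 0.010,
                         window = c("hamming", "hann", "rectangular"),
                         preemphasis = 0.97) {
  window <- match.arg(window)
  if (!(frame_len > hop && hop > 0)) {
    rlang::abort("need frame_len > hop > 0", class = "frcc_invalid_parameter")
  }
  ls <- frame_len * sample_rate
  hs <- hop * sample_rate
  if (abs(ls - round(ls)) > 1e-9 || abs(hs - round(hs)) > 1e-9) {
    rlang::abort("frame_len and hop must be whole sample counts at this rate",
                 class = "frcc_invalid_parameter")
  }
  structure(list(sample_rate = sample_rate, frame_len = frame_len, hop = hop,
                 window = window, preemphasis = preemphasis,
                 frame_samples = as.integer(round(ls)),
                 hop_samples = as.integer(round(hs))),
            class = "frame_params")
}

.window_taper <- function(n, type) {
  k <- seq_len(n) - 1
  switch(type,
    hamming = 0.54 - 0.46 * cos(2 * pi * k / (n - 1)),
    hann = 0.5 - 0.5 * cos(2 * pi * k / (n - 1)),
    rectangular = rep(1, n)
  )
}

#' FrCC extraction configuration
#'
#' @param alpha fractional rotation angle in radians, in `(0, pi)` exclusive
#'   (the endpoints collapse the fractional frequency axis).
#' @param n_ceps number of cepstral coefficients kept (indices `1..n_ceps`;
#'   the order-0 energy term is dropped).
#' @param n_mels number of triangular Mel filters.
#' @param n_fft transform length; frames are zero-padded to this length.
#' @param delta_window half-width of the delta regression window (frames).
#' @param log_floor floor applied to filter energies before the logarithm.
#' @return A list of class `frcc_config`.
#' @export
frcc_config <- function(alpha = pi / 2, n_ceps = 12, n_mels = 24, n_fft = 256,
                        delta_window = 2, log_floor = 1e-10) {
  alpha <- as_alpha(alpha)
  if (!(alpha > 0 && alpha < pi)) {
    rlang::abort("`alpha` must lie strictly inside (0, pi)", class = "frcc_degenerate_order")
  }
  if (n_ceps < 1 || n_ceps > n_mels) {
    rlang::abort("need 1 <= n_ceps <= n_mels", class = "frcc_invalid_parameter")
  }
  if (log_floor <= 0) rlang::abort("`log_floor` must be positive", class = "frcc_invalid_parameter")
  if (n_fft %% 2 != 0) rlang::abort("`n_fft` must be even", class = "frcc_invalid_parameter")
  structure(list(alpha = alpha, n_ceps = as.integer(n_ceps),
                 n_mels = as.integer(n_mels), n_fft = as.integer(n_fft),
                 delta_window = as.integer(delta_window), log_floor = log_floor),
            class = "frcc_config")
}

#' Split a signal into windowed short-time frames
#'
#' Frames of `frame_len` seconds advancing by `hop` seconds; any trailing
#' partial frame is dropped, giving `1 + floor((n - L) / H)` frames for a
#' length-`n` signal with `L` frame samples and `H` hop samples.  Each frame
#' is multiplied by the configured taper.
#'
#' @param samples numeric vector.
#' @param params a [frame_params()] object.
#' @return A numeric matrix with one row per frame.
#' @export
frame_signal <- function(samples, params = frame_params()) {
  L <- params$frame_samples
  H <- params$hop_samples
  n <- length(samples)
  if (n < L) {
    rlang::abort(sprintf("signal too short: %d samples given, at least %d (one %g ms frame) required",
                         n, L, 1000 * params$frame_len),
                 class = "frcc_short_input")
  }
  if (!all(is.finite(samples))) rlang::abort("samples must be finite", class = "frcc_invalid_input")
  nf <- 1L + (n - L) %/% H
  w <- .window_taper(L, params$window)
  starts <- (seq_len(nf) - 1L) * H
  idx <- outer(starts, seq_len(L), `+`)  # nf x L index matrix
  frames <- matrix(samples[idx], nrow = nf, ncol = L)
  frames * rep(w, each = nf)
}

#' Mel mapping of a fractional-domain frequency
#'
#' `mel_of(u) = 1125 * ln(1 + u / 700)`, applied to the fractional-domain
#' frequency `u` (Hz-equivalent); strictly increasing.
#'
#' @param u nonnegative frequency value(s).
#' @return Mel value(s).
#' @export
mel_of <- function(u) {
  if (any(u < 0)) rlang::abort("frequency must be nonnegative", class = "frcc_invalid_parameter")
  1125 * log(1 + u / 700)
}

.mel_inv <- function(m) 700 * (exp(m / 1125) - 1)

## Triangular filterbank with Mel-spaced edges snapped to spectrum bins.
## `u_top` is the frequency of the (hypothetical) bin `n_bins`, i.e. bin i
## (0-based) sits at u_i = i * u_top / n_bins.  Unit peak at the center bin.
.tri_bank <- function(n_mels, n_bins, u_top) {
  edges_mel <- seq(0, mel_of(u_top), length.out = n_mels + 2)
  edges_u <- .mel_inv(edges_mel)
  b <- round(edges_u / u_top * n_bins)
  b[length(b)] <- min(b[length(b)], n_bins - 1)
  for (i in seq.int(2, length(b))) b[i] <- max(b[i], b[i - 1] + 1)  # keep centers distinct
  if (b[length(b)] > n_bins - 1) {
    rlang::abort("too many filters for this spectral resolution", class = "frcc_invalid_parameter")
  }
  H <- matrix(0, n_mels, n_bins)
  bins <- 0:(n_bins - 1)
  for (m in seq_len(n_mels)) {
    lo <- b[m]; ce <- b[m + 1]; hi <- b[m + 2]
    up <- bins > lo & bins <= ce
    dn <- bins > ce & bins < hi
    H[m, up] <- (bins[up] - lo) / (ce - lo)
    H[m, dn] <- (hi - bins[dn]) / (hi - ce)
  }
  H
}

#' Standard Mel filterbank on the linear frequency axis
#'
#' Reference triangular filterbank for the ordinary Fourier spectrum,
#' covering `[0, sample_rate/2]` with Mel-spaced, unit-peak filters.  This is
#' the filterbank of the MFCC reference path and equals the fractional bank
#' at `alpha = pi/2`.
#'
#' @param n_mels number of filters.
#' @param n_bins number of nonnegative-frequency spectrum bins.
#' @param sample_rate sampling rate in Hz.
#' @return An `n_mels x n_bins` nonnegative matrix.
#' @export
mel_filterbank <- function(n_mels, n_bins, sample_rate) {
  .tri_bank(n_mels, n_bins, sample_rate / 2)
}

#' Fractional Mel filterbank
#'
#' Triangular filters on the fractional frequency axis `u = f * sin(alpha)`,
#' with Mel-spaced edges over `(0, (sample_rate/2) * sin(alpha)]`.  Because
#' only `sin(alpha)` enters, orders symmetric about `pi/2` share a bank, and
#' at `alpha = pi/2` the bank coincides with [mel_filterbank()].
#'
#' @param config a [frcc_config()] (supplies `alpha` and `n_mels`).
#' @param n_bins number of nonnegative-`u` spectrum bins.
#' @param sample_rate sampling rate in Hz.
#' @return An `n_mels x n_bins` nonnegative matrix.
#' @export
fractional_filterbank <- function(config, n_bins, sample_rate) {
  sa <- sin(config$alpha)
  if (sa <= .frft_degenerate_tol) {
    rlang::abort("sin(alpha) = 0 collapses the fractional frequency axis",
                 class = "frcc_degenerate_order")
  }
  .tri_bank(config$n_mels, n_bins, sample_rate / 2 * sa)
}

## Type-II DCT basis of the log filter energies, orthonormal over the n_mels
## filters; rows are coefficient indices 1..n_ceps (the 0th term is dropped).
.dct_basis <- function(n_ceps, n_mels) {
  sqrt(2 / n_mels) * cos(pi * outer(seq_len(n_ceps), seq_len(n_mels) - 0.5) / n_mels)
}

## FrCC of windowed frames (rows = frames): FrFT magnitude on the u >= 0
## half-axis, filterbank projection, floored log, truncated DCT.
.frcc_from_frames <- function(frames, config, sample_rate, bank = NULL) {
  nf <- config$n_fft
  n_bins <- nf %/% 2L
  if (ncol(frames) > nf) {
    rlang::abort("frame longer than n_fft", class = "frcc_invalid_parameter")
  }
  if (is.null(bank)) bank <- fractional_filterbank(config, n_bins, sample_rate)
  x <- matrix(0, nf, nrow(frames))
  x[seq_len(ncol(frames)), ] <- t(frames)
  spec <- frft_mat(x, config$alpha)
  mag <- Mod(spec[(n_bins + 1L):nf, , drop = FALSE])  # bins with u >= 0
  energies <- bank %*% mag
  loge <- log(pmax(energies, config$log_floor))
  t(.dct_basis(config$n_ceps, config$n_mels) %*% loge)
}

#' FrCC of a single windowed frame
#'
#' One frame through the fractional cepstral pipeline: FrFT at the configured
#' order, magnitude spectrum on the nonnegative-`u` half-axis, triangular
#' filterbank projection, floored natural log, and an orthonormal type-II DCT
#' truncated to `n_ceps` coefficients (dropping the order-0 term).
#'
#' @param frame numeric vector (already windowed), length at most
#'   `config$n_fft`.
#' @param config a [frcc_config()].
#' @param sample_rate sampling rate in Hz.
#' @param bank optional precomputed filterbank (from
#'   [fractional_filterbank()] with `n_bins = config$n_fft / 2`).
#' @return Numeric vector of `n_ceps` cepstral coefficients.
#' @export
frcc_frame <- function(frame, config, sample_rate, bank = NULL) {
  if (anyNA(frame)) rlang::abort("NaN in frame", class = "frcc_invalid_input")
  if (!is.null(bank) && ncol(bank) != config$n_fft %/% 2L) {
    rlang::abort("filterbank resolution does not match n_fft", class = "frcc_invalid_parameter")
  }
  drop(.frcc_from_frames(matrix(frame, nrow = 1), config, sample_rate, bank))
}

## Reference MFCC path: ordinary DFT magnitude + standard Mel bank + same
## floored-log/DCT cepstra.  Kept separate from the FrFT route so the
## alpha = pi/2 identity is a genuine cross-check.
.mfcc_from_frames <- function(frames, config, sample_rate) {
  nf <- config$n_fft
  n_bins <- nf %/% 2L
  x <- matrix(0, nf, nrow(frames))
  x[seq_len(ncol(frames)), ] <- t(frames)
  mag <- Mod(stats::mvfft(x))[seq_len(n_bins), , drop = FALSE]
  bank <- mel_filterbank(config$n_mels, n_bins, sample_rate)
  loge <- log(pmax(bank %*% mag, config$log_floor))
  t(.dct_basis(config$n_ceps, config$n_mels) %*% loge)
}

#' MFCC of windowed frames (reference path)
#'
#' Conventional Mel cepstra computed with the ordinary (fast) Fourier
#' transform and the standard Mel filterbank, using the same floored log and
#' DCT as the fractional path.  FrCC at `alpha = pi/2` equals this output up
#' to the unitary DFT scaling, which only offsets the (dropped) order-0 term.
#'
#' @param frames numeric matrix of windowed frames (rows = frames).
#' @inheritParams frcc_frame
#' @return Matrix of cepstra, one row per frame.
#' @export
mfcc_frames <- function(frames, config, sample_rate) {
  .mfcc_from_frames(frames, config, sample_rate)
}

#' Delta (regression) coefficients
#'
#' First-order temporal regression over a `half_width`-frame window,
#' `delta_t = sum_k k (c_{t+k} - c_{t-k}) / (2 sum_k k^2)`, with edge frames
#' replicated beyond the boundaries.
#'
#' @param coeffs numeric matrix (rows = frames).
#' @param half_width regression half-width in frames (>= 1).
#' @return Matrix of the same shape.
#' @export
delta_features <- function(coeffs, half_width = 2) {
  if (half_width < 1) rlang::abort("half_width must be >= 1", class = "frcc_invalid_parameter")
  coeffs <- as.matrix(coeffs)
  n <- nrow(coeffs)
  denom <- 2 * sum((seq_len(half_width))^2)
  out <- matrix(0, n, ncol(coeffs))
  for (k in seq_len(half_width)) {
    fwd <- pmin(seq_len(n) + k, n)
    bwd <- pmax(seq_len(n) - k, 1)
    out <- out + k * (coeffs[fwd, , drop = FALSE] - coeffs[bwd, , drop = FALSE])
  }
  out / denom
}

#' Extract an FrCC feature sequence from an utterance
#'
#' Full front-end: optional pre-emphasis, short-time framing with taper,
#' FrCC cepstra per frame and their delta coefficients, concatenated into a
#' `T x (2 * n_ceps)` feature matrix.  Deterministic: identical input and
#' configuration give bit-identical output.
#'
#' @param x an utterance (a list with `samples` and `sample_rate`, as
#'   produced by [gen_utterance()] or [read_wav()]) or a bare numeric vector.
#' @param config a [frcc_config()].
#' @param params a [frame_params()]; when `x` carries a sample rate it
#'   overrides `params$sample_rate`.
#' @return An object of class `frcc_features`: list with `features`
#'   (`T x 2*n_ceps` matrix), `alpha`, `label`, `id`, `sample_rate`.
#' @examples
#' u <- gen_cosine(0.2 * pi, n = 8000)
#' f <- extract_features(u, frcc_config(alpha = 0.4 * pi))
#' dim(f$features)
#' @export
extract_features <- function(x, config = frcc_config(), params = frame_params()) {
  if (is.numeric(x)) x <- list(samples = x, sample_rate = params$sample_rate)
  sr <- x$sample_rate %||% params$sample_rate
  if (sr != params$sample_rate) {
    params <- frame_params(sample_rate = sr, frame_len = params$frame_len,
                           hop = params$hop, window = params$window,
                           preemphasis = params$preemphasis)
  }
  s <- x$samples
  if (params$preemphasis > 0) {
    s <- c(s[1], s[-1] - params$preemphasis * s[-length(s)])
  }
  frames <- frame_signal(s, params)
  ceps <- .frcc_from_frames(frames, config, sr)
  feats <- cbind(ceps, delta_features(ceps, config$delta_window))
  colnames(feats) <- c(sprintf("c%02d", seq_len(config$n_ceps)),
                       sprintf("d%02d", seq_len(config$n_ceps)))
  structure(list(features = feats, alpha = config$alpha,
                 label = x$label %||% NA_character_, id = x$id %||% NA_character_,
                 sample_rate = sr),
            class = "frcc_features")
}

#' @method print frcc_features
#' @export
print.frcc_features <- function(x, ...) {
  cat(sprintf("<frcc_features> %d frames x %d coefficients, alpha = %.4f pi, label = %s\n",
              nrow(x$features), ncol(x$features), x$alpha / pi, x$label))
  invisible(x)
}

#' @method as_tibble frcc_features
#' @export
as_tibble.frcc_features <- function(x, ...) {
  out <- tibble::as_tibble(x$features)
  dplyr::bind_cols(
    tibble::tibble(id = x$id, frame = seq_len(nrow(x$features)),
                   alpha = x$alpha, label = x$label),
    out
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
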
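# shared fixtures, all generated in code

rel_l2 <- function(a, b) sqrt(sum(Mod(a - b)^2)) / sqrt(sum(Mod(b)^2))

`%||%` <- function(a, b) if (is.null(a)) b else a

# Gaussian pulse sampled on the dimensionless grid of a given order
gauss_pulse <- function(n, order = pi / 2) exp(-frft_grid(n, order)^2 / 2)

# seeded complex test vector
rand_signal <- function(n, seed = 1) {
  withr::with_seed(seed, complex(real = rnorm(n), imaginary = rnorm(n)))
}

# synthetic vowel: harmonic stack with 1/h amplitudes below 3.6 kHz
vowel <- function(f0, duration = 0.2, fs = 8000) {
  tt <- seq(0, duration - 1 / fs, by = 1 / fs)
  h <- seq_len(floor(3600 / f0))
  colSums((1 / h) * t(sapply(h, function(k) cos(2 * pi * k * f0 * tt + k))))
}

# brute-force Fisher criterion J(w) = (w'(m1-m2))^2 / (w' dw w)
fisher_J <- function(w, x1, x2) {
  m1 <- colMeans(x1); m2 <- colMeans(x2)
  dw <- crossprod(sweep(x1, 2, m1)) + crossprod(sweep(x2, 2, m2))
  drop((sum(w * (m1 - m2)))^2 / (t(w) %*% dw %*% w))
}

# exhaustive-path log-likelihood of a discrete HMM (oracle for forward)
brute_loglik <- function(obs, model) {
  n <- model$n_states
  paths <- as.matrix(expand.grid(rep(list(seq_len(n)), length(obs))))
  p <- apply(paths, 1, function(st) {
    pr <- model$pi[st[1]] * model$B[st[1], obs[1]]
    for (t in seq_along(obs)[-1]) {
      pr <- pr * model$A[st[t - 1], st[t]] * model$B[st[t], obs[t]]
    }
    pr
  })
  list(loglik = log(sum(p)),
       best = paths[which.max(p), ],
       best_logprob = log(max(p)))
}

# tiny corpus settings reused by pipeline tests
tiny_synth <- function(seed, ...) {
  synth_config(n_utts_per_class = 6, utt_duration = 0.4, seed = seed, ...)
}
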
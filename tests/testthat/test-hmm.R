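ref_model <- function() {
  hmm_model(
    A = rbind(c(0.7, 0.2, 0.1), c(0.1, 0.6, 0.3), c(0.3, 0.3, 0.4)),
    B = rbind(c(0.5, 0.2, 0.2, 0.1), c(0.1, 0.4, 0.4, 0.1), c(0.25, 0.25, 0.25, 0.25)),
    pi = c(0.6, 0.3, 0.1)
  )
}

test_that("stochasticity of the model container is validated", {
  expect_error(hmm_model(diag(2), rbind(c(0.5, 0.5), c(0.6, 0.5)), c(0.5, 0.5)),
               class = "frcc_invalid_parameter")
  expect_error(hmm_model(diag(2), diag(2), c(1, 0, 0)), class = "frcc_invalid_parameter")
})

test_that("forward log-likelihood has its single-state and uniform closed forms", {
  m1 <- hmm_model(matrix(1, 1, 1), matrix(c(0.2, 0.3, 0.5), 1), 1)
  obs <- c(1, 3, 3, 2, 1)
  expect_equal(hmm_forward(obs, m1), sum(log(c(0.2, 0.5, 0.5, 0.3, 0.2))))
  mu <- hmm_model(matrix(1 / 3, 3, 3), matrix(1 / 4, 3, 4), rep(1 / 3, 3))
  expect_equal(hmm_forward(c(2, 4, 1, 1, 3, 2), mu), 6 * log(1 / 4))
})

test_that("forward and Viterbi match exhaustive path enumeration", {
  m <- ref_model()
  obs_sets <- list(c(1, 2, 4, 3, 1), c(4, 4, 1, 2, 2), c(3, 1, 1, 1, 4))
  for (obs in obs_sets) {
    oracle <- brute_loglik(obs, m)
    expect_equal(hmm_forward(obs, m), oracle$loglik, tolerance = 1e-10)
    vit <- hmm_viterbi(obs, m)
    expect_equal(vit$logprob, oracle$best_logprob, tolerance = 1e-10)
    expect_equal(vit$path, unname(oracle$best))
    expect_lte(vit$logprob, hmm_forward(obs, m))  # max path <= sum over paths
  }
  expect_error(hmm_forward(c(1, 5), m), class = "frcc_invalid_input")
})

test_that("deterministic transitions force the unique consistent path", {
  A <- rbind(c(0, 1), c(1, 0))        # alternating states
  B <- rbind(c(1, 0), c(0, 1))        # state identifies the symbol
  m <- hmm_model(A, B, c(1, 0))
  v <- hmm_viterbi(c(1, 2, 1, 2, 1), m)
  expect_equal(v$path, c(1, 2, 1, 2, 1))
  expect_equal(v$logprob, 0)
})

test_that("Baum-Welch log-likelihood is monotone on seeded runs", {
  withr::with_seed(3, {
    seqs <- replicate(10, hmm_sample(ref_model(), 40), simplify = FALSE)
  })
  for (sd in c(5, 17)) {
    fit <- hmm_fit(seqs, n_states = 3, n_symbols = 4, seed = sd, max_iter = 25)
    tr <- attr(fit, "loglik_trace")
    expect_true(all(diff(tr) > -1e-8))
    expect_true(all(abs(rowSums(fit$A) - 1) < 1e-10))
    expect_true(all(abs(rowSums(fit$B) - 1) < 1e-10))
  }
})

test_that("max_iter = 0 reproduces the seeded Dirichlet initialization", {
  seqs <- list(c(1, 2, 1), c(2, 2, 1))
  m0 <- hmm_fit(seqs, n_states = 2, n_symbols = 2, seed = 11, max_iter = 0)
  set.seed(11)
  A <- matrix(rexp(4), 2, 2); A <- A / rowSums(A)
  B <- matrix(rexp(4), 2, 2); B <- B / rowSums(B)
  p <- rexp(2); p <- p / sum(p)
  expect_equal(unname(m0$A), A)
  expect_equal(unname(m0$B), B)
  expect_equal(m0$pi, p)
  expect_error(hmm_fit(list(), 2, 2), class = "frcc_invalid_input")
})

test_that("vector quantization recovers separated blobs and handles degeneracies", {
  withr::with_seed(21, {
    centers <- rbind(c(0, 0), c(10, 0), c(0, 10))
    x <- do.call(rbind, lapply(1:3, function(i) {
      sweep(matrix(rnorm(2 * 120, sd = 0.5), ncol = 2), 2, centers[i, ], `+`)
    }))
  })
  cb <- vq_fit(x, K = 3, seed = 2)
  # each true center has a centroid within 3*sigma/sqrt(n/K)
  tol <- 3 * 0.5 / sqrt(120)
  for (i in 1:3) {
    d <- sqrt(rowSums(sweep(cb$centroids, 2, centers[i, ])^2))
    expect_lt(min(d), tol * 3)  # per-coordinate bound, conservative in 2-D
  }
  # K = T: every point its own centroid, zero quantization error
  y <- matrix(seq_len(12), 6, 2)
  cb2 <- vq_fit(y, K = 6, seed = 1)
  sym <- vq_encode(y, cb2)
  expect_equal(sort(sym), 1:6)
  expect_equal(max(abs(y - cb2$centroids[sym, ])), 0)
  # duplicates only: documented duplicate-centroid tie-break
  dup <- matrix(1, 5, 3)
  cb3 <- vq_fit(dup, K = 2, seed = 1)
  expect_equal(nrow(cb3$centroids), 2)
  expect_equal(vq_encode(dup, cb3), rep(1L, 5))  # ties go to the lowest index
  expect_error(vq_fit(dup[1:1, , drop = FALSE], K = 2), class = "frcc_insufficient_data")
})

test_that("maximum-likelihood classification separates well-separated models", {
  m_true <- hmm_model(rbind(c(0.9, 0.1), c(0.1, 0.9)),
                      rbind(c(0.8, 0.1, 0.1), c(0.1, 0.1, 0.8)), c(0.5, 0.5))
  m_lie <- hmm_model(rbind(c(0.5, 0.5), c(0.5, 0.5)),
                     rbind(c(0.1, 0.8, 0.1), c(0.1, 0.8, 0.1)), c(0.5, 0.5))
  cb <- structure(list(centroids = matrix(c(0, 1, 2), 3, 1), K = 3L),
                  class = "frcc_codebook")
  hits <- 0
  for (i in 1:100) {
    obs <- hmm_sample(m_true, 200, seed = 1000 + i)
    feats <- matrix(cb$centroids[obs, ], ncol = 1)
    hits <- hits + (hmm_classify(feats, cb, m_true, m_lie) == "omega1")
  }
  expect_gt(hits / 100, 0.9)
  # exact tie: identical models -> first label
  expect_equal(hmm_classify(matrix(0, 1, 1), cb, m_true, m_true,
                            labels = c("t", "l")), "t")
  # single-frame sequence is valid
  expect_true(hmm_classify(matrix(2, 1, 1), cb, m_true, m_lie) %in%
                c("omega1", "omega2"))
})
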
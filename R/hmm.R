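#' Discrete-observation hidden Markov model
#'
#' Container for an `N`-state HMM over `M` discrete observation symbols:
#' transition matrix `A` (`a_ij = P(x_{t+1} = s_j | x_t = s_i)`), emission
#' matrix `B` (`b_j(k) = P(y_t = o_k | x_t = s_j)`) and initial distribution
#' `pi`.  Rows of `A`, rows of `B` and `pi` must each sum to one.
#'
#' @param A `N x N` transition matrix.
#' @param B `N x M` emission matrix.
#' @param pi length-`N` initial state distribution.
#' @return An object of class `frcc_hmm`.
#' @export
hmm_model <- function(A, B, pi) {
  A <- as.matrix(A); B <- as.matrix(B); pi <- as.numeric(pi)
  n <- nrow(A)
  if (ncol(A) != n || nrow(B) != n || length(pi) != n) {
    rlang::abort("inconsistent HMM dimensions", class = "frcc_invalid_parameter")
  }
  if (any(A < 0) || any(B < 0) || any(pi < 0) ||
      max(abs(rowSums(A) - 1)) > 1e-10 || max(abs(rowSums(B) - 1)) > 1e-10 ||
      abs(sum(pi) - 1) > 1e-10) {
    rlang::abort("A rows, B rows and pi must be stochastic", class = "frcc_invalid_parameter")
  }
  structure(list(A = A, B = B, pi = pi, n_states = n, n_symbols = ncol(B)),
            class = "frcc_hmm")
}

#' @method print frcc_hmm
#' @export
print.frcc_hmm <- function(x, ...) {
  cat(sprintf("<frcc_hmm> %d states, %d symbols\n", x$n_states, x$n_symbols))
  invisible(x)
}

#' @method tidy frcc_hmm
#' @export
tidy.frcc_hmm <- function(x, ...) {
  dplyr::bind_rows(
    tidyr::expand_grid(matrix = "transition", from = seq_len(x$n_states),
                       to = seq_len(x$n_states)) |>
      dplyr::mutate(value = as.vector(t(x$A))),
    tidyr::expand_grid(matrix = "emission", from = seq_len(x$n_states),
                       to = seq_len(x$n_symbols)) |>
      dplyr::mutate(value = as.vector(t(x$B)))
  )
}

#' @method glance frcc_hmm
#' @export
glance.frcc_hmm <- function(x, ...) {
  tibble::tibble(n_states = x$n_states, n_symbols = x$n_symbols,
                 loglik = attr(x, "loglik") %||% NA_real_,
                 iterations = attr(x, "iterations") %||% NA_integer_)
}

.check_obs <- function(obs, m) {
  obs <- as.integer(obs)
  if (length(obs) == 0) rlang::abort("empty observation sequence", class = "frcc_invalid_input")
  if (any(obs < 1L | obs > m)) {
    rlang::abort(sprintf("observation symbols must lie in 1..%d", m), class = "frcc_invalid_input")
  }
  obs
}

## Scaled forward pass.  Returns log P(obs | model) plus the scaled alpha
## matrix and per-step scaling constants (used by Baum-Welch).
.forward_scaled <- function(obs, model) {
  A <- model$A; B <- model$B
  n <- model$n_states; T_ <- length(obs)
  alpha <- matrix(0, n, T_)
  scale <- numeric(T_)
  a <- model$pi * B[, obs[1]]
  scale[1] <- sum(a)
  if (scale[1] == 0) return(list(loglik = -Inf))
  alpha[, 1] <- a / scale[1]
  if (T_ > 1) for (t in 2:T_) {
    a <- drop(crossprod(A, alpha[, t - 1])) * B[, obs[t]]
    scale[t] <- sum(a)
    if (scale[t] == 0) return(list(loglik = -Inf))
    alpha[, t] <- a / scale[t]
  }
  list(loglik = sum(log(scale)), alpha = alpha, scale = scale)
}

.backward_scaled <- function(obs, model, scale) {
  A <- model$A; B <- model$B
  n <- model$n_states; T_ <- length(obs)
  beta <- matrix(0, n, T_)
  beta[, T_] <- 1
  if (T_ > 1) for (t in (T_ - 1):1) {
    beta[, t] <- drop(A %*% (B[, obs[t + 1]] * beta[, t + 1])) / scale[t + 1]
  }
  beta
}

#' Log-likelihood of a symbol sequence under an HMM
#'
#' `log P(obs | model)` by the scaled forward recursion (per-step
#' normalization constants accumulated in log space, avoiding underflow).
#'
#' @param obs integer vector of symbols in `1..n_symbols`.
#' @param model a [hmm_model()].
#' @return A single log-probability (may be `-Inf`).
#' @export
hmm_forward <- function(obs, model) {
  obs <- .check_obs(obs, model$n_symbols)
  .forward_scaled(obs, model)$loglik
}

#' Most likely state path (Viterbi decoding)
#'
#' Maximizes the joint log-probability of states and observations; ties are
#' broken toward the lower state index.
#'
#' @inheritParams hmm_forward
#' @return List with `path` (integer states) and `logprob`.
#' @export
hmm_viterbi <- function(obs, model) {
  obs <- .check_obs(obs, model$n_symbols)
  n <- model$n_states; T_ <- length(obs)
  logA <- log(model$A); logB <- log(model$B)
  d <- log(model$pi) + logB[, obs[1]]
  back <- matrix(0L, n, T_)
  if (T_ > 1) for (t in 2:T_) {
    cand <- d + logA  # cand[i, j] = d_i + log a_ij
    best <- apply(cand, 2, which.max)  # ties -> lowest index
    d <- cand[cbind(best, seq_len(n))] + logB[, obs[t]]
    back[, t] <- best
  }
  path <- integer(T_)
  path[T_] <- which.max(d)
  if (T_ > 1) for (t in T_:2) path[t - 1] <- back[path[t], t]
  list(path = path, logprob = max(d))
}

## Seeded Dirichlet(1) rows: normalized Exp(1) draws.
.dirichlet_rows <- function(n, m) {
  x <- matrix(stats::rexp(n * m), n, m)
  x / rowSums(x)
}

#' Train an HMM by Baum-Welch (EM)
#'
#' Multi-sequence expectation-maximization with per-step scaling.  The total
#' log-likelihood is non-decreasing across iterations (up to numerical
#' slack); training stops when the improvement falls below `tol` or after
#' `max_iter` iterations.  Initialization draws Dirichlet(1) rows for `A`,
#' `B` and `pi` under the given seed, so runs are reproducible;
#' `max_iter = 0` returns the seeded initialization unchanged.
#'
#' @param sequences list of integer symbol vectors (each in `1..n_symbols`).
#' @param n_states number of hidden states.
#' @param n_symbols observation alphabet size.
#' @param seed integer seed for the initialization.
#' @param max_iter iteration cap.
#' @param tol absolute log-likelihood improvement for convergence.
#' @return A `frcc_hmm` with attributes `loglik` (final total log-likelihood),
#'   `loglik_trace` and `iterations`.
#' @export
hmm_fit <- function(sequences, n_states = 3, n_symbols = 4, seed = 1,
                    max_iter = 100, tol = 1e-6) {
  if (!is.list(sequences)) sequences <- list(sequences)
  if (length(sequences) == 0 || any(lengths(sequences) == 0)) {
    rlang::abort("need at least one nonempty sequence", class = "frcc_invalid_input")
  }
  sequences <- lapply(sequences, .check_obs, m = n_symbols)
  old_seed <- .save_rng()
  on.exit(.restore_rng(old_seed))
  set.seed(as.integer(seed))
  model <- hmm_model(.dirichlet_rows(n_states, n_states),
                     .dirichlet_rows(n_states, n_symbols),
                     drop(.dirichlet_rows(1, n_states)))
  trace <- numeric(0)
  it <- 0L
  floor_p <- 1e-12  # keep rows stochastic and strictly positive
  while (it < max_iter) {
    num_A <- matrix(0, n_states, n_states)
    den_A <- numeric(n_states)
    num_B <- matrix(0, n_states, n_symbols)
    den_B <- numeric(n_states)
    num_pi <- numeric(n_states)
    ll <- 0
    for (obs in sequences) {
      fw <- .forward_scaled(obs, model)
      if (!is.finite(fw$loglik)) next
      ll <- ll + fw$loglik
      beta <- .backward_scaled(obs, model, fw$scale)
      gamma <- fw$alpha * beta          # already normalized per column
      gamma <- sweep(gamma, 2, colSums(gamma), "/")
      T_ <- length(obs)
      num_pi <- num_pi + gamma[, 1]
      for (k in seq_len(n_symbols)) {
        sel <- obs == k
        if (any(sel)) num_B[, k] <- num_B[, k] + rowSums(gamma[, sel, drop = FALSE])
      }
      den_B <- den_B + rowSums(gamma)
      if (T_ > 1) {
        for (t in seq_len(T_ - 1)) {
          xi <- model$A * (fw$alpha[, t] %o% (model$B[, obs[t + 1]] * beta[, t + 1])) /
            fw$scale[t + 1]
          xi <- xi / sum(xi)
          num_A <- num_A + xi
        }
        den_A <- den_A + rowSums(gamma[, -T_, drop = FALSE])
      }
    }
    trace <- c(trace, ll)
    A <- pmax(num_A / pmax(den_A, .Machine$double.xmin), floor_p)
    B <- pmax(num_B / pmax(den_B, .Machine$double.xmin), floor_p)
    pi_ <- pmax(num_pi / sum(num_pi), floor_p)
    model <- hmm_model(A / rowSums(A), B / rowSums(B), pi_ / sum(pi_))
    it <- it + 1L
    if (length(trace) > 1 && abs(trace[it] - trace[it - 1]) < tol) break
  }
  final_ll <- sum(vapply(sequences, function(o) .forward_scaled(o, model)$loglik, numeric(1)))
  attr(model, "loglik") <- final_ll
  attr(model, "loglik_trace") <- c(trace, final_ll)
  attr(model, "iterations") <- it
  attr(model, "seed") <- as.integer(seed)
  model
}

#' Sample a symbol sequence from an HMM
#'
#' @param model a [hmm_model()].
#' @param len sequence length.
#' @param seed optional integer seed.
#' @return Integer vector of observation symbols.
#' @export
hmm_sample <- function(model, len, seed = NULL) {
  if (!is.null(seed)) {
    old_seed <- .save_rng()
    on.exit(.restore_rng(old_seed))
    set.seed(as.integer(seed))
  }
  obs <- integer(len)
  s <- sample.int(model$n_states, 1, prob = model$pi)
  for (t in seq_len(len)) {
    obs[t] <- sample.int(model$n_symbols, 1, prob = model$B[s, ])
    if (t < len) s <- sample.int(model$n_states, 1, prob = model$A[s, ])
  }
  obs
}

#' Fit a vector-quantization codebook
#'
#' Seeded k-means centroids over pooled feature vectors, used to discretize
#' continuous feature sequences into HMM observation symbols.  Degenerate
#' inputs with fewer than `K` distinct rows are handled by taking each
#' distinct row as a centroid and recycling centroids to fill the remaining
#' slots (the documented empty-cluster tie-break).
#'
#' @param features `T x d` numeric matrix of pooled feature vectors (`T >= K`).
#' @param K codebook size (>= 2).
#' @param seed integer seed for the k-means initialization.
#' @param max_iter iteration cap for k-means.
#' @return An object of class `frcc_codebook`: list with `centroids`
#'   (`K x d`) and `K`.
#' @export
vq_fit <- function(features, K, seed = 1, max_iter = 50) {
  features <- as.matrix(features)
  if (K < 2) rlang::abort("K must be >= 2", class = "frcc_invalid_parameter")
  if (nrow(features) < K) {
    rlang::abort(sprintf("need at least K = %d rows, got %d", K, nrow(features)),
                 class = "frcc_insufficient_data")
  }
  old_seed <- .save_rng()
  on.exit(.restore_rng(old_seed))
  set.seed(as.integer(seed))
  distinct <- unique(features)
  if (nrow(distinct) < K) {
    reps <- K - nrow(distinct)
    centroids <- rbind(distinct, distinct[rep_len(seq_len(nrow(distinct)), reps), , drop = FALSE])
  } else {
    km <- tryCatch(
      stats::kmeans(features, centers = K, iter.max = max_iter, nstart = 3),
      error = function(e) NULL
    )
    if (is.null(km)) {
      init <- distinct[sample.int(nrow(distinct), K), , drop = FALSE]
      km <- stats::kmeans(features, centers = init, iter.max = max_iter,
                          algorithm = "Lloyd")
    }
    centroids <- km$centers
  }
  rownames(centroids) <- NULL
  structure(list(centroids = unname(as.matrix(centroids)), K = as.integer(K)),
            class = "frcc_codebook")
}

#' Quantize feature vectors against a codebook
#'
#' Nearest-centroid (Euclidean) assignment; ties go to the lowest centroid
#' index.
#'
#' @param features numeric matrix (rows = vectors) or a single vector.
#' @param codebook a [vq_fit()] codebook.
#' @return Integer vector of symbols in `1..K`.
#' @export
vq_encode <- function(features, codebook) {
  x <- if (is.matrix(features)) features else matrix(features, nrow = 1)
  cc <- codebook$centroids
  if (ncol(x) != ncol(cc)) rlang::abort("dimension mismatch", class = "frcc_invalid_input")
  d2 <- outer(rowSums(x^2), rowSums(cc^2), "+") - 2 * x %*% t(cc)
  max.col(-d2, ties.method = "first")
}

#' Classify a feature sequence with a pair of class HMMs
#'
#' Quantizes the feature sequence with the shared codebook and returns the
#' label of the model with the larger forward log-likelihood; an exact tie
#' goes to the first (class-1) model.
#'
#' @param features a `frcc_features` object or a bare feature matrix.
#' @param codebook a [vq_fit()] codebook shared by both models.
#' @param model1 HMM of the first class.
#' @param model2 HMM of the second class.
#' @param labels length-2 character vector of class labels.
#' @return A single label.
#' @export
hmm_classify <- function(features, codebook, model1, model2,
                         labels = c("omega1", "omega2")) {
  if (inherits(features, "frcc_features")) features <- features$features
  if (model1$n_states != model2$n_states || model1$n_symbols != model2$n_symbols) {
    rlang::abort("class models must share N and M", class = "frcc_invalid_parameter")
  }
  obs <- vq_encode(features, codebook)
  if (hmm_forward(obs, model1) >= hmm_forward(obs, model2)) labels[1] else labels[2]
}

## Save/restore the global RNG state so seeded helpers do not perturb the
## caller's random stream.
.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
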
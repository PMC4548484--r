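#' Vector variance ratio of two feature sets
#'
#' Ratio of the summed squared deviations from the respective mean vectors,
#' \deqn{R = \frac{\sum_i \|a_i - \bar a\|^2}{\sum_j \|b_j - \bar b\|^2}.}
#' `R < 1` means the numerator features cluster more tightly around their
#' center than the denominator features.  Used to compare the clustering
#' performance of FrCC (numerator) against MFCC (denominator) per class.
#'
#' @param feat_a,feat_b numeric matrices (rows = vectors, equal column
#'   count; row counts may differ) or `frcc_features` objects.
#' @return A single nonnegative number.
#' @examples
#' a <- matrix(rnorm(40), ncol = 2)
#' variance_ratio(a, a)  # 1
#' @export
variance_ratio <- function(feat_a, feat_b) {
  if (inherits(feat_a, "frcc_features")) feat_a <- feat_a$features
  if (inherits(feat_b, "frcc_features")) feat_b <- feat_b$features
  feat_a <- as.matrix(feat_a); feat_b <- as.matrix(feat_b)
  if (nrow(feat_a) == 0 || nrow(feat_b) == 0) {
    rlang::abort("feature sets must be nonempty", class = "frcc_invalid_input")
  }
  if (ncol(feat_a) != ncol(feat_b)) rlang::abort("dimension mismatch", class = "frcc_invalid_input")
  dev <- function(m) sum(sweep(m, 2, colMeans(m))^2)
  den <- dev(feat_b)
  if (den == 0) {
    rlang::abort("denominator features are all identical (zero variance)",
                 class = "frcc_degenerate_denominator")
  }
  dev(feat_a) / den
}

#' Confusion counts of a binary classifier
#'
#' Tallies true/false positives and negatives, with the stated label taken
#' as the positive class (deceptive speech, by convention).
#'
#' @param truth character vector of true labels.
#' @param pred character vector of predicted labels.
#' @param positive label counted as positive.
#' @return A list of class `frcc_confusion` with fields `tp`, `fp`, `tn`,
#'   `fn` and `positive`.
#' @export
confusion_counts <- function(truth, pred, positive = "deceptive") {
  if (length(truth) != length(pred)) rlang::abort("length mismatch", class = "frcc_invalid_input")
  p <- truth == positive
  structure(list(tp = sum(p & pred == positive), fp = sum(!p & pred == positive),
                 tn = sum(!p & pred != positive), fn = sum(p & pred != positive),
                 positive = positive),
            class = "frcc_confusion")
}

#' @method print frcc_confusion
#' @export
print.frcc_confusion <- function(x, ...) {
  cat(sprintf("<frcc_confusion> tp=%d fp=%d tn=%d fn=%d (positive = %s)\n",
              x$tp, x$fp, x$tn, x$fn, x$positive))
  invisible(x)
}

#' Sensitivity and specificity from confusion counts
#'
#' Sensitivity (true positive rate) `TP / (TP + FN)` and specificity (true
#' negative rate) `TN / (FP + TN)`.
#'
#' @param counts a [confusion_counts()] object, or a list with fields
#'   `tp`, `fp`, `tn`, `fn`.
#' @return Named numeric vector `c(sensitivity, specificity)`, both in
#'   `[0, 1]`.
#' @export
sensitivity_specificity <- function(counts) {
  with(counts, {
    if (tp + fn == 0) rlang::abort("sensitivity undefined: no positive samples (tp + fn = 0)",
                                   class = "frcc_undefined_rate")
    if (fp + tn == 0) rlang::abort("specificity undefined: no negative samples (fp + tn = 0)",
                                   class = "frcc_undefined_rate")
    c(sensitivity = tp / (tp + fn), specificity = tn / (fp + tn))
  })
}

#' @rdname sensitivity_specificity
#' @export
accuracy_of <- function(counts) {
  with(counts, (tp + tn) / (tp + tn + fp + fn))
}

#' Stratified utterance-level train/test split
#'
#' Splits a labeled corpus per class at the utterance level (avoiding
#' train/test leakage between overlapping frames of one recording).  The
#' train share per class is `fraction`, rounded half-down to a whole count
#' and clamped to leave at least one utterance on each side.  Reproducible
#' under `seed`.
#'
#' @param corpus a tibble with a `label` column (one row per utterance).
#' @param fraction train fraction per class.
#' @param seed integer seed.
#' @return List with tibbles `train` and `test`.
#' @export
split_train_test <- function(corpus, fraction = 0.30, seed = 1) {
  counts <- table(corpus$label)
  if (length(counts) < 2 || any(counts < 2)) {
    rlang::abort("need at least 2 utterances in each of two classes",
                 class = "frcc_insufficient_data")
  }
  old_seed <- .save_rng()
  on.exit(.restore_rng(old_seed))
  set.seed(as.integer(seed))
  train_idx <- unlist(lapply(names(counts), function(lb) {
    rows <- which(corpus$label == lb)
    n_train <- min(max(ceiling(fraction * length(rows) - 0.5), 1L), length(rows) - 1L)
    sample(rows, n_train)
  }))
  list(train = corpus[sort(train_idx), , drop = FALSE],
       test = corpus[setdiff(seq_len(nrow(corpus)), train_idx), , drop = FALSE])
}

## Precompute per-utterance windowed frames once (framing does not depend on
## the fractional order, so the angle sweep reuses them across the grid).
.prep_frames <- function(corpus, params) {
  utts <- .corpus_utts(corpus)
  frames <- lapply(utts, function(u) {
    s <- u$samples
    if (params$preemphasis > 0) s <- c(s[1], s[-1] - params$preemphasis * s[-length(s)])
    frame_signal(as.numeric(s), params)
  })
  list(frames = frames, labels = corpus$label, ids = corpus$id)
}

## FrCC + delta features of prepared frames at one order.  All utterances are
## transformed in one batch, then split for the per-utterance deltas.
.features_at_alpha <- function(prep, alpha, config, sample_rate) {
  cfg <- config
  cfg$alpha <- alpha
  big <- do.call(rbind, prep$frames)
  ceps <- .frcc_from_frames(big, cfg, sample_rate)
  sizes <- vapply(prep$frames, nrow, integer(1))
  ends <- cumsum(sizes)
  starts <- ends - sizes + 1
  purrr::map2(starts, ends, function(a, b) {
    cc <- ceps[a:b, , drop = FALSE]
    cbind(cc, delta_features(cc, cfg$delta_window))
  })
}

## Frame-level LDA evaluation at one order.
.eval_lda <- function(train_feats, train_labels, test_feats, test_labels,
                      class_labels) {
  x1 <- do.call(rbind, train_feats[train_labels == class_labels[1]])
  x2 <- do.call(rbind, train_feats[train_labels == class_labels[2]])
  model <- lda_fit(x1, x2, labels = class_labels)
  truth <- rep(test_labels, vapply(test_feats, nrow, integer(1)))
  pred <- lda_decide(lda_project(do.call(rbind, test_feats), model), model)
  cm <- confusion_counts(truth, pred, positive = class_labels[2])
  list(confusion = cm, model = model)
}

## Utterance-level HMM evaluation at one order: shared VQ codebook on pooled
## training frames, one model per class, maximum-likelihood decision.
.eval_hmm <- function(train_feats, train_labels, test_feats, test_labels,
                      class_labels, n_states, n_symbols, seed, max_iter) {
  codebook <- vq_fit(do.call(rbind, train_feats), K = n_symbols, seed = seed)
  seqs <- lapply(train_feats, vq_encode, codebook = codebook)
  m1 <- hmm_fit(seqs[train_labels == class_labels[1]], n_states, n_symbols,
                seed = seed, max_iter = max_iter)
  m2 <- hmm_fit(seqs[train_labels == class_labels[2]], n_states, n_symbols,
                seed = seed + 1L, max_iter = max_iter)
  pred <- vapply(test_feats, hmm_classify, character(1),
                 codebook = codebook, model1 = m1, model2 = m2,
                 labels = class_labels)
  cm <- confusion_counts(test_labels, pred, positive = class_labels[2])
  list(confusion = cm, models = list(m1, m2), codebook = codebook)
}

#' Optimal-order sweep over the fractional angle grid
#'
#' Trains and evaluates the chosen classifier on FrCC features at every
#' order of the grid, under one fixed stratified utterance split, and selects
#' the best order by held-out accuracy.  The default grid is the 99 interior
#' points `0.01*pi, ..., 0.99*pi`.  LDA accuracy is frame-level (each frame
#' vector classified independently); HMM accuracy is utterance-level
#' (maximum forward likelihood over the quantized sequence).  Duplicate grid
#' entries are collapsed to a single evaluation.  Ties on accuracy are broken
#' toward the order closest to `pi/2`, preferring the conventional transform
#' when no gain exists.
#'
#' @param corpus a labeled corpus tibble (see [gen_corpus()]).
#' @param grid numeric vector of orders in `(0, pi)`.
#' @param classifier `"lda"` or `"hmm"`.
#' @param config a [frcc_config()] (its `alpha` is overridden by the grid).
#' @param params a [frame_params()].
#' @param fraction train fraction for [split_train_test()].
#' @param seed integer seed (split, VQ and HMM initialization).
#' @param n_states,n_symbols HMM geometry (HMM back-end only).
#' @param hmm_max_iter Baum-Welch iteration cap (HMM back-end only).
#' @return A tibble of class `frcc_sweep` with columns `alpha`, `accuracy`,
#'   `sensitivity`, `specificity`, and attributes `best_alpha`,
#'   `best_accuracy`, `classifier`, `seed`.
#' @examples
#' corpus <- gen_corpus(synth_config(n_utts_per_class = 4, utt_duration = 0.3))
#' sw <- angle_sweep(corpus, grid = c(0.4, 0.5, 0.6) * pi)
#' attr(sw, "best_alpha") / pi
#' @export
angle_sweep <- function(corpus, grid = seq(0.01, 0.99, by = 0.01) * pi,
                        classifier = c("lda", "hmm"),
                        config = frcc_config(), params = frame_params(),
                        fraction = 0.30, seed = 1,
                        n_states = 3, n_symbols = 4, hmm_max_iter = 30) {
  classifier <- match.arg(classifier)
  grid <- unique(as.numeric(grid))
  if (length(grid) == 0) rlang::abort("empty order grid", class = "frcc_invalid_parameter")
  if (any(grid <= 0 | grid >= pi)) {
    rlang::abort("grid orders must lie strictly inside (0, pi)", class = "frcc_degenerate_order")
  }
  class_labels <- if (all(c("normal", "deceptive") %in% corpus$label)) {
    c("normal", "deceptive")
  } else sort(unique(corpus$label))

  split <- split_train_test(corpus, fraction = fraction, seed = seed)
  sr <- params$sample_rate
  prep_tr <- .prep_frames(split$train, params)
  prep_te <- .prep_frames(split$test, params)

  rows <- purrr::map_dfr(grid, function(a) {
    ftr <- .features_at_alpha(prep_tr, a, config, sr)
    fte <- .features_at_alpha(prep_te, a, config, sr)
    ev <- if (classifier == "lda") {
      .eval_lda(ftr, prep_tr$labels, fte, prep_te$labels, class_labels)
    } else {
      .eval_hmm(ftr, prep_tr$labels, fte, prep_te$labels, class_labels,
                n_states, n_symbols, seed, hmm_max_iter)
    }
    ss <- sensitivity_specificity(ev$confusion)
    tibble::tibble(alpha = a, accuracy = accuracy_of(ev$confusion),
                   sensitivity = ss[["sensitivity"]],
                   specificity = ss[["specificity"]])
  })

  best_acc <- max(rows$accuracy)
  cand <- rows$alpha[rows$accuracy == best_acc]
  best_alpha <- cand[which.min(abs(cand - pi / 2))]

  structure(rows,
            class = c("frcc_sweep", class(rows)),
            best_alpha = best_alpha, best_accuracy = best_acc,
            classifier = classifier, seed = as.integer(seed),
            n_train = nrow(split$train), n_test = nrow(split$test))
}

#' @method glance frcc_sweep
#' @export
glance.frcc_sweep <- function(x, ...) {
  tibble::tibble(best_alpha = attr(x, "best_alpha"),
                 best_accuracy = attr(x, "best_accuracy"),
                 accuracy_at_pi_2 = {
                   i <- which.min(abs(x$alpha - pi / 2))
                   x$accuracy[i]
                 },
                 classifier = attr(x, "classifier"),
                 n_orders = nrow(x))
}

#' @rdname angle_sweep
#' @param object a `frcc_sweep` tibble.
#' @param ... unused.
#' @method autoplot frcc_sweep
#' @export
autoplot.frcc_sweep <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$alpha / pi, y = .data$accuracy)) +
    ggplot2::geom_line(colour = "grey30") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_vline(xintercept = 0.5, linetype = "dashed", colour = "red") +
    ggplot2::geom_vline(xintercept = attr(object, "best_alpha") / pi,
                        linetype = "dotted", colour = "blue") +
    ggplot2::labs(x = expression(alpha / pi), y = "held-out accuracy",
                  title = sprintf("Order sweep (%s back-end): best alpha = %.2f pi",
                                  attr(object, "classifier"),
                                  attr(object, "best_alpha") / pi)) +
    ggplot2::theme_minimal()
}
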
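test_that("variance ratio has its exact closed-form values", {
  withr::with_seed(1, b <- matrix(rnorm(60), 20, 3))
  expect_equal(variance_ratio(b, b), 1)
  ctr <- colMeans(b)
  a <- sweep(sweep(b, 2, ctr), 1, rep(0.5, 20), `*`)
  a <- sweep(a, 2, ctr, `+`)                 # half deviations about the mean
  expect_equal(variance_ratio(a, b), 0.25)
  expect_equal(variance_ratio(matrix(2, 5, 3), b), 0)
  expect_error(variance_ratio(b, matrix(1, 4, 3)), class = "frcc_degenerate_denominator")
  # scale law: scaling deviations by k scales R by k^2
  for (k in c(0.3, 2, 7)) {
    ak <- sweep(sweep(sweep(b, 2, ctr), 1, rep(k, 20), `*`), 2, ctr, `+`)
    expect_equal(variance_ratio(ak, b), k^2)
  }
})

test_that("sensitivity and specificity follow their defining ratios", {
  cm <- list(tp = 9, fn = 1, fp = 2, tn = 8)
  expect_equal(sensitivity_specificity(cm),
               c(sensitivity = 0.9, specificity = 0.8))
  expect_equal(sensitivity_specificity(list(tp = 5, fn = 0, fp = 0, tn = 7)),
               c(sensitivity = 1, specificity = 1))
  expect_error(sensitivity_specificity(list(tp = 0, fn = 0, fp = 1, tn = 1)),
               "sensitivity", class = "frcc_undefined_rate")
  expect_error(sensitivity_specificity(list(tp = 1, fn = 1, fp = 0, tn = 0)),
               "specificity", class = "frcc_undefined_rate")
  cc <- confusion_counts(c("deceptive", "normal", "deceptive"),
                         c("deceptive", "deceptive", "normal"))
  expect_equal(unlist(cc[c("tp", "fp", "tn", "fn")]), c(tp = 1, fp = 1, tn = 0, fn = 1))
  expect_equal(accuracy_of(cc), 1 / 3)
})

test_that("train/test split is stratified, disjoint and seeded", {
  corpus <- tibble::tibble(id = sprintf("u%02d", 1:20),
                           label = rep(c("normal", "deceptive"), each = 10))
  sp <- split_train_test(corpus, fraction = 0.3, seed = 4)
  expect_equal(as.integer(table(sp$train$label)), c(3L, 3L))  # 30% of 10, half-down
  expect_equal(as.integer(table(sp$test$label)), c(7L, 7L))
  expect_length(intersect(sp$train$id, sp$test$id), 0)
  sp2 <- split_train_test(corpus, fraction = 0.3, seed = 4)
  expect_identical(sp$train$id, sp2$train$id)
  sp3 <- split_train_test(corpus, fraction = 0.3, seed = 5)
  expect_false(identical(sp$train$id, sp3$train$id))
  expect_error(split_train_test(corpus[c(1, 11), ], 0.3, 1),
               class = "frcc_insufficient_data")
})

test_that("a singleton grid reproduces the direct MFCC-equivalent evaluation", {
  corpus <- gen_corpus(tiny_synth(8))
  sw <- angle_sweep(corpus, grid = pi / 2, seed = 8)
  expect_equal(nrow(sw), 1)
  expect_equal(attr(sw, "best_alpha"), pi / 2)
  # manual evaluation on the same split
  sp <- split_train_test(corpus, 0.3, seed = 8)
  cfg <- frcc_config(alpha = pi / 2)
  getf <- function(tb) lapply(seq_len(nrow(tb)), function(i) {
    extract_features(list(samples = tb$samples[[i]], sample_rate = 8000),
                     cfg)$features
  })
  ftr <- getf(sp$train); fte <- getf(sp$test)
  m <- lda_fit(do.call(rbind, ftr[sp$train$label == "normal"]),
               do.call(rbind, ftr[sp$train$label == "deceptive"]),
               labels = c("normal", "deceptive"))
  truth <- rep(sp$test$label, vapply(fte, nrow, integer(1)))
  pred <- lda_decide(lda_project(do.call(rbind, fte), m), m)
  expect_equal(sw$accuracy, accuracy_of(confusion_counts(truth, pred)))
})

test_that("duplicate grid entries collapse and ties prefer pi/2", {
  corpus <- gen_corpus(tiny_synth(2))
  sw <- angle_sweep(corpus, grid = c(0.5, 0.5, 0.4, 0.4) * pi, seed = 2)
  expect_equal(nrow(sw), 2)
  expect_error(angle_sweep(corpus, grid = numeric(0)), class = "frcc_invalid_parameter")
  expect_error(angle_sweep(corpus, grid = c(0, 0.5) * pi), class = "frcc_degenerate_order")
  # best accuracy is the profile maximum, hence >= the pi/2 entry
  expect_gte(attr(sw, "best_accuracy"), sw$accuracy[sw$alpha == pi / 2])
})

test_that("sweep summaries and plots carry the profile", {
  corpus <- gen_corpus(tiny_synth(13))
  sw <- angle_sweep(corpus, grid = c(0.45, 0.5) * pi, seed = 13)
  gl <- glance(sw)
  expect_equal(gl$n_orders, 2)
  expect_equal(gl$best_accuracy, max(sw$accuracy))
  expect_s3_class(autoplot(sw), "ggplot")
})
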
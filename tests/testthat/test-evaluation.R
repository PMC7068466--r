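test_that("fold plans partition the corpus with balanced sizes", {
  corpus <- make_corpus(sprintf("note text number %d", 1:20),
                        labels = rep(c("acute_lbp", "other"), c(4, 16)))
  folds <- make_folds(corpus, k = 10, seed = 3)
  sizes <- table(folds$assignments)
  expect_true(all(sizes == 2))  # n=20, k=10
  expect_setequal(names(folds$assignments), corpus$note_id)

  # determinism
  folds2 <- make_folds(corpus, k = 10, seed = 3)
  expect_identical(folds$assignments, folds2$assignments)
  expect_identical(folds$val_sets, folds2$val_sets)

  # validation sets come from the fold's training portion
  for (f in 1:10) {
    test_ids <- names(folds$assignments)[folds$assignments == f]
    expect_length(intersect(folds$val_sets[[f]], test_ids), 0)
  }
  expect_error(make_folds(corpus, k = 30), "exceeds")
})

test_that("stratified folds spread the positives evenly", {
  corpus <- make_corpus(sprintf("text %d body words", 1:100),
                        labels = rep(c("acute_lbp", "other"), c(10, 90)))
  folds <- make_folds(corpus, k = 10, seed = 1)
  y <- manual_labels(corpus)
  pos_per_fold <- vapply(1:10, function(f)
    sum(y[names(folds$assignments)[folds$assignments == f]]), numeric(1))
  expect_true(all(pos_per_fold == 1))
})

test_that("icd10 labels are code-set membership", {
  corpus <- make_corpus(c("a b c", "d e f", "g h i"),
                        icd10 = list(c("M54.5", "E11"), "E11", character(0)))
  expect_equal(unname(icd10_labels(corpus)), c(1, 0, 0))
})

test_that("threshold tuning maximizes F with ties toward the smallest", {
  # perfect separation: every threshold in (0.1, 0.9] yields F = 1;
  # smallest winning grid point is 0.2
  scores <- c(rep(0.9, 5), rep(0.1, 5))
  labels <- rep(c(1, 0), each = 5)
  expect_equal(tune_threshold(scores, labels), 0.2)

  # all scores identical: everything predicted positive at the lowest
  # threshold, F = 2p / (p + 1)
  s2 <- rep(0.5, 10)
  l2 <- rep(c(1, 0), c(3, 7))
  th <- tune_threshold(s2, l2)
  expect_equal(th, 0.1)
  p <- mean(l2)
  expect_equal(unname(binary_metrics(s2, l2, th)["f_score"]), 2 * p / (p + 1))

  expect_equal(tune_threshold(scores, labels, grid = 1.0), 1.0)
})

test_that("metrics match hand-derived values on the worked example", {
  scores <- c(0.9, 0.8, 0.4, 0.2)
  labels <- c(1, 0, 1, 0)
  m <- compute_metrics(scores, labels, threshold = 0.5)
  expect_equal(m$precision, 0.5)
  expect_equal(m$recall, 0.5)
  expect_equal(m$f_score, 0.5)
  expect_equal(m$auc_roc, 0.75)  # 3 of 4 pairs correctly ordered

  # perfect ranking
  mp <- compute_metrics(c(0.9, 0.8, 0.1), c(1, 1, 0), threshold = 0.5)
  expect_equal(unlist(mp[c("precision", "recall", "f_score", "auc_roc",
                           "auc_prc")]),
               c(precision = 1, recall = 1, f_score = 1, auc_roc = 1,
                 auc_prc = 1))

  expect_error(auc_roc(c(0.1, 0.2), c(1, 1)), "both classes")
  expect_error(auc_prc(c(0.1, 0.2), c(0, 0)), "both classes")
})

test_that("random scores give near-chance AUC at large n", {
  with_seed(12, {
    s <- runif(4000)
    l <- rbinom(4000, 1, 0.3)
  })
  expect_lt(abs(auc_roc(s, l) - 0.5), 0.05)
})

test_that("metric implementations agree with pROC on random data", {
  with_seed(77, {
    for (i in 1:5) {
      n <- 50
      s <- round(runif(n), 2)  # ties likely
      l <- rbinom(n, 1, 0.4)
      if (length(unique(l)) < 2) next
      ref <- as.numeric(suppressMessages(
        pROC::auc(pROC::roc(l, s, levels = c(0, 1), direction = "<"))))
      expect_equal(auc_roc(s, l), ref, tolerance = 1e-12)
    }
  })
})

test_that("score distribution report bins and exceedance counts are coherent", {
  scores <- c(0.95, 0.9, 0.85, 0.6, 0.3, 0.1)
  labels <- c(1, 1, 1, 0, 0, 0)
  rep <- score_distribution_report(scores, labels)
  exc <- rep$exceedance
  pos_counts <- exc$acute_lbp
  expect_true(all(diff(pos_counts) <= 0))  # monotone in the threshold
  expect_equal(exc$acute_lbp[exc$threshold == 0.5], 3)  # all positives > 0.5
  expect_equal(sum(rep$histogram$count), length(scores))

  empty <- score_distribution_report(numeric(0), numeric(0))
  expect_equal(nrow(empty$histogram), 0)
})

test_that("benchmark reports are internally consistent and reproducible", {
  corpus <- generate_corpus(synthetic_config(n_notes = 240, seed = 5,
                                             positive_rate = 0.15,
                                             length_log_mean = log(30)))
  proc <- preprocess_corpus(corpus)
  folds <- make_folds(corpus, k = 2, seed = 4)
  models <- list(model_wordsearch(), model_bon_lr())
  bm <- run_benchmark(corpus, models, folds, "manual", processed = proc,
                      min_count = 3, seed = 6)

  # per-fold F equals the harmonic mean of that fold's P and R
  with(bm$report, for (i in seq_along(f_score)) {
    expected <- if (precision[i] + recall[i] == 0) 0 else
      2 * precision[i] * recall[i] / (precision[i] + recall[i])
    expect_equal(f_score[i], expected, tolerance = 1e-12)
  })
  expect_true(all(unlist(bm$report[, 5:9]) >= 0 &
                  unlist(bm$report[, 5:9]) <= 1))

  # every note scored exactly once per model as a test item
  ws_preds <- bm$predictions[bm$predictions$model == "WordSearch", ]
  expect_setequal(ws_preds$note_id, corpus$note_id)
  expect_equal(anyDuplicated(ws_preds$note_id), 0)

  # bit-reproducibility
  bm2 <- run_benchmark(corpus, models, folds, "manual", processed = proc,
                       min_count = 3, seed = 6)
  expect_identical(bm$report, bm2$report)
  expect_identical(bm$predictions$score, bm2$predictions$score)

  # prediction files round-trip
  path <- tempfile(fileext = ".csv")
  write_predictions(bm$predictions, path)
  expect_equal(nrow(read.csv(path)), nrow(bm$predictions))
})

test_that("the ICD-10 baseline score is the silver label itself", {
  corpus <- generate_corpus(synthetic_config(n_notes = 200, seed = 9,
                                             positive_rate = 0.2,
                                             length_log_mean = log(25)))
  proc <- preprocess_corpus(corpus)
  folds <- make_folds(corpus, k = 2, seed = 1)
  bm <- run_benchmark(corpus, list(model_icd10(corpus)), folds, "manual",
                      processed = proc, min_count = 3, seed = 1)
  preds <- bm$predictions
  silver <- icd10_labels(corpus)
  expect_equal(preds$score, unname(silver[preds$note_id]))
})

test_that("subsampling keeps bookkeeping and reduces to the benchmark at 1.0", {
  corpus <- generate_corpus(synthetic_config(n_notes = 200, seed = 13,
                                             positive_rate = 0.15,
                                             length_log_mean = log(25)))
  proc <- preprocess_corpus(corpus)
  folds <- make_folds(corpus, k = 2, seed = 2)
  model <- model_bon_lr()
  sub <- subsample_experiment(corpus, model, c(0.5, 1.0), folds,
                              processed = proc, min_count = 3, seed = 3)
  expect_equal(nrow(sub$rows), 2 * folds$k)  # fractions x folds

  bm <- run_benchmark(corpus, list(model), folds, "manual", processed = proc,
                      min_count = 3, seed = 3)
  full <- sub$rows[sub$rows$fraction == 1, ]
  expect_equal(sort(full$auc_roc), sort(bm$report$auc_roc), tolerance = 1e-12)
})
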
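sw <- default_stopwords()

test_that("n-gram extraction enumerates within-sentence windows", {
  counts <- extract_ngrams(pn(c("low", "back", "pain")), nmax = 2,
                           stopwords = character(0))
  expect_equal(counts[c("low", "back", "pain", "low back", "back pain")],
               setNames(rep(1L, 5),
                        c("low", "back", "pain", "low back", "back pain")))
  expect_equal(length(counts), 5)

  # stop words are removed before n-grams are formed
  all_stop <- extract_ngrams(pn(c("the", "of", "and")), stopwords = sw)
  expect_equal(length(all_stop), 0)
  bridged <- extract_ngrams(pn(c("acute", "the", "pain")), nmax = 2,
                            stopwords = sw)
  expect_true("acute pain" %in% names(bridged))

  # n-grams never cross sentence boundaries
  two <- extract_ngrams(pn(c("a2", "b2"), c("c2")), nmax = 2,
                        stopwords = character(0))
  expect_false("b2 c2" %in% names(two))
})

test_that("idf follows the smoothed closed form", {
  docs <- list(c(g = 1L), c(g = 2L), c(g = 1L))
  space <- fit_feature_space(docs)
  expect_equal(unname(space$idf["g"]), log(4 / 4) + 1)  # in every doc -> 1

  docs2 <- list(c(g = 1L, h = 1L), c(h = 1L), c(h = 2L))
  space2 <- fit_feature_space(docs2)
  expect_equal(unname(space2$idf["g"]), log(2) + 1, tolerance = 1e-12)

  restricted <- fit_feature_space(docs2, lexicon = "h")
  expect_equal(restricted$ngrams, "h")
  expect_error(fit_feature_space(docs2, lexicon = "absent"), "lexicon")
})

test_that("tfidf vectors match the brute-force oracle on a toy corpus", {
  with_seed(31, {
    vocab_pool <- c("acute", "lbp", "pain", "spasm", "acute lbp", "mri")
    corpus_counts <- lapply(1:5, function(i) {
      k <- sample(2:5, 1)
      grams <- sample(vocab_pool, k)
      setNames(sample(1:4, k, replace = TRUE), grams)
    })
    space <- fit_feature_space(corpus_counts)
    for (i in 1:5) {
      mine <- tfidf_vector(corpus_counts[[i]], space)
      oracle <- tfidf_oracle(corpus_counts, space$ngrams, corpus_counts[[i]])
      expect_lt(max(abs(mine - oracle[names(mine)])), 1e-10)
    }
    # matrix form agrees with the vector form
    M <- tfidf_matrix(corpus_counts, space)
    for (i in 1:5)
      expect_lt(max(abs(M[i, ] - tfidf_vector(corpus_counts[[i]], space))),
                1e-12)
  })
})

test_that("tfidf vectors are L2-normalized or zero", {
  space <- fit_feature_space(list(c(a = 1L), c(b = 1L)))
  expect_equal(sum(tfidf_vector(c(a = 2L), space)^2), 1)
  expect_equal(sum(tfidf_vector(setNames(integer(0), character(0)),
                                space)^2), 0)
  v <- tfidf_vector(c(a = 2L), space)
  expect_equal(unname(v["a"]), 1)  # single coordinate normalizes to unit
})

separable_fixture <- function(n = 60, seed = 8) {
  with_seed(seed, {
    pos <- lapply(1:(n / 2), function(i)
      pn(c("acute", "lbp", sample(c("visit", "exam", "note"), 3, TRUE))))
    neg <- lapply(1:(n / 2), function(i)
      pn(sample(c("visit", "exam", "note", "glucose", "knee"), 5, TRUE)))
    list(notes = c(pos, neg), y = rep(c(1, 0), each = n / 2))
  })
}

test_that("LASSO logistic regression separates a planted-phrase fixture", {
  fx <- separable_fixture()
  counts <- lapply(fx$notes, extract_ngrams, nmax = 2,
                   stopwords = character(0))
  space <- fit_feature_space(counts)
  X <- tfidf_matrix(counts, space)
  lm <- train_lasso_lr(X, fx$y, l1_strength = 1e-4)
  scores <- lr_score(lm, X)
  expect_equal(mean((scores >= 0.5) == fx$y), 1)  # training accuracy 1.0

  # planted signal carries nonzero weight
  nz <- names(lm$coefficients)[lm$coefficients > 0]
  expect_true(any(c("acute", "lbp", "acute lbp") %in% nz))

  # huge penalty shrinks everything to the intercept = logit(prevalence)
  lm0 <- train_lasso_lr(X, fx$y, l1_strength = 10)
  expect_true(all(lm0$coefficients == 0))
  expect_equal(unique(round(lr_score(lm0, X), 10)),
               round(mean(fx$y), 10))

  # determinism
  lm2 <- train_lasso_lr(X, fx$y, l1_strength = 1e-4)
  expect_identical(lm$coefficients, lm2$coefficients)

  expect_error(train_lasso_lr(X, rep(1, nrow(X))), "single class")
})

test_that("lr_score is the sigmoid of the linear predictor", {
  m <- structure(list(coefficients = c(a = 0, b = 0), intercept = 0,
                      l1_strength = 1, feature_names = c("a", "b")),
                 class = "linear_model")
  expect_equal(lr_score(m, c(a = 1, b = 1)), 0.5)
  m$intercept <- 2
  expect_equal(lr_score(m, c(a = 0, b = 0)), 1 / (1 + exp(-2)),
               tolerance = 1e-12)
  # monotone in a positive-coefficient feature
  m2 <- structure(list(coefficients = c(a = 1.5, b = 0), intercept = 0,
                       l1_strength = 1, feature_names = c("a", "b")),
                  class = "linear_model")
  s <- vapply(c(0.1, 0.5, 0.9), function(w) lr_score(m2, c(a = w, b = 0)),
              numeric(1))
  expect_true(all(diff(s) > 0))
  expect_error(lr_score(m, c(a = 1)), "mismatch")
})

test_that("lexicon files expand phrases into their constituent n-grams", {
  path <- tempfile()
  writeLines(c("Prescribed muscle relaxant", "acute LBP"), path)
  lex <- read_lexicon(path)
  expect_true(all(c("prescribe muscle relaxant", "muscle relaxant",
                    "acute lbp", "acute", "lbp") %in% lex))

  # the shipped lexicon is nonempty and within the length bound
  shipped <- read_lexicon()
  expect_gt(length(shipped), 50)
  expect_lte(max(lengths(strsplit(shipped, " "))), 5)
})

test_that("linear models serialize with intercept header", {
  fx <- separable_fixture(20)
  counts <- lapply(fx$notes, extract_ngrams, nmax = 1,
                   stopwords = character(0))
  space <- fit_feature_space(counts)
  lm <- train_lasso_lr(tfidf_matrix(counts, space), fx$y, l1_strength = 1e-3)
  path <- tempfile()
  write_linear_model(lm, path)
  lines <- readLines(path)
  expect_match(lines[1], "^#intercept\t")
  expect_equal(length(lines) - 2, sum(lm$coefficients != 0))
})
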
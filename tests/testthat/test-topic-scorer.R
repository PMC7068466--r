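# small two-group corpus with disjoint vocabularies
disjoint_corpus <- function(n_per_group = 25, len = 30, seed = 5) {
  va <- c("spine", "lumbar", "spasm", "sciatica", "strain")
  vb <- c("insulin", "glucose", "diabetes", "metformin", "diet")
  with_seed(seed, c(
    lapply(seq_len(n_per_group), function(i) sample(va, len, replace = TRUE)),
    lapply(seq_len(n_per_group), function(i) sample(vb, len, replace = TRUE))
  ))
}

toy_vocab <- function(tokens_list) {
  build_vocabulary(lapply(tokens_list, function(t) pn(t)), min_count = 1)
}

test_that("LDA separates documents with disjoint vocabularies", {
  toks <- disjoint_corpus()
  vocab <- toy_vocab(toks)
  tm <- fit_lda(toks, vocab, K = 2, seed = 3, n_iter = 100)
  tops <- split(top_topic_words(tm, 5), top_topic_words(tm, 5)$topic_id)
  groups <- lapply(tops, function(g)
    mean(g$word %in% c("spine", "lumbar", "spasm", "sciatica", "strain")))
  # each topic's top words come from exactly one group
  expect_setequal(round(unlist(groups)), c(0, 1))
})

test_that("LDA is reproducible and rows are normalized", {
  toks <- disjoint_corpus(10, 15)
  vocab <- toy_vocab(toks)
  a <- fit_lda(toks, vocab, K = 3, seed = 9, n_iter = 30)
  b <- fit_lda(toks, vocab, K = 3, seed = 9, n_iter = 30)
  expect_identical(a$phi, b$phi)
  expect_equal(rowSums(a$phi), rep(1, 3), tolerance = 1e-8)
  theta <- infer_doc_topics(a, toks[1:5], n_iter = 20, seed = 2)
  expect_equal(rowSums(theta), rep(1, 5), tolerance = 1e-8)
  # K larger than the corpus warns but fits
  expect_warning(fit_lda(toks[1:4], toy_vocab(toks[1:4]), K = 6, seed = 1,
                         n_iter = 10), "exceeds")
})

test_that("keyword relevance follows Bayes rule under the chosen prior", {
  phi <- rbind(c(0.03, 0.97), c(0.01, 0.99))
  tm <- toy_topic_model(phi, c("acute", "filler"))
  r <- rank_topics_for_keywords(tm, "acute", prior = "uniform")
  expect_equal(r$relevance[r$topic_id == 1], 0.75)
  expect_equal(r$relevance[r$topic_id == 2], 0.25)

  # zero-mass case: all keyword mass on topic 2
  phi0 <- rbind(c(0, 0.5, 0.5), c(0.2, 0.4, 0.4))
  tm0 <- toy_topic_model(phi0, c("acute", "x", "y"))
  r0 <- rank_topics_for_keywords(tm0, "acute", prior = "uniform")
  expect_equal(r0$topic_id[1], 2)
  expect_equal(r0$relevance[1], 1)  # one in-vocabulary keyword

  # ranking is invariant to keyword order; OOV keywords warn
  tm2 <- toy_topic_model(rbind(c(0.6, 0.2, 0.2), c(0.1, 0.5, 0.4)),
                         c("acute", "back", "pain"))
  ra <- rank_topics_for_keywords(tm2, c("acute", "back", "pain"))
  rb <- rank_topics_for_keywords(tm2, c("pain", "acute", "back"))
  expect_equal(ra, rb)
  expect_warning(rank_topics_for_keywords(tm2, c("acute", "zzz")), "zzz")
  expect_error(suppressWarnings(rank_topics_for_keywords(tm2, "zzz")),
               "no keyword")
})

test_that("topic retention validates ids and the fallback takes top-m", {
  phi <- rbind(c(0.8, 0.1, 0.1), c(0.1, 0.8, 0.1), c(0.1, 0.1, 0.8))
  tm <- toy_topic_model(phi, c("acute", "b", "c"))
  expect_equal(retain_topics(tm, c(3, 1))$retained, c(1L, 3L))
  expect_error(retain_topics(tm, 4), "out of range")
  expect_error(retain_topics(tm, integer(0)), "non-empty")
  expect_equal(retain_top_topics(tm, 1, keywords = "acute")$retained, 1L)
})

test_that("topic score reads the max retained-topic probability", {
  # deterministic phi: each word belongs to one topic
  phi <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  tm <- toy_topic_model(phi, c("wa", "wb", "wc"))
  doc <- c(rep("wa", 1), rep("wb", 2), rep("wc", 7))
  theta <- infer_doc_topics(tm, list(doc), n_iter = 200, seed = 4)
  # assignments are forced by the 0/1 phi, so theta is exactly the
  # Dirichlet-smoothed count vector (n_k + alpha) / (N + K * alpha)
  expect_equal(as.numeric(theta), (c(1, 2, 7) + 1 / 3) / 11,
               tolerance = 1e-9)

  s_top <- topic_score(retain_topics(tm, 3), list(doc), n_iter = 200, seed = 4)
  expect_equal(s_top, max(theta[, 3]), tolerance = 1e-9)
  s_pair <- topic_score(retain_topics(tm, c(1, 2)), list(doc),
                        n_iter = 200, seed = 4)
  expect_equal(s_pair, max(theta[, 1:2]), tolerance = 1e-9)
  s_all <- topic_score(retain_topics(tm, 1:3), list(doc),
                       n_iter = 200, seed = 4)
  expect_equal(s_all, max(theta), tolerance = 1e-9)

  # enlarging the retained set never decreases any score
  expect_gte(s_all, s_pair)
  expect_gte(s_all, s_top)

  expect_error(topic_score(tm, list(doc)), "retained")
  expect_warning(sc0 <- topic_score(retain_topics(tm, 1), list(character(0)),
                                    seed = 1), "empty")
  expect_equal(sc0, 0)
})

test_that("topic report writes relevance and top words", {
  toks <- disjoint_corpus(10, 15)
  vocab <- toy_vocab(toks)
  tm <- fit_lda(toks, vocab, K = 2, seed = 3, n_iter = 30)
  path <- tempfile(fileext = ".tsv")
  write_topic_report(tm, path, n = 5, keywords = c("spine", "lumbar"))
  tab <- read.delim(path)
  expect_setequal(unique(tab$topic_id), 1:2)
  expect_equal(nrow(tab), 10)
})
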
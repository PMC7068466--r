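test_that("configuration pins the published architecture defaults", {
  cfg <- convnet_config()
  expect_equal(cfg$embed_dim, 300L)
  expect_equal(cfg$kernel_sizes, 1:5)
  expect_equal(cfg$filters, 200L)
  expect_equal(cfg$fc_sizes, c(600L, 600L))
  expect_equal(cfg$dropout, 0.5)
  expect_equal(cfg$lr, 0.001)
  expect_equal(cfg$epochs, 5L)
  expect_equal(cfg$batch_size, 32L)
  # pooled concatenation length = |kernels| x filters
  expect_equal(length(cfg$kernel_sizes) * cfg$filters, 1000L)
})

test_that("forward pass shapes and ranges hold on a toy network", {
  params <- lbpnotes:::.cn_init(10L, 4L, 1:5, 2L, 6L, 6L, 1L, NULL)
  expect_equal(dim(params$emb), c(11L, 4L))
  expect_true(all(params$emb[1, ] == 0))  # frozen padding row
  att <- lbpnotes:::.cn_attribute(params, c(3L, 5L, 2L, 7L, 1L, 4L))
  expect_equal(length(att$contribution), 10L)  # 5 kernels x 2 filters
  s <- lbpnotes:::.cn_score(params, list(c(3L, 5L), integer(0), 1:8))
  expect_true(all(s > 0 & s < 1))
})

test_that("pooled activation is invariant to signal position within padding", {
  model <- single_path_model()
  # "acute lbp" at the start vs buried among zero-embedding filler
  doc_a <- c("acute", "lbp", "filler", "filler", "filler")
  doc_b <- c("filler", "filler", "acute", "lbp", "filler")
  s <- convnet_score(model, list(doc_a, doc_b))
  expect_equal(s[1], s[2], tolerance = 1e-12)
})

test_that("skip-gram embeddings reflect shared contexts", {
  with_seed(17, {
    ctx <- c("prescribed", "for", "muscle", "spasm")
    sents <- c(
      lapply(1:60, function(i) pn(c(sample(ctx), "flexeril"))),
      lapply(1:60, function(i) pn(c(sample(ctx), "cyclobenzaprine"))),
      lapply(1:60, function(i) pn(sample(c("glucose", "insulin", "diet",
                                           "thyroid", "renal"), 5, TRUE)))
    )
  })
  vocab <- build_vocabulary(sents, min_count = 2)
  emb <- pretrain_embeddings(sents, vocab, dim = 16, epochs = 20, seed = 3)
  expect_equal(dim(emb), c(length(vocab$terms), 16L))
  cos <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  sim_drugs <- cos(emb["flexeril", ], emb["cyclobenzaprine", ])
  sim_bg <- cos(emb["flexeril", ], emb["glucose", ])
  expect_gt(sim_drugs, sim_bg)

  # determinism
  emb2 <- pretrain_embeddings(sents, vocab, dim = 16, epochs = 20, seed = 3)
  expect_identical(emb, emb2)
})

trainable_fixture <- function(n = 300, seed = 21) {
  with_seed(seed, {
    bg <- c("visit", "exam", "glucose", "knee", "thyroid", "renal", "diet",
            "screen", "refill", "stable")
    notes <- lapply(1:n, function(i) sample(bg, 12, replace = TRUE))
    y <- rep(c(1, 0), length.out = n)
    for (i in which(y == 1)) {
      at <- sample(1:8, 1)
      notes[[i]] <- append(notes[[i]], c("acute", "lbp", "flare"), after = at)
    }
    list(tokens = notes, y = y)
  })
}

test_that("training separates planted phrases and is bit-reproducible", {
  fx <- trainable_fixture()
  vocab <- build_vocabulary(lapply(fx$tokens, pn), min_count = 1)
  cfg <- small_convnet_config(seed = 2, embed_dim = 8, filters = 8, fc = 16)
  idx <- 1:200
  test_idx <- 201:300
  m <- train_convnet(fx$tokens[idx], fx$y[idx], vocab, cfg,
                     fx$tokens[test_idx], fx$y[test_idx])
  expect_equal(length(m$val_loss), cfg$epochs)  # exactly config epochs
  s <- convnet_score(m, fx$tokens[test_idx])
  expect_gt(auc_roc(s, fx$y[test_idx]), 0.95)

  m2 <- train_convnet(fx$tokens[idx], fx$y[idx], vocab, cfg,
                      fx$tokens[test_idx], fx$y[test_idx])
  expect_identical(m$params, m2$params)
  expect_identical(m$val_loss, m2$val_loss)

  # label-randomized corpus trains to chance
  ynull <- with_seed(5, sample(fx$y[idx]))
  mnull <- train_convnet(fx$tokens[idx], ynull, vocab, cfg)
  snull <- convnet_score(mnull, fx$tokens[test_idx])
  expect_lt(abs(auc_roc(snull, fx$y[test_idx]) - 0.5), 0.15)

  expect_error(train_convnet(fx$tokens[1:4], rep(1, 4), vocab, cfg),
               "single class")
})

test_that("a single-path network attributes its trigger n-gram first", {
  model <- single_path_model()
  att <- attribute_ngrams(model, c("filler", "acute", "lbp", "filler"),
                          note_id = "t1")
  expect_equal(att$ngram[1], "acute lbp")
  expect_gt(att$contribution[1], 0)

  # occlusion identity on the single unit: contribution equals the full
  # logit shift against the zeroed-pool bias path
  base <- attr(att, "base_logit")
  zeroed <- lbpnotes:::.cn_head_logit(model$params, 0)
  expect_equal(att$contribution[1], base - zeroed, tolerance = 1e-10)
})

test_that("each unit contribution matches the exhaustive occlusion oracle", {
  params <- lbpnotes:::.cn_init(6L, 4L, c(1L, 2L), 3L, 5L, 5L, 7L, NULL)
  doc <- c(2L, 4L, 1L, 6L, 3L)
  att <- lbpnotes:::.cn_attribute(params, doc)
  for (u in seq_along(att$contribution)) {
    occluded <- att$pooled
    occluded[u] <- 0
    oracle <- att$base_logit - lbpnotes:::.cn_head_logit(params, occluded)
    expect_equal(att$contribution[u], oracle, tolerance = 1e-10)
  }
})

test_that("contributions sum close to the total pool-occlusion shift on a
           near-linear 3-filter toy net", {
  # kernels {2}, 3 filters, additive head: logit ~ sum of pooled activations
  params <- list(
    emb = rbind(c(0, 0), c(1, 0), c(0, 1), c(0.5, 0.5)),
    kernel_sizes = 2L,
    conv_w = list(rbind(c(1, 0, 0, 1), c(0, 1, 1, 0), c(0.5, 0.5, 0.5, 0.5))),
    conv_b = list(c(0, 0, 0)),
    w1 = matrix(1, 3, 1), b1 = 0, g1 = 1, be1 = 0, bn1_mean = 0, bn1_var = 1,
    w2 = matrix(1, 1, 1), b2 = 0, g2 = 1, be2 = 0, bn2_mean = 0, bn2_var = 1,
    w_out = 1, b_out = 0)
  doc <- c(2L, 3L, 1L, 3L, 2L)
  att <- lbpnotes:::.cn_attribute(params, doc)
  zero_logit <- lbpnotes:::.cn_head_logit(params, rep(0, 3))
  total_shift <- att$base_logit - zero_logit
  expect_gt(abs(total_shift), 0.5)  # a regime where the shift is meaningful
  expect_lt(abs(sum(att$contribution) - total_shift), 0.25 * abs(total_shift))
})

test_that("empty notes are scored from padding with a flag", {
  model <- single_path_model()
  expect_warning(s <- convnet_score(model, list(character(0))), "empty")
  expect_true(s > 0 && s < 1)
})
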
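#' Fit a latent Dirichlet allocation topic model
#'
#' Collapsed Gibbs sampling with symmetric Dirichlet priors
#' (`alpha = 1/K` on document-topic, `beta = 0.01` on topic-word). The
#' sampler is single-threaded and seeded, so a fixed seed reproduces the
#' topic-word matrix exactly. A held-out fraction of documents can be set
#' aside to report fold-in perplexity in support of choosing `K`.
#'
#' @param corpus_tokens List of token vectors (one per document), already
#'   encoded against a vocabulary.
#' @param vocab The vocabulary the tokens are encoded against.
#' @param K Number of topics (default 200).
#' @param seed Integer seed.
#' @param n_iter Gibbs sweeps (default 150).
#' @param alpha,beta Dirichlet hyperparameters; defaults `1/K` and `0.01`.
#' @param heldout_fraction Fraction of documents held out for the perplexity
#'   report (default 0, i.e. train on everything and report training-set
#'   perplexity).
#' @return A `topic_model`: `list(K, phi, topic_prior, vocab, retained,
#'   perplexity, seed, ...)` where `phi` is the K x V topic-word matrix.
#' @export
fit_lda <- function(corpus_tokens, vocab, K = 200, seed = 1, n_iter = 150,
                    alpha = 1 / K, beta = 0.01, heldout_fraction = 0) {
  stopifnot(length(corpus_tokens) > 0, K >= 2)
  if (K > length(corpus_tokens))
    warning("K = ", K, " exceeds the number of documents (",
            length(corpus_tokens), ")")
  docs <- lapply(corpus_tokens, tokens_to_ids, vocab = vocab)
  keep <- vapply(docs, length, integer(1)) > 0
  train_docs <- docs[keep]
  heldout <- list()
  if (heldout_fraction > 0 && length(train_docs) > 10) {
    n_out <- max(1L, floor(heldout_fraction * length(train_docs)))
    idx <- seeded_sample(length(train_docs), n_out, seed + 7L)
    heldout <- train_docs[idx]
    train_docs <- train_docs[-idx]
  }
  fit <- .lda_gibbs_fit(train_docs, as.integer(K), length(vocab$terms),
                        alpha, beta, as.integer(n_iter), as.integer(seed))
  model <- structure(list(
    K = K, phi = fit$phi, topic_prior = fit$topic_counts / sum(fit$topic_counts),
    vocab = vocab, retained = integer(0), alpha = alpha, beta = beta,
    seed = seed, n_iter = n_iter, perplexity = NA_real_
  ), class = "topic_model")
  eval_docs <- if (length(heldout)) heldout else train_docs
  theta <- .lda_gibbs_infer(model$phi, eval_docs, alpha, 50L, as.integer(seed))
  ll <- 0; nw <- 0
  for (i in seq_along(eval_docs)) {
    p <- theta[i, , drop = TRUE] %*% model$phi[, eval_docs[[i]] + 1L, drop = FALSE]
    ll <- ll + sum(log(pmax(p, 1e-300)))
    nw <- nw + length(eval_docs[[i]])
  }
  model$perplexity <- exp(-ll / max(1, nw))
  model
}

#' Rank topics by relevance to a keyword set
#'
#' Relevance of topic `k` is `sum over keywords w of p(k | w)`, with
#' `p(k | w)` proportional to `p(w | k) p(k)` under either the model's
#' empirical topic prior or a uniform prior. Out-of-vocabulary keywords are
#' skipped with a warning.
#'
#' @param model A `topic_model`.
#' @param keywords Character vector of (preprocessed) keyword tokens; the
#'   default is the acuity keyword set "acute", "low", "back", "pain",
#'   "lbp", "bp".
#' @param prior `"model"` (empirical topic proportions) or `"uniform"`.
#' @return Data frame `(topic_id, relevance)` in descending relevance;
#'   `topic_id` is 1-based.
#' @export
rank_topics_for_keywords <- function(model,
                                     keywords = c("acute", "low", "back",
                                                  "pain", "lbp", "bp"),
                                     prior = c("model", "uniform")) {
  prior <- match.arg(prior)
  in_vocab <- keywords %in% model$vocab$terms
  if (any(!in_vocab))
    warning("keywords not in vocabulary, skipped: ",
            paste(keywords[!in_vocab], collapse = ", "))
  keywords <- keywords[in_vocab]
  if (!length(keywords)) stop("no keyword is in the vocabulary")
  pk <- if (prior == "model") model$topic_prior else rep(1 / model$K, model$K)
  relevance <- rep(0, model$K)
  for (w in keywords) {
    col <- model$vocab$index[[w]] + 1L
    post <- model$phi[, col] * pk
    tot <- sum(post)
    if (tot > 0) relevance <- relevance + post / tot
  }
  out <- data.frame(topic_id = order(-relevance),
                    relevance = sort(relevance, decreasing = TRUE))
  rownames(out) <- NULL
  out
}

#' Record the reviewed (retained) topics
#'
#' The manual topic review is externalized: pass the reviewed topic ids, or
#' use [retain_top_topics()] for the non-interactive top-m fallback.
#'
#' @param model A `topic_model`.
#' @param topic_ids Integer vector of 1-based topic ids to retain.
#' @return The model with `retained` set.
#' @export
retain_topics <- function(model, topic_ids) {
  topic_ids <- as.integer(topic_ids)
  if (!length(topic_ids)) stop("retained topic set must be non-empty")
  if (any(topic_ids < 1 | topic_ids > model$K))
    stop("topic ids out of range 1..", model$K)
  model$retained <- sort(unique(topic_ids))
  model
}

#' Retain the top-m keyword-ranked topics (non-interactive fallback)
#'
#' @param model A `topic_model`.
#' @param m Number of topics to retain.
#' @param keywords,prior Passed to [rank_topics_for_keywords()].
#' @return The model with `retained` set to the `m` most relevant topics.
#' @export
retain_top_topics <- function(model, m = 2,
                              keywords = c("acute", "low", "back", "pain",
                                           "lbp", "bp"),
                              prior = "model") {
  ranking <- rank_topics_for_keywords(model, keywords, prior)
  retain_topics(model, head(ranking$topic_id, m))
}

#' Infer document-topic distributions for new documents
#'
#' Fold-in Gibbs sampling with the fitted topic-word matrix held fixed;
#' counts are averaged over the post-burn-in sweeps.
#'
#' @param model A `topic_model`.
#' @param corpus_tokens List of token vectors.
#' @param n_iter Fold-in sweeps (default 50).
#' @param seed Integer seed.
#' @return Matrix (documents x K) of topic probabilities (rows sum to 1).
#' @export
infer_doc_topics <- function(model, corpus_tokens, n_iter = 50,
                             seed = model$seed) {
  docs <- lapply(corpus_tokens, tokens_to_ids, vocab = model$vocab)
  .lda_gibbs_infer(model$phi, docs, model$alpha, as.integer(n_iter),
                   as.integer(seed))
}

#' TopicModel score of notes
#'
#' The score of a note is the maximum inferred probability among the
#' retained topics — the probability that the note refers to an acute-LBP
#' episode under the reviewed-topic reading.
#'
#' @param model A `topic_model` with a non-empty retained set.
#' @param corpus_tokens List of token vectors (empty notes score 0 with a
#'   warning).
#' @param n_iter,seed Passed to [infer_doc_topics()].
#' @return Numeric vector of scores in `[0, 1]`.
#' @export
topic_score <- function(model, corpus_tokens, n_iter = 50, seed = model$seed) {
  if (!length(model$retained)) stop("no retained topics; see retain_topics()")
  empty <- vapply(corpus_tokens, function(x)
    length(tokens_to_ids(x, model$vocab)) == 0, logical(1))
  if (any(empty)) warning(sum(empty), " empty note(s) scored 0")
  theta <- infer_doc_topics(model, corpus_tokens, n_iter, seed)
  scores <- apply(theta[, model$retained, drop = FALSE], 1, max)
  scores[empty] <- 0
  scores
}

#' Top words of each topic
#'
#' @param model A `topic_model`.
#' @param n Words per topic (default 20).
#' @param topic_ids Topics to report (default all).
#' @return Data frame `(topic_id, rank, word, probability)`.
#' @export
top_topic_words <- function(model, n = 20, topic_ids = seq_len(model$K)) {
  rows <- lapply(topic_ids, function(k) {
    ord <- order(-model$phi[k, ])[seq_len(min(n, ncol(model$phi)))]
    data.frame(topic_id = k, rank = seq_along(ord),
               word = model$vocab$terms[ord],
               probability = model$phi[k, ord], stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write a topic report TSV
#'
#' One row per (topic, word) with the keyword relevance of the topic and its
#' top words, for manual topic review.
#'
#' @param model A `topic_model`.
#' @param path Output TSV path.
#' @param n Words per topic.
#' @inheritParams rank_topics_for_keywords
#' @return `path`, invisibly.
#' @export
write_topic_report <- function(model, path, n = 20,
                               keywords = c("acute", "low", "back", "pain",
                                            "lbp", "bp")) {
  ranking <- rank_topics_for_keywords(model, keywords)
  words <- top_topic_words(model, n, ranking$topic_id)
  out <- merge(ranking, words, by = "topic_id", sort = FALSE)
  write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

# deterministic sample(n, k) that leaves the caller's RNG state untouched
seeded_sample <- function(n, k, seed) {
  with_seed(seed, sample.int(n, k))
}
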
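#' Model specifications for the benchmark
#'
#' Each model is a `list(name, fit, score)` with
#' `fit(ctx, train_enc, y_train, val_enc, y_val)` and
#' `score(ctx, fitted, enc_notes)`, where `ctx` carries the fold vocabulary,
#' a per-fold cache and the fold seed. [lbp_models()] assembles the standard
#' set compared in the study: WordSearch, TopicModel, BoN-LR, FeatEng-LR and
#' ConvNet.
#'
#' @param topic_k,topic_m Topics fitted and retained by the TopicModel.
#' @param convnet ConvNet configuration ([convnet_config()]).
#' @param lexicon FeatEng n-gram lexicon ([read_lexicon()]).
#' @return Named list of model specifications.
#' @export
lbp_models <- function(topic_k = 20, topic_m = 2,
                       convnet = convnet_config(),
                       lexicon = read_lexicon()) {
  list(
    WordSearch = model_wordsearch(),
    TopicModel = model_topicmodel(K = topic_k, m = topic_m),
    `BoN-LR` = model_bon_lr(),
    `FeatEng-LR` = model_feateng_lr(lexicon = lexicon),
    ConvNet = model_convnet(config = convnet)
  )
}

# shared per-fold n-gram count cache
ngram_counts_cached <- function(ctx, enc_notes, nmax, stopwords) {
  lapply(enc_notes, function(p) {
    key <- p$note_id
    if (!is.null(key) && !is.na(key) && exists(key, ctx$cache))
      return(get(key, ctx$cache))
    counts <- extract_ngrams(p, nmax, stopwords)
    if (!is.null(key) && !is.na(key)) assign(key, counts, ctx$cache)
    counts
  })
}

#' WordSearch model specification
#'
#' Unsupervised: counts non-negated keyword mentions ([wordsearch_score()]);
#' training labels are ignored (the threshold sweep still applies).
#'
#' @param phrases,triggers,window Passed to [wordsearch_score()]; defaults
#'   load the shipped keyword and NegEx configurations once.
#' @return A model specification.
#' @export
model_wordsearch <- function(phrases = default_keywords(),
                             triggers = negex_triggers(), window = 5) {
  list(
    name = "WordSearch",
    fit = function(ctx, train_enc, y_train, val_enc, y_val) NULL,
    score = function(ctx, fitted, enc_notes)
      vapply(enc_notes, wordsearch_score, numeric(1), phrases = phrases,
             triggers = triggers, window = window)
  )
}

#' TopicModel specification
#'
#' Fits LDA on the whole training portion (not only ICD-coded notes), ranks
#' topics against the acuity keywords, retains the reviewed topics (or the
#' top-m fallback) and scores notes by their maximum retained-topic
#' probability.
#'
#' @param K Number of topics.
#' @param m Top-m fallback for the retained set when `retained` is `NULL`.
#' @param retained Optional explicit reviewed topic ids (1-based).
#' @param n_iter,infer_iter Gibbs sweeps for fitting and fold-in inference.
#' @param keywords Acuity keyword tokens.
#' @return A model specification.
#' @export
model_topicmodel <- function(K = 200, m = 2, retained = NULL, n_iter = 120,
                             infer_iter = 40,
                             keywords = c("acute", "low", "back", "pain",
                                          "lbp", "bp")) {
  list(
    name = "TopicModel",
    fit = function(ctx, train_enc, y_train, val_enc, y_val) {
      tm <- fit_lda(flatten_tokens(train_enc), ctx$vocab, K = K,
                    seed = ctx$seed, n_iter = n_iter)
      if (!is.null(retained)) retain_topics(tm, retained)
      else retain_top_topics(tm, m, keywords)
    },
    score = function(ctx, fitted, enc_notes)
      suppressWarnings(topic_score(fitted, flatten_tokens(enc_notes),
                                   n_iter = infer_iter, seed = ctx$seed))
  )
}

#' Bag-of-n-grams LASSO logistic regression specification
#'
#' @param nmax Maximum n-gram length (default 5).
#' @param stopwords Stop-word set (default shipped English list).
#' @param l1_strength Optional fixed penalty; otherwise selected on the
#'   validation split.
#' @return A model specification.
#' @export
model_bon_lr <- function(nmax = 5, stopwords = default_stopwords(),
                         l1_strength = NULL) {
  list(
    name = "BoN-LR",
    fit = function(ctx, train_enc, y_train, val_enc, y_val) {
      counts <- ngram_counts_cached(ctx, train_enc, nmax, stopwords)
      space <- fit_feature_space(counts)
      X <- tfidf_matrix(counts, space)
      Xv <- tfidf_matrix(ngram_counts_cached(ctx, val_enc, nmax, stopwords),
                         space)
      lm <- train_lasso_lr(X, y_train, l1_strength, Xv, y_val,
                           seed = ctx$seed)
      list(space = space, lm = lm)
    },
    score = function(ctx, fitted, enc_notes) {
      X <- tfidf_matrix(ngram_counts_cached(ctx, enc_notes, nmax, stopwords),
                        fitted$space)
      lr_score(fitted$lm, X)
    }
  )
}

#' Feature-engineered (lexicon-restricted) LASSO specification
#'
#' Identical to [model_bon_lr()] but the feature space is restricted to a
#' curated n-gram lexicon.
#'
#' @inheritParams model_bon_lr
#' @param lexicon Character vector of allowed n-grams.
#' @return A model specification.
#' @export
model_feateng_lr <- function(lexicon = read_lexicon(), nmax = 5,
                             stopwords = default_stopwords(),
                             l1_strength = NULL) {
  list(
    name = "FeatEng-LR",
    fit = function(ctx, train_enc, y_train, val_enc, y_val) {
      counts <- ngram_counts_cached(ctx, train_enc, nmax, stopwords)
      space <- fit_feature_space(counts, lexicon = lexicon)
      X <- tfidf_matrix(counts, space)
      Xv <- tfidf_matrix(ngram_counts_cached(ctx, val_enc, nmax, stopwords),
                         space)
      lm <- train_lasso_lr(X, y_train, l1_strength, Xv, y_val,
                           seed = ctx$seed)
      list(space = space, lm = lm)
    },
    score = function(ctx, fitted, enc_notes) {
      X <- tfidf_matrix(ngram_counts_cached(ctx, enc_notes, nmax, stopwords),
                        fitted$space)
      lr_score(fitted$lm, X)
    }
  )
}

#' ConvNet model specification
#'
#' Pretrains skip-gram embeddings on the fold's training notes, then trains
#' the convolutional classifier. The fold seed overrides `config$seed` so
#' folds are independent but reproducible.
#'
#' @param config A [convnet_config()].
#' @param pretrain Pretrain embeddings with skip-gram (default `TRUE`).
#' @param w2v_epochs Skip-gram epochs.
#' @return A model specification.
#' @export
model_convnet <- function(config = convnet_config(), pretrain = TRUE,
                          w2v_epochs = 5) {
  list(
    name = "ConvNet",
    fit = function(ctx, train_enc, y_train, val_enc, y_val) {
      cfg <- config
      cfg$seed <- ctx$seed
      emb <- if (pretrain)
        pretrain_embeddings(train_enc, ctx$vocab, dim = cfg$embed_dim,
                            epochs = w2v_epochs, seed = ctx$seed) else NULL
      train_convnet(flatten_tokens(train_enc), y_train, ctx$vocab, cfg,
                    flatten_tokens(val_enc), y_val, embeddings = emb)
    },
    score = function(ctx, fitted, enc_notes)
      suppressWarnings(convnet_score(fitted, flatten_tokens(enc_notes)))
  )
}

#' ICD-10 baseline specification
#'
#' The "model" that labels a note positive iff the M54.5 code is attached to
#' it; the score is the silver label itself.
#'
#' @param corpus The corpus whose code sets are looked up by note id.
#' @param positive_code Positive ICD-10 code.
#' @return A model specification.
#' @export
model_icd10 <- function(corpus, positive_code = "M54.5") {
  silver <- icd10_labels(corpus, positive_code)
  list(
    name = "ICD-10",
    fit = function(ctx, train_enc, y_train, val_enc, y_val) NULL,
    score = function(ctx, fitted, enc_notes) {
      ids <- vapply(enc_notes, `[[`, character(1), "note_id")
      unname(silver[ids])
    }
  )
}
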
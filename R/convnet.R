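#' ConvNet hyperparameter configuration
#'
#' Defaults follow the reference architecture: 300-dimensional embeddings,
#' parallel 1-D convolutions with kernel sizes 1..5 and 200 filters each
#' (pooled concatenation of length 5 x 200 = 1000), two fully connected
#' layers of size 600 with batch normalization and ReLU, dropout 0.5 on the
#' pooled vector and between the fully connected layers, and training with
#' Adam (learning rate 0.001) on binary cross-entropy for 5 epochs with batch
#' size 32.
#'
#' @param embed_dim Embedding dimension.
#' @param kernel_sizes Convolution kernel sizes.
#' @param filters Filters per kernel size.
#' @param fc_sizes Sizes of the two fully connected layers.
#' @param dropout Dropout rate.
#' @param lr Adam learning rate.
#' @param epochs Training epochs (no early stopping).
#' @param batch_size Mini-batch size.
#' @param seed Integer seed for initialization, shuffling and dropout.
#' @return A `convnet_config` list.
#' @export
convnet_config <- function(embed_dim = 300, kernel_sizes = 1:5, filters = 200,
                           fc_sizes = c(600, 600), dropout = 0.5, lr = 0.001,
                           epochs = 5, batch_size = 32, seed = 1) {
  stopifnot(length(fc_sizes) == 2, all(kernel_sizes >= 1), filters >= 1)
  structure(list(embed_dim = as.integer(embed_dim),
                 kernel_sizes = as.integer(sort(kernel_sizes)),
                 filters = as.integer(filters),
                 fc_sizes = as.integer(fc_sizes), dropout = dropout, lr = lr,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed)), class = "convnet_config")
}

#' Pretrain skip-gram word embeddings on the note corpus
#'
#' Word2vec-style skip-gram with negative sampling, trained only on the
#' provided notes (no external corpus), single-threaded and seeded so a fixed
#' seed gives identical embeddings.
#'
#' @param processed List of encoded `processed_note` objects (sentences are
#'   the context units).
#' @param vocab The vocabulary the notes are encoded against.
#' @param dim Embedding dimension (default 300).
#' @param window Maximum (dynamic) context window (default 5).
#' @param negative Negative samples per positive pair (default 5).
#' @param epochs Passes over the corpus (default 5).
#' @param lr Initial learning rate with linear decay (default 0.025).
#' @param seed Integer seed.
#' @return Matrix (vocabulary size x dim) with vocabulary terms as row names.
#' @export
pretrain_embeddings <- function(processed, vocab, dim = 300, window = 5,
                                negative = 5, epochs = 5, lr = 0.025,
                                seed = 1) {
  stopifnot(length(processed) > 0)
  sentences <- unlist(lapply(processed, function(p)
    lapply(p$sentences, tokens_to_ids, vocab = vocab)), recursive = FALSE)
  sentences <- sentences[vapply(sentences, length, integer(1)) > 1]
  emb <- .sgns_train(sentences, length(vocab$terms), as.integer(dim),
                     as.integer(window), as.integer(negative),
                     as.integer(epochs), lr, as.integer(seed))
  rownames(emb) <- vocab$terms
  emb
}

# flattened 1-based token id sequences (0 is the padding id)
docs_as_ids <- function(tokens_list, vocab) {
  lapply(tokens_list, function(toks) tokens_to_ids(toks, vocab) + 1L)
}

#' Train the ConvNet classifier
#'
#' Minimizes binary cross-entropy with Adam for exactly `config$epochs`
#' epochs (no early stopping); the per-epoch validation loss is recorded.
#' Embeddings are initialized from `embeddings` (typically
#' [pretrain_embeddings()]) and fine-tuned during training; the padding
#' vector stays frozen at zero.
#'
#' @param train_tokens List of token vectors (flattened encoded notes).
#' @param y Binary training labels (both classes required).
#' @param vocab Vocabulary the tokens are encoded against.
#' @param config A [convnet_config()].
#' @param val_tokens,val_y Optional validation split (loss history only).
#' @param embeddings Optional initial embedding matrix (vocabulary x
#'   embed_dim); random initialization when omitted.
#' @return A `convnet_model`: `list(params, vocab, config, train_loss,
#'   val_loss)`.
#' @export
train_convnet <- function(train_tokens, y, vocab, config = convnet_config(),
                          val_tokens = list(), val_y = numeric(0),
                          embeddings = NULL) {
  y <- as.numeric(y)
  if (length(unique(y)) < 2) stop("training labels contain a single class")
  stopifnot(length(train_tokens) == length(y))
  params <- .cn_init(length(vocab$terms), config$embed_dim,
                     config$kernel_sizes, config$filters,
                     config$fc_sizes[1], config$fc_sizes[2], config$seed,
                     embeddings)
  docs <- docs_as_ids(train_tokens, vocab)
  vdocs <- docs_as_ids(val_tokens, vocab)
  fit <- .cn_train(params, docs, y, vdocs, as.numeric(val_y), config$epochs,
                   config$batch_size, config$lr, config$dropout, config$seed)
  structure(list(params = fit$params, vocab = vocab, config = config,
                 train_loss = fit$train_loss, val_loss = fit$val_loss),
            class = "convnet_model")
}

#' Score notes with a trained ConvNet
#'
#' Full forward pass (convolutions, global max-pool, fully connected head
#' with running batch-norm statistics, sigmoid). Notes shorter than the
#' largest kernel — including empty notes, which are flagged with a warning —
#' are padded with the frozen zero embedding.
#'
#' @param model A `convnet_model`.
#' @param tokens_list List of token vectors.
#' @return Scores in `(0, 1)`.
#' @export
convnet_score <- function(model, tokens_list) {
  docs <- docs_as_ids(tokens_list, model$vocab)
  empty <- vapply(docs, length, integer(1)) == 0
  if (any(empty))
    warning(sum(empty), " empty note(s) scored from all-padding input")
  as.numeric(.cn_score(model$params, docs))
}

#' Log-odds n-gram attribution for one note
#'
#' For each max-pool unit, the input window (an n-gram of that kernel's
#' size) that produced the max activation is identified; the unit's
#' contribution is `logit(score) - logit(score with that unit's pooled
#' activation occluded to 0)`. Contributions are summed per distinct n-gram
#' and returned in descending order.
#'
#' @param model A `convnet_model`.
#' @param tokens Token vector of one encoded note.
#' @param note_id Identifier carried on the output rows.
#' @return Data frame `(note_id, ngram, contribution)`, descending
#'   contribution.
#' @export
attribute_ngrams <- function(model, tokens, note_id = NA_character_) {
  doc <- docs_as_ids(list(tokens), model$vocab)[[1]]
  att <- .cn_attribute(model$params, doc)
  padded <- c(doc, rep(0L, max(model$config$kernel_sizes)))
  ngrams <- vapply(seq_along(att$unit_kernel), function(u) {
    k <- att$unit_kernel[u]
    ids <- padded[att$unit_start[u]:(att$unit_start[u] + k - 1)]
    ids <- ids[ids > 0]
    if (!length(ids)) return("<pad>")
    paste(model$vocab$terms[ids], collapse = " ")
  }, character(1))
  agg <- tapply(att$contribution, ngrams, sum)
  out <- data.frame(note_id = note_id, ngram = names(agg),
                    contribution = as.numeric(agg), stringsAsFactors = FALSE)
  out <- out[out$ngram != "<pad>", , drop = FALSE]
  out <- out[order(-out$contribution), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "base_logit") <- att$base_logit
  attr(out, "score") <- att$score
  out
}

#' Aggregate n-gram attributions over notes
#'
#' Per-note attributions are filtered to each note's `top_per_note` n-grams
#' and then averaged over notes, giving a corpus-level ranking of the
#' n-grams that drive positive predictions.
#'
#' @param model A `convnet_model`.
#' @param tokens_list List of encoded token vectors.
#' @param note_ids Optional identifiers.
#' @param top_per_note Per-note filter before averaging (default 10).
#' @return Data frame `(ngram, mean_contribution, n_notes)`, descending.
#' @export
aggregate_attributions <- function(model, tokens_list, note_ids = NULL,
                                   top_per_note = 10) {
  if (is.null(note_ids)) note_ids <- as.character(seq_along(tokens_list))
  per_note <- lapply(seq_along(tokens_list), function(i)
    head(attribute_ngrams(model, tokens_list[[i]], note_ids[i]), top_per_note))
  all <- do.call(rbind, per_note)
  if (is.null(all) || !nrow(all))
    return(data.frame(ngram = character(0), mean_contribution = numeric(0),
                      n_notes = integer(0)))
  agg <- aggregate(contribution ~ ngram, data = all, FUN = mean)
  cnt <- aggregate(note_id ~ ngram, data = all, FUN = length)
  out <- merge(agg, cnt, by = "ngram")
  names(out) <- c("ngram", "mean_contribution", "n_notes")
  out <- out[order(-out$mean_contribution), , drop = FALSE]
  rownames(out) <- NULL
  out
}
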
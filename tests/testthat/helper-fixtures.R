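# Fixture builders shared across test files.

# build a corpus data frame directly from parallel vectors
make_corpus <- function(texts, note_ids = sprintf("n%d", seq_along(texts)),
                        labels = rep("unreviewed", length(texts)),
                        icd10 = rep(list(character(0)), length(texts)),
                        encounter_ids = rep(NA_character_, length(texts)),
                        timestamps = rep(NA_character_, length(texts))) {
  notes <- lapply(seq_along(texts), function(i) list(
    note_id = note_ids[i], encounter_id = encounter_ids[i], text = texts[i],
    icd10 = icd10[[i]], label = labels[i], timestamp = timestamps[i]))
  lbpnotes:::new_corpus(notes, provenance = "test fixture")
}

write_jsonl <- function(records, path = tempfile(fileext = ".jsonl")) {
  writeLines(vapply(records, function(r)
    jsonlite::toJSON(r, auto_unbox = TRUE), character(1)), path)
  path
}

# small processed-note constructor
pn <- function(..., note_id = "n1") {
  structure(list(note_id = note_id, sentences = list(...)),
            class = "processed_note")
}

# a scaled-down ConvNet configuration used throughout the tests: same
# architecture family, narrow layers so CPU training stays in seconds
small_convnet_config <- function(seed = 1, lr = 0.01, dropout = 0.2,
                                 embed_dim = 32, filters = 32, fc = 64) {
  convnet_config(embed_dim = embed_dim, filters = filters,
                 fc_sizes = c(fc, fc), lr = lr, dropout = dropout, seed = seed)
}

# hand-built single-path ConvNet: one kernel of size 2, one filter that fires
# exactly on the token pair ("acute", "lbp"), identity-ish head
single_path_params <- function(out_weight = 1, out_bias = -1) {
  list(
    emb = rbind(c(0, 0),           # padding
                c(1, 0),           # "acute"
                c(0, 1),           # "lbp"
                c(0, 0)),          # "filler" (zero embedding)
    kernel_sizes = 2L,
    conv_w = list(matrix(c(1, 0, 0, 1), nrow = 1)),
    conv_b = list(0),
    w1 = matrix(1, 1, 1), b1 = 0, g1 = 1, be1 = 0,
    bn1_mean = 0, bn1_var = 1,
    w2 = matrix(1, 1, 1), b2 = 0, g2 = 1, be2 = 0,
    bn2_mean = 0, bn2_var = 1,
    w_out = out_weight, b_out = out_bias
  )
}

single_path_vocab <- function() {
  structure(list(terms = c("acute", "lbp", "filler"),
                 index = c(acute = 0L, lbp = 1L, filler = 2L),
                 freq = c(acute = 5L, lbp = 5L, filler = 5L),
                 min_count = 1), class = "vocabulary")
}

single_path_model <- function(...) {
  structure(list(params = single_path_params(...),
                 vocab = single_path_vocab(),
                 config = convnet_config(embed_dim = 2, kernel_sizes = 2,
                                         filters = 1, fc_sizes = c(1, 1))),
            class = "convnet_model")
}

# topic model object with fully specified phi, for read-off tests
toy_topic_model <- function(phi, terms, prior = NULL,
                            retained = integer(0)) {
  structure(list(
    K = nrow(phi), phi = phi,
    topic_prior = if (is.null(prior)) rep(1 / nrow(phi), nrow(phi)) else prior,
    vocab = structure(list(terms = terms,
                           index = setNames(seq_along(terms) - 1L, terms),
                           freq = setNames(rep(5L, length(terms)), terms),
                           min_count = 1), class = "vocabulary"),
    retained = retained, alpha = 1 / nrow(phi), beta = 0.01, seed = 1,
    n_iter = 0, perplexity = NA_real_), class = "topic_model")
}
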
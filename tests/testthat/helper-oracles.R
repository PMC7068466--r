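# Independent brute-force oracles. These deliberately re-derive each quantity
# with the most literal possible algorithm (explicit loops, pair enumeration,
# step integration) so they share no code path with the implementation.

# Levenshtein distance by the full dynamic program
lev_oracle <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  na <- length(ca)
  nb <- length(cb)
  d <- matrix(0, na + 1, nb + 1)
  d[, 1] <- 0:na
  d[1, ] <- 0:nb
  for (i in seq_len(na)) {
    for (j in seq_len(nb)) {
      cost <- if (ca[i] == cb[j]) 0 else 1
      d[i + 1, j + 1] <- min(d[i, j + 1] + 1, d[i + 1, j] + 1, d[i, j] + cost)
    }
  }
  d[na + 1, nb + 1]
}

# precision / recall / F by explicit counting loops
prf_oracle <- function(scores, labels, threshold) {
  tp <- fp <- fn <- 0
  for (i in seq_along(scores)) {
    pred <- scores[i] >= threshold
    if (pred && labels[i] == 1) tp <- tp + 1
    if (pred && labels[i] == 0) fp <- fp + 1
    if (!pred && labels[i] == 1) fn <- fn + 1
  }
  p <- if (tp + fp == 0) 0 else tp / (tp + fp)
  r <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f <- if (p + r == 0) 0 else 2 * p * r / (p + r)
  c(precision = p, recall = r, f_score = f)
}

# AUC-ROC by enumerating all positive/negative pairs (ties count 1/2)
auc_roc_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (sp in pos) for (sn in neg)
    total <- total + if (sp > sn) 1 else if (sp == sn) 0.5 else 0
  total / (length(pos) * length(neg))
}

# AUC-PRC by explicit threshold sweep over distinct scores + step integration
auc_prc_oracle <- function(scores, labels) {
  ths <- sort(unique(scores), decreasing = TRUE)
  n_pos <- sum(labels == 1)
  r_prev <- 0
  area <- 0
  for (t in ths) {
    pred <- scores >= t
    tp <- sum(pred & labels == 1)
    fp <- sum(pred & labels == 0)
    p <- tp / (tp + fp)
    r <- tp / n_pos
    area <- area + (r - r_prev) * p
    r_prev <- r
  }
  area
}

# TF-IDF by the most explicit loop possible
tfidf_oracle <- function(corpus_counts, ngrams, doc_counts) {
  N <- length(corpus_counts)
  idf <- numeric(length(ngrams))
  for (g in seq_along(ngrams)) {
    df <- 0
    for (d in corpus_counts) if (ngrams[g] %in% names(d)) df <- df + 1
    idf[g] <- log((1 + N) / (1 + df)) + 1
  }
  v <- numeric(length(ngrams))
  for (g in seq_along(ngrams)) {
    cnt <- doc_counts[ngrams[g]]
    v[g] <- if (is.na(cnt)) 0 else cnt * idf[g]
  }
  nrm <- sqrt(sum(v^2))
  if (nrm > 0) v <- v / nrm
  setNames(v, ngrams)
}

random_token <- function(len) paste(sample(letters[1:6], len, replace = TRUE),
                                    collapse = "")
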
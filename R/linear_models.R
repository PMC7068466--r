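#' English stop-word list
#'
#' The fixed stop-word list applied before n-gram formation, expanded with
#' the normalized form of each entry so that lemmatized tokens are also
#' filtered.
#'
#' @param path Optional plain-text file (one word per line); defaults to the
#'   list shipped with the package.
#' @return Character vector of stop words.
#' @export
default_stopwords <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "stopwords.txt", package = "lbpnotes")
  words <- readLines(path, warn = FALSE)
  words <- words[nzchar(trimws(words))]
  bare <- gsub("'", "", words)
  unique(c(words, bare, lemmatize_tokens(bare)))
}

#' Extract n-gram counts from a note
#'
#' Stop words are removed first; all contiguous n-grams of length `1..nmax`
#' are then formed within sentences (never across sentence boundaries) and
#' counted.
#'
#' @param note A `processed_note` or a list of token vectors.
#' @param nmax Maximum n-gram length (default 5).
#' @param stopwords Set of terms removed before n-gram formation.
#' @return Named integer vector of n-gram counts (tokens joined by spaces).
#' @export
extract_ngrams <- function(note, nmax = 5, stopwords = default_stopwords()) {
  sentences <- if (inherits(note, "processed_note")) note$sentences else note
  grams <- unlist(lapply(sentences, function(toks) {
    toks <- toks[!toks %in% stopwords]
    nt <- length(toks)
    if (!nt) return(character(0))
    unlist(lapply(seq_len(min(nmax, nt)), function(n) {
      if (n == 1) return(toks)
      starts <- seq_len(nt - n + 1)
      vapply(starts, function(s) paste(toks[s:(s + n - 1)], collapse = " "),
             character(1))
    }))
  }), use.names = FALSE)
  if (!length(grams)) return(setNames(integer(0), character(0)))
  tab <- table(grams)
  setNames(as.integer(tab), names(tab))
}

#' Fit an n-gram feature space with smoothed IDF weights
#'
#' Indexes every n-gram seen in the corpus (bag-of-n-grams mode) or only the
#' intersection with a curated lexicon (feature-engineering mode), and
#' computes `idf(g) = ln((1 + N) / (1 + df(g))) + 1` where `N` is the number
#' of documents and `df` the document frequency.
#'
#' @param corpus_counts List of [extract_ngrams()] results, one per document.
#' @param lexicon Optional character vector of allowed n-grams.
#' @return A `ngram_space`: `list(ngrams, idf, lexicon_mode)`.
#' @export
fit_feature_space <- function(corpus_counts, lexicon = NULL) {
  stopifnot(length(corpus_counts) > 0)
  N <- length(corpus_counts)
  df <- table(unlist(lapply(corpus_counts, names), use.names = FALSE))
  ngrams <- sort(names(df), method = "radix")
  if (!is.null(lexicon)) {
    ngrams <- intersect(ngrams, lexicon)
    if (!length(ngrams))
      stop("lexicon does not intersect the corpus n-grams")
  }
  idf <- log((1 + N) / (1 + as.numeric(df[ngrams]))) + 1
  structure(list(ngrams = ngrams, idf = setNames(idf, ngrams),
                 lexicon_mode = !is.null(lexicon), n_docs = N),
            class = "ngram_space")
}

#' TF-IDF vector of one document
#'
#' `entry(g) = count(g) * idf(g)`, then L2-normalized. N-grams outside the
#' feature space are ignored.
#'
#' @param counts An [extract_ngrams()] result.
#' @param space An [fit_feature_space()] result.
#' @return Named numeric vector over the full feature space (dense; use
#'   [tfidf_matrix()] for corpora).
#' @export
tfidf_vector <- function(counts, space) {
  v <- setNames(numeric(length(space$ngrams)), space$ngrams)
  hit <- intersect(names(counts), space$ngrams)
  v[hit] <- counts[hit] * space$idf[hit]
  nrm <- sqrt(sum(v^2))
  if (nrm > 0) v <- v / nrm
  v
}

#' Sparse TF-IDF matrix of a corpus
#'
#' @param corpus_counts List of [extract_ngrams()] results.
#' @param space An [fit_feature_space()] result.
#' @return A `dgCMatrix` (documents x n-grams), rows L2-normalized.
#' @export
tfidf_matrix <- function(corpus_counts, space) {
  lookup <- setNames(seq_along(space$ngrams), space$ngrams)
  triplets <- lapply(seq_along(corpus_counts), function(i) {
    counts <- corpus_counts[[i]]
    j <- lookup[names(counts)]
    keep <- !is.na(j)
    if (!any(keep)) return(NULL)
    j <- j[keep]
    x <- as.numeric(counts[keep]) * space$idf[j]
    nrm <- sqrt(sum(x^2))
    if (nrm > 0) x <- x / nrm
    cbind(i = i, j = unname(j), x = x)
  })
  trip <- do.call(rbind, triplets)
  if (is.null(trip))
    return(Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                dims = c(length(corpus_counts),
                                         length(space$ngrams)),
                                dimnames = list(NULL, space$ngrams)))
  Matrix::sparseMatrix(i = trip[, "i"], j = trip[, "j"], x = trip[, "x"],
                       dims = c(length(corpus_counts), length(space$ngrams)),
                       dimnames = list(NULL, space$ngrams))
}

#' L1-regularized (LASSO) logistic regression
#'
#' Fits the penalized logistic regression with `glmnet`. When `l1_strength`
#' is not given, a small lambda grid is fitted and the value maximizing the
#' F score on the validation split is retained (falling back to validation
#' AUC-free selection of the smallest lambda when no validation data are
#' supplied).
#'
#' @param X Sparse or dense feature matrix (documents x features).
#' @param y Binary labels (0/1), both classes present.
#' @param l1_strength Optional fixed lambda.
#' @param X_val,y_val Optional validation split used to pick lambda.
#' @param seed Integer seed (fitting is deterministic; the seed only guards
#'   degenerate tie-breaks).
#' @return A `linear_model`: `list(coefficients, intercept, l1_strength,
#'   feature_names)`.
#' @export
train_lasso_lr <- function(X, y, l1_strength = NULL, X_val = NULL,
                           y_val = NULL, seed = 1) {
  y <- as.numeric(y)
  if (length(unique(y)) < 2) stop("training labels contain a single class")
  pad <- ncol(X) < 2
  if (pad) X <- cbind(X, 0)
  fit <- if (is.null(l1_strength)) {
    # data-driven path: from the smallest all-zero lambda down two decades
    glmnet::glmnet(X, y, family = "binomial", alpha = 1, nlambda = 25,
                   lambda.min.ratio = 0.01, standardize = FALSE)
  } else {
    glmnet::glmnet(X, y, family = "binomial", alpha = 1,
                   lambda = l1_strength, standardize = FALSE)
  }
  lambda <- if (!is.null(l1_strength)) {
    l1_strength
  } else if (!is.null(X_val) && !is.null(y_val) &&
             length(unique(y_val)) == 2) {
    Xv <- if (pad) cbind(X_val, 0) else X_val
    preds <- predict(fit, Xv, type = "response")
    f_at <- apply(preds, 2, function(s) {
      th <- tune_threshold(s, y_val)
      m <- binary_metrics(s, y_val, th)
      m[["f_score"]]
    })
    fit$lambda[which.max(f_at)]
  } else {
    min(fit$lambda)
  }
  beta <- as.numeric(predict(fit, s = lambda, type = "coefficients"))
  intercept <- beta[1]
  coefs <- beta[-1]
  if (pad) coefs <- coefs[-length(coefs)]
  feature_names <- colnames(X)[seq_along(coefs)]
  structure(list(coefficients = setNames(coefs, feature_names),
                 intercept = intercept, l1_strength = lambda,
                 feature_names = feature_names),
            class = "linear_model")
}

#' Score documents with a linear model
#'
#' @param model A `linear_model`.
#' @param X Feature matrix (documents x features) or a single named vector
#'   from [tfidf_vector()].
#' @return Sigmoid scores in `(0, 1)`.
#' @export
lr_score <- function(model, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1, dimnames = list(NULL, names(X)))
  if (ncol(X) != length(model$coefficients))
    stop("feature dimension mismatch: model has ",
         length(model$coefficients), ", input has ", ncol(X))
  as.numeric(sigmoid(as.numeric(X %*% model$coefficients) + model$intercept))
}

#' Read a curated n-gram lexicon
#'
#' Each line is a concept phrase; phrases are preprocessed with the note
#' pipeline (including stop-word removal) and expanded into all their
#' contiguous n-grams of length `1..nmax`.
#'
#' @param path Lexicon file; defaults to the small illustrative lexicon of
#'   acute-LBP diagnosis/medication/recommendation phrases shipped with the
#'   package.
#' @param nmax Maximum n-gram length.
#' @param stopwords Stop words removed before n-gram expansion.
#' @param lemmatize Passed to the preprocessing pipeline.
#' @return Character vector of distinct n-grams.
#' @export
read_lexicon <- function(path = NULL, nmax = 5,
                         stopwords = default_stopwords(), lemmatize = TRUE) {
  if (is.null(path))
    path <- system.file("extdata", "feateng_lexicon.txt", package = "lbpnotes")
  phrases <- readLines(path, warn = FALSE)
  phrases <- phrases[nzchar(trimws(phrases))]
  toks <- preprocess_phrases(phrases, lemmatize)
  grams <- unlist(lapply(toks, function(tk)
    names(extract_ngrams(list(tk), nmax, stopwords))), use.names = FALSE)
  sort(unique(grams), method = "radix")
}

#' Serialize a linear model as TSV
#'
#' Writes an intercept header line followed by the nonzero (n-gram,
#' coefficient) pairs.
#'
#' @param model A `linear_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_linear_model <- function(model, path) {
  nz <- model$coefficients[model$coefficients != 0]
  lines <- c(sprintf("#intercept\t%.10g", model$intercept),
             sprintf("#l1_strength\t%.10g", model$l1_strength),
             paste(names(nz), format(nz, digits = 10), sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}
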
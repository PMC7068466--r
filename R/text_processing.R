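#' Clean, sentence-split, tokenize and normalize a note
#'
#' Applies the note preprocessing pipeline: URLs, emails and numeric dates are
#' stripped, the text is lowercased and split into sentences on terminal
#' punctuation and newlines, sentences are tokenized, and punctuation-only or
#' number-leading tokens (including dose strings such as `10mg`) are dropped.
#' Tokens are then normalized with a rule-based English inflectional
#' normalizer (plural / `-ing` / `-ed` stripping with an exception list);
#' set `lemmatize = FALSE` to keep surface forms (lowercased only).
#'
#' @param raw_text A non-empty string.
#' @param note_id Optional note identifier carried on the result.
#' @param lemmatize Normalize inflectional suffixes (default `TRUE`).
#' @return A `processed_note`: `list(note_id, sentences)` where `sentences`
#'   is a list of character token vectors. A note may legitimately produce
#'   zero tokens.
#' @export
clean_and_tokenize <- function(raw_text, note_id = NA_character_,
                               lemmatize = TRUE) {
  stopifnot(is.character(raw_text), length(raw_text) == 1, nzchar(raw_text))
  txt <- tolower(raw_text)
  for (pat in cleaning_patterns()) txt <- gsub(pat, " ", txt, perl = TRUE)
  sents <- strsplit(txt, "[.!?;\n]+")[[1]]
  sentences <- lapply(sents, function(s) {
    toks <- strsplit(s, "[^a-z0-9']+")[[1]]
    toks <- gsub("^'+|'+$", "", toks)
    toks <- toks[nzchar(toks)]
    toks <- toks[grepl("^[a-z]", toks)]          # drops numbers and doses
    if (lemmatize) toks <- lemmatize_tokens(toks)
    toks
  })
  sentences <- sentences[vapply(sentences, length, integer(1)) > 0]
  structure(list(note_id = note_id, sentences = sentences),
            class = "processed_note")
}

#' Cleaning patterns used before tokenization
#'
#' Regular expressions (applied in order, case-insensitively on lowercased
#' text) that remove emails, URLs and date strings before sentence splitting.
#'
#' @return Named character vector of PCRE patterns.
#' @export
cleaning_patterns <- function() {
  c(
    email = "[[:alnum:]._%+-]+@[[:alnum:].-]+\\.[a-z]{2,}",
    url = "(https?://\\S+|www\\.\\S+|\\b[[:alnum:].-]+\\.(com|org|net|edu|gov|io)(/\\S*)?)",
    date_numeric = "\\b\\d{1,4}[/-]\\d{1,2}([/-]\\d{1,4})?\\b",
    date_iso = "\\b\\d{4}-\\d{2}-\\d{2}(t[0-9:.]+z?)?\\b",
    date_month = paste0("\\b(jan|feb|mar|apr|may|jun|jul|aug|sep|oct|nov|dec)",
                        "[a-z]*\\.?\\s+\\d{1,2}(st|nd|rd|th)?,?(\\s+\\d{2,4})?\\b")
  )
}

# Rule-based inflectional normalizer. Deterministic and intentionally
# conservative: it only needs to map inflected variants of the same word to a
# shared form, consistently across notes, keywords and lexica.
lemmatize_tokens <- function(tokens) {
  if (!length(tokens)) return(tokens)
  exceptions <- c(
    was = "be", were = "be", is = "be", are = "be", am = "be", been = "be",
    has = "have", had = "have", having = "have",
    did = "do", does = "do", done = "do",
    went = "go", goes = "go", feet = "foot", teeth = "tooth",
    men = "man", women = "woman", children = "child",
    taken = "take", took = "take", given = "give", gave = "give",
    worse = "bad", worst = "bad", better = "good", best = "good",
    this = "this"
  )
  vapply(tokens, function(tok) {
    if (!is.na(exceptions[tok])) return(unname(exceptions[tok]))
    n <- nchar(tok)
    # plural stripping
    if (endsWith(tok, "ies") && n > 4) {
      tok <- paste0(substr(tok, 1, n - 3), "y")
    } else if (endsWith(tok, "sses") || endsWith(tok, "xes") ||
               endsWith(tok, "ches") || endsWith(tok, "shes") ||
               endsWith(tok, "zes")) {
      tok <- substr(tok, 1, nchar(tok) - 2)
    } else if (endsWith(tok, "s") && !endsWith(tok, "ss") &&
               !endsWith(tok, "us") && !endsWith(tok, "is") && n > 3) {
      tok <- substr(tok, 1, n - 1)
    }
    n <- nchar(tok)
    strip_verb <- function(stem) {
      m <- nchar(stem)
      last <- substr(stem, m, m)
      prev <- if (m > 1) substr(stem, m - 1, m - 1) else ""
      if (m > 2 && last == prev && last != "s")
        stem <- substr(stem, 1, m - 1)               # running -> run
      else if (last %in% c("b", "c", "g", "u", "v", "z"))
        stem <- paste0(stem, "e")                    # prescrib -> prescribe
      stem
    }
    if (endsWith(tok, "ing") && n >= 7) {
      stem <- substr(tok, 1, n - 3)
      if (nchar(stem) >= 4) tok <- strip_verb(stem)
    } else if (endsWith(tok, "ed") && n >= 6) {
      stem <- substr(tok, 1, n - 2)
      if (nchar(stem) >= 4) tok <- strip_verb(stem)
    }
    tok
  }, character(1), USE.NAMES = FALSE)
}

#' Preprocess every note in a corpus
#'
#' @param corpus A corpus data frame.
#' @param lemmatize Passed to [clean_and_tokenize()].
#' @return A named list of `processed_note` objects keyed by `note_id`.
#' @export
preprocess_corpus <- function(corpus, lemmatize = TRUE) {
  out <- lapply(seq_len(nrow(corpus)), function(i)
    clean_and_tokenize(corpus$text[i], corpus$note_id[i], lemmatize))
  names(out) <- corpus$note_id
  out
}

#' Fit the minimum-count vocabulary
#'
#' Keeps every token whose corpus frequency is at least `min_count`, indexed
#' deterministically by descending frequency with lexicographic tie-breaks
#' (indices contiguous from 0).
#'
#' @param processed List of `processed_note` objects (typically the training
#'   portion of a fold).
#' @param min_count Minimum corpus frequency (default 5).
#' @return A `vocabulary`: `list(terms, index, freq, min_count)`.
#' @export
build_vocabulary <- function(processed, min_count = 5) {
  stopifnot(length(processed) > 0, min_count >= 1)
  tokens <- unlist(lapply(processed, function(p) unlist(p$sentences)),
                   use.names = FALSE)
  freq <- table(tokens)
  freq <- freq[freq >= min_count]
  if (!length(freq))
    stop("no term reaches min_count = ", min_count)
  ord <- order(-as.integer(freq), names(freq), method = "radix")
  terms <- names(freq)[ord]
  structure(list(
    terms = terms,
    index = setNames(seq_along(terms) - 1L, terms),
    freq = setNames(as.integer(freq)[ord], terms),
    min_count = min_count,
    source = sprintf("%d notes", length(processed))
  ), class = "vocabulary")
}

#' Correct an out-of-vocabulary token by minimum edit distance
#'
#' An in-vocabulary token is returned unchanged. Otherwise the vocabulary
#' term with the minimum Levenshtein distance is returned, provided the
#' distance does not exceed `max_distance`; ties break toward the higher
#' corpus frequency, then lexicographically. If no term is close enough the
#' token is discarded (`NA`). Set `max_distance = Inf` to always map to the
#' nearest term.
#'
#' @param token A non-empty token.
#' @param vocab A [build_vocabulary()] result.
#' @param max_distance Maximum accepted edit distance (default 2).
#' @return The corrected token, or `NA_character_` for DISCARD.
#' @export
correct_oov <- function(token, vocab, max_distance = 2) {
  stopifnot(nzchar(token))
  if (token %in% vocab$terms) return(token)
  d <- drop(adist(token, vocab$terms))
  md <- min(d)
  if (md > max_distance) return(NA_character_)
  # vocab$terms is ordered by (desc frequency, lexicographic), so the first
  # minimum implements the tie-break
  vocab$terms[which.min(d)]
}

# Correction map for a set of tokens (vectorized adist, with a cheap exact
# length-difference pruning bound).
oov_correction_map <- function(tokens, vocab, max_distance = 2) {
  tokens <- unique(tokens)
  out <- setNames(tokens, tokens)
  inv <- tokens %in% vocab$terms
  oov <- tokens[!inv]
  if (length(oov)) {
    d <- adist(oov, vocab$terms)
    for (i in seq_along(oov)) {
      md <- min(d[i, ])
      out[oov[i]] <- if (is.finite(max_distance) && md > max_distance)
        NA_character_ else vocab$terms[which.min(d[i, ])]
    }
  }
  out
}

#' Map a processed note onto the vocabulary
#'
#' Every token is passed through [correct_oov()]; discarded tokens are
#' dropped, so the result contains only vocabulary members.
#'
#' @param processed A `processed_note`.
#' @param vocab A vocabulary.
#' @param max_distance Passed to [correct_oov()].
#' @return A `processed_note` with corrected, in-vocabulary tokens.
#' @export
encode_note <- function(processed, vocab, max_distance = 2) {
  encode_notes(list(processed), vocab, max_distance)[[1]]
}

#' Map many processed notes onto the vocabulary
#'
#' Same contract as [encode_note()] but corrections for repeated
#' out-of-vocabulary tokens are computed once across the whole set.
#'
#' @param processed A list of `processed_note` objects.
#' @param vocab A vocabulary.
#' @param max_distance Passed to [correct_oov()].
#' @return A list of encoded `processed_note` objects (names preserved).
#' @export
encode_notes <- function(processed, vocab, max_distance = 2) {
  all_tokens <- unique(unlist(lapply(processed, function(p)
    unlist(p$sentences)), use.names = FALSE))
  cmap <- oov_correction_map(all_tokens, vocab, max_distance)
  out <- lapply(processed, function(p) {
    sentences <- lapply(p$sentences, function(s) {
      mapped <- unname(cmap[s])
      mapped[!is.na(mapped)]
    })
    structure(list(note_id = p$note_id, sentences = sentences),
              class = "processed_note")
  })
  names(out) <- names(processed)
  out
}

#' Serialize a vocabulary as two-column TSV
#'
#' @param vocab A vocabulary.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vocabulary <- function(vocab, path) {
  writeLines(paste(vocab$terms, vocab$index, sep = "\t"), path)
  invisible(path)
}

# token vectors (one per note, sentences flattened) for model input
flatten_tokens <- function(processed) {
  lapply(processed, function(p) unlist(p$sentences, use.names = FALSE))
}

# map token strings to 0-based vocabulary ids, dropping unknowns
tokens_to_ids <- function(tokens, vocab) {
  idx <- vocab$index[tokens]
  as.integer(idx[!is.na(idx)])
}
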
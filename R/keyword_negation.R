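#' Acute-LBP keyword phrases
#'
#' The four keyword phrases used by the WordSearch model ("acute low back
#' pain", "acute lbp", "acute low bp", "acute back pain"), preprocessed with
#' the same pipeline as the notes so that matching runs on normalized tokens.
#'
#' @param path Optional plain-text file with one phrase per line; defaults to
#'   the list shipped with the package.
#' @param lemmatize Passed to [clean_and_tokenize()].
#' @return List of token vectors.
#' @export
default_keywords <- function(path = NULL, lemmatize = TRUE) {
  if (is.null(path))
    path <- system.file("extdata", "keywords.txt", package = "lbpnotes")
  phrases <- readLines(path, warn = FALSE)
  phrases <- phrases[nzchar(trimws(phrases))]
  preprocess_phrases(phrases, lemmatize)
}

#' Preprocess raw phrases with the note pipeline
#'
#' @param phrases Character vector of phrases.
#' @param lemmatize Passed to [clean_and_tokenize()].
#' @return List of token vectors (empty phrases dropped).
#' @export
preprocess_phrases <- function(phrases, lemmatize = TRUE) {
  out <- lapply(phrases, function(ph) {
    p <- clean_and_tokenize(ph, lemmatize = lemmatize)
    unlist(p$sentences, use.names = FALSE)
  })
  out[vapply(out, length, integer(1)) > 0]
}

#' NegEx trigger lexicon
#'
#' Pre-negation triggers, post-negation triggers and scope terminators, read
#' from an editable two-column TSV (`pre`/`post`/`term`, phrase) and
#' preprocessed with the note pipeline.
#'
#' @param path Optional TSV path; defaults to the lexicon shipped with the
#'   package.
#' @param lemmatize Passed to [clean_and_tokenize()].
#' @return `list(pre, post, term)`, each a list of token vectors.
#' @export
negex_triggers <- function(path = NULL, lemmatize = TRUE) {
  if (is.null(path))
    path <- system.file("extdata", "negex_triggers.tsv", package = "lbpnotes")
  tab <- read.delim(path, header = FALSE, col.names = c("type", "phrase"),
                    stringsAsFactors = FALSE)
  list(
    pre = preprocess_phrases(tab$phrase[tab$type == "pre"], lemmatize),
    post = preprocess_phrases(tab$phrase[tab$type == "post"], lemmatize),
    term = preprocess_phrases(tab$phrase[tab$type == "term"], lemmatize)
  )
}

# positions (start indices) where phrase occurs in tokens
match_positions <- function(tokens, phrase) {
  np <- length(phrase)
  nt <- length(tokens)
  if (np == 0 || nt < np) return(integer(0))
  hits <- which(tokens == phrase[1])
  hits <- hits[hits + np - 1 <= nt]
  if (np > 1)
    hits <- hits[vapply(hits, function(s)
      all(tokens[s:(s + np - 1)] == phrase), logical(1))]
  hits
}

#' Find keyword mentions in a processed note
#'
#' Every contiguous token-sequence match of a keyword phrase is returned,
#' longest phrase first so that overlapping shorter phrases are suppressed
#' (e.g. "acute low back pain" is reported once, not also as "acute back
#' pain"). Polarity is initially `"affirmed"`.
#'
#' @param note A `processed_note`.
#' @param phrases List of token vectors (see [default_keywords()]).
#' @return Data frame with columns `sentence_index`, `start_token`, `length`,
#'   `phrase`, `polarity`.
#' @export
find_keyword_mentions <- function(note, phrases = default_keywords()) {
  phrases <- phrases[order(-vapply(phrases, length, integer(1)))]
  rows <- list()
  for (si in seq_along(note$sentences)) {
    toks <- note$sentences[[si]]
    used <- logical(length(toks))
    for (ph in phrases) {
      np <- length(ph)
      for (s in match_positions(toks, ph)) {
        span <- s:(s + np - 1)
        if (any(used[span])) next
        used[span] <- TRUE
        rows[[length(rows) + 1]] <- data.frame(
          sentence_index = si, start_token = s, length = np,
          phrase = paste(ph, collapse = " "), polarity = "affirmed",
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows))
    return(data.frame(sentence_index = integer(0), start_token = integer(0),
                      length = integer(0), phrase = character(0),
                      polarity = character(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out[order(out$sentence_index, out$start_token), , drop = FALSE]
}

#' NegEx polarity of one mention
#'
#' A mention is negated iff a pre-negation trigger ends within `window`
#' tokens before it with no scope terminator between trigger and mention, or
#' a post-negation trigger starts within `window` tokens after it (again with
#' no intervening terminator). Otherwise it is affirmed.
#'
#' @param sentence Token vector containing the mention.
#' @param start_token,length Position and token length of the mention.
#' @param triggers A [negex_triggers()] lexicon.
#' @param window Scope window in tokens (default 5).
#' @return `"negated"` or `"affirmed"`.
#' @export
negex_polarity <- function(sentence, start_token, length,
                           triggers = negex_triggers(), window = 5) {
  stopifnot(start_token >= 1, start_token + length - 1 <= base::length(sentence))
  mention_end <- start_token + length - 1

  term_positions <- unlist(lapply(triggers$term, function(tp) {
    pos <- match_positions(sentence, tp)
    if (!base::length(pos)) return(integer(0))
    unlist(lapply(pos, function(s) s:(s + base::length(tp) - 1)))
  }))

  for (tp in triggers$pre) {
    for (s in match_positions(sentence, tp)) {
      t_end <- s + base::length(tp) - 1
      if (t_end >= start_token) next
      if (start_token - t_end > window) next
      between <- if (t_end + 1 <= start_token - 1)
        (t_end + 1):(start_token - 1) else integer(0)
      if (!any(between %in% term_positions)) return("negated")
    }
  }
  for (tp in triggers$post) {
    for (s in match_positions(sentence, tp)) {
      if (s <= mention_end) next
      if (s - mention_end > window) next
      between <- if (mention_end + 1 <= s - 1)
        (mention_end + 1):(s - 1) else integer(0)
      if (!any(between %in% term_positions)) return("negated")
    }
  }
  "affirmed"
}

#' Annotate keyword mentions with negation polarity
#'
#' @inheritParams find_keyword_mentions
#' @inheritParams negex_polarity
#' @return The mention table of [find_keyword_mentions()] with `polarity`
#'   filled in by [negex_polarity()].
#' @export
annotate_mentions <- function(note, phrases = default_keywords(),
                              triggers = negex_triggers(), window = 5) {
  mentions <- find_keyword_mentions(note, phrases)
  if (nrow(mentions)) {
    mentions$polarity <- vapply(seq_len(nrow(mentions)), function(i) {
      negex_polarity(note$sentences[[mentions$sentence_index[i]]],
                     mentions$start_token[i], mentions$length[i],
                     triggers, window)
    }, character(1))
  }
  mentions
}

#' WordSearch score of a note
#'
#' Counts non-negated keyword mentions and squashes the count `c` into a
#' score `1 - exp(-c)` in `[0, 1)`. Any strictly monotone map of the count
#' gives identical rankings (hence identical AUCs); this one is bounded so it
#' composes with the standard threshold sweep.
#'
#' @inheritParams annotate_mentions
#' @return Score in `[0, 1)`; 0 iff no affirmed mention.
#' @export
wordsearch_score <- function(note, phrases = default_keywords(),
                             triggers = negex_triggers(), window = 5) {
  mentions <- annotate_mentions(note, phrases, triggers, window)
  n_affirmed <- sum(mentions$polarity == "affirmed")
  1 - exp(-n_affirmed)
}
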
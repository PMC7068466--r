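#' Read a corpus of clinical notes
#'
#' A corpus is a data frame with one row per note and columns `note_id`,
#' `encounter_id`, `text`, `icd10` (list column of character vectors),
#' `label` (`"acute_lbp"`, `"other"` or `"unreviewed"`) and `timestamp`.
#' Missing optional fields default to an empty code set, an `"unreviewed"`
#' label and `NA` encounter/timestamp. Row order follows the input file, so
#' iteration is deterministic.
#'
#' @param path Path to a JSONL file (one object per line with keys `note_id`,
#'   `encounter_id`, `text`, `icd10`, `label`, `timestamp`) or a CSV file with
#'   the same column names (`icd10` as a `;`-separated string).
#' @param format `"jsonl"` or `"csv"`; guessed from the file extension when
#'   omitted.
#' @return A `lbp_corpus` data frame.
#' @export
load_corpus <- function(path, format = c("auto", "jsonl", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "jsonl"
  }
  if (!file.exists(path)) stop("corpus file not found: ", path)
  if (format == "jsonl") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    recs <- lapply(lines, jsonlite::fromJSON, simplifyVector = TRUE)
  } else {
    df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
    recs <- lapply(seq_len(nrow(df)), function(i) {
      r <- as.list(df[i, , drop = FALSE])
      if (!is.null(r$icd10)) {
        r$icd10 <- strsplit(r$icd10[[1]], ";", fixed = TRUE)[[1]]
        r$icd10 <- r$icd10[nzchar(r$icd10)]
      }
      r
    })
  }
  notes <- lapply(seq_along(recs), function(i) {
    r <- recs[[i]]
    if (is.null(r$note_id) || !nzchar(as.character(r$note_id)[1]))
      stop("record ", i, " is missing note_id")
    if (is.null(r$text) || is.na(r$text[1]) || !nzchar(as.character(r$text)[1]))
      stop("record ", i, " (note_id ", r$note_id, ") has empty text")
    label <- if (is.null(r$label) || !nzchar(as.character(r$label)[1]))
      "unreviewed" else as.character(r$label)[1]
    if (!label %in% c("acute_lbp", "other", "unreviewed"))
      stop("record ", i, ": unknown label '", label, "'")
    codes <- if (is.null(r$icd10)) character(0) else
      unique(as.character(unlist(r$icd10)))
    codes <- codes[!is.na(codes) & nzchar(codes)]
    list(
      note_id = as.character(r$note_id)[1],
      encounter_id = if (is.null(r$encounter_id) ||
                         !nzchar(as.character(r$encounter_id)[1])) NA_character_
                     else as.character(r$encounter_id)[1],
      text = as.character(r$text)[1],
      icd10 = codes,
      label = label,
      timestamp = if (is.null(r$timestamp) ||
                      !nzchar(as.character(r$timestamp)[1])) NA_character_
                  else as.character(r$timestamp)[1]
    )
  })
  corpus <- new_corpus(notes, provenance = path)
  dup <- duplicated(corpus$note_id)
  if (any(dup))
    stop("duplicate note_id: ", paste(unique(corpus$note_id[dup]), collapse = ", "))
  corpus
}

new_corpus <- function(notes, provenance = "in-memory") {
  corpus <- data.frame(
    note_id = vapply(notes, `[[`, character(1), "note_id"),
    encounter_id = vapply(notes, `[[`, character(1), "encounter_id"),
    text = vapply(notes, `[[`, character(1), "text"),
    label = vapply(notes, `[[`, character(1), "label"),
    timestamp = vapply(notes, `[[`, character(1), "timestamp"),
    stringsAsFactors = FALSE
  )
  corpus$icd10 <- lapply(notes, `[[`, "icd10")
  attr(corpus, "provenance") <- provenance
  class(corpus) <- c("lbp_corpus", "data.frame")
  corpus
}

#' Write a corpus to JSONL
#'
#' @param corpus A corpus data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path) {
  lines <- vapply(seq_len(nrow(corpus)), function(i) {
    jsonlite::toJSON(list(
      note_id = corpus$note_id[i],
      encounter_id = corpus$encounter_id[i],
      text = corpus$text[i],
      icd10 = corpus$icd10[[i]],
      label = corpus$label[i],
      timestamp = corpus$timestamp[i]
    ), auto_unbox = TRUE, null = "null", na = "null")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Remove short and duplicate notes
#'
#' Drops notes whose whitespace-tokenized text has fewer than `min_words`
#' tokens, then exact-duplicate texts (after trimming outer whitespace),
#' keeping the first occurrence. An optional list of exclusion regular
#' expressions removes matching notes first.
#'
#' @param corpus A corpus data frame.
#' @param min_words Minimum word count (default 3).
#' @param exclude_patterns Optional character vector of regular expressions;
#'   notes whose text matches any pattern are removed.
#' @return The filtered corpus, with a `filter_counts` attribute reporting
#'   how many notes each rule removed.
#' @export
filter_corpus <- function(corpus, min_words = 3, exclude_patterns = NULL) {
  stopifnot(min_words >= 1)
  n0 <- nrow(corpus)
  n_excluded <- 0L
  if (length(exclude_patterns)) {
    hit <- Reduce(`|`, lapply(exclude_patterns, grepl, x = corpus$text))
    n_excluded <- sum(hit)
    corpus <- corpus[!hit, , drop = FALSE]
  }
  wc <- vapply(strsplit(trimws(corpus$text), "\\s+"), length, integer(1))
  short <- wc < min_words
  corpus <- corpus[!short, , drop = FALSE]
  dup <- duplicated(trimws(corpus$text))
  corpus <- corpus[!dup, , drop = FALSE]
  if (nrow(corpus) == 0)
    stop("filter_corpus removed every note (", n0, " inputs)")
  rownames(corpus) <- NULL
  attr(corpus, "filter_counts") <- c(excluded = n_excluded,
                                     short = sum(short), duplicate = sum(dup))
  class(corpus) <- c("lbp_corpus", "data.frame")
  corpus
}

#' Join progress notes of the same encounter
#'
#' Notes sharing an `encounter_id` are concatenated in timestamp order (ties
#' broken by `note_id`) into a single note whose id is the encounter id.
#' Labels merge as `acute_lbp` if any member is `acute_lbp`, else `other` if
#' any is `other`, else `unreviewed`; ICD-10 code sets take the union. Notes
#' without an encounter id pass through unchanged.
#'
#' @param corpus A corpus data frame.
#' @return A corpus with one row per encounter (plus unjoined notes).
#' @export
join_progress_notes <- function(corpus) {
  has_enc <- !is.na(corpus$encounter_id)
  singles <- corpus[!has_enc, , drop = FALSE]
  grouped <- corpus[has_enc, , drop = FALSE]
  if (nrow(grouped) == 0) return(corpus)
  joined <- lapply(split(seq_len(nrow(grouped)), grouped$encounter_id),
                   function(idx) {
    g <- grouped[idx, , drop = FALSE]
    ts <- g$timestamp
    ts[is.na(ts)] <- ""  # absent timestamps sort first, ties fall to note_id
    ord <- order(ts, g$note_id)
    g <- g[ord, , drop = FALSE]
    labels <- g$label
    label <- if ("acute_lbp" %in% labels) "acute_lbp"
             else if ("other" %in% labels) "other" else "unreviewed"
    list(
      note_id = g$encounter_id[1],
      encounter_id = g$encounter_id[1],
      text = paste(g$text, collapse = "\n"),
      icd10 = unique(unlist(g$icd10)),
      label = label,
      timestamp = g$timestamp[1]
    )
  })
  out <- new_corpus(c(
    joined,
    lapply(seq_len(nrow(singles)), function(i) list(
      note_id = singles$note_id[i], encounter_id = singles$encounter_id[i],
      text = singles$text[i], icd10 = singles$icd10[[i]],
      label = singles$label[i], timestamp = singles$timestamp[i]
    ))
  ), provenance = attr(corpus, "provenance"))
  # keep a stable order: first appearance of each output id in the input
  first_seen <- ifelse(has_enc, corpus$encounter_id, corpus$note_id)
  out[order(match(out$note_id, unique(first_seen))), , drop = FALSE]
}

#' Write per-note prediction scores
#'
#' @param predictions Data frame with columns `note_id`, `score`, `label`,
#'   `model`, `fold`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(predictions, path) {
  stopifnot(all(c("note_id", "score", "label", "model", "fold") %in%
                  names(predictions)))
  write.csv(predictions, path, row.names = FALSE)
  invisible(path)
}
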
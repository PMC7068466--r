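#' Synthetic-corpus generator configuration
#'
#' Defaults emulate the statistical structure of a primary-care note corpus:
#' ~5% acute-LBP prevalence, 40% of positives expressing acuity only through
#' paraphrases, 10% of controls carrying a negated keyword mention, 1%
#' per-token misspellings, ICD-10 silver labels discordant with the manual
#' labels at precision 0.32 / recall 0.68, and log-normal note lengths
#' clipped to `[7, 2000]` words.
#'
#' @param n_notes Number of notes (at least 10).
#' @param positive_rate Acute-LBP prevalence.
#' @param paraphrase_rate Fraction of positives with paraphrase-only acuity.
#' @param negation_rate Fraction of controls with a negated keyword mention.
#' @param misspelling_rate Per-token single-character-edit probability.
#' @param icd_precision,icd_recall Target ICD-vs-manual discordance.
#' @param length_log_mean,length_log_sd Log-normal note-length parameters.
#' @param length_min,length_max Length clip bounds in words.
#' @param seed Integer seed.
#' @return A validated `synthetic_config` list.
#' @export
synthetic_config <- function(n_notes = 2000, positive_rate = 0.05,
                             paraphrase_rate = 0.4, negation_rate = 0.1,
                             misspelling_rate = 0.01, icd_precision = 0.32,
                             icd_recall = 0.68, length_log_mean = log(60),
                             length_log_sd = 0.9, length_min = 7,
                             length_max = 2000, seed = 1) {
  rates <- c(positive_rate = positive_rate, paraphrase_rate = paraphrase_rate,
             negation_rate = negation_rate, misspelling_rate = misspelling_rate,
             icd_precision = icd_precision, icd_recall = icd_recall)
  if (any(rates < 0 | rates > 1))
    stop("all rates must be in [0, 1]")
  if (n_notes < 10) stop("n_notes must be at least 10")
  if (icd_precision > 0) {
    # expected coded controls per control note must not exceed 1
    fp_rate <- positive_rate * icd_recall * (1 - icd_precision) /
      (icd_precision * (1 - positive_rate))
    if (fp_rate > 1)
      stop("infeasible icd_precision/icd_recall/positive_rate combination: ",
           "required control coding rate ", round(fp_rate, 3),
           " exceeds 1; icd_precision must be at least ",
           signif(positive_rate * icd_recall /
                    (positive_rate * icd_recall + (1 - positive_rate)), 3))
  }
  structure(list(n_notes = as.integer(n_notes), positive_rate = positive_rate,
                 paraphrase_rate = paraphrase_rate,
                 negation_rate = negation_rate,
                 misspelling_rate = misspelling_rate,
                 icd_precision = icd_precision, icd_recall = icd_recall,
                 length_log_mean = length_log_mean,
                 length_log_sd = length_log_sd,
                 length_min = as.integer(length_min),
                 length_max = as.integer(length_max),
                 seed = as.integer(seed)), class = "synthetic_config")
}

#' Load a phrase bank
#'
#' The phrase bank holds the building blocks of synthetic notes: the four
#' direct keyword phrases, acuity paraphrases, medication/recommendation
#' support phrases, non-LBP background filler sentences, and templates for
#' inserting affirmed or negated mentions. The direct and background
#' vocabularies are disjoint enough that background notes never contain a
#' direct phrase.
#'
#' @param path Optional JSON file; defaults to the bank shipped with the
#'   package.
#' @return A `phrase_bank` list.
#' @export
default_phrase_bank <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "phrase_bank.json", package = "lbpnotes")
  bank <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  structure(bank, class = "phrase_bank")
}

# single-character edit (substitute / insert / delete) on tokens >= 4 chars
misspell_token <- function(tok) {
  n <- nchar(tok)
  if (n < 4) return(tok)
  pos <- sample.int(n, 1)
  letters_pool <- letters
  switch(sample(c("sub", "ins", "del"), 1),
    sub = paste0(substr(tok, 1, pos - 1), sample(letters_pool, 1),
                 substr(tok, pos + 1, n)),
    ins = paste0(substr(tok, 1, pos), sample(letters_pool, 1),
                 substr(tok, pos + 1, n)),
    del = if (n > 4) paste0(substr(tok, 1, pos - 1), substr(tok, pos + 1, n))
          else tok)
}

apply_misspellings <- function(text, rate) {
  if (rate <= 0) return(text)
  toks <- strsplit(text, " ", fixed = TRUE)[[1]]
  hit <- runif(length(toks)) < rate
  toks[hit] <- vapply(toks[hit], misspell_token, character(1))
  paste(toks, collapse = " ")
}

fill_template <- function(template, phrase) {
  sub("{X}", phrase, template, fixed = TRUE)
}

#' Generate a synthetic clinical-note corpus
#'
#' Builds `n_notes` notes of background clinical filler at log-normal target
#' lengths. Positive notes receive 1-3 acuity insertions: with probability
#' `1 - paraphrase_rate` a direct keyword phrase (plus supporting
#' medication/recommendation phrases), otherwise paraphrases and support
#' phrases only, so those positives contain no search keyword. A
#' `negation_rate` fraction of controls receives a negated keyword mention.
#' Tokens are misspelled by single-character edits at `misspelling_rate`.
#' ICD-10 M54.5 codes are assigned so that, in expectation, the silver label
#' has the configured precision and recall against the manual labels. The
#' whole corpus is reproducible from `config$seed`.
#'
#' @param config A [synthetic_config()].
#' @param bank A [default_phrase_bank()].
#' @return A corpus data frame with ground-truth `label` and `icd10` sets,
#'   plus a `ground_truth` attribute recording per-note generator choices.
#' @export
generate_corpus <- function(config = synthetic_config(),
                            bank = default_phrase_bank()) {
  with_seed(config$seed, {
    n <- config$n_notes
    is_pos <- rbinom(n, 1, config$positive_rate) == 1
    # silver-label mechanism: code positives at icd_recall; code controls at
    # the false-positive rate implied by the target precision
    fp_rate <- if (config$icd_precision > 0)
      config$positive_rate * config$icd_recall *
        (1 - config$icd_precision) /
        (config$icd_precision * (1 - config$positive_rate)) else 0
    coded <- ifelse(is_pos, runif(n) < config$icd_recall,
                    runif(n) < fp_rate)
    lengths <- pmin(pmax(round(rlnorm(n, config$length_log_mean,
                                      config$length_log_sd)),
                         config$length_min), config$length_max)
    paraphrase_only <- is_pos & runif(n) < config$paraphrase_rate
    negated_control <- !is_pos & runif(n) < config$negation_rate

    texts <- character(n)
    for (i in seq_len(n)) {
      sents <- character(0)
      wc <- 0
      while (wc < lengths[i]) {
        s <- sample(bank$background_sentences, 1)
        sents <- c(sents, s)
        wc <- wc + length(strsplit(s, " ", fixed = TRUE)[[1]])
      }
      if (is_pos[i]) {
        n_sig <- sample(1:3, 1)
        sig <- character(0)
        if (paraphrase_only[i]) {
          sig <- vapply(sample(bank$paraphrases,
                               min(n_sig, length(bank$paraphrases))),
                        function(ph) fill_template(
                          sample(bank$signal_templates, 1), ph),
                        character(1))
        } else {
          sig <- vapply(sample(bank$direct_phrases, min(n_sig, 2),
                               replace = FALSE),
                        function(ph) fill_template(
                          sample(bank$signal_templates, 1), ph),
                        character(1))
        }
        sig <- c(sig, sample(bank$support_phrases, min(2, n_sig)))
        pos_at <- sample(seq_len(length(sents) + 1), length(sig),
                         replace = TRUE)
        for (j in order(pos_at, decreasing = TRUE))
          sents <- append(sents, sig[j], after = pos_at[j] - 1)
      } else if (negated_control[i]) {
        neg <- fill_template(sample(bank$negation_templates, 1),
                             sample(bank$direct_phrases, 1))
        sents <- append(sents, neg,
                        after = sample(seq_len(length(sents) + 1), 1) - 1)
      }
      texts[i] <- apply_misspellings(paste0(paste(sents, collapse = ". "), "."),
                                     config$misspelling_rate)
    }

    ids <- sprintf("note%05d", seq_len(n))
    days <- sample(0:729, n, replace = TRUE)
    notes <- lapply(seq_len(n), function(i) list(
      note_id = ids[i], encounter_id = ids[i], text = texts[i],
      icd10 = if (coded[i]) "M54.5" else character(0),
      label = if (is_pos[i]) "acute_lbp" else "other",
      timestamp = format(as.Date("2016-01-01") + days[i])
    ))
    corpus <- new_corpus(notes, provenance = sprintf(
      "synthetic corpus (n=%d, seed=%d)", n, config$seed))
    attr(corpus, "ground_truth") <- data.frame(
      note_id = ids, positive = is_pos, paraphrase_only = paraphrase_only,
      negated_control = negated_control, coded = coded,
      target_length = lengths, stringsAsFactors = FALSE)
    attr(corpus, "config") <- config
    corpus
  })
}

#' Summary statistics of a corpus
#'
#' @param corpus A corpus data frame.
#' @return A list with the note count, manual-label prevalence, word-length
#'   quantiles, and the ICD-vs-manual confusion matrix with the implied
#'   silver-label precision and recall (`NA` when codes or labels are
#'   absent).
#' @export
describe_corpus <- function(corpus) {
  wc <- vapply(strsplit(corpus$text, "\\s+"), length, integer(1))
  y <- manual_labels(corpus)
  silver <- icd10_labels(corpus)
  reviewed <- corpus$label != "unreviewed"
  conf <- if (any(reviewed)) table(
    manual = factor(y[reviewed], levels = c(0, 1)),
    icd10 = factor(silver[reviewed], levels = c(0, 1))) else NA
  tp <- if (is.table(conf)) conf["1", "1"] else NA_real_
  list(
    n_notes = nrow(corpus),
    prevalence = if (any(reviewed)) mean(y[reviewed]) else NA_real_,
    n_icd_coded = sum(silver),
    length_quantiles = quantile(wc, c(0, 0.25, 0.5, 0.75, 1)),
    confusion = conf,
    icd_precision = if (is.table(conf) && sum(conf[, "1"]) > 0)
      tp / sum(conf[, "1"]) else NA_real_,
    icd_recall = if (is.table(conf) && sum(conf["1", ]) > 0)
      tp / sum(conf["1", ]) else NA_real_
  )
}
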
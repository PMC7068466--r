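#' Evaluation labels (manual annotations)
#'
#' Notes manually annotated `acute_lbp` are positive; `other` and
#' `unreviewed` notes count as negatives, matching the acute-LBP-versus-rest
#' framing. `strict = TRUE` restricts to reviewed notes (returns `NA` for
#' unreviewed ones).
#'
#' @param corpus A corpus data frame.
#' @param strict Return `NA` for unreviewed notes.
#' @return Named 0/1 vector (names = note ids).
#' @export
manual_labels <- function(corpus, strict = FALSE) {
  y <- as.numeric(corpus$label == "acute_lbp")
  if (strict) y[corpus$label == "unreviewed"] <- NA_real_
  setNames(y, corpus$note_id)
}

#' Silver labels from ICD-10 codes
#'
#' A note is positive iff the generic low-back-pain code (`M54.5` by
#' default) is in its code set. Doubles as the ICD-10 baseline "model",
#' whose score is the label itself.
#'
#' @param corpus A corpus data frame.
#' @param positive_code The code treated as positive (default `"M54.5"`).
#' @return Named 0/1 vector.
#' @export
icd10_labels <- function(corpus, positive_code = "M54.5") {
  y <- vapply(corpus$icd10, function(codes) positive_code %in% codes,
              logical(1))
  setNames(as.numeric(y), corpus$note_id)
}

#' Stratified k-fold plan with per-fold validation splits
#'
#' Random partition into `k` test folds (sizes differing by at most 1), with
#' every note in exactly one test fold. Within each fold's training portion a
#' seeded 90/10 train/validation split is precomputed. Stratification (on the
#' manual evaluation label) is the default because at ~5% prevalence
#' unstratified folds are unstable at k = 10.
#'
#' @param corpus A corpus data frame.
#' @param k Number of folds (default 10).
#' @param seed Integer seed.
#' @param stratify Stratify folds and validation splits by manual label.
#' @param val_fraction Validation fraction of each training portion.
#' @return A `fold_plan`: `list(k, seed, assignments, val_sets, ...)` where
#'   `assignments` maps note_id to test-fold index and `val_sets[[f]]` lists
#'   the validation note ids of fold `f`.
#' @export
make_folds <- function(corpus, k = 10, seed = 1, stratify = TRUE,
                       val_fraction = 0.1) {
  n <- nrow(corpus)
  if (k > n) stop("k = ", k, " exceeds corpus size ", n)
  ids <- corpus$note_id
  y <- manual_labels(corpus)
  strata <- if (stratify) split(ids, y[ids]) else list(all = ids)
  ordered <- unlist(lapply(seq_along(strata), function(s)
    with_seed(seed + s, sample(strata[[s]]))), use.names = FALSE)
  assignments <- setNames(rep_len(seq_len(k), n), ordered)

  val_sets <- lapply(seq_len(k), function(f) {
    pool <- ordered[assignments[ordered] != f]
    pool_strata <- if (stratify) split(pool, y[pool]) else list(all = pool)
    unlist(lapply(seq_along(pool_strata), function(s) {
      ps <- pool_strata[[s]]
      n_val <- max(1L, round(val_fraction * length(ps)))
      with_seed(seed * 1000L + f * 10L + s, sample(ps, n_val))
    }), use.names = FALSE)
  })
  structure(list(k = k, seed = seed, stratify = stratify,
                 val_fraction = val_fraction,
                 assignments = assignments[ids], val_sets = val_sets),
            class = "fold_plan")
}

#' Tune the decision threshold on a grid
#'
#' Returns the grid threshold maximizing the F score of `label = score >=
#' threshold`; ties break toward the smallest threshold.
#'
#' @param scores Numeric scores.
#' @param labels Binary labels (both classes present).
#' @param grid Threshold grid (default 0.1 to 1.0 in 0.1 steps).
#' @return The selected threshold.
#' @export
tune_threshold <- function(scores, labels, grid = seq(0.1, 1, by = 0.1)) {
  stopifnot(length(unique(labels)) == 2)
  f <- vapply(grid, function(th)
    binary_metrics(scores, labels, th)[["f_score"]], numeric(1))
  grid[which.max(f)]  # which.max takes the first (smallest) maximizer
}

#' Precision, recall and F at a threshold
#'
#' @param scores Numeric scores.
#' @param labels Binary labels.
#' @param threshold Decision threshold (`score >= threshold` is positive).
#' @return Named vector `precision`, `recall`, `f_score` (0 where undefined).
#' @export
binary_metrics <- function(scores, labels, threshold) {
  pred <- as.numeric(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  c(precision = precision, recall = recall, f_score = f)
}

#' Area under the ROC curve (rank statistic with tie correction)
#'
#' @param scores Numeric scores.
#' @param labels Binary labels (both classes present).
#' @return AUC-ROC in `[0, 1]`.
#' @export
auc_roc <- function(scores, labels) {
  labels <- as.numeric(labels)
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) stop("AUC-ROC needs both classes")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Area under the precision-recall curve (step integration)
#'
#' Average-precision form: thresholds descend over the distinct score
#' values and `AUC = sum over steps of (R_i - R_{i-1}) * P_i`.
#'
#' @param scores Numeric scores.
#' @param labels Binary labels (both classes present).
#' @return AUC-PRC in `(0, 1]`.
#' @export
auc_prc <- function(scores, labels) {
  labels <- as.numeric(labels)
  n_pos <- sum(labels == 1)
  if (n_pos == 0 || sum(labels == 0) == 0) stop("AUC-PRC needs both classes")
  ord <- order(-scores)
  s <- scores[ord]
  y <- labels[ord]
  tp <- cumsum(y)
  fp <- cumsum(1 - y)
  last <- c(s[-1] != s[-length(s)], TRUE)  # last index of each tied block
  tp <- tp[last]; fp <- fp[last]
  precision <- tp / (tp + fp)
  recall <- tp / n_pos
  sum(diff(c(0, recall)) * precision)
}

#' All evaluation metrics at once
#'
#' @inheritParams binary_metrics
#' @return Named list with `precision`, `recall`, `f_score` (at the
#'   threshold), `auc_roc` and `auc_prc` (threshold-free).
#' @export
compute_metrics <- function(scores, labels, threshold = 0.5) {
  m <- binary_metrics(scores, labels, threshold)
  list(precision = m[["precision"]], recall = m[["recall"]],
       f_score = m[["f_score"]], auc_roc = auc_roc(scores, labels),
       auc_prc = auc_prc(scores, labels), threshold = threshold)
}

#' Run the cross-validation benchmark
#'
#' Per fold: the vocabulary is fitted on the fold's training portion, all
#' notes are encoded against it, each model is fitted on the training portion
#' with labels from `label_source` (`"manual"` or `"icd10"`), the decision
#' threshold is tuned on the validation split, and the held-out test fold is
#' scored. Metrics are always computed against the manual annotations.
#'
#' @param corpus A corpus with manual labels (and ICD-10 codes when
#'   `label_source = "icd10"`).
#' @param models Named list of model specifications (see [lbp_models()]).
#' @param folds A [make_folds()] plan.
#' @param label_source Training label source.
#' @param processed Optional precomputed [preprocess_corpus()] result.
#' @param min_count Vocabulary minimum count (default 5).
#' @param max_distance Out-of-vocabulary correction cap (default 2).
#' @param seed Base seed for model fitting.
#' @param verbose Print per-fold progress.
#' @return An `lbp_benchmark`: `list(report, summary, predictions)`.
#' @export
run_benchmark <- function(corpus, models, folds,
                          label_source = c("manual", "icd10"),
                          processed = NULL, min_count = 5, max_distance = 2,
                          seed = 1, verbose = FALSE) {
  label_source <- match.arg(label_source)
  for (m in models)
    if (!is.function(m$fit) || !is.function(m$score))
      stop("every model needs fit() and score() functions")
  if (is.null(processed)) processed <- preprocess_corpus(corpus)
  y_eval <- manual_labels(corpus)
  y_train_all <- if (label_source == "manual") y_eval else icd10_labels(corpus)

  report <- list()
  predictions <- list()
  for (f in seq_len(folds$k)) {
    test_ids <- names(folds$assignments)[folds$assignments == f]
    val_ids <- folds$val_sets[[f]]
    train_ids <- setdiff(corpus$note_id, c(test_ids, val_ids))
    vocab <- build_vocabulary(processed[train_ids], min_count)
    enc <- encode_notes(processed[c(train_ids, val_ids, test_ids)], vocab,
                        max_distance)
    ctx <- list(vocab = vocab, cache = new.env(parent = emptyenv()),
                seed = seed + f)
    for (mi in seq_along(models)) {
      model <- models[[mi]]
      fitted <- model$fit(ctx, enc[train_ids], y_train_all[train_ids],
                          enc[val_ids], y_train_all[val_ids])
      val_scores <- model$score(ctx, fitted, enc[val_ids])
      threshold <- if (length(unique(y_train_all[val_ids])) == 2)
        tune_threshold(val_scores, y_train_all[val_ids]) else 0.5
      test_scores <- model$score(ctx, fitted, enc[test_ids])
      met <- compute_metrics(test_scores, y_eval[test_ids], threshold)
      report[[length(report) + 1]] <- data.frame(
        model = model$name, fold = f, label_source = label_source,
        threshold = threshold, precision = met$precision,
        recall = met$recall, f_score = met$f_score, auc_roc = met$auc_roc,
        auc_prc = met$auc_prc, stringsAsFactors = FALSE)
      predictions[[length(predictions) + 1]] <- data.frame(
        note_id = test_ids, score = test_scores,
        label = as.numeric(test_scores >= threshold), model = model$name,
        fold = f, stringsAsFactors = FALSE)
      if (verbose)
        message(sprintf("fold %d %s: F=%.3f AUC-ROC=%.3f", f, model$name,
                        met$f_score, met$auc_roc))
    }
  }
  report <- do.call(rbind, report)
  summary <- do.call(rbind, lapply(split(report, report$model), function(g)
    data.frame(model = g$model[1], label_source = label_source,
               precision = mean(g$precision), recall = mean(g$recall),
               f_score = mean(g$f_score), auc_roc = mean(g$auc_roc),
               auc_prc = mean(g$auc_prc), stringsAsFactors = FALSE)))
  rownames(summary) <- NULL
  structure(list(report = report, summary = summary,
                 predictions = do.call(rbind, predictions)),
            class = "lbp_benchmark")
}

#' @export
print.lbp_benchmark <- function(x, ...) {
  cat("Cross-validation benchmark (", max(x$report$fold), " folds, ",
      x$summary$label_source[1], " training labels)\n\n", sep = "")
  print(x$summary, digits = 3, row.names = FALSE)
  invisible(x)
}

#' Annotation subsampling experiment
#'
#' For each fraction, the positively annotated notes of every fold's
#' training portion are randomly subsampled and the discarded positives are
#' removed from the training set (not relabeled); evaluation is unchanged.
#'
#' @param corpus,folds,label_source,processed,min_count,max_distance,seed As
#'   in [run_benchmark()].
#' @param model A single model specification.
#' @param fractions Fractions in (0, 1] of positive annotations to keep.
#' @return `list(rows, summary)`: one row per (fraction, fold) with
#'   `n_positive_annotations`, `auc_roc`, `auc_prc`, plus per-fraction means.
#' @export
subsample_experiment <- function(corpus, model, fractions, folds,
                                 label_source = "manual", processed = NULL,
                                 min_count = 5, max_distance = 2, seed = 1) {
  stopifnot(all(fractions > 0 & fractions <= 1))
  if (is.null(processed)) processed <- preprocess_corpus(corpus)
  y_eval <- manual_labels(corpus)
  y_train_all <- if (label_source == "manual") y_eval else icd10_labels(corpus)
  rows <- list()
  for (f in seq_len(folds$k)) {
    test_ids <- names(folds$assignments)[folds$assignments == f]
    val_ids <- folds$val_sets[[f]]
    train_ids <- setdiff(corpus$note_id, c(test_ids, val_ids))
    vocab <- build_vocabulary(processed[train_ids], min_count)
    enc <- encode_notes(processed[c(train_ids, val_ids, test_ids)], vocab,
                        max_distance)
    pos_ids <- train_ids[y_train_all[train_ids] == 1]
    neg_ids <- setdiff(train_ids, pos_ids)
    for (fr in fractions) {
      n_keep <- round(fr * length(pos_ids))
      if (n_keep == 0) {
        warning("fraction ", fr, " leaves no positive annotations; skipped")
        next
      }
      keep_pos <- if (n_keep == length(pos_ids)) pos_ids else
        with_seed(seed * 100L + f, sample(pos_ids, n_keep))
      sub_ids <- c(keep_pos, neg_ids)
      ctx <- list(vocab = vocab, cache = new.env(parent = emptyenv()),
                  seed = seed + f)
      fitted <- model$fit(ctx, enc[sub_ids], y_train_all[sub_ids],
                          enc[val_ids], y_train_all[val_ids])
      test_scores <- model$score(ctx, fitted, enc[test_ids])
      rows[[length(rows) + 1]] <- data.frame(
        fraction = fr, fold = f, n_positive_annotations = n_keep,
        auc_roc = auc_roc(test_scores, y_eval[test_ids]),
        auc_prc = auc_prc(test_scores, y_eval[test_ids]),
        stringsAsFactors = FALSE)
    }
  }
  rows <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(split(rows, rows$fraction), function(g)
    data.frame(fraction = g$fraction[1],
               n_positive_annotations = mean(g$n_positive_annotations),
               auc_roc = mean(g$auc_roc), auc_prc = mean(g$auc_prc))))
  rownames(summary) <- NULL
  list(rows = rows, summary = summary)
}

#' Score-distribution report
#'
#' Per-class score histograms (bin width 0.1) and counts of notes scoring
#' above 0.2, 0.5 and 0.7.
#'
#' @param scores Numeric scores in `[0, 1]`.
#' @param labels Binary labels.
#' @param thresholds Exceedance thresholds.
#' @return `list(histogram, exceedance)` data frames.
#' @export
score_distribution_report <- function(scores, labels,
                                      thresholds = c(0.2, 0.5, 0.7)) {
  if (!length(scores))
    return(list(histogram = data.frame(), exceedance = data.frame()))
  breaks <- seq(0, 1, by = 0.1)
  bin <- cut(pmin(pmax(scores, 0), 1 - 1e-12), breaks, right = FALSE,
             include.lowest = TRUE)
  histogram <- as.data.frame(table(class = ifelse(labels == 1, "acute_lbp",
                                                  "control"), bin = bin))
  names(histogram)[3] <- "count"
  exceedance <- do.call(rbind, lapply(thresholds, function(th)
    data.frame(threshold = th,
               acute_lbp = sum(scores > th & labels == 1),
               control = sum(scores > th & labels == 0),
               acute_lbp_total = sum(labels == 1),
               control_total = sum(labels == 0))))
  list(histogram = histogram, exceedance = exceedance)
}
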
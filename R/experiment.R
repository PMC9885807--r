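# Orchestration of the four-method screening comparison and the
# classifier-training study, with table-style reports.

#' Compare four screening methods against a gold standard
#'
#' Runs, on one labeled corpus, the four screening routes -- simulated
#' dual-human title/abstract and full-text screening, and dictionary
#' (regex) screening of title/abstract (threshold 1) and full text
#' (threshold 2) -- and evaluates each against the gold labels with
#' [confusion()] and [metrics()]. For the count-scored regex methods, AUC
#' over all thresholds is also reported; AUC for binary human decisions is
#' not derivable and is reported as `NA`.
#'
#' Human title/abstract reviewers can only recognize relevance that the
#' abstract signals, so their stage-visible truth is
#' `gold & (tiab match count >= 1)`; full-text reviewers see the gold
#' truth. Methods needing full text are computed on the subset of records
#' that have one (the subset size is recorded in the report).
#'
#' @param corpus A `labeled_corpus` from [generate_corpus()], or a list
#'   with `records` and `labels`.
#' @param term_set Term set for the dictionary methods (default
#'   [ogd_term_set()]).
#' @param tiab_threshold,fulltext_threshold Match-count inclusion
#'   thresholds (defaults 1 and 2).
#' @param reviewer_error Per-reviewer error rates as in
#'   [simulate_reviewers()].
#' @param optimize_fulltext_threshold Re-derive the full-text threshold
#'   from the corpus's count ROC via [optimal_threshold()] instead of
#'   using `fulltext_threshold`.
#' @param seed Integer seed (reviewer simulation).
#' @return A `comparison_report`: data.frame with one row per method
#'   (`method`, `n`, `tp`, `tn`, `fp`, `fn`, `sensitivity`, `specificity`,
#'   `precision`, `d`, `auc`, `threshold`), with the decision and score
#'   tables attached as attributes `decisions` and `scores`.
#' @export
run_comparison <- function(corpus, term_set = ogd_term_set(),
                           tiab_threshold = 1L, fulltext_threshold = 2L,
                           reviewer_error = list(r1 = c(fnr = 0.1, fpr = 0.01),
                                                 r2 = c(fnr = 0.1, fpr = 0.01),
                                                 r3 = c(fnr = 0.1, fpr = 0.01)),
                           optimize_fulltext_threshold = FALSE,
                           seed = 1L) {
  records <- corpus$records
  gold <- check_named(corpus$labels, "corpus labels")
  pattern <- build_term_pattern(term_set)

  rx_tiab <- screen_corpus(records, pattern, "tiab", tiab_threshold)
  tiab_counts <- setNames(rx_tiab$scores$count, rx_tiab$scores$record_id)

  has_ft <- !is.na(records$full_text)
  if (!all(has_ft))
    message(sum(!has_ft), " record(s) lack full text and were skipped ",
            "by the full-text methods")
  ft_records <- records[has_ft, , drop = FALSE]
  gold_ft <- gold[ft_records$id]
  rx_ft_all <- screen_corpus(ft_records, pattern, "fulltext", 1L)
  ft_counts <- setNames(rx_ft_all$scores$count, rx_ft_all$scores$record_id)
  ft_roc <- roc_curve(ft_counts, gold_ft)
  if (optimize_fulltext_threshold)
    fulltext_threshold <- optimal_threshold(ft_roc)

  # simulated human screening
  tiab_truth <- gold & tiab_counts[names(gold)] >= 1
  human_tiab <- simulate_reviewers(tiab_truth, reviewer_error,
                                   seed = seed, stage = "tiab")
  human_ft <- simulate_reviewers(gold_ft, reviewer_error,
                                 seed = seed + 1L, stage = "fulltext")

  row_for <- function(method, decisions, gold_use, auc = NA_real_,
                      threshold = NA_real_) {
    cm <- confusion(decisions, gold_use)
    m <- metrics(cm)
    data.frame(method = method, n = length(decisions),
               tp = cm$tp, tn = cm$tn, fp = cm$fp, fn = cm$fn,
               sensitivity = m$sensitivity, specificity = m$specificity,
               precision = m$precision, d = m$d, auc = auc,
               threshold = threshold, stringsAsFactors = FALSE)
  }
  tiab_roc <- roc_curve(tiab_counts, gold)
  rows <- rbind(
    row_for("human_tiab",
            setNames(human_tiab$reconciled, human_tiab$record_id), gold),
    row_for("human_fulltext",
            setNames(human_ft$reconciled, human_ft$record_id), gold_ft),
    row_for("regex_tiab", tiab_counts >= tiab_threshold, gold,
            auc = tiab_roc$auc, threshold = tiab_threshold),
    row_for("regex_fulltext", ft_counts >= fulltext_threshold, gold_ft,
            auc = ft_roc$auc, threshold = fulltext_threshold))
  decisions <- rbind(
    data.frame(record_id = human_tiab$record_id, stage = "tiab",
               source = "human_tiab", include = human_tiab$reconciled),
    data.frame(record_id = human_ft$record_id, stage = "fulltext",
               source = "human_fulltext", include = human_ft$reconciled),
    rx_tiab$decisions,
    data.frame(record_id = names(ft_counts), stage = "fulltext",
               source = "regex_fulltext",
               include = unname(ft_counts >= fulltext_threshold)))
  scores <- rbind(rx_tiab$scores, rx_ft_all$scores)
  attr(rows, "decisions") <- validate_decisions(decisions)
  attr(rows, "scores") <- scores
  attr(rows, "n_fulltext") <- nrow(ft_records)
  attr(rows, "seed") <- seed
  class(rows) <- c("comparison_report", "data.frame")
  rows
}

#' @method print comparison_report
#' @export
print.comparison_report <- function(x, digits = 3, ...) {
  cat("Screening-method comparison over", x$n[1], "records (",
      attr(x, "n_fulltext"), "with full text )\n")
  y <- as.data.frame(x)
  for (col in c("sensitivity", "specificity", "precision", "d", "auc"))
    y[[col]] <- round_half_up(y[[col]], digits)
  print(y, row.names = FALSE)
  invisible(x)
}

#' Classifier training study with one error-correction round
#'
#' Splits a labeled corpus, trains the SVM-SGD screener on the training
#' split, picks the validation-set score threshold reaching the target
#' sensitivity, then runs one error-correction round (rescreen the `k`
#' largest human/machine discrepancies through the oracle, retrain) and
#' reports initial and corrected validation performance with both
#' thresholds.
#'
#' @param corpus `labeled_corpus` or list with `records` and `labels`.
#' @param train_fraction Training fraction (default 0.8).
#' @param target_sensitivity Target validation sensitivity (default 0.95).
#' @param k Discrepancies rescreened in the correction round.
#' @param oracle Rescreening oracle (named logical vector or function);
#'   defaults to the corpus's own labels, i.e. no label was wrong.
#' @param seed Integer seed shared by the split and both trainings.
#' @param ... Further arguments to [train_screener()].
#' @return A list of class `classifier_study`: `initial` and `corrected`
#'   (each with `threshold` and validation `metrics`), the two models, the
#'   correction report and the seed.
#' @export
run_classifier_study <- function(corpus, train_fraction = 0.8,
                                 target_sensitivity = 0.95, k = 100L,
                                 oracle = NULL, seed = 1L, ...) {
  records <- corpus$records
  labels <- check_named(corpus$labels, "corpus labels")
  if (is.null(oracle)) oracle <- labels
  sp <- split_corpus(records, labels, train_fraction, seed)
  model <- train_screener(sp$train$records, sp$train$labels,
                          seed = seed, ...)
  vsc <- predict(model, sp$validation$records, type = "score")
  thr <- threshold_for_sensitivity(vsc, sp$validation$labels,
                                   target_sensitivity)
  initial <- list(threshold = thr,
                  metrics = metrics(confusion(vsc >= thr,
                                              sp$validation$labels)))
  corr <- correct_and_retrain(records, labels, model, oracle, k = k,
                              train_fraction = train_fraction,
                              target_sensitivity = target_sensitivity,
                              seed = seed)
  structure(list(initial = initial, corrected = corr$report$post,
                 model = model, corrected_model = corr$model,
                 corrected_labels = corr$labels,
                 correction = corr$report, seed = as.integer(seed)),
            class = "classifier_study")
}

#' @method print classifier_study
#' @export
print.classifier_study <- function(x, ...) {
  cat("Classifier study (seed", x$seed, ")\n initial   (threshold",
      format(round(x$initial$threshold, 3)), "): ")
  print(x$initial$metrics)
  cat(" corrected (threshold",
      format(round(x$corrected$threshold, 3)), "): ")
  print(x$corrected$metrics)
  cat(" decisions reversed in correction:", x$correction$n_reversed, "\n")
  invisible(x)
}

#' Write a comparison report to CSV and JSON twins
#'
#' @param report A `comparison_report`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_comparison_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  df <- as.data.frame(report)
  write.csv(df, file.path(dir, "comparison.csv"), row.names = FALSE)
  jsonlite::write_json(df, file.path(dir, "comparison.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA,
                       na = "null")
  write.csv(attr(report, "decisions"), file.path(dir, "decisions.csv"),
            row.names = FALSE)
  write.csv(attr(report, "scores"), file.path(dir, "scores.csv"),
            row.names = FALSE)
  invisible(dir)
}
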
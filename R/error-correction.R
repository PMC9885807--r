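# Error-correction loop: rank human/machine discrepancies, rescreen the
# top k through an oracle, apply corrections, retrain, report the delta.

#' Rank human/machine discrepancies
#'
#' For every record, the discrepancy magnitude is `|label - score|` with
#' the human label coded 0/1 and the machine score in \[0, 1\]. Returns the
#' `k` records with the largest discrepancy, ties broken by record id
#' (stable); `k` larger than the corpus returns everything.
#'
#' @param labels Named logical (or 0/1) human labels keyed by record id.
#' @param scores Named numeric machine scores in \[0, 1\] over the same ids.
#' @param k Number of records to return (>= 0).
#' @return A data.frame `record_id`, `human_label`, `machine_score`,
#'   `magnitude`, sorted by non-increasing magnitude.
#' @examples
#' rank_discrepancies(c(A = 1, B = 1, C = 0),
#'                    c(A = 0.1, B = 0.9, C = 0.8), k = 2)
#' @export
rank_discrepancies <- function(labels, scores, k) {
  labels <- check_named(labels, "labels")
  scores <- check_named(scores, "scores")
  check_same_ids(labels, scores, "labels", "scores")
  if (!is.numeric(k) || length(k) != 1L || k < 0)
    stop_vs("k must be a single non-negative count")
  ids <- sort(names(labels))
  lab <- as.numeric(as.logical(labels[ids]))
  sc <- as.numeric(scores[ids])
  mag <- abs(lab - sc)
  ord <- order(-mag, ids)
  out <- data.frame(record_id = ids[ord], human_label = lab[ord] == 1,
                    machine_score = sc[ord], magnitude = mag[ord],
                    stringsAsFactors = FALSE)
  head(out, min(k, nrow(out)))
}

#' Correct the largest discrepancies and retrain
#'
#' Implements one round of the error-correction protocol: score the full
#' labeled corpus with the current model, take the `k` records with the
#' largest human/machine discrepancy, replace their labels with the
#' rescreening oracle's verdicts, then re-split (same seed, so the
#' validation records are unchanged) and retrain with the same
#' hyperparameters. The report compares pre- and post-correction
#' performance on the validation split at the sensitivity-targeted
#' threshold.
#'
#' @param records Record data.frame (the full labeled corpus).
#' @param labels Named logical labels keyed by record id.
#' @param model The current `screener_model` (trained on the train split of
#'   this corpus under `seed`).
#' @param oracle Rescreening verdicts: either a named logical vector
#'   covering at least the ranked ids, or a function `id -> logical`.
#' @param k Number of discrepancies to rescreen (default 100).
#' @param train_fraction,target_sensitivity,seed Protocol parameters; must
#'   match those used to train `model` for the pre/post comparison to share
#'   a validation split.
#' @return A list with `model` (the retrained `screener_model`), `labels`
#'   (the corrected labels) and `report`, a `correction_report`: `k`,
#'   `n_reversed`, `n_confirmed`, `reversed_ids`, `pre`/`post` (each with
#'   `threshold` and validation [metrics()]).
#' @export
correct_and_retrain <- function(records, labels, model, oracle, k = 100L,
                                train_fraction = 0.8,
                                target_sensitivity = 0.95, seed = 1L) {
  labels <- check_named(labels, "labels")
  scores <- predict(model, records, type = "score")
  ranked <- rank_discrepancies(labels, scores, k)
  ask <- function(id) {
    v <- if (is.function(oracle)) oracle(id) else
      if (id %in% names(oracle)) oracle[[id]] else NA
    if (is.na(v) || !is.logical(as.logical(v)))
      stop_vs("oracle has no verdict for record ", id)
    as.logical(v)
  }
  verdicts <- vapply(ranked$record_id, ask, logical(1))
  reversed <- verdicts != as.logical(labels[ranked$record_id])
  corrected <- labels
  corrected[ranked$record_id] <- verdicts
  eval_at <- function(labs, mod) {
    sp <- split_corpus(records, labs, train_fraction, seed)
    vsc <- predict(mod, sp$validation$records, type = "score")
    thr <- threshold_for_sensitivity(vsc, sp$validation$labels,
                                     target_sensitivity)
    list(threshold = thr,
         metrics = metrics(confusion(vsc >= thr, sp$validation$labels)))
  }
  pre <- eval_at(labels, model)
  sp <- split_corpus(records, corrected, train_fraction, seed)
  h <- model$hyperparameters
  model2 <- train_screener(sp$train$records, sp$train$labels,
                           ngram_max = h$ngram_max, min_df = h$min_df,
                           alpha = h$alpha, epochs = h$epochs,
                           weighting = model$weighting, seed = seed)
  post <- eval_at(corrected, model2)
  report <- structure(list(k = nrow(ranked),
                           n_reversed = sum(reversed),
                           n_confirmed = sum(!reversed),
                           reversed_ids = ranked$record_id[reversed],
                           pre = pre, post = post),
                      class = "correction_report")
  list(model = model2, labels = corrected, report = report)
}

#' @method print correction_report
#' @export
print.correction_report <- function(x, ...) {
  cat("Error-correction round over the top", x$k, "discrepancies\n",
      " decisions reversed:", x$n_reversed,
      " confirmed:", x$n_confirmed, "\n")
  cat(" pre  (threshold ", format(round(x$pre$threshold, 3)), "): ",
      sep = "")
  print(x$pre$metrics)
  cat(" post (threshold ", format(round(x$post$threshold, 3)), "): ",
      sep = "")
  print(x$post$metrics)
  invisible(x)
}
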
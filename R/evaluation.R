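# Diagnostic-accuracy evaluation: confusion matrices, sensitivity /
# specificity / precision, the Euclidean distance d to the perfect
# operating point, step-curve ROC with trapezoidal AUC, threshold
# selection, and corpus-scale projection arithmetic.

#' Confusion matrix
#'
#' `confusion_matrix()` builds a confusion matrix from counts;
#' `confusion()` tallies one from paired include/exclude decisions and
#' gold-standard labels (named logical vectors over the same record ids).
#'
#' @param tp,tn,fp,fn Non-negative counts of true positives, true
#'   negatives, false positives and false negatives.
#' @return An object of class `confusion_matrix` (a named list of the four
#'   counts).
#' @examples
#' cm <- confusion_matrix(tp = 275, tn = 4846, fp = 7, fn = 44)
#' metrics(cm)
#' @export
confusion_matrix <- function(tp, tn, fp, fn) {
  counts <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(!is.finite(counts)) || any(counts < 0))
    stop_vs("confusion counts must be finite and non-negative")
  structure(as.list(counts), class = "confusion_matrix")
}

#' @rdname confusion_matrix
#' @param decisions Named logical vector: a method's include decision per
#'   record id.
#' @param gold Named logical vector: the gold-standard label per record id;
#'   must cover exactly the decided ids.
#' @export
confusion <- function(decisions, gold) {
  decisions <- check_named(as.logical(decisions) |>
                             setNames(names(decisions)), "decisions")
  gold <- check_named(as.logical(gold) |> setNames(names(gold)), "gold")
  check_same_ids(decisions, gold)
  g <- gold[names(decisions)]
  confusion_matrix(tp = sum(decisions & g), tn = sum(!decisions & !g),
                   fp = sum(decisions & !g), fn = sum(!decisions & g))
}

#' @method print confusion_matrix
#' @export
print.confusion_matrix <- function(x, ...) {
  cat("Confusion matrix (n =", x$tp + x$tn + x$fp + x$fn, ")\n")
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(c("included", "excluded"),
                              c("relevant", "irrelevant")))
  print(m)
  invisible(x)
}

#' Screening performance metrics
#'
#' Sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`, precision
#' `tp/(tp+fp)` and the Euclidean distance `d` to the perfect operating
#' point (see [euclidean_distance()]). A zero denominator makes the
#' corresponding metric undefined, returned as `NA` (never an error); `d`
#' is defined iff both sensitivity and specificity are.
#'
#' @param cm A [confusion_matrix()].
#' @return An object of class `screen_metrics`: list with `sensitivity`,
#'   `specificity`, `precision`, `d` (each a proportion or `NA`).
#' @examples
#' metrics(confusion_matrix(316, 4851, 2, 3))
#' @export
metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  total <- cm$tp + cm$tn + cm$fp + cm$fn
  if (total == 0) stop_vs("empty confusion matrix: all counts zero")
  frac <- function(num, den) if (den == 0) NA_real_ else num / den
  sens <- frac(cm$tp, cm$tp + cm$fn)
  spec <- frac(cm$tn, cm$tn + cm$fp)
  prec <- frac(cm$tp, cm$tp + cm$fp)
  d <- if (is.na(sens) || is.na(spec)) NA_real_ else
    euclidean_distance(sens, spec)
  structure(list(sensitivity = sens, specificity = spec, precision = prec,
                 d = d), class = "screen_metrics")
}

#' @method print screen_metrics
#' @export
print.screen_metrics <- function(x, digits = 3, ...) {
  fmt <- function(v) if (is.na(v)) "undefined" else
    format(round_half_up(v, digits), nsmall = digits)
  cat("sensitivity:", fmt(x$sensitivity),
      " specificity:", fmt(x$specificity),
      " precision:", fmt(x$precision),
      " d:", fmt(x$d), "\n")
  invisible(x)
}

#' Euclidean distance to the perfect operating point
#'
#' `d = sqrt((1 - sensitivity)^2 + (1 - specificity)^2)`: the distance of
#' an operating point from perfect performance (sensitivity = specificity
#' = 1). Smaller is better; `d = 0` iff the point is perfect, and the
#' worst case is `sqrt(2)`.
#'
#' @param sensitivity,specificity Proportions in \[0, 1\].
#' @return The distance, a real in \[0, sqrt(2)\].
#' @examples
#' euclidean_distance(0.862, 0.998)
#' @export
euclidean_distance <- function(sensitivity, specificity) {
  check_proportion(sensitivity, "sensitivity")
  check_proportion(specificity, "specificity")
  sqrt((1 - sensitivity)^2 + (1 - specificity)^2)
}

#' ROC curve over score thresholds
#'
#' Sweeps the inclusion rule `score >= threshold` over every distinct
#' observed score, producing the empirical step curve with its anchors at
#' (FPR, TPR) = (0, 0) (threshold above all scores) and (1, 1) (threshold
#' at the minimum score). AUC is the trapezoidal area under the step
#' curve, which equals the tie-adjusted Mann-Whitney statistic.
#'
#' @param scores Named numeric vector of scores (match counts or
#'   classifier scores) keyed by record id.
#' @param gold Named logical vector of gold labels over the same ids; must
#'   contain at least one positive and one negative.
#' @return An object of class `screen_roc`: data.frame `points` with
#'   columns `threshold`, `fpr`, `tpr` (sorted by increasing threshold,
#'   ending in the `Inf` anchor), plus an `auc` element.
#' @examples
#' sc <- c(a = 3, b = 1, c = 2, d = 0)
#' gold <- c(a = TRUE, b = TRUE, c = FALSE, d = FALSE)
#' roc_curve(sc, gold)$auc
#' @export
roc_curve <- function(scores, gold) {
  scores <- check_named(scores, "scores")
  gold <- check_named(gold, "gold")
  check_same_ids(scores, gold, "scores", "gold")
  g <- as.logical(gold[names(scores)])
  npos <- sum(g); nneg <- sum(!g)
  if (npos == 0 || nneg == 0)
    stop_vs("ROC needs at least one positive and one negative gold label")
  thr <- c(sort(unique(scores)), Inf)
  tpr <- vapply(thr, function(t) sum(scores >= t & g) / npos, numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & !g) / nneg, numeric(1))
  pts <- data.frame(threshold = thr, fpr = fpr, tpr = tpr)
  ord <- order(pts$fpr, pts$tpr)
  auc <- sum(diff(pts$fpr[ord]) *
               (head(pts$tpr[ord], -1) + tail(pts$tpr[ord], -1)) / 2)
  structure(list(points = pts, auc = auc, n_pos = npos, n_neg = nneg),
            class = "screen_roc")
}

#' @method print screen_roc
#' @export
print.screen_roc <- function(x, ...) {
  cat("ROC over", nrow(x$points), "thresholds;",
      x$n_pos, "positives,", x$n_neg, "negatives; AUC =",
      format(round_half_up(x$auc, 3), nsmall = 3), "\n")
  invisible(x)
}

#' @method plot screen_roc
#' @export
plot.screen_roc <- function(x, ...) {
  ord <- order(x$points$fpr, x$points$tpr)
  plot(x$points$fpr[ord], x$points$tpr[ord], type = "s",
       xlab = "False positive rate", ylab = "True positive rate",
       xlim = c(0, 1), ylim = c(0, 1), ...)
  abline(0, 1, lty = 3, col = "grey60")
  invisible(x)
}

#' Threshold minimizing the distance to perfect performance
#'
#' Returns the threshold on a [roc_curve()] whose operating point
#' (sensitivity = TPR, specificity = 1 - FPR) minimizes
#' [euclidean_distance()]. Ties are broken toward higher specificity, then
#' toward the higher threshold.
#'
#' @param curve A `screen_roc`.
#' @return The selected threshold (finite; the `Inf` anchor is only
#'   selected if it strictly wins, which requires a degenerate curve).
#' @export
optimal_threshold <- function(curve) {
  stopifnot(inherits(curve, "screen_roc"))
  p <- curve$points
  d <- sqrt((1 - p$tpr)^2 + p$fpr^2)
  ord <- order(d, p$fpr, -p$threshold)
  p$threshold[ord[1]]
}

#' Largest threshold achieving a target sensitivity
#'
#' Scans the distinct observed scores as candidate thresholds (inclusion
#' rule `score >= threshold`) and returns the largest whose sensitivity
#' reaches `target`. Because sensitivity is non-increasing in the
#' threshold, this is the most specific operating point that still
#' retrieves the target share of relevant records. If even the minimum
#' positive score falls short (impossible for attainable targets), the
#' minimum positive score is returned with a warning (sensitivity-1
#' fallback).
#'
#' @param scores,gold Named vectors as in [roc_curve()]; `gold` needs at
#'   least one positive.
#' @param target Target sensitivity in (0, 1\], e.g. 0.95.
#' @return The selected threshold.
#' @examples
#' sc <- c(p1 = 0.9, p2 = 0.8, p3 = 0.2, n1 = 0.5, n2 = 0.1)
#' gold <- c(p1 = TRUE, p2 = TRUE, p3 = TRUE, n1 = FALSE, n2 = FALSE)
#' threshold_for_sensitivity(sc, gold, 0.95)  # 0.2: all 3 positives needed
#' @export
threshold_for_sensitivity <- function(scores, gold, target = 0.95) {
  if (!is_proportion(target) || target <= 0)
    stop_vs("target must be in (0, 1]")
  scores <- check_named(scores, "scores")
  gold <- check_named(gold, "gold")
  check_same_ids(scores, gold, "scores", "gold")
  g <- as.logical(gold[names(scores)])
  if (!any(g)) stop_vs("gold has no positive labels")
  npos <- sum(g)
  thr <- sort(unique(scores), decreasing = TRUE)
  sens <- vapply(thr, function(t) sum(scores >= t & g) / npos, numeric(1))
  ok <- which(sens >= target)
  if (!length(ok)) {
    warning("no threshold reaches sensitivity ", target,
            "; falling back to the minimum positive score", call. = FALSE)
    return(min(scores[g]))
  }
  thr[ok[1]]
}

#' Extrapolate a total from a count found at known sensitivity
#'
#' If a method with sensitivity `s` finds `found` relevant records, the
#' estimated true total is `found / s`. Used to project the number of
#' relevant studies in a corpus portion that could only be screened by a
#' method of known (estimated) sensitivity.
#'
#' @param found Non-negative count of records identified.
#' @param assumed_sensitivity Sensitivity in (0, 1\].
#' @return The estimated total (real; rounding left to the caller).
#' @examples
#' extrapolate_total(66, 0.890)
#' @export
extrapolate_total <- function(found, assumed_sensitivity) {
  if (!is.numeric(found) || length(found) != 1L || found < 0)
    stop_vs("found must be a single non-negative count")
  if (!is_proportion(assumed_sensitivity) || assumed_sensitivity == 0)
    stop_vs("assumed_sensitivity must be in (0, 1]")
  found / assumed_sensitivity
}

#' Project screening performance to corpus scale
#'
#' Exact expected-count arithmetic for applying a screening method with
#' given sensitivity and specificity to a corpus of `corpus_size` records
#' of which a fraction `prevalence` is truly relevant:
#' positives = prevalence x size, false negatives = (1 - sensitivity) x
#' positives, false positives = (1 - specificity) x (size - positives),
#' and the labelled-positive yield = sensitivity x positives + false
#' positives. All values are real (expected counts); rounding is left to
#' presentation.
#'
#' @param corpus_size Corpus size (> 0).
#' @param prevalence,sensitivity,specificity Proportions in \[0, 1\].
#' @return An object of class `corpus_projection`: list with
#'   `corpus_size`, `prevalence`, `true_positives`, `false_positives`,
#'   `false_negatives`, `true_negatives`, `labelled_positive`.
#' @examples
#' # a 30-million-record corpus, 14.8% relevant, screened at
#' # sensitivity 0.954 / specificity 0.85
#' project_corpus_scale(30e6, 0.148, 0.954, 0.85)
#' @export
project_corpus_scale <- function(corpus_size, prevalence, sensitivity,
                                 specificity) {
  if (!is.numeric(corpus_size) || length(corpus_size) != 1L ||
      corpus_size <= 0)
    stop_vs("corpus_size must be a single positive number")
  check_proportion(prevalence, "prevalence")
  check_proportion(sensitivity, "sensitivity")
  check_proportion(specificity, "specificity")
  positives <- prevalence * corpus_size
  negatives <- corpus_size - positives
  tp <- sensitivity * positives
  fn <- (1 - sensitivity) * positives
  fp <- (1 - specificity) * negatives
  tn <- specificity * negatives
  structure(list(corpus_size = corpus_size, prevalence = prevalence,
                 true_positives = tp, false_positives = fp,
                 false_negatives = fn, true_negatives = tn,
                 labelled_positive = tp + fp),
            class = "corpus_projection")
}

#' @method print corpus_projection
#' @export
print.corpus_projection <- function(x, ...) {
  f <- function(v) format(v, big.mark = ",", scientific = FALSE)
  cat("Corpus of", f(x$corpus_size), "records at prevalence",
      x$prevalence, "\n",
      " labelled positive:", f(signif(x$labelled_positive, 3)), "\n",
      " wrongly included (FP):", f(signif(x$false_positives, 3)), "\n",
      " wrongly excluded (FN):", f(signif(x$false_negatives, 3)), "\n")
  invisible(x)
}
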
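# Dual-reviewer reconciliation with third-reviewer arbitration, and
# gold-standard construction from reconciled full-text decisions plus
# senior re-evaluation of cross-method conflicts.

#' Reconcile dual-reviewer decisions
#'
#' Two independent reviewers screen each record; where they agree, that
#' decision stands and the arbitrator is never consulted. Where they
#' disagree, the third reviewer's arbitration decision is used; a
#' disagreement without an arbitration decision is an error (condition
#' class `"needs_arbitration"`, carrying the offending record ids).
#' The result is symmetric in the first two reviewers.
#'
#' @param first,second Logical include decisions of reviewers 1 and 2
#'   (vectors of equal length, optionally named by record id).
#' @param arbitration Optional logical vector of third-reviewer decisions;
#'   only consulted (and only required to be non-`NA`) where `first` and
#'   `second` disagree.
#' @return Logical vector of reconciled decisions.
#' @examples
#' reconcile(c(TRUE, TRUE), c(TRUE, FALSE), c(NA, FALSE))
#' @export
reconcile <- function(first, second, arbitration = NULL) {
  nm <- names(first)
  first <- as.logical(first); second <- as.logical(second)
  names(first) <- nm
  if (length(first) != length(second))
    stop_vs("reviewer decision vectors differ in length")
  disagree <- first != second
  out <- first
  if (any(disagree)) {
    if (is.null(arbitration))
      arbitration <- rep(NA, length(first))
    arbitration <- as.logical(arbitration)
    missing <- disagree & is.na(arbitration)
    if (any(missing)) {
      ids <- names(first)[missing] %||% which(missing)
      stop(structure(class = c("needs_arbitration", "error", "condition"),
                     list(message = paste0(
                       "disagreement without arbitration for record(s): ",
                       paste(ids, collapse = ", ")),
                       call = sys.call(-1), record_ids = ids)))
    }
    out[disagree] <- arbitration[disagree]
  }
  out
}

#' Build the gold-standard label set
#'
#' Reconciled human full-text decisions are taken as the most complete
#' single source of truth. Any record on which another screening method
#' disagrees with the full-text decision is re-evaluated by a senior
#' reviewer (the oracle), whose verdict becomes the gold label for that
#' record; all other records keep the full-text decision.
#'
#' @param fulltext_reconciled Named logical vector: reconciled human
#'   full-text decisions over the analysis set.
#' @param other_method_decisions List of named logical vectors (e.g. human
#'   TiAb, regex TiAb at its threshold, regex full text at its threshold),
#'   each covering the same ids.
#' @param senior_oracle Senior re-evaluation verdicts: named logical vector
#'   or function `id -> logical`; must be defined on every conflicted id.
#' @return An object of class `gold_standard`: data.frame `record_id`,
#'   `include`, `provenance` (`"reconciled_fulltext"` or
#'   `"senior_reevaluation"`).
#' @export
build_gold_standard <- function(fulltext_reconciled, other_method_decisions,
                                senior_oracle) {
  ft <- check_named(fulltext_reconciled, "fulltext_reconciled")
  if (!is.list(other_method_decisions))
    other_method_decisions <- list(other_method_decisions)
  conflicted <- rep(FALSE, length(ft))
  names(conflicted) <- names(ft)
  for (m in other_method_decisions) {
    m <- check_named(m, "a method decision map")
    check_same_ids(ft, m, "fulltext decisions", "method decisions")
    conflicted <- conflicted | (as.logical(m[names(ft)]) != as.logical(ft))
  }
  include <- as.logical(ft)
  provenance <- rep("reconciled_fulltext", length(ft))
  for (id in names(ft)[conflicted]) {
    v <- if (is.function(senior_oracle)) senior_oracle(id) else
      if (id %in% names(senior_oracle)) senior_oracle[[id]] else NA
    if (is.na(v)) stop_vs("senior oracle has no verdict for conflicted ",
                          "record ", id)
    include[names(ft) == id] <- as.logical(v)
    provenance[names(ft) == id] <- "senior_reevaluation"
  }
  structure(data.frame(record_id = names(ft), include = include,
                       provenance = provenance, stringsAsFactors = FALSE,
                       row.names = NULL),
            class = c("gold_standard", "data.frame"))
}

#' @method print gold_standard
#' @export
print.gold_standard <- function(x, ...) {
  cat("Gold standard over", nrow(x), "records:", sum(x$include),
      "includes (", sum(x$provenance == "senior_reevaluation"),
      "set by senior re-evaluation )\n")
  invisible(x)
}

#' Named label vector from a gold standard
#'
#' @param gold A `gold_standard` (or any data.frame with `record_id` and
#'   `include`).
#' @return Named logical vector keyed by record id.
#' @export
gold_vector <- function(gold) {
  check_named(setNames(gold$include, gold$record_id), "gold standard")
}
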
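# Seeded synthetic corpora with the statistical structure the screening
# comparison assumes: low prevalence of relevant records, term mentions
# appearing more reliably in full text than in abstracts, long-tailed
# integer match-count distributions, a two-pool topic-vocabulary signal,
# and simulated dual reviewers with independent error rates.

#' Specification for a synthetic screening corpus
#'
#' Defaults emulate the exemplar in vitro review corpus: 5172 records at
#' 6.2% prevalence of relevant records; relevant full texts carry
#' `1 + Poisson(12)` term mentions (capped at 281, the long right tail of
#' observed full-text counts); a relevant record's abstract carries at
#' least one mention with probability 0.862 (so title/abstract screening
#' misses about 14% of relevant records through abstract omission), with
#' `1 + Poisson(1.5)` mentions capped at 15; irrelevant records mention
#' the terms spuriously with probability 0.03 (`1 + Poisson(1)` mentions,
#' a 0.17 share of which also reach the abstract). Titles and filler text
#' are drawn from two topic word pools -- an in vitro pool and an
#' "other-topic" pool -- mixed at `pool_mixing` toward the record's own
#' class, which gives the classifier an imperfect (overlapping-vocabulary)
#' signal. Reviewer error rates apply per reviewer and stage simulation.
#'
#' @param n_records Corpus size.
#' @param prevalence Proportion of truly relevant records.
#' @param relevant_ft_mean,relevant_ft_cap Full-text mention distribution
#'   for relevant records: `1 + Poisson(mean)`, capped.
#' @param abstract_mention_prob Probability a relevant record's abstract
#'   carries at least one mention.
#' @param relevant_tiab_mean,relevant_tiab_cap Abstract mention counts for
#'   relevant records (given the mention event): `1 + Poisson(mean)`,
#'   capped.
#' @param irrelevant_mention_prob Probability an irrelevant record
#'   mentions the terms at all.
#' @param irrelevant_ft_mean Full-text mentions for such records:
#'   `1 + Poisson(mean)`.
#' @param irrelevant_abstract_share Probability that a mentioning
#'   irrelevant record also carries one mention in its abstract.
#' @param pool_size Words per topic pool.
#' @param pool_mixing Probability a token is drawn from the record's own
#'   class pool (0.5 = indistinguishable vocabularies).
#' @param title_len,abstract_len,fulltext_len Token counts for generated
#'   text fields.
#' @param reviewer_fnr,reviewer_fpr Per-reviewer false-negative and
#'   false-positive rates used by [simulate_reviewers()] defaults.
#' @return An object of class `synthetic_spec` (a validated list).
#' @export
synthetic_spec <- function(n_records = 5172L, prevalence = 0.062,
                           relevant_ft_mean = 12, relevant_ft_cap = 281L,
                           abstract_mention_prob = 0.862,
                           relevant_tiab_mean = 1.5,
                           relevant_tiab_cap = 15L,
                           irrelevant_mention_prob = 0.03,
                           irrelevant_ft_mean = 1,
                           irrelevant_abstract_share = 0.17,
                           pool_size = 60L, pool_mixing = 0.62,
                           title_len = 8L, abstract_len = 60L,
                           fulltext_len = 400L,
                           reviewer_fnr = 0.1, reviewer_fpr = 0.01) {
  spec <- list(n_records = as.integer(n_records),
               prevalence = check_proportion(prevalence, "prevalence"),
               relevant_ft_mean = relevant_ft_mean,
               relevant_ft_cap = as.integer(relevant_ft_cap),
               abstract_mention_prob =
                 check_proportion(abstract_mention_prob,
                                  "abstract_mention_prob"),
               relevant_tiab_mean = relevant_tiab_mean,
               relevant_tiab_cap = as.integer(relevant_tiab_cap),
               irrelevant_mention_prob =
                 check_proportion(irrelevant_mention_prob,
                                  "irrelevant_mention_prob"),
               irrelevant_ft_mean = irrelevant_ft_mean,
               irrelevant_abstract_share =
                 check_proportion(irrelevant_abstract_share,
                                  "irrelevant_abstract_share"),
               pool_size = as.integer(pool_size),
               pool_mixing = check_proportion(pool_mixing, "pool_mixing"),
               title_len = as.integer(title_len),
               abstract_len = as.integer(abstract_len),
               fulltext_len = as.integer(fulltext_len),
               reviewer_fnr = check_proportion(reviewer_fnr, "reviewer_fnr"),
               reviewer_fpr = check_proportion(reviewer_fpr, "reviewer_fpr"))
  if (spec$n_records < 1L) stop_vs("n_records must be positive")
  if (spec$relevant_ft_cap < 1L)
    stop_vs("relevant_ft_cap must be at least 1: every relevant full ",
            "text carries a mention")
  if (spec$relevant_ft_mean < 0 || spec$irrelevant_ft_mean < 0 ||
      spec$relevant_tiab_mean < 0)
    stop_vs("Poisson means must be non-negative")
  structure(spec, class = "synthetic_spec")
}

#' @method print synthetic_spec
#' @export
print.synthetic_spec <- function(x, ...) {
  cat("Synthetic corpus spec: n =", x$n_records, ", prevalence =",
      x$prevalence, "\n  full-text mentions: relevant 1+Pois(",
      x$relevant_ft_mean, ") cap ", x$relevant_ft_cap,
      "; irrelevant event p = ", x$irrelevant_mention_prob, "\n",
      "  abstract mention probability (relevant): ",
      x$abstract_mention_prob, "\n  topic pools: ", x$pool_size,
      " words each, own-pool mixing ", x$pool_mixing, "\n", sep = "")
  invisible(x)
}

# The surface forms injected as term mentions; all match the packaged OGD
# pattern exactly once each.
MENTION_VARIANTS <- c("oxygen-glucose deprivation", "OGD",
                      "oxygen and glucose deprivation",
                      "deprived of oxygen and glucose")

topic_pools <- function(pool_size) {
  list(relevant = sprintf("cellassay%02d", seq_len(pool_size)),
       irrelevant = sprintf("clinfield%02d", seq_len(pool_size)))
}

# Token stream of length len from the two pools, mixed toward `own`.
draw_tokens <- function(len, pools, own, mixing) {
  from_own <- runif(len) < mixing
  other <- setdiff(c("relevant", "irrelevant"), own)
  tok <- character(len)
  tok[from_own] <- sample(pools[[own]], sum(from_own), replace = TRUE)
  tok[!from_own] <- sample(pools[[other]], sum(!from_own), replace = TRUE)
  tok
}

# Interleave `n_mentions` mention strings into a token stream.
inject_mentions <- function(tokens, n_mentions) {
  if (n_mentions == 0L) return(paste(tokens, collapse = " "))
  mentions <- sample(MENTION_VARIANTS, n_mentions, replace = TRUE)
  slots <- sort(sample.int(length(tokens) + 1L, n_mentions,
                           replace = TRUE)) - 1L
  pieces <- character()
  prev <- 0L
  for (i in seq_len(n_mentions)) {
    pieces <- c(pieces, tokens[seq_len(slots[i] - prev) + prev],
                mentions[i])
    prev <- slots[i]
  }
  pieces <- c(pieces, if (prev < length(tokens))
    tokens[(prev + 1L):length(tokens)])
  paste(pieces, collapse = " ")
}

rpois_capped <- function(n, mean, cap) pmin(1L + rpois(n, mean), cap)

#' Generate a labeled synthetic corpus
#'
#' Draws labels `Bernoulli(prevalence)`, then builds each record's title,
#' abstract and full text from class-conditional topic-pool token streams
#' with the drawn number of term mentions injected. The full text is the
#' abstract followed by a body, so full-text match counts always dominate
#' title/abstract counts; the number of full-text mentions equals the
#' drawn count exactly (mention variants cannot overlap or merge).
#'
#' @param spec A [synthetic_spec()].
#' @param seed Integer seed; generation is reproducible.
#' @return A list of class `labeled_corpus`: `records` (data.frame as in
#'   [read_records()]), `labels` (named logical ground truth), and the
#'   drawn `tiab_mentions` / `fulltext_mentions` counts (named integer).
#' @examples
#' corp <- generate_corpus(synthetic_spec(n_records = 50), seed = 1)
#' table(corp$labels)
#' @export
generate_corpus <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(seed)
  n <- spec$n_records
  labels <- runif(n) < spec$prevalence
  pools <- topic_pools(spec$pool_size)
  # mention counts
  ft <- integer(n); ab <- integer(n)
  nrel <- sum(labels)
  if (nrel) {
    ft[labels] <- rpois_capped(nrel, spec$relevant_ft_mean,
                               spec$relevant_ft_cap)
    event <- runif(nrel) < spec$abstract_mention_prob
    ab_rel <- integer(nrel)
    ab_rel[event] <- rpois_capped(sum(event), spec$relevant_tiab_mean,
                                  spec$relevant_tiab_cap)
    ab[labels] <- pmin(ab_rel, ft[labels])
  }
  nirr <- n - nrel
  if (nirr) {
    event <- runif(nirr) < spec$irrelevant_mention_prob
    ft_irr <- integer(nirr)
    ft_irr[event] <- 1L + rpois(sum(event), spec$irrelevant_ft_mean)
    ab_irr <- integer(nirr)
    ab_irr[event] <- as.integer(runif(sum(event)) <
                                  spec$irrelevant_abstract_share)
    ft[!labels] <- ft_irr
    ab[!labels] <- pmin(ab_irr, ft_irr)
  }
  ids <- sprintf("syn-%05d", seq_len(n))
  cls <- ifelse(labels, "relevant", "irrelevant")
  title <- character(n); abstract <- character(n); fulltext <- character(n)
  for (i in seq_len(n)) {
    title[i] <- paste(draw_tokens(spec$title_len, pools, cls[i],
                                  spec$pool_mixing), collapse = " ")
    abstract[i] <- inject_mentions(
      draw_tokens(spec$abstract_len, pools, cls[i], spec$pool_mixing),
      ab[i])
    body <- inject_mentions(
      draw_tokens(spec$fulltext_len, pools, cls[i], spec$pool_mixing),
      ft[i] - ab[i])
    fulltext[i] <- paste(abstract[i], body)
  }
  records <- data.frame(id = ids, title = title, abstract = abstract,
                        full_text = fulltext,
                        is_conference_abstract = FALSE, language = "en",
                        stringsAsFactors = FALSE)
  structure(list(records = records,
                 labels = setNames(labels, ids),
                 tiab_mentions = setNames(ab, ids),
                 fulltext_mentions = setNames(ft, ids),
                 spec = spec, seed = as.integer(seed)),
            class = "labeled_corpus")
}

#' @method print labeled_corpus
#' @export
print.labeled_corpus <- function(x, ...) {
  cat("Synthetic labeled corpus:", nrow(x$records), "records,",
      sum(x$labels), "relevant (seed", x$seed, ")\n")
  invisible(x)
}

#' Simulate dual reviewers with arbitration
#'
#' Each of reviewers 1 and 2 independently misclassifies the truth with
#' the given false-negative rate (on positives) and false-positive rate
#' (on negatives); where they disagree, reviewer 3 (the arbitrator)
#' produces an arbitration decision by the same error process with its own
#' rates. Reconciliation follows [reconcile()].
#'
#' `truth` is whatever a reviewer could in principle get right at this
#' stage: for a title/abstract stage that is typically
#' `labels & (tiab mentions > 0)` (a relevant record whose abstract never
#' signals relevance cannot be recognized from the abstract).
#'
#' @param truth Named logical vector of stage-visible truth per record.
#' @param error Named list of per-reviewer error rates: elements `r1`,
#'   `r2`, `r3`, each `c(fnr = , fpr = )`.
#' @param seed Integer seed.
#' @param stage Stage recorded in the output (`"tiab"` or `"fulltext"`).
#' @return A data.frame of class `review_set`: `record_id`, `reviewer1`,
#'   `reviewer2`, `arbitration` (`NA` where not consulted), `reconciled`,
#'   `stage`.
#' @examples
#' tr <- setNames(rep(c(TRUE, FALSE), 5), paste0("r", 1:10))
#' simulate_reviewers(tr, seed = 1)
#' @export
simulate_reviewers <- function(truth,
                               error = list(r1 = c(fnr = 0.1, fpr = 0.01),
                                            r2 = c(fnr = 0.1, fpr = 0.01),
                                            r3 = c(fnr = 0.1, fpr = 0.01)),
                               seed = 1L, stage = "tiab") {
  truth <- check_named(truth, "truth")
  truth <- setNames(as.logical(truth), names(truth))
  for (r in c("r1", "r2", "r3")) {
    er <- error[[r]]
    if (is.null(er) || !all(c("fnr", "fpr") %in% names(er)) ||
        !all(er >= 0 & er <= 1))
      stop_vs("error$", r, " must supply fnr and fpr in [0, 1]")
  }
  set.seed(seed)
  flip <- function(er) {
    p <- ifelse(truth, er[["fnr"]], er[["fpr"]])
    xor(truth, runif(length(truth)) < p)
  }
  r1 <- flip(error$r1); r2 <- flip(error$r2); r3 <- flip(error$r3)
  arbitration <- ifelse(r1 != r2, r3, NA)
  out <- data.frame(record_id = names(truth), reviewer1 = r1,
                    reviewer2 = r2, arbitration = arbitration,
                    reconciled = reconcile(r1, r2, arbitration),
                    stage = stage, stringsAsFactors = FALSE,
                    row.names = NULL)
  class(out) <- c("review_set", "data.frame")
  out
}
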
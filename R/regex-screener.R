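# Dictionary screening: term-variant patterns, match counting, and
# threshold-based inclusion decisions.

# Dash glyphs folded to ASCII hyphen before matching: hyphen, non-breaking
# hyphen, figure dash, en dash, em dash, minus sign.
DASH_CLASS <- "[\\u2010\\u2011\\u2012\\u2013\\u2014\\u2212]"

# Separator class allowed between the words of a multiword term:
# whitespace, hyphen (after dash folding) or slash, in any run.
WORD_SEP <- "(?:[\\s/-]+)"

#' Normalize text for pattern matching
#'
#' Applies Unicode NFKC normalization and folds the dash glyph family
#' (hyphen, non-breaking hyphen, figure/en/em dash, minus sign) to the
#' ASCII hyphen, so that e.g. "oxygen–glucose deprivation" from a PDF
#' extraction matches the same pattern as "oxygen-glucose deprivation".
#'
#' @param text Character vector.
#' @return Normalized character vector.
#' @export
normalize_text <- function(text) {
  out <- stringi::stri_trans_nfkc(enc2utf8(as.character(text)))
  stringi::stri_replace_all_charclass(out, DASH_CLASS, "-")
}

#' Term sets for dictionary screening
#'
#' A term set is a list of term specifications. Each term has a `phrase`
#' (a word sequence), optional `variants` (alternative word sequences, e.g.
#' conjunction forms), and an optional `abbrev` (an abbreviation matched at
#' word boundaries). `ogd_term_set()` returns the packaged exemplar set for
#' oxygen-glucose deprivation; `read_term_set()` loads a YAML file with the
#' same structure (top-level key `terms`).
#'
#' @param terms A list of term specifications, each a list with elements
#'   `phrase` (character vector of words), `variants` (list of character
#'   vectors, optional) and `abbrev` (string, optional).
#' @return An object of class `term_set`.
#' @examples
#' ts <- term_set(list(list(phrase = c("oxygen", "glucose", "deprivation"),
#'                          abbrev = "OGD")))
#' @export
term_set <- function(terms) {
  if (!is.list(terms) || !length(terms))
    stop_vs("a term set needs at least one term")
  terms <- lapply(seq_along(terms), function(i) {
    t <- terms[[i]]
    if (is.null(t$phrase) && is.null(t$abbrev))
      stop_vs("term ", i, " has neither a phrase nor an abbrev")
    if (!is.null(t$phrase)) {
      t$phrase <- as.character(unlist(t$phrase))
      if (!length(t$phrase) || any(!nzchar(t$phrase)))
        stop_vs("term ", i, ": phrase words must be non-empty")
    }
    t$variants <- lapply(t$variants %||% list(), function(v) {
      v <- as.character(unlist(v))
      if (!length(v) || any(!nzchar(v)))
        stop_vs("term ", i, ": variant words must be non-empty")
      v
    })
    if (!is.null(t$abbrev)) {
      t$abbrev <- as.character(t$abbrev)
      if (!nzchar(t$abbrev)) stop_vs("term ", i, ": empty abbreviation")
    }
    t
  })
  structure(list(terms = terms), class = "term_set")
}

#' @rdname term_set
#' @param path Path to a YAML term-set file.
#' @export
read_term_set <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$terms)) stop_vs("term-set YAML needs a top-level 'terms' key")
  term_set(cfg$terms)
}

#' @rdname term_set
#' @export
ogd_term_set <- function() {
  read_term_set(system.file("extdata", "ogd_terms.yaml",
                            package = "vitroscreen"))
}

#' @method print term_set
#' @export
print.term_set <- function(x, ...) {
  cat("Term set with", length(x$terms), "term(s)\n")
  for (t in x$terms) {
    if (!is.null(t$phrase)) cat("  phrase:", paste(t$phrase, collapse = " "),
                                if (length(t$variants))
                                  sprintf("(+%d variants)", length(t$variants)),
                                "\n")
    if (!is.null(t$abbrev)) cat("  abbrev:", t$abbrev, "\n")
  }
  invisible(x)
}

#' Compile a term set into a matching pattern
#'
#' Builds a single regular expression matching every surface form of every
#' term. Multiword phrases allow any run of whitespace, hyphen (after dash
#' folding, see [normalize_text()]) or slash between words and are matched
#' case-insensitively; abbreviations are matched at word boundaries and,
#' by default, case-sensitively (so "OGD" does not fire inside "logden" or
#' on lowercase "ogd"). Matching is non-overlapping, leftmost first, with
#' longer alternatives preferred at the same start position.
#'
#' @param terms A [term_set()] (or a bare list accepted by it).
#' @param abbrev_case_sensitive Match abbreviations exactly as written
#'   (default TRUE).
#' @return An object of class `term_pattern` with the compiled regex.
#' @examples
#' p <- build_term_pattern(ogd_term_set())
#' count_matches("oxygen–glucose deprivation impaired viability", p)
#' @export
build_term_pattern <- function(terms, abbrev_case_sensitive = TRUE) {
  if (!inherits(terms, "term_set")) terms <- term_set(terms)
  phrase_alts <- character(); abbrev_alts <- character()
  for (t in terms$terms) {
    seqs <- c(if (!is.null(t$phrase)) list(t$phrase), t$variants)
    for (s in seqs) {
      words <- vapply(s, escape_regex, character(1))
      phrase_alts <- c(phrase_alts, paste(words, collapse = WORD_SEP))
    }
    if (!is.null(t$abbrev))
      abbrev_alts <- c(abbrev_alts, escape_regex(t$abbrev))
  }
  # longest-first so leftmost matching prefers the longer surface form
  phrase_alts <- phrase_alts[order(-nchar(phrase_alts))]
  parts <- character()
  if (length(phrase_alts))
    parts <- c(parts, sprintf("(?i:\\b(?:%s)\\b)",
                              paste(phrase_alts, collapse = "|")))
  if (length(abbrev_alts)) {
    ab <- sprintf("\\b(?:%s)\\b", paste(abbrev_alts, collapse = "|"))
    if (!abbrev_case_sensitive) ab <- sprintf("(?i:%s)", ab)
    parts <- c(parts, ab)
  }
  structure(list(regex = paste(parts, collapse = "|"),
                 terms = terms,
                 abbrev_case_sensitive = abbrev_case_sensitive),
            class = "term_pattern")
}

escape_regex <- function(x) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", x)

#' @method print term_pattern
#' @export
print.term_pattern <- function(x, ...) {
  cat("Compiled term pattern:\n  ", x$regex, "\n", sep = "")
  invisible(x)
}

#' Count term-pattern matches in a text
#'
#' Counts non-overlapping, left-to-right matches of a compiled
#' [build_term_pattern()] pattern in a text after [normalize_text()]
#' normalization. A count of one means some surface form of the term is
#' mentioned exactly once, two means twice, and so on.
#'
#' @param text A character string (possibly empty or `NA`; both count 0).
#' @param pattern A `term_pattern`.
#' @return A non-negative integer count (vectorized over `text`).
#' @export
count_matches <- function(text, pattern) {
  stopifnot(inherits(pattern, "term_pattern"))
  text <- as.character(text)
  out <- integer(length(text))
  ok <- !is.na(text) & nzchar(text)
  if (any(ok)) {
    norm <- normalize_text(text[ok])
    m <- gregexpr(pattern$regex, norm, perl = TRUE)
    out[ok] <- vapply(m, function(mm) sum(mm > 0L), integer(1))
  }
  out
}

#' Screen a corpus by match-count threshold
#'
#' Scores every record by the number of pattern matches in its
#' title+abstract (`scope = "tiab"`, joined with a single non-matching
#' space) or full text (`scope = "fulltext"`), and includes a record iff
#' its count is at least `threshold`. With the packaged OGD term set the
#' operating thresholds are 1 match for title/abstract and 2 matches for
#' full text.
#'
#' Records lacking a full text cannot be scored at `scope = "fulltext"`;
#' they are skipped (reported in `skipped`, with a message), never silently
#' dropped.
#'
#' @param records Record data.frame (see [read_records()]).
#' @param pattern A compiled `term_pattern`.
#' @param scope `"tiab"` or `"fulltext"`.
#' @param threshold Positive integer minimum match count for inclusion.
#' @param source Identifier recorded in the decisions (default
#'   `"regex_<scope>"`).
#' @return A list with `scores` (data.frame `record_id`, `scope`, `count`),
#'   `decisions` (decision data.frame as in [write_decisions()]) and
#'   `skipped` (ids without full text when `scope = "fulltext"`).
#' @examples
#' recs <- data.frame(id = "r1", title = "OGD model",
#'                    abstract = "oxygen-glucose deprivation in PC-12",
#'                    full_text = NA_character_,
#'                    is_conference_abstract = FALSE, language = "en")
#' screen_corpus(recs, build_term_pattern(ogd_term_set()), "tiab", 1)
#' @export
screen_corpus <- function(records, pattern, scope = c("tiab", "fulltext"),
                          threshold = 1L, source = NULL) {
  scope <- match.arg(scope)
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold < 1)
    stop_vs("threshold must be a positive integer (got ",
            deparse(threshold), ")")
  source <- source %||% paste0("regex_", scope)
  if (scope == "tiab") {
    text <- ifelse(is.na(records$abstract), records$title,
                   paste(records$title, records$abstract))
    scored <- records$id
  } else {
    has_ft <- !is.na(records$full_text)
    if (!all(has_ft))
      message(sum(!has_ft), " record(s) lack full text and were skipped ",
              "at fulltext scope")
    text <- records$full_text[has_ft]
    scored <- records$id[has_ft]
  }
  counts <- count_matches(text, pattern)
  scores <- data.frame(record_id = scored, scope = scope, count = counts,
                       stringsAsFactors = FALSE)
  decisions <- data.frame(record_id = scored,
                          stage = scope, source = source,
                          include = counts >= threshold,
                          stringsAsFactors = FALSE)
  list(scores = scores, decisions = decisions,
       skipped = setdiff(records$id, scored))
}
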
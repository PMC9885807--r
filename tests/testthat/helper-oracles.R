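# Independent oracles and fixture builders shared across tests.

# Surface variants of the packaged OGD term set as token sequences,
# longest first (matching the scan preference of the compiled pattern).
OGD_VARIANT_TOKENS <- list(
  c("deprived", "of", "oxygen", "and", "glucose"),
  c("deprivation", "of", "oxygen", "and", "glucose"),
  c("oxygen", "and", "glucose", "deprivation"),
  c("glucose", "and", "oxygen", "deprivation"),
  c("oxygen", "glucose", "deprivation"))

# Brute-force match counter, independent of the regex implementation:
# fold dash glyphs, cut the text into alphanumeric tokens with their
# separator gaps, then scan tokens left to right, at each position trying
# the variants longest first (phrases case-insensitive, words joined only
# by space/hyphen/slash runs; "OGD" as its own exact-case token).
naive_count_oracle <- function(text) {
  for (g in c("‐", "‑", "‒", "–", "—", "−"))
    text <- gsub(g, "-", text, fixed = TRUE)
  m <- gregexpr("[A-Za-z0-9]+", text)[[1]]
  if (m[1] == -1L) return(0L)
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  tokens <- substring(text, starts, starts + lens - 1L)
  ntok <- length(tokens)
  gap_ok <- logical(max(ntok - 1L, 0L))
  if (ntok > 1L) {
    gaps <- substring(text, starts[-ntok] + lens[-ntok], starts[-1L] - 1L)
    gap_ok <- grepl("^[ \t\r\n/-]+$", gaps)
  }
  low <- tolower(tokens)
  i <- 1L; count <- 0L
  while (i <= ntok) {
    if (tokens[i] == "OGD") { count <- count + 1L; i <- i + 1L; next }
    matched <- FALSE
    for (v in OGD_VARIANT_TOKENS) {
      k <- length(v)
      if (i + k - 1L <= ntok &&
          all(low[i:(i + k - 1L)] == v) &&
          all(gap_ok[i:(i + k - 2L)])) {
        count <- count + 1L; i <- i + k; matched <- TRUE; break
      }
    }
    if (!matched) i <- i + 1L
  }
  count
}

# Tie-adjusted pairwise-comparison (Mann-Whitney) AUC oracle.
mann_whitney_auc <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  cmp <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  mean(cmp)
}

# Minimal record data.frame builder.
make_records <- function(id, title = "title", abstract = "abstract",
                         full_text = NA_character_, conference = FALSE,
                         language = "en") {
  data.frame(id = id, title = title, abstract = abstract,
             full_text = full_text, is_conference_abstract = conference,
             language = language, stringsAsFactors = FALSE)
}

# Random filler text that can never match the OGD pattern.
filler_text <- function(n_tokens) {
  paste(sample(sprintf("tok%02d", 1:40), n_tokens, replace = TRUE),
        collapse = " ")
}

# Random text mixing OGD surface forms with filler and punctuation noise;
# returns the text (the oracle provides the expected count).
random_mention_text <- function() {
  surface <- c("oxygen-glucose deprivation", "oxygen–glucose deprivation",
               "OGD", "ogd", "oxygen and glucose deprivation",
               "deprived of oxygen and glucose", "oxygen/glucose/deprivation",
               "oxygen  glucose deprivation", "LOGDEN", "glucose",
               "deprivation of oxygen and glucose")
  n <- sample(0:6, 1)
  pieces <- character(0)
  for (i in seq_len(n)) {
    pieces <- c(pieces, filler_text(sample(0:4, 1)), sample(surface, 1))
  }
  pieces <- c(pieces, filler_text(sample(0:4, 1)))
  pieces <- pieces[nzchar(pieces)]
  seps <- sample(c(" ", ", ", "; ", ". ", " - "),
                 max(length(pieces) - 1L, 0L), replace = TRUE)
  paste0(pieces, c(seps, ""), collapse = "")
}
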
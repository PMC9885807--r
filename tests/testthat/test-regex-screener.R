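pattern <- build_term_pattern(ogd_term_set())

test_that("known OGD surface forms are counted correctly", {
  expect_identical(
    count_matches("oxygen–glucose deprivation impaired viability", pattern),
    1L)
  expect_identical(
    count_matches(paste("Cells deprived of oxygen and glucose (OGD) for",
                        "4 h; OGD reduced survival."), pattern),
    3L)
  expect_identical(count_matches("", pattern), 0L)
  expect_identical(count_matches(NA_character_, pattern), 0L)
  # word-boundary contract for the abbreviation
  expect_identical(count_matches("LOGDEN", pattern), 0L)
  # abbreviation is exact-case by default, configurable
  expect_identical(count_matches("the ogd model", pattern), 0L)
  insens <- build_term_pattern(ogd_term_set(), abbrev_case_sensitive = FALSE)
  expect_identical(count_matches("the ogd model", insens), 1L)
})

test_that("dash glyphs, slashes and spacing variants all match", {
  for (txt in c("oxygen-glucose deprivation", "oxygen–glucose deprivation",
                "oxygen—glucose deprivation", "oxygen‑glucose deprivation",
                "oxygen/glucose deprivation", "oxygen  glucose  deprivation",
                "OXYGEN GLUCOSE DEPRIVATION",
                "oxygen-\nglucose deprivation"))
    expect_identical(count_matches(txt, pattern), 1L)
  # a comma breaks the phrase
  expect_identical(count_matches("oxygen, glucose deprivation", pattern), 0L)
})

test_that("term-set validation rejects malformed inputs", {
  expect_error(term_set(list()), "at least one")
  expect_error(term_set(list(list())), "neither")
  expect_error(term_set(list(list(phrase = c("a", "")))), "non-empty")
  expect_error(build_term_pattern(list(list(abbrev = ""))), "empty")
})

test_that("YAML term sets load and extend the packaged exemplar", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("terms:",
               "  - phrase: [middle, cerebral, artery, occlusion]",
               "    abbrev: MCAO"), f)
  p <- build_term_pattern(read_term_set(f))
  expect_identical(count_matches("middle cerebral artery occlusion (MCAO)",
                                 p), 2L)
})

test_that("corpus screening applies the count threshold over the scope", {
  recs <- make_records(
    sprintf("r%d", 1:4), title = "neuro study",
    abstract = c("no mention here",
                 "one oxygen-glucose deprivation mention",
                 "OGD and more OGD",
                 paste(rep("OGD", 5), collapse = " then ")))
  out <- screen_corpus(recs, pattern, "tiab", threshold = 1)
  expect_identical(out$scores$count, c(0L, 1L, 2L, 5L))
  expect_identical(out$decisions$record_id[out$decisions$include],
                   c("r2", "r3", "r4"))
  out2 <- screen_corpus(recs, pattern, "tiab", threshold = 2)
  expect_identical(out2$decisions$record_id[out2$decisions$include],
                   c("r3", "r4"))
  expect_error(screen_corpus(recs, pattern, "tiab", threshold = 0),
               "threshold")
})

test_that("full-text screening skips records without full text, loudly", {
  recs <- make_records(c("a", "b"), full_text = c("OGD OGD", NA))
  expect_message(out <- screen_corpus(recs, pattern, "fulltext", 2),
                 "skipped")
  expect_identical(out$scores$record_id, "a")
  expect_identical(out$skipped, "b")
  expect_true(out$decisions$include)
})

test_that("match counts agree with the brute-force variant-scan oracle", {
  set.seed(421)
  for (i in 1:300) {
    txt <- random_mention_text()
    expect_identical(count_matches(txt, pattern),
                     as.integer(naive_count_oracle(txt)),
                     info = txt)
  }
})

test_that("counts are additive across non-matching delimiters", {
  set.seed(97)
  for (i in 1:100) {
    a <- random_mention_text(); b <- random_mention_text()
    expect_identical(count_matches(paste(a, b, sep = "\n\n"), pattern),
                     count_matches(a, pattern) + count_matches(b, pattern))
  }
})

test_that("raising the threshold never grows the included set", {
  recs <- make_records(sprintf("r%02d", 1:30),
                       abstract = vapply(1:30, function(i) {
                         set.seed(i); random_mention_text()
                       }, character(1)))
  prev <- NULL
  for (thr in 1:6) {
    inc <- with(screen_corpus(recs, pattern, "tiab", thr)$decisions,
                record_id[include])
    if (!is.null(prev)) expect_true(all(inc %in% prev))
    prev <- inc
  }
})

test_that("title/abstract counts never exceed full-text counts when the
           full text embeds the abstract", {
  set.seed(55)
  abstracts <- replicate(40, random_mention_text())
  recs <- make_records(sprintf("r%02d", 1:40), title = "OGD in PC-12",
                       abstract = abstracts,
                       full_text = paste(abstracts, "body text with OGD"))
  tiab <- screen_corpus(recs, pattern, "tiab", 1)$scores$count
  ft <- screen_corpus(recs, pattern, "fulltext", 1)$scores$count
  expect_true(all(tiab <= ft))
})
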
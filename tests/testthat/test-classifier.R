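# A small labeled corpus with disjoint class vocabularies (linearly
# separable by construction) used by several blocks.
separable_corpus <- function(n = 120, seed = 5) {
  set.seed(seed)
  lab <- rep(c(TRUE, FALSE), length.out = n)
  text <- ifelse(lab,
                 replicate(n, paste(sample(sprintf("vitro%02d", 1:20), 12,
                                           TRUE), collapse = " ")),
                 replicate(n, paste(sample(sprintf("clinic%02d", 1:20), 12,
                                           TRUE), collapse = " ")))
  list(records = make_records(sprintf("s%03d", 1:n), title = "t",
                              abstract = text),
       labels = setNames(lab, sprintf("s%03d", 1:n)))
}

test_that("vocabulary enumerates word n-grams up to length three", {
  v <- fit_vocabulary("a b c", min_df = 1)
  expect_identical(sort(v$grams), sort(c("a", "b", "c", "a b", "b c",
                                         "a b c")))
  v2 <- fit_vocabulary(c("one two", "one two", "three"), min_df = 2)
  expect_identical(v2$grams, c("one", "one two", "two"))
  expect_error(fit_vocabulary(c("", "  ")), "all-empty")
  expect_error(fit_vocabulary("a b", min_df = 5), "min_df")
  expect_identical(fit_vocabulary(c("x y", "x z"), min_df = 1),
                   fit_vocabulary(c("x y", "x z"), min_df = 1))
})

test_that("the train/validation split has floor sizes, is disjoint and seeded", {
  n <- 2453
  recs <- make_records(sprintf("r%04d", 1:n))
  labs <- setNames(rep(c(TRUE, FALSE), length.out = n), recs$id)
  sp <- split_corpus(recs, labs, 0.8, seed = 42)
  expect_identical(nrow(sp$train$records), 1962L)
  expect_identical(nrow(sp$validation$records), 491L)
  expect_length(intersect(sp$train$records$id, sp$validation$records$id), 0)
  expect_setequal(c(sp$train$records$id, sp$validation$records$id), recs$id)
  sp2 <- split_corpus(recs, labs, 0.8, seed = 42)
  expect_identical(sp$train$records$id, sp2$train$records$id)
  sp3 <- split_corpus(recs, labs, 0.8, seed = 43)
  expect_false(identical(sp$train$records$id, sp3$train$records$id))
  expect_error(split_corpus(recs[1, , drop = FALSE], labs[1], 0.8, 1),
               "at least 2")
  expect_error(split_corpus(recs, labs, 1.2, 1), "between 0 and 1")
})

test_that("training is deterministic and requires both classes", {
  cc <- separable_corpus()
  m1 <- train_screener(cc$records, cc$labels, min_df = 1, seed = 9)
  m2 <- train_screener(cc$records, cc$labels, min_df = 1, seed = 9)
  expect_identical(m1$weights, m2$weights)
  expect_identical(m1$calibration, m2$calibration)
  m3 <- train_screener(cc$records, cc$labels, min_df = 1, seed = 10)
  expect_false(identical(m3$weights, m1$weights))
  expect_error(train_screener(cc$records[cc$labels, ],
                              cc$labels[cc$labels], min_df = 1),
               "both classes")
  expect_error(train_screener(cc$records[0, ], cc$labels[0]), "empty")
})

test_that("a separable corpus is separated, with ordered calibrated scores", {
  cc <- separable_corpus(n = 200)
  sp <- split_corpus(cc$records, cc$labels, 0.8, seed = 2)
  m <- train_screener(sp$train$records, sp$train$labels, min_df = 1,
                      seed = 2)
  vsc <- predict(m, sp$validation$records, type = "score")
  expect_true(all(vsc >= 0 & vsc <= 1))
  expect_equal(roc_curve(vsc, sp$validation$labels)$auc, 1)
  # the recall-targeted threshold may legitimately stop at exactly the
  # target (excluding the lowest-scoring positives it can afford to)
  thr <- threshold_for_sensitivity(vsc, sp$validation$labels, 0.95)
  mm <- metrics(confusion(vsc >= thr, sp$validation$labels))
  expect_gte(mm$sensitivity, 0.95)
  expect_identical(mm$specificity, 1)
  # an include's text outscores an exclude's text
  expect_gt(vsc[which(sp$validation$labels)[1]],
            vsc[which(!sp$validation$labels)[1]])
})

test_that("calibrated scores increase strictly with the linear margin", {
  cc <- separable_corpus()
  m <- train_screener(cc$records, cc$labels, min_df = 1, seed = 1)
  mar <- predict(m, cc$records, type = "margin")
  sc <- predict(m, cc$records, type = "score")
  ord <- order(mar)
  expect_true(all(diff(sc[ord]) >= 0))
  # positive slope guarantees strict monotonicity up to plogis saturation
  expect_gt(m$calibration["slope"], 0)
})

test_that("records made of unseen tokens score at the bias and do not
           perturb other records", {
  cc <- separable_corpus()
  m <- train_screener(cc$records, cc$labels, min_df = 1, seed = 3)
  base <- predict(m, cc$records, type = "score")
  oov <- make_records("oov1", title = "zzz", abstract = "qqq www eee")
  both <- predict(m, rbind(cc$records, oov), type = "score")
  expect_equal(both[names(base)], base, tolerance = 1e-12)
  empty <- make_records("e1", title = "", abstract = NA)
  expect_warning(s0 <- predict(m, empty, type = "score"), "empty document")
  expect_true(s0 >= 0 && s0 <= 1)
})

test_that("reshuffling by seed moves weights but barely moves validation AUC", {
  corp <- generate_corpus(synthetic_spec(n_records = 900,
                                         prevalence = 0.30), seed = 77)
  sp <- split_corpus(corp$records, corp$labels, 0.8, seed = 77)
  aucs <- vapply(1:5, function(s) {
    m <- train_screener(sp$train$records, sp$train$labels, seed = s)
    roc_curve(predict(m, sp$validation$records, type = "score"),
              sp$validation$labels)$auc
  }, numeric(1))
  expect_lt(max(aucs) - min(aucs), 0.05)
})

test_that("models survive a JSON save/load round trip exactly", {
  cc <- separable_corpus()
  m <- train_screener(cc$records, cc$labels, min_df = 1, seed = 4)
  f <- withr::local_tempfile(fileext = ".json")
  write_screener_model(m, f)
  m2 <- read_screener_model(f)
  expect_equal(predict(m2, cc$records, type = "score"),
               predict(m, cc$records, type = "score"), tolerance = 1e-12)
  expect_equal(coef(m2), coef(m), tolerance = 1e-12)
  expect_error(read_screener_model(
    withr::local_tempfile(fileext = ".json", lines = "{}")), "not a")
})
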
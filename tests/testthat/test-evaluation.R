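test_that("confusion tallies decisions against gold and validates ids", {
  gold <- setNames(rep(c(TRUE, FALSE), 5), sprintf("r%d", 1:10))
  cm <- confusion(gold, gold)
  expect_identical(c(cm$tp, cm$tn, cm$fp, cm$fn), c(5L, 5L, 0L, 0L))
  # hand-enumerated 5-record fixture with two disagreements
  dec <- c(a = TRUE, b = FALSE, c = TRUE, d = FALSE, e = TRUE)
  g5 <- c(a = TRUE, b = TRUE, c = FALSE, d = FALSE, e = TRUE)
  cm5 <- confusion(dec, g5)
  expect_identical(c(cm5$tp, cm5$tn, cm5$fp, cm5$fn), c(2L, 1L, 1L, 1L))
  expect_error(confusion(dec[-1], g5), "only in gold: a")
})

test_that("metrics implement the standard ratios with NA for 0/0", {
  m <- metrics(confusion_matrix(2, 1, 1, 1))
  expect_equal(m$sensitivity, 2 / 3)
  expect_equal(m$specificity, 1 / 2)
  expect_equal(m$precision, 2 / 3)
  expect_equal(m$d, sqrt((1 / 3)^2 + (1 / 2)^2))
  u <- metrics(confusion_matrix(0, 10, 0, 0))
  expect_true(is.na(u$sensitivity))
  expect_identical(u$specificity, 1)
  expect_true(is.na(u$precision))
  expect_true(is.na(u$d))
  expect_error(metrics(confusion_matrix(0, 0, 0, 0)), "all counts zero")
  expect_error(confusion_matrix(-1, 0, 0, 0), "non-negative")
})

test_that("sensitivity and specificity invert their defining products", {
  set.seed(3)
  for (i in 1:50) {
    cm <- confusion_matrix(sample(0:50, 1), sample(0:50, 1),
                           sample(0:50, 1), sample(1:50, 1))
    m <- metrics(cm)
    if (!is.na(m$sensitivity))
      expect_equal(m$sensitivity * (cm$tp + cm$fn), cm$tp, tolerance = 1e-12)
    if (!is.na(m$specificity))
      expect_equal(m$specificity * (cm$tn + cm$fp), cm$tn, tolerance = 1e-12)
  }
})

test_that("distance to the perfect corner behaves as a distance", {
  expect_identical(euclidean_distance(1, 1), 0)
  expect_equal(euclidean_distance(0, 0), sqrt(2))
  expect_error(euclidean_distance(1.2, 0.5), "\\[0, 1\\]")
  # monotone decreasing in each argument
  s <- seq(0, 1, by = 0.1)
  expect_true(all(diff(vapply(s, euclidean_distance,
                              specificity = 0.7, numeric(1))) < 0))
  expect_true(all(diff(vapply(s, euclidean_distance,
                              sensitivity = 0.3, numeric(1))) < 0))
})

test_that("ROC anchors, conventions and errors are as specified", {
  sep <- c(p1 = 5, p2 = 4, n1 = 1, n2 = 0)
  gsep <- c(p1 = TRUE, p2 = TRUE, n1 = FALSE, n2 = FALSE)
  r <- roc_curve(sep, gsep)
  expect_identical(r$auc, 1)
  expect_identical(r$points$fpr[r$points$threshold == Inf], 0)
  expect_identical(r$points$tpr[r$points$threshold == Inf], 0)
  expect_identical(r$points$tpr[1], 1)  # at the minimum score: all included
  tied <- roc_curve(c(a = 2, b = 2, c = 2),
                    c(a = TRUE, b = FALSE, c = TRUE))
  expect_identical(nrow(tied$points), 2L)
  expect_identical(tied$auc, 0.5)
  expect_error(roc_curve(c(a = 1), c(a = TRUE)), "positive and one negative")
})

test_that("trapezoidal AUC equals the Mann-Whitney oracle", {
  expect_identical(
    roc_curve(c(a = 3, b = 1, c = 2, d = 0),
              c(a = TRUE, b = TRUE, c = FALSE, d = FALSE))$auc,
    mann_whitney_auc(c(3, 1, 2, 0), c(TRUE, TRUE, FALSE, FALSE)))
  set.seed(11)
  for (i in 1:100) {
    n <- sample(4:30, 1)
    g <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, replace = TRUE))
    sc <- setNames(sample(0:5, n, replace = TRUE), sprintf("r%d", 1:n))
    expect_equal(roc_curve(sc, setNames(g, names(sc)))$auc,
                 mann_whitney_auc(sc, g), tolerance = 1e-12)
  }
})

test_that("TPR and FPR fall monotonically as the count threshold rises", {
  set.seed(12)
  sc <- setNames(sample(0:8, 40, replace = TRUE), sprintf("r%d", 1:40))
  g <- setNames(c(TRUE, FALSE, sample(c(TRUE, FALSE), 38, TRUE)), names(sc))
  p <- roc_curve(sc, g)$points
  expect_true(all(diff(p$tpr) <= 0))
  expect_true(all(diff(p$fpr) <= 0))
})

test_that("the optimal threshold minimizes d with a specificity tie-break", {
  # threshold 1: sens 1.0 / spec 0.50; threshold 2: sens 0.90 / spec 0.99
  sc <- c(setNames(c(rep(2, 9), 1), paste0("p", 1:10)),
          setNames(c(rep(1, 50), rep(0, 49), 2), paste0("n", 1:100)))
  g <- setNames(grepl("^p", names(sc)), names(sc))
  g[names(sc) == "n100"] <- FALSE
  r <- roc_curve(sc, g)
  expect_identical(optimal_threshold(r), 2)
  # tie in d resolved toward the higher-specificity operating point
  sc2 <- c(setNames(c(rep(3, 9), 1), paste0("p", 1:10)),
           setNames(c(rep(0, 9), 2), paste0("n", 1:10)))
  g2 <- setNames(grepl("^p", names(sc2)), names(sc2))
  r2 <- roc_curve(sc2, g2)
  d_at <- function(thr) {
    p <- r2$points[r2$points$threshold == thr, ]
    sqrt((1 - p$tpr)^2 + p$fpr^2)
  }
  expect_equal(d_at(3), d_at(1))   # genuine tie
  expect_identical(optimal_threshold(r2), 3)
  # separable scores: the separating threshold, d = 0
  rsep <- roc_curve(c(p = 4, q = 3, n = 1),
                    c(p = TRUE, q = TRUE, n = FALSE))
  expect_identical(optimal_threshold(rsep), 3)
})

test_that("the recall-targeted threshold is the largest reaching target", {
  sc <- c(p1 = 0.9, p2 = 0.8, p3 = 0.2, n1 = 0.5, n2 = 0.1)
  g <- c(p1 = TRUE, p2 = TRUE, p3 = TRUE, n1 = FALSE, n2 = FALSE)
  expect_identical(threshold_for_sensitivity(sc, g, 0.95), 0.2)
  expect_identical(threshold_for_sensitivity(sc, g, 2 / 3), 0.8)
  expect_identical(threshold_for_sensitivity(sc, g, 1), 0.2)
  sep <- c(p = 1, n = 0); gs <- c(p = TRUE, n = FALSE)
  expect_identical(threshold_for_sensitivity(sep, gs, 0.95), 1)
  expect_error(threshold_for_sensitivity(sc, g, 0), "target")
  expect_error(threshold_for_sensitivity(sc, setNames(rep(FALSE, 5),
                                                      names(sc)), 0.9),
               "no positive")
})

test_that("extrapolation from assumed sensitivity is plain division", {
  expect_identical(extrapolate_total(310, 1), 310)
  expect_equal(extrapolate_total(66, 0.890), 66 / 0.890)
  expect_error(extrapolate_total(10, 0), "\\(0, 1\\]")
  # consistency with a published sensitivity estimate: 350 of 395
  expect_identical(round(350 / 395, 3), 0.886)
})

test_that("corpus-scale projection conserves counts", {
  pr <- project_corpus_scale(1e6, 0.1, 0.9, 0.8)
  expect_equal(pr$true_positives + pr$false_negatives, 0.1 * 1e6)
  expect_equal(pr$false_positives + pr$true_negatives, 0.9 * 1e6)
  expect_equal(pr$labelled_positive, pr$true_positives + pr$false_positives)
  perfect <- project_corpus_scale(1e6, 0.1, 1, 1)
  expect_identical(perfect$false_positives, 0)
  expect_identical(perfect$false_negatives, 0)
  expect_equal(perfect$labelled_positive, 1e5)
  none <- project_corpus_scale(1e6, 0, 0.9, 0.8)
  expect_equal(none$labelled_positive, 0.2 * 1e6)
})
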
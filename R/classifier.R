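# Tri-gram bag-of-words featurization and the SVM-SGD screening
# classifier with Platt-calibrated inclusion scores in [0, 1].

#' Tokenize text for the bag-of-words model
#'
#' Lowercases and splits on runs of non-alphanumeric characters; every
#' non-empty alphanumeric token is kept (including single letters and
#' digits), making the tokenization deterministic and language-agnostic.
#'
#' @param text Character vector.
#' @return A list of character vectors of tokens, one per input text.
#' @export
tokenize <- function(text) {
  text <- tolower(enc2utf8(as.character(text)))
  text[is.na(text)] <- ""
  out <- strsplit(text, "[^a-z0-9]+")
  lapply(out, function(t) t[nzchar(t)])
}

# Word n-grams of length 1..nmax for one token vector; n-gram words are
# joined by a single space.
word_ngrams <- function(tokens, nmax = 3L) {
  L <- length(tokens)
  if (L == 0L) return(character())
  out <- vector("list", nmax)
  out[[1L]] <- tokens
  for (n in seq_len(nmax)[-1L]) {
    if (L < n) break
    g <- tokens[seq_len(L - n + 1L)]
    for (k in seq_len(n - 1L))
      g <- paste(g, tokens[seq_len(L - n + 1L) + k])
    out[[n]] <- g
  }
  unlist(out, use.names = FALSE)
}

#' Fit a bag-of-words vocabulary
#'
#' Builds the vocabulary of word uni-, bi- and tri-grams (configurable via
#' `ngram_max`) over a text corpus, dropping n-grams seen in fewer than
#' `min_df` documents. The vocabulary is sorted lexicographically, so it is
#' deterministic given the same corpus and settings.
#'
#' @param texts Character vector of documents (at least one non-empty).
#' @param ngram_max Maximum n-gram length (default 3).
#' @param min_df Minimum document frequency (default 2).
#' @return An object of class `screen_vocabulary`: list with `grams`
#'   (character vector; position = feature index), `ngram_max`, `min_df`.
#' @examples
#' fit_vocabulary(c("a b c"), min_df = 1)$grams
#' @export
fit_vocabulary <- function(texts, ngram_max = 3L, min_df = 2L) {
  toks <- tokenize(texts)
  if (!any(lengths(toks) > 0L))
    stop_vs("cannot fit a vocabulary on an all-empty corpus")
  per_doc <- lapply(toks, function(t) unique(word_ngrams(t, ngram_max)))
  df <- table(unlist(per_doc, use.names = FALSE))
  grams <- sort(names(df)[df >= min_df])
  if (!length(grams))
    stop_vs("empty vocabulary: no n-gram reaches min_df = ", min_df)
  structure(list(grams = grams, ngram_max = as.integer(ngram_max),
                 min_df = as.integer(min_df)),
            class = "screen_vocabulary")
}

#' @method print screen_vocabulary
#' @export
print.screen_vocabulary <- function(x, ...) {
  cat("Bag-of-words vocabulary:", length(x$grams), "n-grams (1..",
      x$ngram_max, "), min document frequency ", x$min_df, "\n", sep = "")
  invisible(x)
}

#' Document-term matrix for a fitted vocabulary
#'
#' Term-frequency counts per document over the vocabulary features;
#' out-of-vocabulary n-grams are ignored. Rows are L2-normalized (the
#' default feature weighting) or tf-idf weighted then L2-normalized.
#'
#' @param texts Character vector of documents.
#' @param vocabulary A [fit_vocabulary()] result.
#' @param weighting `"tf"` (term frequency, L2-normalized rows) or
#'   `"tfidf"`.
#' @param idf Precomputed idf vector (internal; supplied when scoring with
#'   a trained model so idf comes from the training corpus).
#' @return A sparse `dgCMatrix`, documents x features.
#' @export
featurize <- function(texts, vocabulary, weighting = c("tf", "tfidf"),
                      idf = NULL) {
  weighting <- match.arg(weighting)
  stopifnot(inherits(vocabulary, "screen_vocabulary"))
  toks <- tokenize(texts)
  grams <- lapply(toks, word_ngrams, nmax = vocabulary$ngram_max)
  doc <- rep(seq_along(grams), lengths(grams))
  feat <- match(unlist(grams, use.names = FALSE), vocabulary$grams)
  keep <- !is.na(feat)
  X <- sparseMatrix(i = doc[keep], j = feat[keep], x = 1,
                    dims = c(length(texts), length(vocabulary$grams)))
  if (weighting == "tfidf") {
    if (is.null(idf)) idf <- attr(vocabulary, "idf") %||%
        log((length(texts) + 1) / (colSums(X > 0) + 1)) + 1
    X <- X %*% Diagonal(x = idf)
  }
  norms <- sqrt(rowSums(X^2))
  norms[norms == 0] <- 1
  Diagonal(x = 1 / norms) %*% X
}

#' Random train/validation split of a labeled corpus
#'
#' Uniform random partition without replacement; the training set has
#' `floor(train_fraction * n)` records. Reproducible by seed.
#'
#' @param records Record data.frame.
#' @param labels Named logical vector of include/exclude labels keyed by
#'   record id, covering every record exactly once.
#' @param train_fraction Fraction in (0, 1), default 0.8.
#' @param seed Integer seed.
#' @return List with `train` and `validation`, each a list of `records`
#'   and `labels`.
#' @export
split_corpus <- function(records, labels, train_fraction = 0.8, seed = 1L) {
  n <- nrow(records)
  if (n < 2L) stop_vs("need at least 2 records to split")
  if (!is.numeric(train_fraction) || train_fraction <= 0 ||
      train_fraction >= 1)
    stop_vs("train_fraction must be strictly between 0 and 1")
  labels <- check_named(labels, "labels")
  check_same_ids(setNames(logical(n), records$id), labels,
                 "records", "labels")
  set.seed(seed)
  idx <- sample.int(n, floor(train_fraction * n))
  mk <- function(i) list(records = records[i, , drop = FALSE],
                         labels = labels[records$id[i]])
  list(train = mk(idx), validation = mk(-idx))
}

tiab_text <- function(records) {
  ifelse(is.na(records$abstract), records$title,
         paste(records$title, records$abstract))
}

#' Train the SVM-SGD screening classifier
#'
#' Fits a linear max-margin classifier (hinge loss, L2 penalty) by
#' stochastic gradient descent on a tri-gram bag-of-words representation
#' of each record's title + abstract, then fits a Platt-style logistic
#' calibration on the training margins so every score lies in \[0, 1\]
#' (higher = stronger prediction of inclusion). Training is fully
#' deterministic given `(corpus, hyperparameters, seed)`: the per-epoch
#' shuffle orders are drawn from the seed.
#'
#' @param records Record data.frame (title/abstract are used).
#' @param labels Named logical include/exclude labels keyed by record id;
#'   both classes must be present.
#' @param ngram_max,min_df Vocabulary settings, see [fit_vocabulary()].
#' @param alpha L2 regularization strength (default 1e-4).
#' @param epochs SGD epochs (default 10).
#' @param weighting Feature weighting, `"tf"` (default) or `"tfidf"`.
#' @param calibration_folds Cross-validation folds for the Platt
#'   calibration (default 3). The calibrator is fitted on out-of-fold
#'   margins, so nearly separable training data does not collapse the
#'   score distribution onto \{0, 1\}; `1` fits on in-sample margins.
#' @param seed Integer seed for the SGD shuffles.
#' @return An object of class `screener_model`.
#' @seealso [predict.screener_model()], [threshold_for_sensitivity()]
#' @export
train_screener <- function(records, labels, ngram_max = 3L, min_df = 2L,
                           alpha = 1e-4, epochs = 10L,
                           weighting = c("tf", "tfidf"),
                           calibration_folds = 3L, seed = 1L) {
  weighting <- match.arg(weighting)
  if (nrow(records) == 0L) stop_vs("empty training set")
  labels <- check_named(labels, "labels")
  check_same_ids(setNames(logical(nrow(records)), records$id), labels,
                 "records", "labels")
  y01 <- as.logical(labels[records$id])
  if (length(unique(y01)) < 2L)
    stop_vs("training set must contain both classes")
  texts <- tiab_text(records)
  vocabulary <- fit_vocabulary(texts, ngram_max = ngram_max,
                               min_df = min_df)
  idf <- if (weighting == "tfidf")
    log((length(texts) + 1) /
          (colSums(featurize_counts(texts, vocabulary) > 0) + 1)) + 1
  X <- featurize(texts, vocabulary, weighting = weighting, idf = idf)
  n <- nrow(X)
  y <- ifelse(y01, 1, -1)
  set.seed(seed)
  sgd_on <- function(rows) {
    Xt <- as(Matrix::t(X[rows, , drop = FALSE]), "CsparseMatrix")
    orders <- t(vapply(seq_len(epochs),
                       function(e) sample.int(length(rows)) - 1L,
                       integer(length(rows))))
    sgd_hinge_fit(Xt@p, Xt@i, Xt@x, y[rows], ncol(X), alpha, orders)
  }
  margins_of <- function(fit, rows) {
    Xt <- as(Matrix::t(X[rows, , drop = FALSE]), "CsparseMatrix")
    as.numeric(linear_margins(Xt@p, Xt@i, Xt@x, fit$weights, fit$bias))
  }
  fit <- sgd_on(seq_len(n))
  # Platt calibration on out-of-fold margins: in-sample margins of a
  # (nearly) separating fit would drive the logistic slope to a step
  # function and saturate every score at 0 or 1
  folds <- max(1L, as.integer(calibration_folds))
  if (folds > 1L) {
    assign <- sample(rep_len(seq_len(folds), n))
    cal_margins <- numeric(n)
    for (f in seq_len(folds)) {
      held <- which(assign == f); rest <- which(assign != f)
      if (length(unique(y01[rest])) < 2L) {  # degenerate fold: in-sample
        cal_margins[held] <- margins_of(fit, held)
      } else {
        cal_margins[held] <- margins_of(sgd_on(rest), held)
      }
    }
  } else {
    cal_margins <- margins_of(fit, seq_len(n))
  }
  calibration <- fit_platt(cal_margins, y01)
  structure(list(vocabulary = vocabulary, weights = fit$weights,
                 bias = fit$bias, calibration = calibration,
                 weighting = weighting, idf = idf,
                 hyperparameters = list(loss = "hinge", alpha = alpha,
                                        epochs = as.integer(epochs),
                                        learning_rate = "optimal",
                                        ngram_max = as.integer(ngram_max),
                                        min_df = as.integer(min_df)),
                 seed = as.integer(seed),
                 n_train = n, n_pos = sum(y01)),
            class = "screener_model")
}

featurize_counts <- function(texts, vocabulary) {
  featurize(texts, vocabulary, weighting = "tf")  # only sparsity pattern used
}

# Platt scaling: logistic map score = plogis(slope * margin + intercept),
# fitted by minimizing cross-entropy against Platt's smoothed targets.
# The slope is parametrized as exp(a) > 0, so calibrated scores are always
# strictly increasing in the margin.
fit_platt <- function(margins, y01) {
  n1 <- sum(y01); n0 <- sum(!y01)
  t <- ifelse(y01, (n1 + 1) / (n1 + 2), 1 / (n0 + 2))
  nll <- function(par) {
    p <- plogis(exp(par[1]) * margins + par[2])
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -sum(t * log(p) + (1 - t) * log(1 - p))
  }
  fit <- optim(c(0, 0), nll, method = "BFGS")
  c(slope = exp(fit$par[1]), intercept = fit$par[2])
}

#' Predict inclusion scores from a trained screener
#'
#' Scores records on their title + abstract. Out-of-vocabulary n-grams are
#' ignored; a record with neither title nor abstract text is scored on the
#' empty document (the calibrated bias) with a warning.
#'
#' @param object A `screener_model`.
#' @param records Record data.frame to score.
#' @param type `"score"` (calibrated, in \[0, 1\]; default), `"margin"`
#'   (raw linear margin), or `"include"` (logical at `threshold`).
#' @param threshold Score threshold for `type = "include"`.
#' @param ... Unused.
#' @return Named numeric (or logical) vector keyed by record id.
#' @method predict screener_model
#' @export
predict.screener_model <- function(object, records,
                                   type = c("score", "margin", "include"),
                                   threshold = 0.5, ...) {
  type <- match.arg(type)
  texts <- tiab_text(records)
  if (any(empty <- !nzchar(trimws(texts))))
    warning(sum(empty), " record(s) have no title/abstract text; ",
            "scored on the empty document", call. = FALSE)
  X <- featurize(texts, object$vocabulary, weighting = object$weighting,
                 idf = object$idf)
  Xt <- as(Matrix::t(X), "CsparseMatrix")
  m <- as.numeric(linear_margins(Xt@p, Xt@i, Xt@x, object$weights,
                                 object$bias))
  out <- switch(type,
                margin = m,
                score = plogis(object$calibration["slope"] * m +
                                 object$calibration["intercept"]),
                include = plogis(object$calibration["slope"] * m +
                                   object$calibration["intercept"]) >=
                  threshold)
  setNames(unname(out), records$id)
}

#' @method print screener_model
#' @export
print.screener_model <- function(x, ...) {
  h <- x$hyperparameters
  cat("Linear SVM-SGD screening classifier\n",
      " features: ", length(x$vocabulary$grams),
      " word n-grams (1..", h$ngram_max, ", min df ", h$min_df, ", ",
      x$weighting, " weighting)\n",
      " training: ", x$n_train, " records (", x$n_pos, " includes), ",
      h$epochs, " epochs, alpha ", format(h$alpha), ", seed ", x$seed, "\n",
      " calibration: score = plogis(",
      format(round(x$calibration["slope"], 4)), " * margin + ",
      format(round(x$calibration["intercept"], 4)), ")\n", sep = "")
  invisible(x)
}

#' @method summary screener_model
#' @export
summary.screener_model <- function(object, n_top = 10, ...) {
  print(object)
  w <- setNames(object$weights, object$vocabulary$grams)
  cat("\nTop inclusion features:\n")
  print(round(sort(w, decreasing = TRUE)[seq_len(min(n_top, length(w)))], 4))
  cat("\nTop exclusion features:\n")
  print(round(sort(w)[seq_len(min(n_top, length(w)))], 4))
  invisible(object)
}

#' @method coef screener_model
#' @export
coef.screener_model <- function(object, ...) {
  c(setNames(object$weights, object$vocabulary$grams),
    "(bias)" = object$bias)
}

#' Save / load a screener model as JSON
#'
#' Versioned plain-text container holding the vocabulary, weights,
#' calibration, hyperparameters and seed; `read_screener_model()` restores
#' an identical model.
#'
#' @param model A `screener_model`.
#' @param path File path.
#' @export
write_screener_model <- function(model, path) {
  stopifnot(inherits(model, "screener_model"))
  payload <- list(container = "vitroscreen/screener_model", version = 1L,
                  vocabulary = model$vocabulary[c("grams", "ngram_max",
                                                  "min_df")],
                  weights = model$weights, bias = model$bias,
                  calibration = as.list(model$calibration),
                  weighting = model$weighting, idf = model$idf,
                  hyperparameters = model$hyperparameters,
                  seed = model$seed, n_train = model$n_train,
                  n_pos = model$n_pos)
  writeLines(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                              null = "null"), path)
  invisible(path)
}

#' @rdname write_screener_model
#' @export
read_screener_model <- function(path) {
  p <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!identical(p$container, "vitroscreen/screener_model"))
    stop_vs(path, " is not a screener model file")
  structure(list(
    vocabulary = structure(list(grams = p$vocabulary$grams,
                                ngram_max = as.integer(p$vocabulary$ngram_max),
                                min_df = as.integer(p$vocabulary$min_df)),
                           class = "screen_vocabulary"),
    weights = as.numeric(p$weights), bias = as.numeric(p$bias),
    calibration = c(slope = as.numeric(p$calibration$slope),
                    intercept = as.numeric(p$calibration$intercept)),
    weighting = p$weighting,
    idf = if (!is.null(p$idf)) as.numeric(p$idf),
    hyperparameters = p$hyperparameters, seed = as.integer(p$seed),
    n_train = p$n_train, n_pos = p$n_pos), class = "screener_model")
}
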
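# Internal helpers shared across modules.

# Half-up rounding to `digits` decimals, for report display (internal values
# stay unrounded; base round() is round-half-even).
round_half_up <- function(x, digits = 3) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_vs <- function(...) stop(..., call. = FALSE)

# Named-vector coercion used throughout: decisions/gold/scores are named
# vectors keyed by record id.
check_named <- function(x, what) {
  if (is.null(names(x)) || anyNA(names(x)) || any(names(x) == ""))
    stop_vs(what, " must be a named vector keyed by record id")
  if (anyDuplicated(names(x)))
    stop_vs(what, " has duplicated record ids: ",
            paste(unique(names(x)[duplicated(names(x))]), collapse = ", "))
  x
}

# Validate that two named vectors cover exactly the same ids; report the
# symmetric difference otherwise.
check_same_ids <- function(a, b, what_a = "decisions", what_b = "gold") {
  only_a <- setdiff(names(a), names(b))
  only_b <- setdiff(names(b), names(a))
  if (length(only_a) || length(only_b)) {
    stop_vs("record id mismatch between ", what_a, " and ", what_b,
            if (length(only_a)) paste0("; only in ", what_a, ": ",
                                       paste(head(only_a, 10), collapse = ", ")),
            if (length(only_b)) paste0("; only in ", what_b, ": ",
                                       paste(head(only_b, 10), collapse = ", ")))
  }
  invisible(TRUE)
}

is_proportion <- function(x) is.numeric(x) && length(x) == 1L &&
  !is.na(x) && x >= 0 && x <= 1

check_proportion <- function(x, what) {
  if (!is_proportion(x)) stop_vs(what, " must be a single number in [0, 1]")
  x
}

# Deterministic record id from source position + title, for inputs that
# carry no explicit id. djb2-style 31-bit rolling hash over UTF-8 bytes;
# stays well inside double precision, stable across platforms.
stable_id <- function(position, title) {
  bytes <- utf8ToInt(enc2utf8(paste0(position, "\x1f", title)))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("rec-%07d-%s", position, format(h, scientific = FALSE))
}
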
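#' Read bibliographic records
#'
#' Reads a corpus of bibliographic records from JSONL (one object per line),
#' CSV (RFC 4180 with header), or RIS. Records carry an id, a title, an
#' optional abstract, an optional full text, a conference-abstract flag and
#' a language code. An absent abstract (missing JSONL key, RIS without AB)
#' is distinct from an empty-string abstract; absent fields are `NA`.
#'
#' When a record has no explicit id, a deterministic id is generated from
#' its position in the file and its title, so repeated reads of the same
#' file produce identical ids.
#'
#' @param path Path to the input file.
#' @param format One of `"jsonl"`, `"csv"`, `"ris"`. Defaults to the file
#'   extension.
#' @return A data.frame with one row per record and columns `id`, `title`,
#'   `abstract`, `full_text`, `is_conference_abstract`, `language`.
#' @examples
#' f <- tempfile(fileext = ".jsonl")
#' writeLines(c(
#'   '{"id":"a","title":"OGD in PC-12 cells","abstract":"An abstract."}',
#'   '{"id":"b","title":"Unrelated clinical trial"}'
#' ), f)
#' read_records(f)
#' @seealso [filter_eligible()], [write_records()]
#' @export
read_records <- function(path, format = c("auto", "jsonl", "csv", "ris")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, jsonl = "jsonl", json = "jsonl", csv = "csv",
                     ris = "ris",
                     stop_vs("cannot infer format from extension '", ext,
                             "'; pass format explicitly"))
  }
  if (!file.exists(path)) stop_vs("file not found: ", path)
  recs <- switch(format,
                 jsonl = read_records_jsonl(path),
                 csv   = read_records_csv(path),
                 ris   = read_records_ris(path))
  if (nrow(recs) == 0L) {
    warning("no records read from ", path, call. = FALSE)
    return(recs)
  }
  # ids: fill absent ones deterministically, then enforce uniqueness
  missing_id <- is.na(recs$id) | recs$id == ""
  if (any(missing_id)) {
    recs$id[missing_id] <- vapply(which(missing_id), function(i)
      stable_id(i, recs$title[i]), character(1))
  }
  dup <- unique(recs$id[duplicated(recs$id)])
  if (length(dup))
    stop_vs("duplicate record ids in ", path, ": ",
            paste(head(dup, 10), collapse = ", "))
  recs
}

empty_records <- function() {
  data.frame(id = character(), title = character(), abstract = character(),
             full_text = character(), is_conference_abstract = logical(),
             language = character(), stringsAsFactors = FALSE)
}

as_record_row <- function(x, line = NA) {
  title <- x$title
  if (is.null(title)) stop_vs("record ", if (!is.na(line)) paste0("at line ", line),
                              " has no title field")
  data.frame(
    id = as.character(x$id %||% NA_character_),
    title = as.character(title),
    abstract = as.character(x$abstract %||% NA_character_),
    full_text = as.character(x$full_text %||% NA_character_),
    is_conference_abstract = isTRUE(x$is_conference_abstract),
    language = as.character(x$language %||% "en"),
    stringsAsFactors = FALSE)
}

read_records_jsonl <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(empty_records())
  rows <- lapply(seq_along(lines), function(i) {
    obj <- tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = TRUE),
                    error = function(e)
                      stop_vs("malformed JSONL at line ", i, " of ", path,
                              ": ", conditionMessage(e)))
    as_record_row(obj, line = i)
  })
  do.call(rbind, rows)
}

read_records_csv <- function(path) {
  df <- tryCatch(
    read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
             encoding = "UTF-8"),
    error = function(e) stop_vs("malformed CSV ", path, ": ",
                                conditionMessage(e)))
  if (nrow(df) == 0L) return(empty_records())
  if (!"title" %in% names(df))
    stop_vs("CSV ", path, " lacks required column 'title'")
  get <- function(col, default) if (col %in% names(df)) df[[col]] else
    rep(default, nrow(df))
  abstract <- get("abstract", NA_character_)
  full_text <- get("full_text", NA_character_)
  # companion boolean columns distinguish absent from empty-string fields;
  # without them an empty cell is read as absent
  if ("has_abstract" %in% names(df)) {
    abstract[!as_bool(df$has_abstract)] <- NA_character_
  } else abstract[!is.na(abstract) & abstract == ""] <- NA_character_
  if ("has_full_text" %in% names(df)) {
    full_text[!as_bool(df$has_full_text)] <- NA_character_
  } else full_text[!is.na(full_text) & full_text == ""] <- NA_character_
  data.frame(
    id = get("id", NA_character_),
    title = df$title,
    abstract = abstract,
    full_text = full_text,
    is_conference_abstract = as_bool(get("is_conference_abstract", "FALSE")),
    language = {
      l <- get("language", "en"); l[is.na(l) | l == ""] <- "en"; l
    },
    stringsAsFactors = FALSE)
}

as_bool <- function(x) {
  out <- tolower(trimws(as.character(x))) %in% c("true", "t", "1", "yes")
  out
}

# RIS reference types that denote conference material
RIS_CONFERENCE_TYPES <- c("CPAPER", "ABST", "CONF")

read_records_ris <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  entries <- list(); cur <- NULL; cur_tag <- NULL
  flush_entry <- function(e) {
    if (is.null(e) || !length(e)) return(NULL)
    join <- function(tag) if (tag %in% names(e))
      paste(e[[tag]], collapse = " ") else NULL
    list(id = join("ID"),
         title = join("TI") %||% join("T1") %||% "",
         abstract = join("AB") %||% join("N2"),
         is_conference_abstract =
           toupper(trimws(join("TY") %||% "")) %in% RIS_CONFERENCE_TYPES,
         language = tolower(substr(join("LA") %||% "en", 1, 2)))
  }
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (grepl("^[A-Z][A-Z0-9]  - ?", ln)) {
      tag <- substr(ln, 1, 2)
      val <- sub("^[A-Z][A-Z0-9]  - ?", "", ln)
      if (tag == "ER") { entries <- c(entries, list(flush_entry(cur)))
                         cur <- NULL; cur_tag <- NULL; next }
      if (tag == "TY" && !is.null(cur))
        stop_vs("RIS entry starting before 'ER  -' at line ", i, " of ", path)
      if (is.null(cur)) cur <- list()
      cur[[tag]] <- c(cur[[tag]], val)
      cur_tag <- tag
    } else if (nzchar(trimws(ln))) {
      if (is.null(cur_tag))
        stop_vs("malformed RIS at line ", i, " of ", path,
                ": continuation line outside an entry")
      cur[[cur_tag]] <- c(cur[[cur_tag]], trimws(ln))
    }
  }
  if (!is.null(cur)) entries <- c(entries, list(flush_entry(cur)))
  entries <- Filter(Negate(is.null), entries)
  if (!length(entries)) return(empty_records())
  do.call(rbind, lapply(entries, as_record_row))
}

#' Write bibliographic records
#'
#' Round-trip counterpart of [read_records()] for the jsonl and csv formats:
#' reading a written file reproduces the records exactly, including the
#' distinction between absent and empty abstracts (missing key in JSONL;
#' `has_abstract` / `has_full_text` companion columns in CSV).
#'
#' @param records Record data.frame as returned by [read_records()].
#' @param path Output path.
#' @param format `"jsonl"` or `"csv"`.
#' @export
write_records <- function(records, path, format = c("jsonl", "csv")) {
  format <- match.arg(format)
  if (format == "jsonl") {
    lines <- vapply(seq_len(nrow(records)), function(i) {
      r <- as.list(records[i, , drop = FALSE])
      r <- lapply(r, function(v) v[[1]])
      if (is.na(r$abstract)) r$abstract <- NULL
      if (is.na(r$full_text)) r$full_text <- NULL
      jsonlite::toJSON(r, auto_unbox = TRUE)
    }, character(1))
    writeLines(lines, path, useBytes = TRUE)
  } else {
    df <- records
    df$has_abstract <- !is.na(df$abstract)
    df$has_full_text <- !is.na(df$full_text)
    df$abstract[is.na(df$abstract)] <- ""
    df$full_text[is.na(df$full_text)] <- ""
    write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  }
  invisible(path)
}

#' Eligibility filter for the screening analysis set
#'
#' Retains records with an abstract, excluding conference abstracts,
#' records with no abstract and non-English records. Records lacking a full
#' text are retained (they remain usable for title/abstract analyses) but
#' can be identified downstream via `is.na(full_text)`; an optional input
#' flag column `no_machine_readable_fulltext` additionally excludes records
#' whose full text could not be converted to machine-readable text.
#'
#' @param records Record data.frame (see [read_records()]).
#' @return A list with `records` (the retained rows) and `ledger`, an
#'   exclusion ledger: `counts`, a named integer vector of exclusions by
#'   reason (from `conference_abstract`, `no_abstract`, `non_english`,
#'   `no_machine_readable_fulltext`), and `reasons`, a named character
#'   vector giving each excluded record's single primary reason (the first
#'   matching reason in that order).
#' @examples
#' recs <- data.frame(
#'   id = c("a", "b", "c"), title = "t",
#'   abstract = c("yes", NA, "yes"),
#'   full_text = NA_character_,
#'   is_conference_abstract = c(FALSE, FALSE, TRUE),
#'   language = "en")
#' filter_eligible(recs)$ledger$counts
#' @export
filter_eligible <- function(records) {
  reason <- rep(NA_character_, nrow(records))
  nmr <- if ("no_machine_readable_fulltext" %in% names(records))
    as_bool(records$no_machine_readable_fulltext) else
      rep(FALSE, nrow(records))
  # one primary reason per excluded record, assessed in fixed order
  reason[is.na(reason) & records$is_conference_abstract] <- "conference_abstract"
  reason[is.na(reason) & is.na(records$abstract)] <- "no_abstract"
  reason[is.na(reason) & records$language != "en"] <- "non_english"
  reason[is.na(reason) & nmr] <- "no_machine_readable_fulltext"
  keep <- is.na(reason)
  counts <- table(factor(reason[!keep],
                         levels = c("conference_abstract", "no_abstract",
                                    "non_english",
                                    "no_machine_readable_fulltext")))
  counts <- counts[counts > 0L]
  ledger <- list(counts = setNames(as.integer(counts), names(counts)),
                 reasons = setNames(reason[!keep], records$id[!keep]))
  list(records = records[keep, , drop = FALSE], ledger = ledger)
}

#' Read and write screening decisions
#'
#' Decisions are stored as CSV (`record_id,stage,source,include`) or JSONL;
#' the pair of functions is a lossless round trip, preserving row order.
#'
#' @param decisions A data.frame with columns `record_id`, `stage` (`"tiab"`
#'   or `"fulltext"`), `source` (reviewer or method identifier) and
#'   `include` (logical).
#' @param path File path.
#' @param format `"csv"` or `"jsonl"`.
#' @param allow_empty Permit writing an empty decision set (default FALSE).
#' @return `write_decisions()` returns `path` invisibly; `read_decisions()`
#'   the decisions data.frame.
#' @export
write_decisions <- function(decisions, path, format = c("csv", "jsonl"),
                            allow_empty = FALSE) {
  format <- match.arg(format)
  decisions <- validate_decisions(decisions)
  if (nrow(decisions) == 0L && !allow_empty)
    stop_vs("refusing to write an empty decision set (allow_empty = FALSE)")
  if (format == "csv") {
    write.csv(decisions, path, row.names = FALSE, fileEncoding = "UTF-8")
  } else {
    lines <- vapply(seq_len(nrow(decisions)), function(i)
      jsonlite::toJSON(lapply(as.list(decisions[i, , drop = FALSE]),
                              function(v) v[[1]]), auto_unbox = TRUE),
      character(1))
    writeLines(lines, path, useBytes = TRUE)
  }
  invisible(path)
}

#' @rdname write_decisions
#' @export
read_decisions <- function(path, format = c("auto", "csv", "jsonl")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (tolower(tools::file_ext(path)) == "jsonl") "jsonl" else "csv"
  if (format == "csv") {
    df <- read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  } else {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    df <- if (length(lines))
      do.call(rbind, lapply(lines, function(l)
        as.data.frame(jsonlite::fromJSON(l), stringsAsFactors = FALSE)))
    else data.frame(record_id = character(), stage = character(),
                    source = character(), include = logical())
  }
  validate_decisions(df)
}

validate_decisions <- function(decisions) {
  need <- c("record_id", "stage", "source", "include")
  miss <- setdiff(need, names(decisions))
  if (length(miss))
    stop_vs("decisions lack column(s): ", paste(miss, collapse = ", "))
  decisions <- decisions[, need, drop = FALSE]
  decisions$record_id <- as.character(decisions$record_id)
  decisions$stage <- as.character(decisions$stage)
  bad <- setdiff(unique(decisions$stage), c("tiab", "fulltext"))
  if (length(bad))
    stop_vs("unknown screening stage(s): ", paste(bad, collapse = ", "))
  decisions$source <- as.character(decisions$source)
  decisions$include <- as.logical(decisions$include)
  rownames(decisions) <- NULL
  decisions
}

#' Extract a named include/exclude vector from a decision table
#'
#' Convenience for evaluation: returns `include` keyed by `record_id` for
#' one `source`/`stage` slice of a decisions data.frame.
#'
#' @param decisions Decisions data.frame (see [write_decisions()]).
#' @param source,stage Optional filters.
#' @return Named logical vector.
#' @export
decision_vector <- function(decisions, source = NULL, stage = NULL) {
  d <- decisions
  if (!is.null(source)) d <- d[d$source == source, , drop = FALSE]
  if (!is.null(stage)) d <- d[d$stage == stage, , drop = FALSE]
  check_named(setNames(d$include, d$record_id), "decision slice")
}
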
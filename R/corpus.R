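## corpus ingest and exchange formats
##
## Canonical corpus format is JSON lines, one object per line with keys
## doc_id, text and optional expert_label, so expert relevance judgements
## travel with the text.  A directory of .txt files (filename stem as
## doc_id) is the convenience alternative.  Text is preserved byte for byte
## at ingest apart from UTF-8 decode repair.

#' Construct a corpus
#'
#' A corpus is an ordered collection of documents: `doc_id` (unique,
#' non-empty), `text` (raw free text, never normalized at ingest) and
#' `expert_label` (logical: relevant to combat exposure according to an
#' expert reviewer; `NA` = unlabeled).  Iteration order is input order and
#' is preserved by every operation in the package.
#'
#' @param doc_id character vector of unique document identifiers.
#' @param text character vector of raw document text.
#' @param expert_label logical vector of expert labels (`NA` allowed).
#' @return a `corpus` object (a data frame).
#' @export
corpus <- function(doc_id, text, expert_label = NA) {
  doc_id <- as.character(doc_id)
  text <- as.character(text)
  expert_label <- as.logical(expert_label)
  if (length(expert_label) == 1L) {
    expert_label <- rep(expert_label, length(doc_id))
  }
  if (length(text) != length(doc_id) ||
      length(expert_label) != length(doc_id)) {
    stop_validation("doc_id, text and expert_label lengths differ")
  }
  if (any(is.na(doc_id) | !nzchar(doc_id))) {
    stop_validation("every document needs a non-empty doc_id")
  }
  dup <- doc_id[duplicated(doc_id)]
  if (length(dup)) {
    stop_validation("duplicate doc_id: ", paste(unique(dup), collapse = ", "))
  }
  out <- data.frame(doc_id = doc_id, text = text,
                    expert_label = expert_label, stringsAsFactors = FALSE)
  class(out) <- c("corpus", "data.frame")
  out
}

#' @export
print.corpus <- function(x, ...) {
  n <- nrow(x)
  lab <- sum(!is.na(x$expert_label))
  cat(sprintf("<corpus> %d document%s (%d labeled)\n", n,
              if (n == 1L) "" else "s", lab))
  if (n) {
    prev <- substr(x$text, 1L, 50L)
    show <- utils::head(data.frame(doc_id = x$doc_id, text = prev,
                                   expert_label = x$expert_label), 10L)
    print.data.frame(show, row.names = FALSE)
    if (n > 10L) cat(sprintf("  ... and %d more\n", n - 10L))
  }
  invisible(x)
}

# decode repair: force valid UTF-8, substituting replacement characters;
# blogs are noisy web text and must not abort a batch
.repair_utf8 <- function(x, where) {
  fixed <- iconv(x, from = "UTF-8", to = "UTF-8", sub = "�")
  bad <- which(is.na(fixed) | fixed != x)
  if (length(bad)) {
    message("corpus_io: repaired invalid UTF-8 in ",
            paste(where[bad], collapse = ", "))
    x[bad] <- ifelse(is.na(fixed[bad]), "�", fixed[bad])
  }
  x
}

#' Read a corpus
#'
#' `format = "jsonl"` reads JSON lines with required keys `doc_id` and
#' `text` and optional `expert_label` (boolean).  `format = "textdir"`
#' reads every `.txt` file in a directory (sorted by filename), using the
#' filename without extension as `doc_id`.  Invalid UTF-8 byte sequences
#' are replaced with U+FFFD and reported per document.
#'
#' @param path file (jsonl) or directory (textdir).
#' @param format one of `"jsonl"`, `"textdir"`.
#' @return a [corpus()] in input order.
#' @export
read_corpus <- function(path, format = c("jsonl", "textdir")) {
  format <- match.arg(format)
  if (format == "jsonl") {
    if (!file.exists(path) || dir.exists(path)) {
      stop_io("corpus file not found: ", path)
    }
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    lines <- .repair_utf8(lines, paste0(basename(path), ":", seq_along(lines)))
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) return(corpus(character(0), character(0), logical(0)))
    recs <- lapply(seq_along(lines), function(i) {
      rec <- tryCatch(jsonlite::fromJSON(lines[[i]], simplifyVector = TRUE),
                      error = function(e) {
                        stop_io("malformed JSON at ", basename(path),
                                " line ", i, ": ", conditionMessage(e))
                      })
      for (f in c("doc_id", "text")) {
        if (is.null(rec[[f]])) {
          stop_validation("missing required field '", f, "' at ",
                          basename(path), " line ", i)
        }
      }
      list(doc_id = as.character(rec$doc_id), text = as.character(rec$text),
           expert_label = if (is.null(rec$expert_label)) NA
                          else as.logical(rec$expert_label))
    })
    corpus(vapply(recs, `[[`, "", "doc_id"),
           vapply(recs, `[[`, "", "text"),
           vapply(recs, `[[`, NA, "expert_label"))
  } else {
    if (!dir.exists(path)) stop_io("corpus directory not found: ", path)
    files <- sort(list.files(path, pattern = "\\.txt$", full.names = TRUE))
    txt <- vapply(files, function(f) {
      paste(readLines(f, encoding = "UTF-8", warn = FALSE), collapse = "\n")
    }, "", USE.NAMES = FALSE)
    txt <- .repair_utf8(txt, basename(files))
    corpus(sub("\\.txt$", "", basename(files)), txt,
           rep(NA, length(files)))
  }
}

#' Write a corpus as JSON lines
#'
#' One object per line with keys `doc_id`, `text` and, where labeled,
#' `expert_label`.  `read_corpus(write_corpus(x))` round-trips exactly.
#'
#' @param x a [corpus()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(x, path) {
  lines <- vapply(seq_len(nrow(x)), function(i) {
    rec <- list(doc_id = x$doc_id[i], text = x$text[i])
    if (!is.na(x$expert_label[i])) rec$expert_label <- x$expert_label[i]
    jsonlite::toJSON(rec, auto_unbox = TRUE)
  }, "")
  ok <- tryCatch({
    writeLines(lines, path, useBytes = TRUE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop_io("cannot write corpus to ", path)
  invisible(path)
}

#' Read an expert-label file
#'
#' Tab-separated `doc_id<TAB>label`, where label is yes/no (or
#' true/false), case-insensitive.  The alternative to carrying labels
#' inside the corpus JSON lines.
#'
#' @param path TSV file.
#' @return named logical vector keyed by doc_id.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop_io("label file not found: ", path)
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          col.names = c("doc_id", "label"),
                          colClasses = "character")
  lab <- tolower(trimws(df$label))
  val <- ifelse(lab %in% c("yes", "true", "1"), TRUE,
                ifelse(lab %in% c("no", "false", "0"), FALSE, NA))
  if (anyNA(val)) {
    stop_validation("unrecognized label value(s): ",
                    paste(unique(df$label[is.na(val)]), collapse = ", "))
  }
  stats::setNames(val, df$doc_id)
}
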
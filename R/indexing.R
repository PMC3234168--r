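## corpus term statistics and TF*IDF indexing weights
##
## One weight per distinct non-stop stem per corpus:
##   tf     = corpus_count / N          (occurrences per document)
##   idf    = log10(N / doc_freq)       (0 when the stem is in every doc)
##   weight = tf * idf
## Log base 10 is the default and is configurable.

#' Corpus term statistics and indexing weights
#'
#' Preprocesses every document, drops stop-flagged word tokens, and
#' computes per-stem corpus statistics: total occurrence count, document
#' frequency, term frequency `tf = corpus_count / N`, inverse document
#' frequency `idf = log(N / doc_freq, log_base)` and the indexing weight
#' `tf * idf`.  Rows are sorted by weight descending, ties broken
#' lexicographically by stem, which makes the ranking deterministic.
#'
#' @param corpus a [corpus()]; must be non-empty.
#' @param stoplist character vector of stop words.
#' @param log_base base of the IDF logarithm (default 10).
#' @return a `term_weights` data frame with columns `stem`,
#'   `corpus_count`, `doc_freq`, `tf`, `idf`, `weight`.
#' @examples
#' cps <- corpus(c("d1", "d2", "d3", "d4"),
#'               c("bomb bomb truck", "truck", "hope", "bomb"))
#' term_statistics(cps)
#' @export
term_statistics <- function(corpus, stoplist = default_stopwords(),
                            log_base = 10) {
  if (nrow(corpus) == 0L) stop_validation("corpus is empty")
  if (!is.numeric(log_base) || log_base <= 1) {
    stop_validation("log_base must be > 1")
  }
  n_docs <- nrow(corpus)
  per_doc <- lapply(seq_len(n_docs), function(i) {
    t <- preprocess_document(corpus[i, ], stoplist)
    unique_and_all <- t$stem[t$is_word & !t$is_stop]
    unique_and_all
  })
  all_stems <- unlist(per_doc, use.names = FALSE)
  if (!length(all_stems)) {
    out <- data.frame(stem = character(0), corpus_count = integer(0),
                      doc_freq = integer(0), tf = numeric(0),
                      idf = numeric(0), weight = numeric(0))
    class(out) <- c("term_weights", "data.frame")
    return(out)
  }
  counts <- table(all_stems)
  dfreq <- table(unlist(lapply(per_doc, unique), use.names = FALSE))
  stems <- names(counts)
  corpus_count <- as.integer(counts)
  doc_freq <- as.integer(dfreq[stems])
  tf <- corpus_count / n_docs
  idf <- log(n_docs / doc_freq, base = log_base)
  weight <- tf * idf
  out <- data.frame(stem = stems, corpus_count = corpus_count,
                    doc_freq = doc_freq, tf = tf, idf = idf,
                    weight = weight, stringsAsFactors = FALSE)
  out <- out[order(-out$weight, out$stem), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("term_weights", "data.frame")
  out
}

#' Select candidate lexicon terms by weight cutoff
#'
#' Returns the stems whose indexing weight lies strictly above the cutoff
#' (default 0.1), preserving the input ranking.  This is the machine half
#' of lexicon construction; deciding which of the surviving stems are
#' actually domain-relevant remains a curator's task.
#'
#' @param weights a `term_weights` data frame from [term_statistics()].
#' @param cutoff non-negative weight threshold, exclusive.
#' @return character vector of stems.
#' @export
select_candidates <- function(weights, cutoff = 0.1) {
  if (!is.numeric(cutoff) || length(cutoff) != 1L || is.na(cutoff) ||
      cutoff < 0) {
    stop_validation("cutoff must be a single non-negative number")
  }
  weights$stem[weights$weight > cutoff]
}

#' Export a frequency-distribution table
#'
#' Writes a TSV for curator review: `stem`, then display-rounded `weight`
#' and `idf` (2 decimals, the layout used when ranked stem lists are
#' printed), then the counts and full-precision values in parallel
#' columns so the export is lossless.
#'
#' @param weights a `term_weights` data frame.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @seealso [read_frequency_table()] for the lossless re-import.
#' @export
export_frequency_table <- function(weights, path) {
  out <- data.frame(
    stem = weights$stem,
    weight = sprintf("%.2f", round_display(weights$weight, 2L)),
    idf = sprintf("%.2f", round_display(weights$idf, 2L)),
    corpus_count = weights$corpus_count,
    doc_freq = weights$doc_freq,
    tf_full = formatC(weights$tf, format = "g", digits = 17),
    idf_full = formatC(weights$idf, format = "g", digits = 17),
    weight_full = formatC(weights$weight, format = "g", digits = 17),
    stringsAsFactors = FALSE
  )
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop_io("cannot write frequency table to ", path)
  invisible(path)
}

#' Re-import an exported frequency table at full precision
#'
#' @param path TSV written by [export_frequency_table()].
#' @return a `term_weights` data frame.
#' @export
read_frequency_table <- function(path) {
  if (!file.exists(path)) stop_io("frequency table not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  out <- data.frame(stem = as.character(df$stem),
                    corpus_count = as.integer(df$corpus_count),
                    doc_freq = as.integer(df$doc_freq),
                    tf = as.numeric(df$tf_full),
                    idf = as.numeric(df$idf_full),
                    weight = as.numeric(df$weight_full),
                    stringsAsFactors = FALSE)
  class(out) <- c("term_weights", "data.frame")
  out
}
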
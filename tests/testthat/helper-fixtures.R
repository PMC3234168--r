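# shared fixtures, built in code

# a minimal two-level lexicon for unit tests (independent of the seed file)
tiny_lexicon <- function() {
  lex <- list(
    categories = data.frame(
      name = c("Exposure", "Emotion", "Event", "Feeling"),
      parent = c(NA, NA, "Exposure", "Emotion"),
      stringsAsFactors = FALSE
    ),
    entries = data.frame(
      stem = c("bomb", "truck", "hope", "boom"),
      category = c("Event", "Event", "Feeling", "Event"),
      stringsAsFactors = FALSE
    )
  )
  lex$entries$surface_variants <-
    list(c("ied"), character(0), character(0), character(0))
  class(lex) <- "lexicon"
  lex
}

tiny_corpus <- function() {
  corpus(
    c("d1", "d2", "d3", "d4"),
    c("bomb bomb truck", "truck", "hope", "bomb"),
    c(TRUE, FALSE, FALSE, TRUE)
  )
}

# brute-force recount of term statistics: explicit loops over documents and
# tokens, aggregation by environment counters (independent of the table()
# path in term_statistics)
brute_term_stats <- function(cps, stoplist, log_base = 10) {
  n <- nrow(cps)
  count <- new.env(parent = emptyenv())
  docs_seen <- new.env(parent = emptyenv())
  for (i in seq_len(n)) {
    toks <- preprocess_document(cps[i, ], stoplist)
    for (j in seq_len(nrow(toks))) {
      if (!toks$is_word[j] || toks$is_stop[j]) next
      s <- toks$stem[j]
      count[[s]] <- (if (is.null(count[[s]])) 0L else count[[s]]) + 1L
      ids <- docs_seen[[s]]
      if (is.null(ids) || !(i %in% ids)) docs_seen[[s]] <- c(ids, i)
    }
  }
  stems <- ls(count)
  if (!length(stems)) {
    return(data.frame(stem = character(0), corpus_count = integer(0),
                      doc_freq = integer(0), tf = numeric(0),
                      idf = numeric(0), weight = numeric(0)))
  }
  cc <- vapply(stems, function(s) count[[s]], 0L)
  df <- vapply(stems, function(s) length(docs_seen[[s]]), 0L)
  out <- data.frame(stem = stems, corpus_count = unname(cc),
                    doc_freq = unname(df), tf = unname(cc) / n,
                    idf = log(n / unname(df), base = log_base),
                    stringsAsFactors = FALSE)
  out$weight <- out$tf * out$idf
  out[order(-out$weight, out$stem), ]
}

# brute-force gazetteer scan: try every entry against every token, tier by
# tier, mirroring the matching contract without the hash lookup
brute_annotate <- function(tokens, lex) {
  hits <- list()
  ent <- lex$entries
  match_one <- function(normalized, stem) {
    for (k in seq_len(nrow(ent))) {
      if (normalized %in% ent$surface_variants[[k]]) return(k)
    }
    for (k in seq_len(nrow(ent))) {
      if (identical(stem, ent$stem[k])) return(k)
    }
    NA_integer_
  }
  for (j in which(tokens$is_word)) {
    k <- match_one(tokens$normalized[j], tokens$stem[j])
    if (is.na(k)) {
      n1 <- gsub("([[:alpha:]])\\1+", "\\1", tokens$normalized[j])
      if (n1 != tokens$normalized[j]) k <- match_one(n1, porter_stem(n1))
    }
    if (!is.na(k)) {
      hits[[length(hits) + 1L]] <-
        data.frame(start = tokens$start[j], stem = ent$stem[k],
                   category = ent$category[k], stringsAsFactors = FALSE)
    }
  }
  if (!length(hits)) {
    return(data.frame(start = integer(0), stem = character(0),
                      category = character(0)))
  }
  do.call(rbind, hits)
}

# random-word corpus over a fixed small vocabulary
random_corpus <- function(n_docs, max_tokens, vocab, seed) {
  set.seed(seed)
  txt <- vapply(seq_len(n_docs), function(i) {
    paste(sample(vocab, sample.int(max_tokens, 1L), replace = TRUE),
          collapse = " ")
  }, "")
  corpus(paste0("r", seq_len(n_docs)), txt)
}
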
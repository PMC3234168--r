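## tokenization and token normalization for noisy blog text

# word = maximal run of letters/digits, allowing internal apostrophes and
# internal hyphens ("Bo-o-om", "don't" are single tokens)
.word_regex <- "[\\p{L}\\p{N}]+(?:['\\-][\\p{L}\\p{N}]+)*"

.empty_tokens <- function() {
  data.frame(surface = character(0), start = integer(0), end = integer(0),
             is_word = logical(0), stringsAsFactors = FALSE)
}

#' Tokenize raw text
#'
#' Splits text into word tokens (maximal runs of letters/digits with
#' internal apostrophes or hyphens kept, so the expressive spelling
#' `"Bo-o-om"` stays one token) and non-word tokens (runs of punctuation).
#' Whitespace is not tokenized.  Offsets are 0-based, half-open character
#' positions into the raw text, so `substr(text, start + 1, end)` recovers
#' the surface.
#'
#' @param text a single character string (empty allowed).
#' @return data frame with columns `surface`, `start`, `end`, `is_word`,
#'   ordered by `start`, tokens non-overlapping.
#' @examples
#' tokenize("I saw the bomb.")
#' @export
tokenize <- function(text) {
  if (!is.character(text) || length(text) != 1L) {
    stop_validation("`text` must be a single character string")
  }
  if (is.na(text) || !nzchar(text)) return(.empty_tokens())

  m <- gregexpr(.word_regex, text, perl = TRUE)[[1L]]
  if (m[1L] == -1L) {
    wstart <- integer(0); wlen <- integer(0)
  } else {
    wstart <- as.integer(m)
    wlen <- attr(m, "match.length")
  }

  # non-word tokens: runs of non-space characters in the gaps between words
  nchar_text <- nchar(text)
  covered <- rep(FALSE, nchar_text)
  for (i in seq_along(wstart)) {
    covered[seq.int(wstart[i], length.out = wlen[i])] <- TRUE
  }
  gaps <- !covered
  pstart <- integer(0); plen <- integer(0)
  if (any(gaps)) {
    r <- rle(gaps)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      seg <- substr(text, starts[k], ends[k])
      pm <- gregexpr("\\S+", seg, perl = TRUE)[[1L]]
      if (pm[1L] != -1L) {
        pstart <- c(pstart, starts[k] + as.integer(pm) - 1L)
        plen <- c(plen, attr(pm, "match.length"))
      }
    }
  }

  start1 <- c(wstart, pstart)                     # 1-based
  len <- c(wlen, plen)
  is_word <- rep(c(TRUE, FALSE), c(length(wstart), length(pstart)))
  ord <- order(start1)
  start1 <- start1[ord]; len <- len[ord]; is_word <- is_word[ord]
  data.frame(
    surface = substring(text, start1, start1 + len - 1L),
    start = start1 - 1L,
    end = start1 + len - 1L,
    is_word = is_word,
    stringsAsFactors = FALSE
  )
}

#' Normalize a word token
#'
#' Lowercases, removes hyphens, and collapses any run of more than two
#' identical letters down to two, so the expressive spellings `"BOOM"`,
#' `"Boooom"` and `"Bo-o-om"` all normalize to `"boom"`.  Runs of exactly
#' two letters are preserved (legitimate English doubling, as in
#' `"attack"`); downstream gazetteer matching additionally tries a
#' run-of-one fallback form for tokens the lexicon does not recognize
#' (see [annotate_document()]).  Idempotent.
#'
#' @param surface character vector of word-token surfaces.
#' @return character vector of normalized forms.
#' @examples
#' normalize_token(c("Boooom", "Bo-o-om", "safe"))
#' @export
normalize_token <- function(surface) {
  if (!is.character(surface)) stop_validation("`surface` must be character")
  x <- tolower(surface)
  x <- gsub("-", "", x, fixed = TRUE)
  gsub("(\\p{L})\\1{2,}", "\\1\\1", x, perl = TRUE)
}

# run-of-one fallback: every doubled (or longer) letter run collapsed to one
.collapse_singles <- function(x) gsub("(\\p{L})\\1+", "\\1", x, perl = TRUE)

#' Stop-word test
#'
#' @param normalized character vector of lowercase normalized tokens.
#' @param stoplist character vector of stop words (see
#'   [default_stopwords()]).
#' @return logical vector: is the token a stop word?
#' @export
is_stop <- function(normalized, stoplist) normalized %in% stoplist

#' Preprocess one document into annotated tokens
#'
#' Runs [tokenize()], then for every word token computes the normalized
#' form, its stop flag (tested on the normalized form, before stemming) and
#' its Porter stem.  No tokens are removed: stop filtering is by flag, so
#' the total word count of the document is preserved for density scoring.
#'
#' @param doc a one-row corpus data frame, or a list with `doc_id` and
#'   `text`.
#' @param stoplist character vector of stop words.
#' @return token data frame with columns `doc_id`, `surface`, `start`,
#'   `end`, `is_word`, `normalized`, `is_stop`, `stem` (the last three are
#'   `NA` for non-word tokens).
#' @examples
#' preprocess_document(list(doc_id = "d1", text = "The bomb detonated."),
#'                     default_stopwords())
#' @export
preprocess_document <- function(doc, stoplist = default_stopwords()) {
  toks <- tokenize(doc$text[[1L]])
  toks$doc_id <- rep(as.character(doc$doc_id[[1L]]), nrow(toks))
  toks$normalized <- NA_character_
  toks$is_stop <- NA
  toks$stem <- NA_character_
  w <- toks$is_word
  if (any(w)) {
    norm <- normalize_token(toks$surface[w])
    toks$normalized[w] <- norm
    toks$is_stop[w] <- is_stop(norm, stoplist)
    toks$stem[w] <- porter_stem(norm)
  }
  toks[c("doc_id", "surface", "start", "end", "is_word",
         "normalized", "is_stop", "stem")]
}

#' Built-in English stop list
#'
#' A standard list of function words (articles, prepositions, conjunctions,
#' pronouns, auxiliaries and light verbs such as *go*, *do*, *have*)
#' shipped as a plain-text data file, one word per line with `#` comments.
#' Deliberately conservative: content-bearing words that a combat-exposure
#' lexicon may need (e.g. *see*, *stop*, *fire*) are not on it.
#'
#' @param path optional path to a user-supplied stop list in the same
#'   format; defaults to the packaged file.
#' @return character vector of lowercase stop words.
#' @export
default_stopwords <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "stopwords.txt", package = "lexdens",
                        mustWork = TRUE)
  }
  if (!file.exists(path)) stop_io("stop list not found: ", path)
  x <- readLines(path, encoding = "UTF-8", warn = FALSE)
  x <- sub("#.*$", "", x)
  x <- trimws(x)
  tolower(x[nzchar(x)])
}
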
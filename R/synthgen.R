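## seeded synthetic-corpus generator
##
## The original blog corpus is not distributable, so the pipeline is
## exercised on generated stand-in corpora that emulate its statistical
## structure: short first-person-style documents whose tokens are drawn
## from the lexicon at a controllable density (inflected so the stemming
## path is exercised) against a fixed neutral background vocabulary, with
## optional elongation/hyphenation spelling noise on lexicon tokens.
## Narrative fluency is explicitly not a goal.

#' Generator configuration
#'
#' Defaults encode the study conditions used throughout the test suite:
#' 50 exposure-positive and 50 control documents of about 150 words
#' (floored at 5), lexicon-token density 10% in positives vs 1% in
#' controls, and a 10% per-lexicon-token chance of a spelling corruption
#' ("boom" -> "boooom" or "bo-o-om").
#'
#' @param n_pos,n_neg counts of positive / control documents.
#' @param len_mean,len_sd words per document (normal, rounded, min 5).
#' @param density_pos,density_neg probability, per token, of drawing from
#'   the lexicon rather than the background vocabulary, by class.
#' @param noise_rate per-lexicon-token corruption probability.
#' @param seed RNG seed; the same seed reproduces the corpus exactly.
#' @return a `gen_config` list.
#' @export
gen_config <- function(n_pos = 50L, n_neg = 50L, len_mean = 150,
                       len_sd = 30, density_pos = 0.10, density_neg = 0.01,
                       noise_rate = 0.10, seed = 1L) {
  cfg <- list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
              len_mean = len_mean, len_sd = len_sd,
              density_pos = density_pos, density_neg = density_neg,
              noise_rate = noise_rate, seed = as.integer(seed))
  if (cfg$n_pos < 0L || cfg$n_neg < 0L) {
    stop_validation("document counts must be non-negative")
  }
  for (f in c("density_pos", "density_neg", "noise_rate")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) {
      stop_validation(f, " must be in [0, 1]")
    }
  }
  if (cfg$len_mean < 5) stop_validation("len_mean must be at least 5 words")
  class(cfg) <- "gen_config"
  cfg
}

#' Background vocabulary
#'
#' The fixed 500-word neutral English list shipped with the package.
#' Words whose stems collide with the given lexicon (or whose normalized
#' form matches a literal surface variant) are dropped defensively, so
#' background tokens can never produce gazetteer hits.
#'
#' @param lexicon lexicon to stay disjoint from (default
#'   [seed_lexicon()]).
#' @param path optional alternative word list (one word per line, `#`
#'   comments).
#' @return character vector of background words.
#' @export
background_vocab <- function(lexicon = seed_lexicon(), path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "background_vocab.txt",
                        package = "lexdens", mustWork = TRUE)
  }
  if (!file.exists(path)) stop_io("background vocabulary not found: ", path)
  x <- readLines(path, encoding = "UTF-8", warn = FALSE)
  x <- trimws(sub("#.*$", "", x))
  x <- tolower(x[nzchar(x)])
  lex_stems <- lexicon$entries$stem
  surf <- unlist(lexicon$entries$surface_variants)
  norm <- normalize_token(x)
  tier2 <- .collapse_singles(norm)
  drop <- porter_stem(norm) %in% lex_stems |
    porter_stem(tier2) %in% lex_stems |
    norm %in% surf | tier2 %in% surf
  if (any(drop)) {
    message("background_vocab: dropped ", sum(drop),
            " word(s) colliding with the lexicon")
  }
  x[!drop]
}

# surface forms per lexicon entry: the stem inflected through a small
# suffix table (with e-drop before vowel-initial suffixes), keeping only
# forms the pipeline stems back to the entry -- this forces generated
# surfaces through the stemming path.  Suffix groups are tried in
# preference order; the derivational fallback group is used only when the
# plain and verbal groups yield nothing (e.g. "explos" -> "explosion").
.gen_suffix_groups <- list(c("", "s"),
                           c("ed", "ing", "ion", "ions"),
                           c("e", "es", "ate", "ated", "ation"))

.entry_forms <- function(lexicon) {
  lapply(seq_len(nrow(lexicon$entries)), function(i) {
    s <- lexicon$entries$stem[i]
    expand <- function(sufs) {
      cands <- paste0(s, sufs)
      if (endsWith(s, "e")) {
        chop <- substr(s, 1L, nchar(s) - 1L)
        vsuf <- sufs[grepl("^[aeiou]", sufs)]
        cands <- c(cands, paste0(chop, vsuf))
      }
      cands <- unique(cands)
      cands[porter_stem(normalize_token(cands)) == s]
    }
    forms <- c(expand(.gen_suffix_groups[[1L]]),
               expand(.gen_suffix_groups[[2L]]))
    if (!length(forms)) forms <- expand(.gen_suffix_groups[[3L]])
    unique(c(forms, lexicon$entries$surface_variants[[i]]))
  })
}

# spelling corruptions emulating expressive blog orthography; both repair
# to the clean form under normalization plus the matcher's run-of-one
# fallback
.corrupt_elongate <- function(word) {
  pos <- gregexpr("[aeiou]", word)[[1L]]
  if (pos[1L] == -1L) return(word)
  i <- pos[sample.int(length(pos), 1L)]
  ch <- substr(word, i, i)
  paste0(substr(word, 1L, i - 1L), strrep(ch, 4L),
         substr(word, i + 1L, nchar(word)))
}

.corrupt_hyphenate <- function(word) {
  pos <- gregexpr("[aeiou]", word)[[1L]]
  if (pos[1L] == -1L) return(word)
  i <- pos[sample.int(length(pos), 1L)]
  ch <- substr(word, i, i)
  paste0(substr(word, 1L, i - 1L), ch, "-", ch, "-", ch,
         substr(word, i + 1L, nchar(word)))
}

#' Sample one synthetic document
#'
#' Each token is independently a lexicon token (an inflected surface of a
#' random entry) with the class density as probability, otherwise a
#' background word.  Lexicon tokens are corrupted with probability
#' `noise_rate` by vowel elongation ("boooom") or hyphenated stutter
#' ("bo-o-om").  Uses the current RNG state; seed upstream for
#' reproducibility.
#'
#' @param cfg a [gen_config()].
#' @param label logical: generate at `density_pos` (TRUE) or
#'   `density_neg`.
#' @param lexicon lexicon to draw term tokens from.
#' @param background background word vector ([background_vocab()]); must
#'   be stem-disjoint from the lexicon.
#' @param forms precomputed [.entry_forms] list (internal optimization).
#' @return a list with `text` (the document string) and `n_lexicon` (how
#'   many tokens were lexicon draws).
#' @export
sample_document <- function(cfg, label, lexicon = seed_lexicon(),
                            background = background_vocab(lexicon),
                            forms = NULL) {
  if (is.null(forms)) forms <- .entry_forms(lexicon)
  density <- if (label) cfg$density_pos else cfg$density_neg
  len <- max(5L, as.integer(round(stats::rnorm(1L, cfg$len_mean,
                                               cfg$len_sd))))
  from_lex <- stats::runif(len) < density
  words <- character(len)
  n_bg <- sum(!from_lex)
  if (n_bg) words[!from_lex] <- background[sample.int(length(background),
                                                      n_bg, replace = TRUE)]
  for (i in which(from_lex)) {
    e <- sample.int(length(forms), 1L)
    w <- forms[[e]][sample.int(length(forms[[e]]), 1L)]
    if (stats::runif(1L) < cfg$noise_rate) {
      w <- if (stats::runif(1L) < 0.5) .corrupt_elongate(w)
           else .corrupt_hyphenate(w)
    }
    words[i] <- w
  }
  list(text = paste0(paste(words, collapse = " "), "."),
       n_lexicon = sum(from_lex))
}

#' Generate a labeled synthetic corpus
#'
#' Generates `n_pos` exposure-dense and `n_neg` control documents,
#' shuffles them deterministically under the configured seed, and labels
#' each with its generating class in `expert_label`.  The caller's RNG
#' state is left untouched.
#'
#' @param cfg a [gen_config()].
#' @param lexicon lexicon for term tokens (default [seed_lexicon()]).
#' @return a [corpus()] with `expert_label` set; the ground-truth table
#'   (`doc_id`, `label`, `target_density`, `n_lexicon`) is attached as
#'   attribute `"truth"`.
#' @examples
#' cps <- generate_corpus(gen_config(n_pos = 3, n_neg = 3, len_mean = 30))
#' cps
#' @export
generate_corpus <- function(cfg, lexicon = seed_lexicon()) {
  if (!inherits(cfg, "gen_config")) cfg <- do.call(gen_config, cfg)
  old_seed <- globalenv()$.Random.seed
  on.exit({
    if (is.null(old_seed)) {
      suppressWarnings(rm(".Random.seed", envir = globalenv()))
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(cfg$seed)

  forms <- .entry_forms(lexicon)
  background <- background_vocab(lexicon)
  labels <- rep(c(TRUE, FALSE), c(cfg$n_pos, cfg$n_neg))
  docs <- lapply(labels, function(lb) {
    sample_document(cfg, lb, lexicon, background, forms)
  })
  ord <- sample.int(length(labels))
  labels <- labels[ord]
  docs <- docs[ord]
  n <- length(docs)
  ids <- sprintf("synth%03d", seq_len(n))
  out <- corpus(ids, vapply(docs, `[[`, "", "text"), labels)
  attr(out, "truth") <- data.frame(
    doc_id = ids, label = labels,
    target_density = ifelse(labels, cfg$density_pos, cfg$density_neg),
    n_lexicon = vapply(docs, `[[`, 0L, "n_lexicon"),
    stringsAsFactors = FALSE
  )
  out
}
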
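## Porter suffix-stripping stemmer (1980 algorithm) with one widely used
## departure: the final-y rule (step 1c) rewrites y -> i only when the y is
## preceded by a consonant, so "deploy" and "say" keep their y while "happy"
## still becomes "happi".  See the methods vignette for the rationale.

.pt_vowels <- c("a", "e", "i", "o", "u")

# consonant test at position i of a letter vector; y is a consonant at the
# start of a word or after a vowel, otherwise it acts as a vowel
.pt_is_cons <- function(chars, i) {
  ch <- chars[[i]]
  if (ch %in% .pt_vowels) return(FALSE)
  if (ch == "y") {
    if (i == 1L) return(TRUE)
    return(!.pt_is_cons(chars, i - 1L))
  }
  TRUE
}

.pt_pattern <- function(word) {
  chars <- strsplit(word, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  if (n == 0L) return(character(0L))
  vapply(seq_len(n), function(i) if (.pt_is_cons(chars, i)) "c" else "v", "")
}

# the measure m: number of vowel-to-consonant transitions, i.e. the m in
# [C](VC)^m[V]
.pt_m <- function(word) {
  pat <- .pt_pattern(word)
  n <- length(pat)
  if (n < 2L) return(0L)
  sum(pat[-n] == "v" & pat[-1L] == "c")
}

.pt_has_vowel <- function(word) any(.pt_pattern(word) == "v")

.pt_ends_double_cons <- function(word) {
  n <- nchar(word)
  if (n < 2L) return(FALSE)
  a <- substr(word, n - 1L, n - 1L)
  b <- substr(word, n, n)
  a == b && .pt_pattern(word)[n] == "c"
}

# *o condition: stem ends consonant-vowel-consonant where the final
# consonant is not w, x or y
.pt_ends_cvc <- function(word) {
  n <- nchar(word)
  if (n < 3L) return(FALSE)
  pat <- .pt_pattern(word)
  last <- substr(word, n, n)
  pat[n - 2L] == "c" && pat[n - 1L] == "v" && pat[n] == "c" &&
    !(last %in% c("w", "x", "y"))
}

.pt_chop <- function(word, suffix) substr(word, 1L, nchar(word) - nchar(suffix))

# apply the first (longest) matching rule of a suffix table; once a suffix
# matches, its condition decides and no shorter suffix is tried
.pt_rule_table <- function(word, table, min_m) {
  sufs <- names(table)
  sufs <- sufs[order(-nchar(sufs))]
  for (suf in sufs) {
    if (endsWith(word, suf)) {
      stem <- .pt_chop(word, suf)
      if (.pt_m(stem) > min_m) return(paste0(stem, table[[suf]]))
      return(word)
    }
  }
  word
}

.pt_step2_table <- c(
  ational = "ate", tional = "tion", enci = "ence", anci = "ance",
  izer = "ize", abli = "able", alli = "al", entli = "ent", eli = "e",
  ousli = "ous", ization = "ize", ation = "ate", ator = "ate",
  alism = "al", iveness = "ive", fulness = "ful", ousness = "ous",
  aliti = "al", iviti = "ive", biliti = "ble"
)

.pt_step3_table <- c(
  icate = "ic", ative = "", alize = "al", iciti = "ic", ical = "ic",
  ful = "", ness = ""
)

.pt_step4_sufs <- c(
  "ement", "ance", "ence", "able", "ible", "ment", "ant", "ent", "ion",
  "ism", "ate", "iti", "ous", "ive", "ize", "al", "er", "ic", "ou"
)

.porter1 <- function(word, plural = TRUE) {
  if (nchar(word) <= 2L) return(word)
  if (!grepl("^[a-z]+$", word)) return(word)
  w <- word

  ## step 1a -- plurals (skippable so lexicon validation can test
  ## stem stability without the plural heuristic firing on stem-final s)
  if (plural) {
    if (endsWith(w, "sses")) {
      w <- paste0(.pt_chop(w, "sses"), "ss")
    } else if (endsWith(w, "ies")) {
      w <- paste0(.pt_chop(w, "ies"), "i")
    } else if (!endsWith(w, "ss") && endsWith(w, "s")) {
      w <- .pt_chop(w, "s")
    }
  }

  ## step 1b -- -ed / -ing
  cleanup <- FALSE
  if (endsWith(w, "eed")) {
    stem <- .pt_chop(w, "eed")
    if (.pt_m(stem) > 0L) w <- paste0(stem, "ee")
  } else if (endsWith(w, "ed")) {
    stem <- .pt_chop(w, "ed")
    if (.pt_has_vowel(stem)) {
      w <- stem
      cleanup <- TRUE
    }
  } else if (endsWith(w, "ing")) {
    stem <- .pt_chop(w, "ing")
    if (.pt_has_vowel(stem)) {
      w <- stem
      cleanup <- TRUE
    }
  }
  if (cleanup) {
    if (endsWith(w, "at") || endsWith(w, "bl") || endsWith(w, "iz")) {
      w <- paste0(w, "e")
    } else if (.pt_ends_double_cons(w) &&
               !substr(w, nchar(w), nchar(w)) %in% c("l", "s", "z")) {
      w <- substr(w, 1L, nchar(w) - 1L)
    } else if (.pt_m(w) == 1L && .pt_ends_cvc(w)) {
      w <- paste0(w, "e")
    }
  }

  ## step 1c -- final y (variant: only after a consonant)
  n <- nchar(w)
  if (n > 2L && endsWith(w, "y")) {
    stem <- substr(w, 1L, n - 1L)
    chars <- strsplit(w, "", fixed = TRUE)[[1L]]
    if (.pt_is_cons(chars, n - 1L) && .pt_has_vowel(stem)) {
      w <- paste0(stem, "i")
    }
  }

  ## steps 2 and 3 -- derivational suffixes, m > 0
  w <- .pt_rule_table(w, as.list(.pt_step2_table), 0L)
  w <- .pt_rule_table(w, as.list(.pt_step3_table), 0L)

  ## step 4 -- residual suffixes, m > 1
  for (suf in .pt_step4_sufs) {
    if (endsWith(w, suf)) {
      stem <- .pt_chop(w, suf)
      ok <- .pt_m(stem) > 1L
      if (suf == "ion") {
        last <- substr(stem, nchar(stem), nchar(stem))
        ok <- ok && last %in% c("s", "t")
        # an -ion ending whose stem lacks s/t is left alone, matching the
        # reference control flow (no shorter suffix can apply)
        if (!(last %in% c("s", "t"))) break
      }
      if (ok) w <- stem
      break
    }
  }

  ## step 5a -- final e
  if (endsWith(w, "e")) {
    stem <- .pt_chop(w, "e")
    m <- .pt_m(stem)
    if (m > 1L || (m == 1L && !.pt_ends_cvc(stem))) w <- stem
  }
  ## step 5b -- -ll with m > 1
  if (.pt_m(w) > 1L && .pt_ends_double_cons(w) && endsWith(w, "l")) {
    w <- substr(w, 1L, nchar(w) - 1L)
  }
  w
}

#' Porter stem of lowercase words
#'
#' Deterministic suffix-stripping stemmer mapping morphological variants to
#' a shared base form (`explosion`, `explosions`, `explosive` all yield
#' `explos`).  The classic algorithm is followed except that a final `y`
#' becomes `i` only when preceded by a consonant, so `deploy` stems to
#' `deploy` rather than `deploi`.
#'
#' Inputs containing characters other than lowercase ASCII letters (digits,
#' apostrophes) and words of one or two letters are returned unchanged.
#'
#' @param x character vector of lowercase, already-normalized word tokens.
#' @return character vector of stems, same length as `x`.
#' @examples
#' porter_stem(c("explosion", "vehicles", "detonated", "deploy"))
#' @export
porter_stem <- function(x) {
  if (!is.character(x)) stop("`x` must be a character vector")
  out <- x
  todo <- !is.na(x)
  out[todo] <- vapply(x[todo], .porter1, "", USE.NAMES = FALSE)
  out
}
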
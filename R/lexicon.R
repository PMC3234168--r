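## the combat-exposure lexicon: a two-level category tree with stem entries
##
## Categories form a tree whose top levels are CombatExposure and Emotion;
## each has two leaf subcategories (Direct/Indirect exposure,
## Protective/Stressful emotion).  Entries are stored pre-stemmed and
## normalized, each mapped to exactly one leaf, optionally with literal
## surface variants (abbreviations such as "ied") that are matched on the
## normalized surface without stemming.

# a stored stem is acceptable when the stemmer, run without its plural
# step, leaves it alone.  A raw surface word like "explosion" is still
# reduced (step 4 strips -ion) and gets rejected, while a true stemmer
# output like "explos" -- not a fixed point of the full algorithm only
# because step 1a would strip its final s -- is accepted.
.stem_self_consistent <- function(stem) {
  .porter1(stem, plural = FALSE) == stem
}

.new_lexicon <- function(categories, entries) {
  structure(list(categories = categories, entries = entries),
            class = "lexicon")
}

#' Validate a lexicon
#'
#' Checks that category names are unique and parent links form a tree,
#' that every entry maps to an existing leaf category, that stems are
#' unique, normalized (lowercase, no hyphens or letter elongation) and
#' self-consistent with the stemmer: running the stemmer (with its plural
#' step disabled, so a stem-final s is tolerated) must leave the stem
#' unchanged.  This catches entries written as raw surface words such as
#' "explosion" instead of "explos".
#'
#' @param lex a `lexicon` object.
#' @return `lex`, invisibly, on success; otherwise a validation error
#'   naming the offending category or entry.
#' @export
validate_lexicon <- function(lex) {
  cats <- lex$categories
  if (anyDuplicated(cats$name)) {
    stop_validation("duplicate category name: ",
                    cats$name[duplicated(cats$name)][1L])
  }
  known <- cats$name
  bad_parent <- !is.na(cats$parent) & !(cats$parent %in% known)
  if (any(bad_parent)) {
    stop_validation("unknown parent category: ",
                    cats$parent[bad_parent][1L])
  }
  # cycle check: walk each node to a root, bounded by tree size
  parent_of <- stats::setNames(cats$parent, cats$name)
  for (nm in cats$name) {
    seen <- character(0)
    cur <- nm
    while (!is.na(parent_of[[cur]])) {
      if (cur %in% seen) stop_validation("cyclic parent links at: ", cur)
      seen <- c(seen, cur)
      cur <- parent_of[[cur]]
    }
  }
  leaves <- setdiff(cats$name, stats::na.omit(cats$parent))
  ent <- lex$entries
  if (nrow(ent)) {
    if (anyDuplicated(ent$stem)) {
      stop_validation("duplicate entry stem: ",
                      ent$stem[duplicated(ent$stem)][1L])
    }
    bad_cat <- !(ent$category %in% leaves)
    if (any(bad_cat)) {
      stop_validation("entry '", ent$stem[bad_cat][1L],
                      "' has non-leaf or unknown category: ",
                      ent$category[bad_cat][1L])
    }
    not_norm <- ent$stem != normalize_token(ent$stem)
    if (any(not_norm)) {
      stop_validation("entry stem not normalized: ", ent$stem[not_norm][1L])
    }
    unreach <- !vapply(ent$stem, .stem_self_consistent, TRUE)
    if (any(unreach)) {
      stop_validation("entry stem is not a stemmer output (store stems, ",
                      "not surface words): ", ent$stem[unreach][1L])
    }
  }
  invisible(lex)
}

#' @export
print.lexicon <- function(x, ...) {
  leaves <- setdiff(x$categories$name, stats::na.omit(x$categories$parent))
  cat(sprintf("<lexicon> %d categories (%d leaves), %d entries\n",
              nrow(x$categories), length(leaves), nrow(x$entries)))
  if (nrow(x$entries)) {
    tab <- table(x$entries$category)
    for (nm in names(tab)) cat(sprintf("  %-12s %d\n", nm, tab[[nm]]))
  }
  invisible(x)
}

#' Load a lexicon from JSON
#'
#' Format: `{"categories":[{"name","parent"}...],` `
#' "entries":[{"stem","category","surface_variants":[...]}...]}` with
#' `parent: null` for top-level categories and `surface_variants`
#' optional.  The result is validated (see [validate_lexicon()]).
#'
#' @param path JSON file.
#' @return a `lexicon` object.
#' @export
load_lexicon <- function(path) {
  if (!file.exists(path)) stop_io("lexicon file not found: ", path)
  raw <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) {
                    stop_io("malformed lexicon JSON: ", conditionMessage(e))
                  })
  if (is.null(raw$categories) || is.null(raw$entries)) {
    stop_validation("lexicon JSON needs 'categories' and 'entries'")
  }
  categories <- data.frame(
    name = vapply(raw$categories, function(c) as.character(c$name), ""),
    parent = vapply(raw$categories, function(c) {
      if (is.null(c$parent)) NA_character_ else as.character(c$parent)
    }, ""),
    stringsAsFactors = FALSE
  )
  entries <- data.frame(
    stem = vapply(raw$entries, function(e) as.character(e$stem), ""),
    category = vapply(raw$entries, function(e) as.character(e$category), ""),
    stringsAsFactors = FALSE
  )
  entries$surface_variants <- lapply(raw$entries, function(e) {
    if (is.null(e$surface_variants)) character(0)
    else normalize_token(vapply(e$surface_variants, as.character, ""))
  })
  validate_lexicon(.new_lexicon(categories, entries))
}

#' Save a lexicon as canonical JSON
#'
#' Serialization is canonical -- categories ordered parents-before-children
#' (and alphabetically within a level), entries sorted by stem, fixed key
#' order, two-space indentation -- so `save_lexicon(load_lexicon(f), f2)`
#' is byte-identical for any file previously written by this function.
#'
#' @param lex a `lexicon` object.
#' @param path output JSON file.
#' @return `path`, invisibly.
#' @export
save_lexicon <- function(lex, path) {
  validate_lexicon(lex)
  cats <- lex$categories
  depth <- function(nm) {
    d <- 0L
    parent_of <- stats::setNames(cats$parent, cats$name)
    while (!is.na(parent_of[[nm]])) {
      nm <- parent_of[[nm]]
      d <- d + 1L
    }
    d
  }
  ord <- order(vapply(cats$name, depth, 0L), cats$name)
  cats <- cats[ord, , drop = FALSE]
  ent <- lex$entries[order(lex$entries$stem), , drop = FALSE]
  cat_list <- lapply(seq_len(nrow(cats)), function(i) {
    list(name = cats$name[i],
         parent = if (is.na(cats$parent[i])) NULL else cats$parent[i])
  })
  ent_list <- lapply(seq_len(nrow(ent)), function(i) {
    rec <- list(stem = ent$stem[i], category = ent$category[i])
    sv <- ent$surface_variants[[i]]
    if (length(sv)) rec$surface_variants <- as.list(sort(sv))
    rec
  })
  json <- jsonlite::toJSON(list(categories = cat_list, entries = ent_list),
                           auto_unbox = TRUE, pretty = 2, null = "null")
  ok <- tryCatch({
    writeLines(json, path, useBytes = TRUE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop_io("cannot write lexicon to ", path)
  invisible(path)
}

#' The built-in combat-exposure seed lexicon
#'
#' Loads the lexicon shipped with the package: the category tree
#' CombatExposure (Direct, Indirect) / Emotion (Protective, Stressful),
#' the twenty highest-weight combat-exposure stems recovered from the
#' pilot frequency analysis (explos, mission, truck, ...), the emotion
#' stems (protective: hope, safe, secur, support; stressful: scare,
#' upset, nervou), the exclamation "boom", and the literal abbreviation
#' variant "ied" attached to the bomb entry.  The split of exposure stems
#' between Direct (acting: fire, shot, attack, weapon, hit, patrol) and
#' Indirect (witnessing/context) is a curator choice; classification only
#' uses top-level categories, so the split does not affect the decision
#' rule.
#'
#' @return a validated `lexicon` object.
#' @export
seed_lexicon <- function() {
  load_lexicon(system.file("extdata", "seed_lexicon.json",
                           package = "lexdens", mustWork = TRUE))
}

#' Compile a lexicon into a gazetteer matcher
#'
#' Builds constant-time hash lookups from entry stems and from literal
#' surface variants to their entries, plus the leaf-to-top-level category
#' map used for reporting.
#'
#' @param lex a validated `lexicon`.
#' @return a `gazetteer_matcher` object.
#' @export
compile_matcher <- function(lex) {
  validate_lexicon(lex)
  stem_env <- new.env(parent = emptyenv(), hash = TRUE)
  surf_env <- new.env(parent = emptyenv(), hash = TRUE)
  ent <- lex$entries
  for (i in seq_len(nrow(ent))) {
    assign(ent$stem[i], i, envir = stem_env)
    for (sv in ent$surface_variants[[i]]) assign(sv, i, envir = surf_env)
  }
  parent_of <- stats::setNames(lex$categories$parent, lex$categories$name)
  top_of <- vapply(lex$categories$name, function(nm) {
    while (!is.na(parent_of[[nm]])) nm <- parent_of[[nm]]
    nm
  }, "")
  structure(list(stem_env = stem_env, surf_env = surf_env,
                 entries = ent, top_of = top_of),
            class = "gazetteer_matcher")
}

#' @export
print.gazetteer_matcher <- function(x, ...) {
  cat(sprintf("<gazetteer_matcher> %d stems, %d literal surfaces\n",
              length(ls(x$stem_env)), length(ls(x$surf_env))))
  invisible(x)
}

# lookup one token; returns entry row index or NA
.match_entry <- function(matcher, normalized, stem) {
  i <- matcher$surf_env[[normalized]]
  if (!is.null(i)) return(i)
  i <- matcher$stem_env[[stem]]
  if (!is.null(i)) return(i)
  NA_integer_
}
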
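## gazetteer annotation, annotation-density scoring and threshold
## classification
##
## A document's "richness" in combat-exposure vocabulary is the ratio of
## gazetteer annotations to its total word count, expressed in percent.
## A batch is classified transductively: the median ratio of the batch is
## the threshold, and a document is relevant when its ratio lies strictly
## above it.

.empty_annotations <- function() {
  data.frame(doc_id = character(0), start = integer(0), end = integer(0),
             surface = character(0), stem = character(0),
             category = character(0), top_category = character(0),
             stringsAsFactors = FALSE)
}

#' Annotate one document with gazetteer hits
#'
#' Every word token is looked up in the matcher: first its normalized
#' surface against literal variants (abbreviations like "ied"), then its
#' stem against entry stems; if neither matches, a run-of-one fallback
#' form (all doubled letter runs collapsed, catching residue of
#' elongations such as "saaafe") is tried the same way.  Stop-flagged
#' tokens remain matchable -- lexicon membership overrides stop status --
#' and every occurrence counts separately.
#'
#' @param doc a one-row corpus data frame or list with `doc_id`, `text`.
#' @param tokens token data frame from [preprocess_document()] for `doc`.
#' @param matcher a [compile_matcher()] result.
#' @return annotation data frame: `doc_id`, `start`, `end`, `surface`
#'   (matched substring of the raw text), `stem` (the lexicon stem),
#'   `category` (leaf) and `top_category`.
#' @export
annotate_document <- function(doc, tokens, matcher) {
  w <- which(tokens$is_word)
  if (!length(w)) return(.empty_annotations())
  idx <- vapply(w, function(i) {
    hit <- .match_entry(matcher, tokens$normalized[i], tokens$stem[i])
    if (is.na(hit)) {
      n1 <- .collapse_singles(tokens$normalized[i])
      if (n1 != tokens$normalized[i]) {
        hit <- .match_entry(matcher, n1, porter_stem(n1))
      }
    }
    hit
  }, 0L)
  keep <- w[!is.na(idx)]
  idx <- idx[!is.na(idx)]
  if (!length(keep)) return(.empty_annotations())
  ent <- matcher$entries[idx, , drop = FALSE]
  data.frame(
    doc_id = tokens$doc_id[keep],
    start = tokens$start[keep],
    end = tokens$end[keep],
    surface = tokens$surface[keep],
    stem = ent$stem,
    category = ent$category,
    top_category = unname(matcher$top_of[ent$category]),
    stringsAsFactors = FALSE
  )
}

#' Score a document's annotation density
#'
#' `n_wc` is the total word count: all word tokens, stop words included,
#' punctuation excluded.  `ratio_pct = 100 * n_ann / n_wc`; a document
#' with no word tokens scores 0 with a warning.
#'
#' @param doc a one-row corpus data frame or list with `doc_id`.
#' @param tokens token data frame for `doc`.
#' @param annotations annotation data frame from [annotate_document()].
#' @return one-row data frame: `doc_id`, `n_ann`, `n_wc`, `ratio_pct`
#'   (full precision; rounding happens only at reporting).
#' @export
score_document <- function(doc, tokens, annotations) {
  n_wc <- sum(tokens$is_word)
  n_ann <- nrow(annotations)
  if (n_wc == 0L) {
    if (n_ann > 0L) stop_validation("annotations on a document with no words")
    warning("document '", doc$doc_id[[1L]],
            "' has no word tokens; ratio set to 0")
    ratio <- 0
  } else {
    ratio <- 100 * n_ann / n_wc
  }
  data.frame(doc_id = as.character(doc$doc_id[[1L]]), n_ann = n_ann,
             n_wc = n_wc, ratio_pct = ratio, stringsAsFactors = FALSE)
}

#' Derive the batch-median classification threshold
#'
#' The threshold is the median of the per-document annotation-density
#' ratios; with an even number of documents, the mean of the two middle
#' order statistics.  Permutation-invariant in document order.
#'
#' @param scores data frame with a `ratio_pct` column (one row per
#'   document).
#' @return the threshold, in percent, at full precision.
#' @export
derive_threshold <- function(scores) {
  if (is.null(scores$ratio_pct) || nrow(scores) == 0L) {
    stop_validation("cannot derive a threshold from an empty batch")
  }
  stats::median(scores$ratio_pct)
}

#' Classify a batch of scored documents
#'
#' A document is relevant when its ratio lies strictly above the
#' threshold; a ratio exactly equal to the threshold is irrelevant (so
#' with an odd batch the median document itself is not automatically
#' positive).  When `threshold_pct` is omitted it is derived from this
#' very batch via [derive_threshold()] -- the transductive mode; pass a
#' fixed value to score new documents against a previously derived
#' threshold.
#'
#' @param scores data frame with `doc_id` and `ratio_pct`.
#' @param threshold_pct optional fixed threshold in percent.
#' @return data frame: `doc_id`, `ratio_pct`, `threshold_pct`, `label`
#'   (logical, relevant to combat exposure).
#' @export
classify_batch <- function(scores, threshold_pct = NULL) {
  if (is.null(threshold_pct)) threshold_pct <- derive_threshold(scores)
  if (!is.numeric(threshold_pct) || length(threshold_pct) != 1L ||
      is.na(threshold_pct)) {
    stop_validation("threshold_pct must be a single number")
  }
  data.frame(doc_id = scores$doc_id, ratio_pct = scores$ratio_pct,
             threshold_pct = threshold_pct,
             label = scores$ratio_pct > threshold_pct,
             stringsAsFactors = FALSE)
}

#' Write annotations and scores as JSON-lines standoff
#'
#' One record per scored document:
#' `{"doc_id","n_ann","n_wc","ratio_pct","label","spans":[{"start","end",`
#' `"surface","stem","category"}...]}` with 0-based half-open character
#' offsets into the raw text.  `label` is `null` for unclassified scores.
#' Round-trips through [read_annotations()].
#'
#' @param annotations annotation data frame (possibly empty); every
#'   `doc_id` must appear in `scores`.
#' @param scores data frame with `doc_id`, `n_ann`, `n_wc`, `ratio_pct`
#'   and optionally `label`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, scores, path) {
  extra <- setdiff(annotations$doc_id, scores$doc_id)
  if (length(extra)) {
    stop_validation("annotations for unscored doc_id: ",
                    paste(extra, collapse = ", "))
  }
  has_label <- "label" %in% names(scores)
  lines <- vapply(seq_len(nrow(scores)), function(i) {
    id <- scores$doc_id[i]
    a <- annotations[annotations$doc_id == id, , drop = FALSE]
    spans <- lapply(seq_len(nrow(a)), function(j) {
      list(start = a$start[j], end = a$end[j], surface = a$surface[j],
           stem = a$stem[j], category = a$category[j])
    })
    rec <- list(doc_id = id, n_ann = scores$n_ann[i], n_wc = scores$n_wc[i],
                ratio_pct = scores$ratio_pct[i],
                label = if (has_label) scores$label[i] else NULL,
                spans = spans)
    jsonlite::toJSON(rec, auto_unbox = TRUE, null = "null", digits = NA)
  }, "")
  ok <- tryCatch({
    writeLines(lines, path, useBytes = TRUE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop_io("cannot write annotations to ", path)
  invisible(path)
}

#' Read a JSON-lines annotation file
#'
#' @param path file written by [write_annotations()].
#' @return list with elements `scores` (data frame, including `label`
#'   where present) and `annotations` (data frame of spans).
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop_io("annotation file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  recs <- lapply(lines, jsonlite::fromJSON, simplifyVector = FALSE)
  scores <- data.frame(
    doc_id = vapply(recs, function(r) as.character(r$doc_id), ""),
    n_ann = vapply(recs, function(r) as.integer(r$n_ann), 0L),
    n_wc = vapply(recs, function(r) as.integer(r$n_wc), 0L),
    ratio_pct = vapply(recs, function(r) as.numeric(r$ratio_pct), 0),
    label = vapply(recs, function(r) {
      if (is.null(r$label)) NA else as.logical(r$label)
    }, NA),
    stringsAsFactors = FALSE
  )
  ann_list <- lapply(recs, function(r) {
    if (!length(r$spans)) return(.empty_annotations()[
      c("doc_id", "start", "end", "surface", "stem", "category")])
    data.frame(
      doc_id = as.character(r$doc_id),
      start = vapply(r$spans, function(s) as.integer(s$start), 0L),
      end = vapply(r$spans, function(s) as.integer(s$end), 0L),
      surface = vapply(r$spans, function(s) as.character(s$surface), ""),
      stem = vapply(r$spans, function(s) as.character(s$stem), ""),
      category = vapply(r$spans, function(s) as.character(s$category), ""),
      stringsAsFactors = FALSE
    )
  })
  list(scores = scores, annotations = do.call(rbind, ann_list))
}
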
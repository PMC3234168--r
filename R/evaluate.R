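## evaluation against an expert reference standard: confusion matrix,
## precision, recall, F-score

#' Confusion matrix of classifications against expert labels
#'
#' Documents without an expert label are skipped with a message.  TP =
#' pipeline-positive and expert-yes; FP = pipeline-positive, expert-no;
#' FN and TN accordingly.
#'
#' @param results data frame from [classify_batch()] (`doc_id`, `label`).
#' @param labels named logical vector keyed by doc_id (see
#'   [read_labels()]), or a data frame with `doc_id` and `expert_label`.
#' @return a `confusion_matrix` object: integer counts `tp`, `fp`, `tn`,
#'   `fn` summing to the number of labeled documents evaluated.
#' @export
confusion_matrix <- function(results, labels) {
  if (is.data.frame(labels)) {
    labels <- stats::setNames(as.logical(labels$expert_label), labels$doc_id)
  }
  labels <- labels[!is.na(labels)]
  keep <- results$doc_id %in% names(labels)
  skipped <- sum(!keep)
  if (skipped) {
    message("evaluate: skipped ", skipped, " unlabeled document(s)")
  }
  res <- results[keep, , drop = FALSE]
  if (nrow(res) == 0L) {
    stop_validation("no classified document has an expert label")
  }
  truth <- unname(labels[res$doc_id])
  pred <- res$label
  cm <- list(tp = sum(pred & truth), fp = sum(pred & !truth),
             tn = sum(!pred & !truth), fn = sum(!pred & truth))
  cm <- lapply(cm, as.integer)
  structure(cm, class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("          expert yes  expert no\n")
  cat(sprintf("pred yes  %10d  %9d\n", x$tp, x$fp))
  cat(sprintf("pred no   %10d  %9d\n", x$fn, x$tn))
  invisible(x)
}

.safe_ratio <- function(num, den, what) {
  if (den == 0L) {
    warning(what, " undefined: zero denominator")
    return(NA_real_)
  }
  num / den
}

#' Precision: TP / (TP + FP)
#'
#' The fraction of retrieved (pipeline-positive) documents that are
#' actually relevant.  Undefined (NA with a warning) when nothing was
#' retrieved.
#'
#' @param cm a [confusion_matrix()].
#' @return numeric in `[0, 1]`, or `NA`.
#' @export
precision <- function(cm) .safe_ratio(cm$tp, cm$tp + cm$fp, "precision")

#' Recall: TP / (TP + FN)
#'
#' Sensitivity: the fraction of all relevant documents that were
#' retrieved.  Undefined (NA with a warning) when no document is
#' expert-positive.
#'
#' @param cm a [confusion_matrix()].
#' @return numeric in `[0, 1]`, or `NA`.
#' @export
recall <- function(cm) .safe_ratio(cm$tp, cm$tp + cm$fn, "recall")

#' F-score: harmonic mean of precision and recall
#'
#' The balanced F1 measure, `2PR / (P + R)`.  Undefined when either
#' component is undefined or both are zero.
#'
#' @param cm a [confusion_matrix()].
#' @return numeric in `[0, 1]`, or `NA`.
#' @export
f_score <- function(cm) {
  p <- suppressWarnings(precision(cm))
  r <- suppressWarnings(recall(cm))
  if (is.na(p) || is.na(r) || (p + r) == 0) {
    warning("f_score undefined")
    return(NA_real_)
  }
  2 * p * r / (p + r)
}

#' The packaged pilot-evaluation scores
#'
#' Twenty blog posts from the pilot evaluation of the combat-exposure
#' pipeline, as per-document annotation-density ratios (percent) with the
#' expert relevance judgement for each.  Feeding these through
#' [derive_threshold()], [classify_batch()] and [confusion_matrix()]
#' reproduces the pilot results: threshold 4.95%, confusion (9, 1, 7, 3),
#' precision 0.90, recall 0.75, F-score 0.82 at two-decimal display.
#'
#' @return data frame: `doc_id`, `ratio_pct`, `expert_label` (logical).
#' @export
pilot_scores <- function() {
  path <- system.file("extdata", "pilot_scores.tsv", package = "lexdens",
                      mustWork = TRUE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  df$expert_label <- tolower(df$expert_label) == "yes"
  df
}

#' Evaluate scored documents against their expert labels
#'
#' The score-level entry point: classifies a batch of pre-computed
#' annotation densities (deriving the batch-median threshold unless one
#' is given) and compares against expert labels.
#'
#' @param scores data frame with `doc_id`, `ratio_pct`, `expert_label`.
#' @param threshold_pct optional fixed threshold.
#' @return a `lexdens_report` (see [evaluate_run()]).
#' @export
evaluate_scores <- function(scores, threshold_pct = NULL) {
  results <- classify_batch(scores, threshold_pct)
  cm <- confusion_matrix(results, scores)
  tab <- data.frame(doc_id = scores$doc_id,
                    expert_label = scores$expert_label,
                    ratio_pct = scores$ratio_pct,
                    label = results$label,
                    stringsAsFactors = FALSE)
  if (!is.null(scores$n_ann)) {
    tab$n_ann <- scores$n_ann
    tab$n_wc <- scores$n_wc
  }
  structure(list(table = tab,
                 threshold_pct = results$threshold_pct[1L],
                 confusion = cm,
                 precision = suppressWarnings(precision(cm)),
                 recall = suppressWarnings(recall(cm)),
                 f_score = suppressWarnings(f_score(cm))),
            class = "lexdens_report")
}

#' Run and evaluate the full pipeline on a labeled corpus
#'
#' Preprocesses and annotates every document with the lexicon gazetteer,
#' scores annotation densities, classifies with the (derived or given)
#' threshold, and evaluates against the corpus expert labels.
#'
#' @param corpus a labeled [corpus()].
#' @param lexicon a `lexicon` (default [seed_lexicon()]).
#' @param stoplist stop words (default [default_stopwords()]).
#' @param threshold_pct optional fixed threshold.
#' @return a `lexdens_report`: per-document table (expert label, counts,
#'   ratio, predicted label), derived threshold, confusion matrix and
#'   metrics, plus per-top-category annotation counts.
#' @export
evaluate_run <- function(corpus, lexicon = seed_lexicon(),
                         stoplist = default_stopwords(),
                         threshold_pct = NULL) {
  if (all(is.na(corpus$expert_label))) {
    stop_validation("evaluate_run needs a corpus with expert labels")
  }
  fit <- density_classifier(corpus, lexicon = lexicon, stoplist = stoplist,
                            threshold_pct = threshold_pct)
  scores <- fit$scores
  scores$expert_label <- corpus$expert_label[match(scores$doc_id,
                                                   corpus$doc_id)]
  rep <- evaluate_scores(scores, fit$threshold_pct)
  rep$category_counts <- fit$category_counts
  rep
}

#' @export
print.lexdens_report <- function(x, digits = 2L, ...) {
  cat(sprintf("Batch of %d labeled documents, threshold %.2f%%\n",
              nrow(x$table), round_display(x$threshold_pct, digits)))
  tab <- x$table
  tab$ratio_pct <- sprintf("%.2f", round_display(tab$ratio_pct, digits))
  tab$expert <- ifelse(tab$expert_label, "yes", "no")
  tab$pipeline <- ifelse(tab$label, "relevant", "irrelevant")
  print.data.frame(tab[c("doc_id", "expert", "ratio_pct", "pipeline")],
                   row.names = FALSE)
  cat("\n")
  print(x$confusion)
  cat(sprintf("\nprecision %.2f  recall %.2f  F-score %.2f\n",
              round_display(x$precision, digits),
              round_display(x$recall, digits),
              round_display(x$f_score, digits)))
  invisible(x)
}

#' Serialize a report to JSON
#'
#' @param x a `lexdens_report`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path) {
  payload <- list(
    threshold_pct = x$threshold_pct,
    confusion = list(tp = x$confusion$tp, fp = x$confusion$fp,
                     tn = x$confusion$tn, fn = x$confusion$fn),
    precision = x$precision, recall = x$recall, f_score = x$f_score,
    documents = x$table
  )
  ok <- tryCatch({
    writeLines(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                                dataframe = "rows", pretty = 2,
                                na = "null"),
               path, useBytes = TRUE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop_io("cannot write report to ", path)
  invisible(path)
}
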
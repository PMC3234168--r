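## the annotation-density classifier as a fitted-model object
##
## Fitting is transductive: the decision threshold is estimated as the
## median annotation-density ratio of the batch being classified.  The
## fitted object carries the threshold, per-document scores and
## annotations, and supports predict() on new documents at the frozen
## threshold.

#' Fit an annotation-density classifier to a corpus
#'
#' Runs the full recognition pipeline over a corpus: tokenization,
#' normalization, stop flagging and stemming; gazetteer annotation with
#' the lexicon; per-document density scores `ratio_pct = 100 * n_ann /
#' n_wc`; and the classification rule `relevant <=> ratio_pct >
#' threshold`.  When `threshold_pct` is `NULL` (the default) the
#' threshold is the batch median of the ratios -- the transductive mode in
#' which the pilot study operated; supply a fixed value to reuse a
#' previously derived cutoff.
#'
#' @param corpus a [corpus()]; must be non-empty.
#' @param lexicon a validated `lexicon` (default [seed_lexicon()]).
#' @param stoplist stop-word vector (default [default_stopwords()]).
#' @param threshold_pct optional fixed decision threshold in percent.
#' @return an object of class `density_classifier` with components
#'   `scores` (doc_id, n_ann, n_wc, ratio_pct), `results` (adds
#'   `threshold_pct` and logical `label`), `annotations` (all gazetteer
#'   hits with spans), `threshold_pct`, `threshold_source`
#'   (`"batch_median"` or `"fixed"`), `category_counts` (per-document
#'   annotation counts by top-level category, reported but not used by
#'   the decision rule) and `call`.
#' @examples
#' cps <- corpus(c("a", "b"),
#'               c("The bomb detonated near the patrol.",
#'                 "We watched a film and ate dinner quietly."))
#' fit <- density_classifier(cps)
#' fit
#' coef(fit)
#' fitted(fit)
#' @export
density_classifier <- function(corpus, lexicon = seed_lexicon(),
                               stoplist = default_stopwords(),
                               threshold_pct = NULL) {
  if (!inherits(corpus, "data.frame") || is.null(corpus$doc_id)) {
    stop_validation("`corpus` must be a corpus data frame")
  }
  if (nrow(corpus) == 0L) stop_validation("corpus is empty")
  matcher <- compile_matcher(lexicon)

  score_rows <- vector("list", nrow(corpus))
  ann_rows <- vector("list", nrow(corpus))
  cat_rows <- vector("list", nrow(corpus))
  tops <- sort(unique(unname(matcher$top_of)))
  for (i in seq_len(nrow(corpus))) {
    doc <- corpus[i, , drop = FALSE]
    toks <- preprocess_document(doc, stoplist)
    ann <- annotate_document(doc, toks, matcher)
    score_rows[[i]] <- score_document(doc, toks, ann)
    ann_rows[[i]] <- ann
    counts <- table(factor(ann$top_category, levels = tops))
    cat_rows[[i]] <- data.frame(doc_id = doc$doc_id, t(as.matrix(counts)),
                                stringsAsFactors = FALSE)
  }
  scores <- do.call(rbind, score_rows)
  annotations <- do.call(rbind, ann_rows)
  category_counts <- do.call(rbind, cat_rows)
  rownames(scores) <- rownames(category_counts) <- NULL

  source <- if (is.null(threshold_pct)) "batch_median" else "fixed"
  results <- classify_batch(scores, threshold_pct)

  structure(list(
    scores = scores,
    results = results,
    annotations = annotations,
    category_counts = category_counts,
    threshold_pct = results$threshold_pct[1L],
    threshold_source = source,
    lexicon = lexicon,
    n_docs = nrow(corpus),
    expert_label = corpus$expert_label,
    call = match.call()
  ), class = "density_classifier")
}

#' @export
print.density_classifier <- function(x, ...) {
  cat("Annotation-density classifier\n")
  cat(sprintf("  documents:  %d\n", x$n_docs))
  cat(sprintf("  threshold:  %.2f%% (%s)\n",
              round_display(x$threshold_pct, 2L),
              if (x$threshold_source == "batch_median")
                "batch median" else "fixed"))
  cat(sprintf("  relevant:   %d of %d\n", sum(x$results$label), x$n_docs))
  invisible(x)
}

#' @export
coef.density_classifier <- function(object, ...) {
  c(threshold_pct = object$threshold_pct)
}

#' @export
fitted.density_classifier <- function(object, ...) {
  stats::setNames(object$results$label, object$results$doc_id)
}

#' Classify new documents at the fitted threshold
#'
#' @param object a fitted `density_classifier`.
#' @param newdata a [corpus()] or character vector of raw texts; omitted,
#'   the fitted batch's results are returned.
#' @param type `"label"` for a named logical vector, `"ratio"` for named
#'   density ratios, `"scores"` for the full classification data frame.
#' @param ... unused.
#' @return depends on `type`.
#' @export
predict.density_classifier <- function(object, newdata = NULL,
                                       type = c("label", "ratio", "scores"),
                                       ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    res <- object$results
  } else {
    if (is.character(newdata)) {
      newdata <- corpus(paste0("doc", seq_along(newdata)), newdata)
    }
    refit <- density_classifier(newdata, lexicon = object$lexicon,
                                threshold_pct = object$threshold_pct)
    res <- refit$results
  }
  switch(type,
         label = stats::setNames(res$label, res$doc_id),
         ratio = stats::setNames(res$ratio_pct, res$doc_id),
         scores = res)
}

#' @export
summary.density_classifier <- function(object, ...) {
  out <- list(fit = object)
  if (any(!is.na(object$expert_label))) {
    labels <- stats::setNames(object$expert_label, object$scores$doc_id)
    cm <- confusion_matrix(object$results, labels)
    out$confusion <- cm
    out$precision <- suppressWarnings(precision(cm))
    out$recall <- suppressWarnings(recall(cm))
    out$f_score <- suppressWarnings(f_score(cm))
  }
  class(out) <- "summary.density_classifier"
  out
}

#' @export
print.summary.density_classifier <- function(x, ...) {
  print(x$fit)
  s <- x$fit$scores$ratio_pct
  cat(sprintf("  ratio_pct:  min %.2f / median %.2f / max %.2f\n",
              round_display(min(s), 2L), round_display(stats::median(s), 2L),
              round_display(max(s), 2L)))
  cc <- x$fit$category_counts
  for (nm in setdiff(names(cc), "doc_id")) {
    cat(sprintf("  %s annotations: %d\n", nm, sum(cc[[nm]])))
  }
  if (!is.null(x$confusion)) {
    cat("\nAgainst expert labels:\n")
    print(x$confusion)
    cat(sprintf("precision %.2f  recall %.2f  F-score %.2f\n",
                round_display(x$precision, 2L), round_display(x$recall, 2L),
                round_display(x$f_score, 2L)))
  }
  invisible(x)
}

#' Plot the fitted density distribution
#'
#' Dot plot of per-document annotation-density ratios in rank order,
#' filled by predicted label, with the decision threshold drawn as a
#' horizontal line.
#'
#' @param x a fitted `density_classifier`.
#' @param ... passed to [plot()].
#' @export
plot.density_classifier <- function(x, ...) {
  s <- x$scores$ratio_pct
  ord <- order(s)
  lab <- x$results$label[ord]
  graphics::plot(seq_along(s), s[ord], pch = ifelse(lab, 19, 1),
                 xlab = "document rank", ylab = "annotation density (%)",
                 main = "Annotation-density classification", ...)
  graphics::abline(h = x$threshold_pct, lty = 2)
  graphics::legend("topleft", pch = c(19, 1), bty = "n",
                   legend = c("relevant", "irrelevant"))
  invisible(x)
}
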
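# confusion matrix and IR metrics

test_that("confusion counts match a brute-force recount on random batches", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- 30L
    res <- data.frame(doc_id = paste0("d", 1:n),
                      ratio_pct = runif(n, 0, 10),
                      label = sample(c(TRUE, FALSE), n, replace = TRUE))
    truth <- setNames(sample(c(TRUE, FALSE), n, replace = TRUE),
                      res$doc_id)
    cm <- confusion_matrix(res, truth)
    tp <- fp <- tn <- fn <- 0L
    for (i in 1:n) {
      p <- res$label[i]; t <- truth[[res$doc_id[i]]]
      if (p && t) tp <- tp + 1L else if (p && !t) fp <- fp + 1L
      else if (!p && t) fn <- fn + 1L else tn <- tn + 1L
    }
    expect_equal(c(cm$tp, cm$fp, cm$tn, cm$fn), c(tp, fp, tn, fn))
    expect_equal(cm$tp + cm$fp + cm$tn + cm$fn, n)
  }
})

test_that("unlabeled documents are skipped, empty overlap is an error", {
  res <- data.frame(doc_id = c("a", "b"), label = c(TRUE, FALSE))
  expect_message(cm <- confusion_matrix(res, c(a = TRUE)), "skipped 1")
  expect_equal(cm$tp + cm$fp + cm$tn + cm$fn, 1L)
  expect_error(suppressMessages(
    confusion_matrix(res, c(z = TRUE))), class = "lexdens_validation_error")
})

test_that("metric formulas and harmonic-mean identities hold", {
  cm <- structure(list(tp = 9L, fp = 1L, tn = 7L, fn = 3L),
                  class = "confusion_matrix")
  expect_equal(precision(cm), 0.9)
  expect_equal(recall(cm), 0.75)
  expect_equal(f_score(cm), 2 * 0.9 * 0.75 / 1.65)
  expect_equal(round_display(f_score(cm), 2L), 0.82)
  # P == R == x implies F == x
  for (x in c(0.25, 0.5, 1)) {
    cmx <- structure(list(tp = 3L, fp = as.integer(3 / x - 3),
                          tn = 0L, fn = as.integer(3 / x - 3)),
                     class = "confusion_matrix")
    expect_equal(f_score(cmx), x)
  }
  # F between min and max of P and R
  expect_gte(f_score(cm), min(precision(cm), recall(cm)))
  expect_lte(f_score(cm), max(precision(cm), recall(cm)))
})

test_that("zero denominators give NA with a warning, not silent zero", {
  cm <- structure(list(tp = 0L, fp = 0L, tn = 10L, fn = 0L),
                  class = "confusion_matrix")
  expect_warning(p <- precision(cm), "undefined")
  expect_warning(r <- recall(cm), "undefined")
  expect_warning(f <- f_score(cm), "undefined")
  expect_true(is.na(p) && is.na(r) && is.na(f))
})

test_that("reports are internally consistent and order-invariant", {
  cps <- generate_corpus(gen_config(n_pos = 10L, n_neg = 10L,
                                    len_mean = 60, seed = 21L))
  rep <- evaluate_run(cps)
  expect_equal(rep$precision, precision(rep$confusion))
  expect_equal(rep$recall, recall(rep$confusion))
  expect_equal(rep$f_score, f_score(rep$confusion))
  expect_equal(nrow(rep$table), nrow(cps))

  shuffled <- cps[rev(seq_len(nrow(cps))), ]
  class(shuffled) <- class(cps)
  rep2 <- evaluate_run(shuffled)
  expect_equal(rep2$threshold_pct, rep$threshold_pct)
  expect_equal(c(rep2$confusion$tp, rep2$confusion$fp),
               c(rep$confusion$tp, rep$confusion$fp))

  # fixed threshold equal to the derived one reproduces the same report
  rep3 <- evaluate_run(cps, threshold_pct = rep$threshold_pct)
  expect_equal(rep3$table$label, rep$table$label)
  expect_equal(rep3$f_score, rep$f_score)

  f <- tempfile(fileext = ".json")
  write_report(rep, f)
  parsed <- jsonlite::fromJSON(f)
  expect_equal(parsed$confusion$tp, rep$confusion$tp)
  expect_equal(parsed$f_score, rep$f_score)
})
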
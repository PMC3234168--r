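# gazetteer annotation, density scoring, threshold classification

ann_setup <- function(text, lex = seed_lexicon()) {
  doc <- list(doc_id = "d1", text = text)
  toks <- preprocess_document(doc, default_stopwords())
  list(doc = doc, toks = toks,
       ann = annotate_document(doc, toks, compile_matcher(lex)))
}

test_that("every lexicon occurrence is annotated, with spans into raw text", {
  s <- ann_setup("The bomb hit the truck")
  expect_equal(nrow(s$ann), 3L)
  expect_setequal(s$ann$stem, c("bomb", "hit", "truck"))
  expect_equal(substr(rep("The bomb hit the truck", 3L),
                      s$ann$start + 1L, s$ann$end), s$ann$surface)

  expect_equal(nrow(ann_setup("a quiet breakfast by the river")$ann), 0L)
  expect_equal(nrow(ann_setup("boom boom")$ann), 2L)  # repeats all count
})

test_that("spelling variants and literal abbreviations are matched", {
  s <- ann_setup("BOOM! Boooom! Bo-o-om! An IED hit us.")
  expect_equal(sum(s$ann$stem == "boom"), 3L)
  expect_true(any(s$ann$surface == "IED" & s$ann$stem == "bomb"))
  # run-of-one fallback catches elongations of single letters
  s2 <- ann_setup("we were saaafe at last")
  expect_true("safe" %in% s2$ann$stem)
})

test_that("stop status does not shadow lexicon membership", {
  # "see" and "stop" are lexicon stems; force a stoplist that flags them
  lex <- seed_lexicon()
  doc <- list(doc_id = "d", text = "I see the stop")
  toks <- preprocess_document(doc, c("i", "the", "see", "stop"))
  expect_true(all(toks$is_stop[toks$surface %in% c("see", "stop")]))
  ann <- annotate_document(doc, toks, compile_matcher(lex))
  expect_setequal(ann$stem, c("see", "stop"))
})

test_that("density scores divide annotations by the full word count", {
  s <- ann_setup("The bomb hit the truck")
  sc <- score_document(s$doc, s$toks, s$ann)
  expect_equal(sc$n_wc, 5L)  # stop words count, punctuation does not
  expect_equal(sc$ratio_pct, 100 * 3 / 5)

  # the printed two-decimal convention: 5 hits in 59 words -> 8.47
  expect_equal(round_display(100 * 5 / 59, 2L), 8.47)

  empty <- ann_setup("...")
  expect_warning(sc0 <- score_document(empty$doc, empty$toks, empty$ann),
                 "no word tokens")
  expect_equal(sc0$ratio_pct, 0)
})

test_that("threshold is the batch median, order-invariant", {
  mk <- function(r) data.frame(doc_id = paste0("d", seq_along(r)),
                               ratio_pct = r)
  expect_equal(derive_threshold(mk(c(1, 2, 3))), 2)
  expect_equal(derive_threshold(mk(c(1, 2, 3, 4))), 2.5)
  set.seed(5)
  r <- runif(15, 0, 12)
  expect_equal(derive_threshold(mk(r)), derive_threshold(mk(sample(r))))
  expect_error(derive_threshold(data.frame(ratio_pct = numeric(0))),
               class = "lexdens_validation_error")
})

test_that("classification is strictly above-threshold", {
  sc <- data.frame(doc_id = c("a", "b", "c"),
                   ratio_pct = c(5.05, 4.84, 4.95))
  res <- classify_batch(sc, threshold_pct = 4.95)
  expect_equal(res$label, c(TRUE, FALSE, FALSE))  # equality -> irrelevant
  # transductive default: threshold derived from the batch itself
  res2 <- classify_batch(sc)
  expect_equal(res2$threshold_pct[1L], 4.95)
  expect_error(classify_batch(sc[0, ]), class = "lexdens_validation_error")
})

test_that("raising n_ann at fixed n_wc never flips relevant to irrelevant", {
  for (n_ann in 0:19) {
    lo <- 100 * n_ann / 20
    hi <- 100 * (n_ann + 1L) / 20
    sc <- data.frame(doc_id = c("x", "y"), ratio_pct = c(lo, hi))
    res <- classify_batch(sc, threshold_pct = 4.95)
    expect_true(res$label[2L] >= res$label[1L])
  }
})

test_that("annotation standoff files round-trip", {
  s <- ann_setup("The bomb hit the truck; boom went the mortar.")
  sc <- score_document(s$doc, s$toks, s$ann)
  sc$label <- TRUE
  f <- tempfile(fileext = ".jsonl")
  write_annotations(s$ann, sc, f)
  back <- read_annotations(f)
  expect_equal(back$scores$doc_id, sc$doc_id)
  expect_equal(back$scores$n_ann, sc$n_ann)
  expect_equal(back$scores$ratio_pct, sc$ratio_pct)
  expect_equal(back$scores$label, TRUE)
  expect_equal(back$annotations$start, s$ann$start)
  expect_equal(back$annotations$surface, s$ann$surface)

  # zero-annotation documents still emit a record with the ratio
  s0 <- ann_setup("quiet breakfast")
  sc0 <- score_document(s0$doc, s0$toks, s0$ann)
  write_annotations(s0$ann, sc0, f)
  rec <- jsonlite::fromJSON(readLines(f))
  expect_equal(rec$n_ann, 0L)
  expect_equal(length(rec$spans), 0L)

  # annotations whose doc_id is missing from the scores are rejected
  sc_other <- sc0
  sc_other$doc_id <- "someone_else"
  expect_error(write_annotations(s$ann, sc_other, f),
               class = "lexdens_validation_error")
})
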
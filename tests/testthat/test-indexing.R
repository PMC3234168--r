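# corpus term statistics and TF*IDF weights

test_that("weights match the hand-computed example", {
  tw <- term_statistics(tiny_corpus())
  bomb <- tw[tw$stem == "bomb", ]
  expect_equal(bomb$corpus_count, 3L)
  expect_equal(bomb$doc_freq, 2L)
  expect_equal(bomb$tf, 0.75)
  expect_equal(bomb$idf, log10(2), tolerance = 1e-12)
  expect_equal(bomb$weight, 0.75 * log10(2), tolerance = 1e-12)
  # sorted by weight desc, ties lexicographic: hope (0.1505...) before truck
  expect_equal(tw$stem, c("bomb", "hope", "truck"))
})

test_that("idf closed forms hold at the boundaries", {
  one <- term_statistics(corpus("d1", "bomb"))
  expect_equal(one$idf, 0)        # doc_freq == N
  expect_equal(one$weight, 0)
  ten <- term_statistics(corpus(paste0("d", 1:10),
                                c("bomb", rep("truck", 9L))))
  expect_equal(ten$idf[ten$stem == "bomb"], 1.0)  # log10(10/1)
})

test_that("term statistics equal a brute-force recount on small corpora", {
  vocab <- c("bomb", "bombs", "truck", "hope", "the", "a", "fire",
             "quiet", "morning", "boom")
  sw <- default_stopwords()
  for (seed in 1:8) {
    cps <- random_corpus(n_docs = sample.int(5L, 1L), max_tokens = 20L,
                         vocab = vocab, seed = seed)
    got <- term_statistics(cps, sw)
    want <- brute_term_stats(cps, sw)
    rownames(got) <- rownames(want) <- NULL
    expect_equal(as.data.frame(got), want, tolerance = 1e-12)
  }
})

test_that("counts are conserved and idf is monotone under corpus growth", {
  sw <- default_stopwords()
  cps <- random_corpus(4L, 15L, c("bomb", "truck", "hope", "fire", "the"),
                       seed = 99)
  tw <- term_statistics(cps, sw)
  total_nonstop <- sum(vapply(seq_len(nrow(cps)), function(i) {
    t <- preprocess_document(cps[i, ], sw)
    sum(t$is_word & !t$is_stop)
  }, 0L))
  expect_equal(sum(tw$corpus_count), total_nonstop)

  grown <- corpus(c(cps$doc_id, "extra"), c(cps$text, "bomb truck"))
  tw2 <- term_statistics(grown, sw)
  for (s in c("bomb", "truck")) {
    expect_equal(tw2$doc_freq[tw2$stem == s], tw$doc_freq[tw$stem == s] + 1L)
    expect_lte(tw2$idf[tw2$stem == s], tw$idf[tw$stem == s])
  }
})

test_that("candidate selection is strictly above the cutoff", {
  w <- data.frame(stem = c("a", "b", "c"), weight = c(0.15, 0.10, 0.05))
  expect_equal(select_candidates(w, 0.1), "a")
  expect_equal(select_candidates(w, 0), c("a", "b", "c"))
  expect_equal(select_candidates(w[0, ], 0.1), character(0))
  expect_error(select_candidates(w, -1), class = "lexdens_validation_error")
})

test_that("frequency table export round-trips at full precision", {
  tw <- term_statistics(tiny_corpus())
  f <- tempfile(fileext = ".tsv")
  export_frequency_table(tw, f)
  hdr <- strsplit(readLines(f, n = 1L), "\t")[[1L]]
  expect_equal(hdr[1:3], c("stem", "weight", "idf"))  # display layout
  back <- read_frequency_table(f)
  expect_equal(back$weight, tw$weight, tolerance = 1e-15)
  expect_equal(back$idf, tw$idf, tolerance = 1e-15)
  export_frequency_table(tw[0, ], f)
  expect_equal(nrow(read_frequency_table(f)), 0L)
})

test_that("empty corpus is a validation error", {
  expect_error(term_statistics(corpus(character(0), character(0))),
               class = "lexdens_validation_error")
})
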
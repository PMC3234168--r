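# synthetic-corpus generator: determinism, density control, noise behaviour

test_that("configuration is validated", {
  expect_error(gen_config(density_pos = 1.2),
               class = "lexdens_validation_error")
  expect_error(gen_config(len_mean = 3), class = "lexdens_validation_error")
  expect_error(gen_config(n_pos = -1), class = "lexdens_validation_error")
})

test_that("the same seed reproduces the corpus exactly", {
  cfg <- gen_config(n_pos = 5L, n_neg = 5L, len_mean = 40, seed = 13L)
  c1 <- generate_corpus(cfg)
  c2 <- generate_corpus(cfg)
  expect_identical(c1$text, c2$text)
  expect_identical(c1$expert_label, c2$expert_label)
  expect_identical(attr(c1, "truth"), attr(c2, "truth"))
  # and the caller's RNG stream is not disturbed
  set.seed(1); a <- runif(1)
  set.seed(1); invisible(generate_corpus(cfg)); b <- runif(1)
  expect_identical(a, b)
})

test_that("density extremes force zero or total annotation", {
  lex <- seed_lexicon()
  m <- compile_matcher(lex)
  cfg0 <- gen_config(n_pos = 2L, n_neg = 0L, len_mean = 50,
                     density_pos = 0, noise_rate = 0, seed = 2L)
  for (i in seq_len(2L)) {
    cps <- generate_corpus(cfg0)
    doc <- cps[i, ]
    toks <- preprocess_document(doc, default_stopwords())
    expect_equal(nrow(annotate_document(doc, toks, m)), 0L)
  }
  cfg1 <- gen_config(n_pos = 2L, n_neg = 0L, len_mean = 50,
                     density_pos = 1, noise_rate = 0, seed = 2L)
  cps <- generate_corpus(cfg1)
  fit <- density_classifier(cps, threshold_pct = 50)
  expect_equal(fit$scores$ratio_pct, c(100, 100))
})

test_that("positive-class hit density matches the target within 3 SD", {
  cfg <- gen_config(n_pos = 20L, n_neg = 0L, len_mean = 200, len_sd = 0,
                    density_pos = 0.10, noise_rate = 0, seed = 31L)
  cps <- generate_corpus(cfg)
  fit <- density_classifier(cps, threshold_pct = 0)
  n_words <- sum(fit$scores$n_wc)
  n_hits <- sum(fit$scores$n_ann)
  p <- cfg$density_pos
  se <- sqrt(p * (1 - p) / n_words)
  expect_lt(abs(n_hits / n_words - p), 3 * se)
  # every lexicon draw produced exactly one annotation (no background hits)
  expect_equal(n_hits, sum(attr(cps, "truth")$n_lexicon))
})

test_that("label recovery improves with class separation", {
  f1_at <- function(dpos) {
    fs <- vapply(1:3, function(s) {
      cfg <- gen_config(n_pos = 25L, n_neg = 25L, len_mean = 100,
                        density_pos = dpos, density_neg = 0.01,
                        noise_rate = 0.1, seed = 100L + s)
      suppressMessages(evaluate_run(generate_corpus(cfg)))$f_score
    }, 0)
    mean(fs)
  }
  grid <- vapply(c(0.02, 0.05, 0.10), f1_at, 0)
  expect_true(all(diff(grid) >= 0))
  expect_gt(grid[3L], 0.9)
})

test_that("spelling noise at 20% keeps at least 90% of annotations", {
  # paired against the generator's ground truth: recall = annotations
  # recovered per lexicon token actually drawn
  recall_at <- function(noise) {
    cfg <- gen_config(n_pos = 30L, n_neg = 0L, len_mean = 100,
                      density_pos = 0.15, noise_rate = noise, seed = 7L)
    cps <- generate_corpus(cfg)
    fit <- density_classifier(cps, threshold_pct = 0)
    nrow(fit$annotations) / sum(attr(cps, "truth")$n_lexicon)
  }
  expect_equal(recall_at(0), 1)          # every clean surface matches
  expect_gte(recall_at(0.2), 0.9 * recall_at(0))
})
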
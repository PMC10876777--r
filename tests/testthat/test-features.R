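test_that("orthographic syllable counting matches hand counts", {
  expect_equal(count_syllables("picnic"), 2L)
  expect_equal(count_syllables("the"), 1L)       # lone-group silent e keeps 1
  expect_equal(count_syllables("beautiful"), 3L) # eau, i, u
  expect_equal(
    count_syllables(c("dog", "basket", "under", "fisherman", "plate",
                      "sky", "banana")),
    c(1L, 2L, 2L, 3L, 1L, 1L, 3L)                # "plate": silent final e
  )
  expect_warning(got <- count_syllables("123"), "alphabetic")
  expect_equal(got, 1L)
  expect_equal(count_syllables("picnic", overrides = c(picnic = 3L)), 3L)
})

test_that("mean log frequency averages ln counts over in-lexicon content words", {
  lex <- tiny_lexicon()
  s <- tagged_sample(c("the", "dog"))  # "dog" NOUN, count 403
  r <- mean_log_frequency(s, lex)
  expect_equal(r$value, log(403), tolerance = 1e-12)
  expect_equal(round(r$value, 3), 5.999)
  expect_equal(r$n_content, 1L)

  s2 <- tagged_sample(c("the", "cat", "tree"))  # counts 100 and 1000
  expect_equal(mean_log_frequency(s2, lex)$value, (log(100) + log(1000)) / 2)
  expect_equal(round(mean_log_frequency(s2, lex)$value, 4), 5.7565)

  # all function words: undefined mean, zero content words
  s3 <- tagged_sample(c("the", "of", "my"))
  r3 <- mean_log_frequency(s3, lex)
  expect_true(is.na(r3$value))
  expect_equal(r3$n_content, 0L)

  # OOV content words excluded from the mean and counted
  s4 <- tagged_sample(c("dog", "zyzzyva"))
  r4 <- mean_log_frequency(s4, lex)
  expect_equal(r4$value, log(403))
  expect_equal(r4$oov, 1L)
  # ... unless an imputation count is requested
  expect_equal(mean_log_frequency(s4, lex, oov_count = 1)$value, log(403) / 2)

  # invariant to token order and to added function words
  s5 <- tagged_sample(c("tree", "the", "cat", "under", "my"))
  expect_equal(mean_log_frequency(s5, lex)$value,
               mean_log_frequency(s2, lex)$value)

  # token vs type averaging
  s6 <- tagged_sample(c("cat", "cat", "tree"))
  expect_equal(mean_log_frequency(s6, lex)$value,
               (2 * log(100) + log(1000)) / 3)
  expect_equal(mean_log_frequency(s6, lex, by = "types")$value,
               (log(100) + log(1000)) / 2)
})

test_that("utterance latencies are previous-offset-to-onset gaps, first word excluded", {
  s <- make_sample(c("a", "b", "c"), c(0.00, 0.80, 1.20),
                   c(0.50, 1.20, 1.60))
  r <- utterance_latencies(s)
  expect_equal(r$per_word, c(0.30, 0.00))
  expect_equal(r$mean, 0.15)

  # perfectly contiguous speech: all gaps zero
  s2 <- make_sample(c("a", "b"), c(0, 0.5), c(0.5, 1.0))
  expect_equal(utterance_latencies(s2)$mean, 0)

  # overlapping ASR timings clamp to zero with a warning
  s3 <- make_sample(c("a", "b"), c(0, 0.4), c(0.5, 1.0))
  expect_warning(r3 <- utterance_latencies(s3), "clamping")
  expect_equal(r3$per_word, 0)

  # fewer than 2 tokens: undefined
  s4 <- make_sample("a", 0, 0.5)
  expect_true(is.na(utterance_latencies(s4)$mean))

  # median aggregation option
  s5 <- make_sample(c("a", "b", "c", "d"), c(0, 1, 2, 3.9),
                    c(0.9, 1.9, 2.9, 4.4))
  expect_equal(utterance_latencies(s5, aggregate = "median")$mean,
               median(c(0.1, 0.1, 1.0)))
})

test_that("articulation rate is syllables over speaking time, pauses excluded", {
  s <- make_sample(c("picnic", "basket"), c(0.0, 0.7), c(0.5, 1.2))
  expect_equal(articulation_rate(s), 4 / 1.0)

  s2 <- make_sample("sky", 0, 0.25)
  expect_equal(articulation_rate(s2), 4)

  # zero total duration: undefined
  s3 <- make_sample("a", 0.5, 0.5)
  expect_true(is.na(articulation_rate(s3)))

  # explicit syllable counts override the heuristic
  s4 <- make_sample("picnic", 0, 1)
  s4$tokens$syllables <- 3L
  expect_equal(articulation_rate(s4), 3)
})

test_that("relational ratio counts case tokens over all tokens", {
  s <- tagged_sample(c("i", "found", "the", "gem", "under", "my", "bed"))
  expect_equal(relational_ratio(s), 1 / 7)
  expect_equal(round(relational_ratio(s), 4), 0.1429)

  expect_equal(relational_ratio(tagged_sample(c("the", "dog", "ran"))), 0)
  expect_equal(relational_ratio(tagged_sample("under")), 1)

  # invariant under duplication of the whole token sequence
  s2 <- tagged_sample(rep(c("i", "found", "the", "gem", "under", "my", "bed"), 2))
  expect_equal(relational_ratio(s2), relational_ratio(s))

  # curated spatial-only list restricts the count
  s3 <- tagged_sample(c("top", "of", "the", "hill", "under", "a", "tree"))
  expect_equal(relational_ratio(s3), 2 / 7)
  expect_equal(relational_ratio(s3, spatial_forms = c("under", "over")), 1 / 7)
})

test_that("timing decomposes into speaking time plus gaps", {
  set.seed(9)
  for (i in 1:20) {
    n <- sample(2:30, 1)
    dur <- runif(n, 0.1, 0.8)
    gap <- runif(n - 1, 0, 0.5)
    start <- cumsum(c(0, dur[-n] + gap))
    s <- make_sample(sprintf("w%d", 1:n), start, start + dur)
    elapsed <- max(s$tokens$end) - min(s$tokens$start)
    raw_gaps <- utterance_latencies(s)$per_word
    expect_equal(elapsed, sum(dur) + sum(raw_gaps))
    expect_lte(sum(pmax(raw_gaps, 0)), sum(raw_gaps) + 1e-12)
  }
})

test_that("extract_features composes all components deterministically", {
  lex <- tiny_lexicon()
  dict <- tiny_dict()
  s <- tagged_sample(c("the", "girl", "found", "a", "picnic", "basket",
                       "under", "the", "tree"))
  fv <- extract_features(s, lex, dict)
  expect_equal(fv$theme_mentioned, 1L)
  expect_equal(fv$total_content_units, 3L)  # girl, picnic, basket
  expect_equal(fv$focus_mentioned, 0L)
  expect_equal(fv$relational_ratio, 1 / 9)
  expect_equal(fv$n_tokens, 9L)
  expect_identical(extract_features(s, lex, dict), fv)  # deterministic

  # undefined components carried as NA, not errors
  empty <- transcript_sample("e", "CN", "picture",
                             tibble::tibble(text = character(),
                                            start = numeric(),
                                            end = numeric()))
  fe <- extract_features(empty, lex, dict)
  expect_true(is.na(fe$mean_log_frequency))
  expect_true(is.na(fe$articulation_rate))
  expect_equal(fe$total_content_units, 0L)
})
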
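test_that("timed transcript JSON parses, validates, and round-trips", {
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(
    list(participant_id = "p1", group = "PCA", task = "picture",
         words = list(list(word = "hello", start = 0.0, end = 0.4),
                      list(word = "world", start = 0.5, end = 1.0))),
    path, auto_unbox = TRUE
  )
  s <- read_timed_transcript(path)
  expect_equal(nrow(s$tokens), 2L)
  expect_identical(s$tokens$text, c("hello", "world"))
  expect_equal(s$tokens$start[1], 0.0)

  # empty word list is a valid sample with zero tokens
  jsonlite::write_json(
    list(participant_id = "p2", group = "CN", task = "job", words = list()),
    path, auto_unbox = TRUE
  )
  expect_equal(nrow(read_timed_transcript(path)$tokens), 0L)

  # end < start names the offending token
  jsonlite::write_json(
    list(participant_id = "p3", group = "PCA", task = "picture",
         words = list(list(word = "oops", start = 0.5, end = 0.3))),
    path, auto_unbox = TRUE
  )
  expect_error(read_timed_transcript(path), "token 1")

  # malformed JSON names the file
  writeLines("{not json", path)
  expect_error(read_timed_transcript(path), "malformed")

  # ASR "s"-suffixed durations are accepted and stripped
  jsonlite::write_json(
    list(participant_id = "p4", group = "CN", task = "picture",
         words = list(list(word = "hi", start = "0.100s", end = "0.600s"))),
    path, auto_unbox = TRUE
  )
  expect_equal(read_timed_transcript(path)$tokens$end, 0.6)

  # write/read round trip preserves order, times, annotation
  s <- make_sample(c("the", "gem"), c(0, 0.6), c(0.4, 1.1),
                   lemma = c("the", "gem"), upos = c("DET", "NOUN"),
                   deprel = c("det", "obj"))
  write_timed_transcript(s, path)
  s2 <- read_timed_transcript(path)
  expect_equal(s2$tokens[c("text", "start", "end", "lemma", "upos", "deprel")],
               s$tokens[c("text", "start", "end", "lemma", "upos", "deprel")])
})

test_that("frequency lexicon reader folds case, merges duplicates, validates", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# corpus_total=2345269", "word\tcount",
               "dog\t100", "Dog\t50", "tree\t1000"), path)
  lex <- read_frequency_lexicon(path)
  expect_equal(unname(lexicon_count(lex, "dog")), 150)
  expect_equal(unname(lexicon_count(lex, "DOG")), 150)  # case-insensitive
  expect_equal(lex$corpus_total, 2345269)
  expect_lte(length(lex$counts), 3L)
  expect_true(is.na(lexicon_count(lex, "zebra")))

  writeLines(c("# corpus_total=100", "word\tcount", "tree\t0"), path)
  expect_error(read_frequency_lexicon(path), "positive")

  writeLines(c("word\tcount", "tree\t5"), path)
  expect_error(read_frequency_lexicon(path), "corpus_total")

  # write/read round trip
  out <- withr::local_tempfile(fileext = ".tsv")
  write_frequency_lexicon(lex, out)
  expect_equal(read_frequency_lexicon(out)$counts, lex$counts)
})

test_that("content-unit dictionary enforces its invariants", {
  expect_error(
    cu_dictionary(list(girl = c("girl", "daughter"), basket = "basket"),
                  theme_unit = "picnic"),
    "theme"
  )
  err <- expect_error(
    cu_dictionary(list(sailboat = c("boat", "sail"), ship = c("ship", "boat")),
                  theme_unit = "ship"),
    "'boat'"
  )
  expect_match(conditionMessage(err), "sailboat")
  expect_match(conditionMessage(err), "ship")

  # shipped 32-unit picnic fixture loads from JSON
  path <- system.file("extdata", "picnic_units_synthetic.json",
                      package = "visiolex")
  dict <- read_cu_dictionary(path)
  expect_length(dict$units, 32L)
  expect_identical(dict$theme_unit, "picnic")
  expect_true("fisherman" %in% names(dict$units))

  # forms are lower-cased on construction
  d <- cu_dictionary(list(girl = c("Girl", "DAUGHTER")), theme_unit = "girl")
  expect_identical(d$units$girl, c("girl", "daughter"))
})

test_that("feature table CSV round-trips at full precision", {
  feats <- rbind(
    tibble::tibble(participant_id = "a", group = "PCA", task = "picture",
                   mean_log_frequency = pi, total_content_units = 7L),
    tibble::tibble(participant_id = "b", group = "CN", task = "picture",
                   mean_log_frequency = exp(1) / 3, total_content_units = 16L)
  )
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(feats, path)
  back <- read_feature_table(path)
  expect_equal(nrow(back), 2L)
  expect_identical(back$mean_log_frequency, feats$mean_log_frequency)

  dup <- rbind(feats, feats[1, ])
  expect_error(write_feature_table(dup, path), "duplicate")
})

test_that("CoNLL-U import drops punctuation and aligns positionally", {
  path <- withr::local_tempfile(fileext = ".conllu")
  writeLines(c(
    "# sent_id = 1",
    "1\tI\tI\tPRON\tPRP\t_\t2\tnsubj\t_\t_",
    "2\tfound\tfind\tVERB\tVBD\t_\t0\troot\t_\t_",
    "3\tthe\tthe\tDET\tDT\t_\t4\tdet\t_\t_",
    "4\tgem\tgem\tNOUN\tNN\t_\t2\tobj\t_\t_",
    "5\tunder\tunder\tADP\tIN\t_\t7\tcase\t_\t_",
    "6\tmy\tmy\tPRON\tPRP$\t_\t7\tnmod:poss\t_\t_",
    "7\tbed\tbed\tNOUN\tNN\t_\t2\tobl\t_\t_",
    "8\t.\t.\tPUNCT\t.\t_\t2\tpunct\t_\t_"
  ), path)
  ann <- read_conllu(path)
  expect_equal(nrow(ann), 7L)  # punctuation dropped
  expect_false("PUNCT" %in% ann$upos)

  words <- c("i", "found", "the", "gem", "under", "my", "bed")
  s <- make_sample(words, seq(0, by = 0.5, length.out = 7),
                   seq(0.4, by = 0.5, length.out = 7))
  s <- apply_conllu_annotation(s, ann)
  expect_identical(s$tokens$deprel[5], "case")
  expect_identical(s$tokens$lemma[2], "find")

  short <- make_sample(words[1:6], seq(0, by = 0.5, length.out = 6),
                       seq(0.4, by = 0.5, length.out = 6))
  expect_error(apply_conllu_annotation(short, ann), "alignment")
})
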
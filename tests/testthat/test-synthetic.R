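test_that("default reference configuration carries the published profiles", {
  cfg <- default_reference_config()
  expect_equal(cfg$profiles$PCA$freq_mean, 6.50)
  expect_equal(cfg$profiles$PCA$latency_sd, 0.54)
  expect_equal(cfg$profiles$CN$theme_p, 0.90)
  expect_equal(cfg$profiles$CN$cu_total_mean, 16.28)
  expect_equal(unname(cfg$n_per_group), c(25L, 29L))
  expect_equal(cfg$n_units, 32L)
})

test_that("feature cohorts are reproducible and converge to profile means", {
  cfg <- default_reference_config(seed = 101)
  a <- generate_feature_cohort(cfg)
  b <- generate_feature_cohort(cfg)
  expect_identical(a, b)  # seed-determined

  # degenerate profile (all sds zero) yields constant columns
  p0 <- group_profile(6, 0, 0.2, 0, 0.08, 0, 10, 0, 1, 0, 3, 0)
  cfg0 <- cohort_config(c(PCA = 5L, CN = 5L), list(PCA = p0, CN = p0),
                        seed = 3)
  f0 <- generate_feature_cohort(cfg0)
  expect_equal(unique(f0$mean_log_frequency), 6)
  expect_equal(unique(f0$mean_utterance_latency), 0.2)
  expect_equal(unique(f0$theme_mentioned), 1L)
  expect_equal(unique(f0$focus_mentioned), 0L)

  # law of large numbers at n = 2000: every feature mean within 2 SE of its
  # profile target (truncation is mean-calibrated, so targets are exact means)
  big <- cohort_config(c(PCA = 2000L, CN = 2000L),
                       default_reference_config()$profiles, seed = 59)
  fb <- generate_feature_cohort(big)
  for (g in c("PCA", "CN")) {
    p <- big$profiles[[g]]
    sub <- fb[fb$group == g, ]
    checks <- list(
      c(mean(sub$mean_log_frequency), p$freq_mean),
      c(mean(sub$mean_utterance_latency), p$latency_mean),
      c(mean(sub$relational_ratio), p$relational_mean),
      c(mean(sub$articulation_rate), p$articulation_mean),
      c(mean(sub$total_content_units), p$cu_total_mean),
      c(mean(sub$theme_mentioned), p$theme_p),
      c(mean(sub$focus_mentioned), p$focus_p)
    )
    ses <- c(sd(sub$mean_log_frequency), sd(sub$mean_utterance_latency),
             sd(sub$relational_ratio), sd(sub$articulation_rate),
             sd(sub$total_content_units), sd(sub$theme_mentioned),
             sd(sub$focus_mentioned)) / sqrt(nrow(sub))
    for (i in seq_along(checks)) {
      expect_lt(abs(checks[[i]][1] - checks[[i]][2]),
                2 * ses[i] + 0.02)  # rounding slack for the integer total
    }
  }
})

test_that("synthetic mention matrices hit mention probabilities and totals", {
  cfg <- cohort_config(c(PCA = 400L, CN = 400L),
                       default_reference_config()$profiles, seed = 67)
  mm <- generate_mention_matrix(cfg)
  expect_identical(dim(mm$mentions), c(800L, 32L))
  pca <- mm$mentions[mm$group == "PCA", ]
  cn <- mm$mentions[mm$group == "CN", ]
  # absolute Monte-Carlo bounds: 3 binomial SEs at n = 400, 3 SEs for totals
  expect_lt(abs(mean(pca[, "fisherman"]) - 0.08), 3 * sqrt(0.08 * 0.92 / 400))
  expect_lt(abs(mean(cn[, "fisherman"]) - 0.93), 3 * sqrt(0.93 * 0.07 / 400))
  expect_lt(abs(mean(rowSums(pca)) - 7.20), 3 * 5.63 / sqrt(400) + 0.1)
  expect_lt(abs(mean(rowSums(cn)) - 16.28), 3 * 4.41 / sqrt(400) + 0.1)
})

test_that("transcript generation embeds gold annotation and honors the seed", {
  cfg <- cohort_config(c(PCA = 3L, CN = 3L),
                       default_reference_config()$profiles, seed = 71)
  tc1 <- generate_transcript_cohort(cfg)
  tc2 <- generate_transcript_cohort(cfg)
  expect_identical(tc1, tc2)
  expect_length(tc1, 6L)
  s <- tc1[[1]]
  expect_false(anyNA(s$tokens$upos))
  expect_true(all(diff(s$tokens$start) >= 0))
  expect_true(all(s$tokens$end >= s$tokens$start))

  # a profile with the focus unit suppressed never mentions it
  prof <- default_reference_config()$profiles
  prof$PCA$focus_p <- 0
  prof$CN$focus_p <- 0
  cfg0 <- cohort_config(c(PCA = 10L, CN = 10L), prof, seed = 73)
  dict <- picnic_cu_dictionary()
  tc0 <- generate_transcript_cohort(cfg0)
  for (smp in tc0) {
    expect_false("fisherman" %in% detect_content_units(smp, dict))
  }

  # a dictionary smaller than n_units is rejected
  expect_error(generate_transcript_cohort(cfg, cu_dict = tiny_dict()),
               "4 units")
})

test_that("extraction on generated transcripts recovers the group profiles", {
  # moderate-n loop closure; the full-scale version runs in the acceptance suite
  cfg <- cohort_config(c(PCA = 60L, CN = 60L),
                       default_reference_config()$profiles, seed = 79)
  dict <- picnic_cu_dictionary()
  lex <- make_synthetic_lexicon(dict)
  feats <- extract_feature_table(generate_transcript_cohort(cfg, dict, lex),
                                 lex, dict)
  expect_equal(sum(feats$oov_count), 0L)
  cn <- feats[feats$group == "CN", ]
  pca <- feats[feats$group == "PCA", ]
  expect_lt(abs(mean(cn$mean_utterance_latency) - 0.03),
            3 * sd(cn$mean_utterance_latency) / sqrt(60) + 1e-3)
  expect_lt(abs(mean(pca$mean_log_frequency) - 6.50),
            3 * sd(pca$mean_log_frequency) / sqrt(60))
  expect_gt(mean(cn$total_content_units), mean(pca$total_content_units))
  expect_gt(mean(cn$focus_mentioned), mean(pca$focus_mentioned))
})

test_that("full-pipeline group differences keep the published signs", {
  dict <- picnic_cu_dictionary()
  lex <- make_synthetic_lexicon(dict)
  signs <- vapply(1:12, function(s) {
    cfg <- default_reference_config(seed = 1000 + s)
    feats <- extract_feature_table(generate_transcript_cohort(cfg, dict, lex),
                                   lex, dict)
    tab <- compare_groups(feats)
    c(freq = tab$t[tab$feature == "mean_log_frequency"] < 0,     # PCA higher
      lat = tab$t[tab$feature == "mean_utterance_latency"] < 0,  # PCA higher
      rel = tab$t[tab$feature == "relational_ratio"] > 0,        # PCA lower
      cu = tab$t[tab$feature == "total_content_units"] > 0)      # PCA lower
  }, logical(4))
  expect_gte(sum(signs["freq", ]), 11)
  expect_gte(sum(signs["lat", ]), 11)
  expect_gte(sum(signs["cu", ]), 11)
  # the relational effect is small (0.08 vs 0.09); require a majority only
  expect_gte(sum(signs["rel", ]), 7)
})
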
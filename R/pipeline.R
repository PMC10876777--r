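#' Recompute the reference-study statistics from their printed inputs
#'
#' Recomputes, from the group summaries and proportions bundled in
#' [default_reference_config()], the statistics a reader can derive from the
#' published tables of the reference picture-description study: the Welch t
#' for content-word log frequency and for content-unit totals, the
#' point-biserial r for the focus ("fisherman") unit from the printed mention
#' percentages, the Bonferroni threshold for 32 units, and the Welch degrees
#' of freedom for the theme ("picnic") mention comparison from counts derived
#' from the printed means. Each check is compared to the published value at
#' display precision (2 decimal places for t / r / df, 4 for the threshold).
#'
#' @return A tibble with columns `check`, `value`, `reference`, `tolerance`,
#'   `pass`.
#' @export
reproduce_reference_stats <- function() {
  cfg <- default_reference_config()
  pca <- cfg$profiles$PCA
  cn <- cfg$profiles$CN
  n1 <- cfg$n_per_group[["PCA"]]
  n2 <- cfg$n_per_group[["CN"]]

  w_freq <- welch_from_summaries(group_summary(pca$freq_mean, pca$freq_sd, n1),
                                 group_summary(cn$freq_mean, cn$freq_sd, n2))
  w_cu <- welch_from_summaries(
    group_summary(pca$cu_total_mean, pca$cu_total_sd, n1),
    group_summary(cn$cu_total_mean, cn$cu_total_sd, n2)
  )

  # binary vectors reconstructed from the printed mention probabilities
  focus_vals <- c(rep(1, round(pca$focus_p * n1)),
                  rep(0, n1 - round(pca$focus_p * n1)),
                  rep(1, round(cn$focus_p * n2)),
                  rep(0, n2 - round(cn$focus_p * n2)))
  grp <- rep(c(1, 0), c(n1, n2))
  pb_focus <- point_biserial(grp, focus_vals)

  theme_pca <- c(rep(1, round(pca$theme_p * n1)),
                 rep(0, n1 - round(pca$theme_p * n1)))
  theme_cn <- c(rep(1, round(cn$theme_p * n2)),
                rep(0, n2 - round(cn$theme_p * n2)))
  w_theme <- welch_from_vectors(theme_pca, theme_cn)

  thr <- bonferroni_threshold(0.05, cfg$n_units)

  checks <- tibble::tibble(
    check = c("welch_t_word_frequency", "welch_t_content_unit_totals",
              "focus_unit_point_biserial_r", "bonferroni_threshold",
              "welch_df_theme_mention"),
    value = c(round(w_freq$t, 2), round(w_cu$t, 2), round(pb_focus$r, 2),
              round(thr, 4), w_theme$df),
    reference = c(-5.02, 6.52, -0.85, 0.0016, 46.77),
    tolerance = c(0.005, 0.005, 0.005, 0.00005, 0.02)
  )
  checks$pass <- abs(checks$value - checks$reference) <= checks$tolerance
  checks
}

#' Run the full synthetic pipeline and write its artifacts
#'
#' Orchestrates every stage on a generated cohort: transcript synthesis,
#' feature extraction, the group comparison table, the content-unit mention
#' matrix and its Bonferroni-controlled screen, and the LOOCV diagnostic
#' classifier. All numeric artifacts are written under `out_dir` together
#' with a manifest recording the seed and configuration, so a rerun with the
#' same seed reproduces the outputs exactly.
#'
#' @param out_dir Output directory (created if needed).
#' @param config A [cohort_config()] (default [default_reference_config()]).
#' @param cu_dict Content-unit dictionary (default [picnic_cu_dictionary()]).
#' @param lexicon Frequency lexicon (default [make_synthetic_lexicon()]).
#' @param ridge Classifier penalty (default `1e-3`).
#' @param alpha Family-wise error rate for the unit screen (default 0.05).
#' @return Invisibly, a list with the in-memory results (`features`,
#'   `comparison`, `mentions`, `cu_screen`, `classification`) and `paths`.
#' @export
run_pipeline <- function(out_dir, config = default_reference_config(),
                         cu_dict = picnic_cu_dictionary(),
                         lexicon = make_synthetic_lexicon(cu_dict),
                         ridge = 1e-3, alpha = 0.05) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  samples <- stage("simulate", generate_transcript_cohort(config, cu_dict,
                                                          lexicon))
  features <- stage("extract",
                    extract_feature_table(samples, lexicon, cu_dict,
                                          focus_unit = config$focus_unit))
  comparison <- stage("compare", compare_groups(features))
  mm <- stage("content-units", mention_matrix(samples, cu_dict))
  screen <- stage("cu-screen", cu_group_screen(mm, alpha = alpha,
                                               m = config$n_units))
  report <- stage("classify", classify_cohort(features, ridge = ridge))

  paths <- list(
    features = file.path(out_dir, "features.csv"),
    comparison = file.path(out_dir, "comparison.csv"),
    mentions = file.path(out_dir, "mentions.csv"),
    cu_screen = file.path(out_dir, "cu_screen.csv"),
    classification = file.path(out_dir, "classification.json"),
    roc = file.path(out_dir, "roc.csv"),
    manifest = file.path(out_dir, "manifest.json")
  )
  write_feature_table(features, paths$features)
  write.csv(as.data.frame(comparison), paths$comparison, row.names = FALSE)
  write_mention_matrix(mm, paths$mentions)
  write.csv(as.data.frame(screen), paths$cu_screen, row.names = FALSE)
  jsonlite::write_json(
    list(accuracy = report$accuracy, precision = report$precision,
         recall = report$recall, auc = report$auc,
         confusion = as.list(report$confusion),
         per_fold = report$per_fold),
    paths$classification, auto_unbox = TRUE, digits = NA
  )
  write.csv(as.data.frame(report$roc_points), paths$roc, row.names = FALSE)
  jsonlite::write_json(
    list(package = "visiolex",
         version = as.character(utils::packageVersion("visiolex")),
         seed = config$seed,
         n_per_group = as.list(config$n_per_group),
         n_units = config$n_units, focus_unit = config$focus_unit,
         ridge = ridge, alpha = alpha),
    paths$manifest, auto_unbox = TRUE, digits = NA
  )
  invisible(list(features = features, comparison = comparison, mentions = mm,
                 cu_screen = screen, classification = report, paths = paths))
}
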
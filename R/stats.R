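#' Group summary statistics
#'
#' The printed form of a group's feature distribution: mean, sample standard
#' deviation (n-1 denominator) and group size, as in a "6.50 +/- 0.53,
#' n = 25" table cell.
#'
#' @param mean Group mean.
#' @param sd Sample standard deviation (>= 0).
#' @param n Group size (>= 2).
#' @return An object of class `group_summary`.
#' @export
group_summary <- function(mean, sd, n) {
  stopifnot(is.numeric(mean), length(mean) == 1L,
            is.numeric(sd), length(sd) == 1L, sd >= 0,
            is.numeric(n), length(n) == 1L, n >= 2)
  structure(list(mean = mean, sd = sd, n = as.integer(n)),
            class = "group_summary")
}

summarize_vector <- function(x) group_summary(mean(x), sd(x), length(x))

#' Welch two-sample t-test from summary statistics
#'
#' Computes the unequal-variance t statistic, Welch-Satterthwaite degrees of
#' freedom and two-sided p-value from group means, sample SDs and sizes —
#' i.e. directly from printed table cells, no raw data required.
#'
#' Sign convention: `t = (b$mean - a$mean) / SE`, with the patient group
#' passed first. The statistic is therefore negative when the first group's
#' mean is the higher one, matching the sign convention of standard two-group
#' feature tables (patients first, controls second).
#'
#' @param a,b [group_summary()] objects (or lists with `mean`, `sd`, `n`);
#'   `a` is the first (patient-style) group.
#' @return An object of class `welch_result`: list with `t`, `df`, `p`,
#'   `mean_diff` (`b - a`) and `direction`.
#' @export
welch_from_summaries <- function(a, b) {
  if (a$sd == 0 && b$sd == 0) {
    stop("degenerate input: both groups have zero standard deviation",
         call. = FALSE)
  }
  va <- a$sd^2 / a$n
  vb <- b$sd^2 / b$n
  se <- sqrt(va + vb)
  t <- (b$mean - a$mean) / se
  df <- (va + vb)^2 / (va^2 / (a$n - 1) + vb^2 / (b$n - 1))
  p <- 2 * pt(-abs(t), df)
  structure(
    list(t = t, df = df, p = p, mean_diff = b$mean - a$mean,
         direction = "second group minus first group"),
    class = "welch_result"
  )
}

#' @export
print.welch_result <- function(x, ...) {
  cat(sprintf("Welch two-sample t-test: t(%.2f) = %.2f, p = %.4g\n",
              x$df, x$t, x$p))
  invisible(x)
}

#' Welch two-sample t-test from raw vectors
#'
#' Identical to [welch_from_summaries()] applied to the vectors' exact means
#' and sample SDs; computed via [stats::t.test()] with `var.equal = FALSE`
#' and the same sign convention (second group minus first group).
#'
#' @param x Values of the first (patient-style) group, length >= 2.
#' @param y Values of the second (control-style) group, length >= 2.
#' @return A `welch_result` (see [welch_from_summaries()]).
#' @export
welch_from_vectors <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L) {
    stop("each group needs at least 2 observations", call. = FALSE)
  }
  ht <- t.test(y, x, var.equal = FALSE)
  structure(
    list(t = unname(ht$statistic), df = unname(ht$parameter),
         p = ht$p.value, mean_diff = mean(y) - mean(x),
         direction = "second group minus first group"),
    class = "welch_result"
  )
}

#' Point-biserial correlation
#'
#' Pearson correlation between a 0/1 group code and a quantitative variable
#' (for a binary variable this is the phi coefficient). Patients are coded 1
#' and controls 0, so negative r means patients are less likely / lower. The
#' two-sided p-value uses the t approximation
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom, as
#' implemented by [stats::cor.test()].
#'
#' @param group 0/1 vector (1 = patient).
#' @param values Numeric vector of the same length.
#' @return An object of class `point_biserial_result`: list with `r`, `p`,
#'   `n`, `df`.
#' @export
point_biserial <- function(group, values) {
  stopifnot(length(group) == length(values))
  if (length(unique(group)) < 2L) {
    stop("both groups must be represented in 'group'", call. = FALSE)
  }
  if (length(unique(values)) < 2L) {
    stop("'values' has zero variance; correlation undefined", call. = FALSE)
  }
  ct <- cor.test(values, as.numeric(group), method = "pearson")
  structure(
    list(r = unname(ct$estimate), p = ct$p.value, n = length(values),
         df = unname(ct$parameter)),
    class = "point_biserial_result"
  )
}

#' @export
print.point_biserial_result <- function(x, ...) {
  cat(sprintf("point-biserial: r = %.2f, p = %.4g (n = %d)\n", x$r, x$p, x$n))
  invisible(x)
}

#' Bonferroni significance threshold
#'
#' `alpha / m`, exactly; display rounding (e.g. 0.05/32 = 0.0015625 shown as
#' 0.0016 at 4 decimal places) is left to the caller.
#'
#' @param alpha Family-wise error rate, in (0, 1).
#' @param m Number of comparisons, >= 1.
#' @return `alpha / m`.
#' @export
bonferroni_threshold <- function(alpha, m) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    stop("alpha must be in (0, 1)", call. = FALSE)
  }
  if (!is.numeric(m) || length(m) != 1L || m < 1 || m != round(m)) {
    stop("m must be a positive integer", call. = FALSE)
  }
  alpha / m
}

#' Point-biserial screen of content-unit mentions
#'
#' Correlates each content unit's 0/1 mention indicator with the group code
#' (patients = 1) and flags units significant under Bonferroni control.
#' Units mentioned by everyone or by no one have zero variance; they are
#' flagged untestable rather than erroring. By default the Bonferroni divisor
#' is the total number of dictionary units (including untestable ones), the
#' convention that yields the familiar 0.05/32 = 0.0016 threshold; pass `m`
#' to override.
#'
#' @param mm A [mention_matrix()].
#' @param positive Group label coded 1 (default `"PCA"`).
#' @param alpha Family-wise error rate (default 0.05).
#' @param m Bonferroni divisor; default `ncol(mm$mentions)`.
#' @return A tibble with one row per unit: `unit`, `r`, `p`, `testable`,
#'   `significant`, plus per-group mention proportions. The threshold used is
#'   attached as attribute `"threshold"`.
#' @export
cu_group_screen <- function(mm, positive = "PCA", alpha = 0.05, m = NULL) {
  mat <- mm$mentions
  g <- as.integer(mm$group == positive)
  if (length(unique(g)) < 2L || min(table(g)) < 2L) {
    stop("need at least 2 participants per group", call. = FALSE)
  }
  m <- m %||% ncol(mat)
  thr <- bonferroni_threshold(alpha, m)
  res <- lapply(colnames(mat), function(u) {
    v <- mat[, u]
    testable <- length(unique(v)) > 1L
    if (testable) {
      pb <- point_biserial(g, v)
      list(unit = u, r = pb$r, p = pb$p, testable = TRUE,
           significant = pb$p < thr)
    } else {
      list(unit = u, r = NA_real_, p = NA_real_, testable = FALSE,
           significant = FALSE)
    }
  })
  out <- tibble::tibble(
    unit = vapply(res, `[[`, character(1L), "unit"),
    r = vapply(res, `[[`, numeric(1L), "r"),
    p = vapply(res, `[[`, numeric(1L), "p"),
    testable = vapply(res, `[[`, logical(1L), "testable"),
    significant = vapply(res, `[[`, logical(1L), "significant"),
    prop_positive = colMeans(mat[g == 1L, , drop = FALSE]),
    prop_control = colMeans(mat[g == 0L, , drop = FALSE])
  )
  attr(out, "threshold") <- thr
  out
}

#' Welch comparisons of all features across groups
#'
#' Produces a per-feature comparison table in the layout of a two-group
#' feature table: group means +/- SD and the Welch t, df and p for each
#' numeric feature, with the patient group passed first (so t is negative
#' when patients score higher).
#'
#' @param features Feature table ([extract_feature_table()] or
#'   [generate_feature_cohort()]).
#' @param first Group label treated as the first (patient) group.
#' @param columns Feature columns to compare; defaults to all numeric
#'   feature columns present.
#' @return A tibble with one row per feature.
#' @export
compare_groups <- function(features, first = "PCA", columns = NULL) {
  default_cols <- c("mean_log_frequency", "mean_utterance_latency",
                    "articulation_rate", "relational_ratio",
                    "total_content_units", "theme_mentioned",
                    "focus_mentioned")
  columns <- columns %||% intersect(default_cols, names(features))
  g1 <- features$group == first
  rows <- lapply(columns, function(col) {
    x <- features[[col]][g1]
    y <- features[[col]][!g1]
    x <- x[!is.na(x)]
    y <- y[!is.na(y)]
    w <- welch_from_vectors(x, y)
    tibble::tibble(
      feature = col,
      mean_1 = mean(x), sd_1 = sd(x), n_1 = length(x),
      mean_2 = mean(y), sd_2 = sd(y), n_2 = length(y),
      t = w$t, df = w$df, p = w$p
    )
  })
  do.call(rbind, rows)
}
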
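#' Fit a ridge-penalized logistic regression
#'
#' Maximizes the penalized log-likelihood
#' `sum(y * log(p) + (1 - y) * log(1 - p)) - ridge/2 * sum(beta^2)` (intercept
#' unpenalized) by Newton iterations with step halving. With any positive
#' ridge the problem is strictly concave, so the fit is deterministic given
#' the inputs and exists even for perfectly separated data — the situation a
#' near-perfect diagnostic feature set produces, where unpenalized maximum
#' likelihood diverges. The default penalty is small enough to perturb
#' non-separable fits negligibly when predictors are standardized.
#'
#' @param X Numeric predictor matrix (no missing values); column names are
#'   kept for coefficient names.
#' @param y 0/1 response vector with both classes present.
#' @param ridge Nonnegative penalty (default `1e-3`).
#' @param max_iter Maximum Newton iterations.
#' @param tol Convergence tolerance on the coefficient step.
#' @return An object of class `logistic_fit`: list with `intercept`,
#'   `coefficients` (named), `ridge`, `iterations`, `converged`.
#' @export
fit_logistic <- function(X, y, ridge = 1e-3, max_iter = 200L, tol = 1e-10) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  stopifnot(nrow(X) == length(y), all(y %in% c(0, 1)), ridge >= 0)
  if (anyNA(X)) stop("missing predictor values", call. = FALSE)
  if (length(unique(y)) < 2L) {
    stop("both classes must be present in y", call. = FALSE)
  }
  Z <- cbind(`(Intercept)` = 1, X)
  p <- ncol(Z)
  pen <- c(0, rep(ridge, p - 1L))
  beta <- numeric(p)
  obj <- function(b) {
    eta <- drop(Z %*% b)
    sum(y * eta - log1p(exp(eta))) - sum(pen * b^2) / 2
  }
  f_old <- obj(beta)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    eta <- drop(Z %*% beta)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-12)
    grad <- drop(crossprod(Z, y - mu)) - pen * beta
    H <- crossprod(Z * w, Z) + diag(pen, p)
    step <- tryCatch(solve(H, grad), error = function(e) {
      stop("singular Hessian in logistic fit (ridge = ", ridge, ")",
           call. = FALSE)
    })
    # step halving keeps Newton monotone far from the optimum
    lambda <- 1
    repeat {
      cand <- beta + lambda * step
      f_new <- obj(cand)
      if (is.finite(f_new) && f_new >= f_old - 1e-12) break
      lambda <- lambda / 2
      if (lambda < 1e-10) break
    }
    beta <- beta + lambda * step
    f_old <- obj(beta)
    if (max(abs(lambda * step)) < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    stop("logistic fit did not converge in ", max_iter,
         " iterations (ridge = ", ridge, ")", call. = FALSE)
  }
  cf <- beta[-1L]
  names(cf) <- colnames(X) %||% paste0("x", seq_along(cf))
  structure(
    list(intercept = beta[1L], coefficients = cf, ridge = ridge,
         iterations = iter, converged = converged),
    class = "logistic_fit"
  )
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("<logistic_fit> ridge = %g, %d iterations\n", x$ridge,
              x$iterations))
  print(c(`(Intercept)` = x$intercept, x$coefficients))
  invisible(x)
}

#' Predicted probabilities from a logistic fit
#'
#' @param fit A [fit_logistic()] result.
#' @param X Predictor matrix with the same columns as the training matrix.
#' @return Vector of predicted probabilities of class 1.
#' @export
predict_logistic <- function(fit, X) {
  X <- as.matrix(X)
  plogis(drop(fit$intercept + X %*% fit$coefficients))
}

standardize_fit <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2L, sd)
  scl[scl == 0 | is.na(scl)] <- 1
  list(center = ctr, scale = scl)
}

standardize_apply <- function(X, st) {
  sweep(sweep(X, 2L, st$center, "-"), 2L, st$scale, "/")
}

#' Leave-one-out cross-validated logistic classification
#'
#' Fits the ridge-penalized logistic model n times, each time holding out one
#' observation, and pools the held-out predicted probabilities. Predictors
#' are standardized within each training fold (the held-out row is
#' transformed with the training fold's centers and scales), binary
#' predictors included. Labels use a fixed 0.5 probability threshold.
#' Accuracy, precision and recall are pooled over folds with class 1 (the
#' patient group) positive; the ROC curve and AUC are computed on the pooled
#' held-out probabilities.
#'
#' @param X Predictor matrix, n >= 4 rows.
#' @param y 0/1 labels, both classes with at least 2 members.
#' @param ridge Nonnegative penalty passed to [fit_logistic()].
#' @param ids Optional row identifiers for the per-fold report.
#' @return An object of class `classification_report`: list with `per_fold`
#'   (tibble: id, truth, probability, prediction), `accuracy`, `precision`,
#'   `recall`, `auc`, `roc_points`, `confusion`.
#' @export
loocv <- function(X, y, ridge = 1e-3, ids = NULL) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  stopifnot(n >= 4L, length(y) == n)
  if (min(table(y)) < 2L) {
    stop("each class needs at least 2 members for LOOCV", call. = FALSE)
  }
  ids <- ids %||% paste0("obs", seq_len(n))
  prob <- numeric(n)
  for (i in seq_len(n)) {
    Xtr <- X[-i, , drop = FALSE]
    ytr <- y[-i]
    if (length(unique(ytr)) < 2L) {
      stop("training fold ", i, " contains a single class", call. = FALSE)
    }
    st <- standardize_fit(Xtr)
    fit <- fit_logistic(standardize_apply(Xtr, st), ytr, ridge = ridge)
    prob[i] <- predict_logistic(fit, standardize_apply(X[i, , drop = FALSE], st))
  }
  pred <- as.integer(prob >= 0.5)
  tp <- sum(pred == 1L & y == 1)
  fp <- sum(pred == 1L & y == 0)
  fn <- sum(pred == 0L & y == 1)
  tn <- sum(pred == 0L & y == 0)
  roc <- roc_auc(prob, y)
  structure(
    list(
      per_fold = tibble::tibble(id = ids, truth = as.integer(y),
                                probability = prob, prediction = pred),
      accuracy = mean(pred == y),
      precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
      recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
      auc = roc$auc,
      roc_points = roc$roc_points,
      confusion = c(tp = tp, fp = fp, fn = fn, tn = tn),
      ridge = ridge
    ),
    class = "classification_report"
  )
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf(paste0("<classification_report> n = %d folds\n",
                     "  accuracy %.4f, precision %.4f, recall %.4f, AUC %.4f\n"),
              nrow(x$per_fold), x$accuracy, x$precision, x$recall, x$auc))
  invisible(x)
}

#' ROC curve and AUC
#'
#' AUC is the pairwise concordance probability: the fraction of
#' (positive, negative) pairs where the positive case received the higher
#' probability, ties counted 1/2 — equivalently the rank-sum (Mann-Whitney)
#' statistic. ROC points come from a threshold sweep over the unique
#' probabilities. Both are invariant under strictly monotone transforms of
#' the probabilities.
#'
#' @param probabilities Predicted probabilities (or any monotone scores).
#' @param labels 0/1 labels, both classes present.
#' @return List with `auc` and `roc_points` (tibble of `fpr`, `tpr` from
#'   (0,0) to (1,1)).
#' @export
roc_auc <- function(probabilities, labels) {
  labels <- as.numeric(labels)
  stopifnot(length(probabilities) == length(labels))
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0L || n0 == 0L) {
    stop("both classes must be present to compute a ROC curve", call. = FALSE)
  }
  r <- rank(probabilities)  # average ranks handle ties as 1/2 concordance
  auc <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thresholds <- c(Inf, sort(unique(probabilities), decreasing = TRUE))
  pts <- vapply(thresholds, function(th) {
    pred <- probabilities >= th
    c(fpr = sum(pred & labels == 0) / n0, tpr = sum(pred & labels == 1) / n1)
  }, numeric(2L))
  list(auc = auc,
       roc_points = tibble::tibble(fpr = pts["fpr", ], tpr = pts["tpr", ]))
}

#' Refit the LOOCV classifier without one predictor
#'
#' Ablation analysis: drops a named predictor column and reruns
#' [loocv()] on the reduced matrix, to measure how much of the
#' classification performance that predictor carries.
#'
#' @param X Predictor matrix with column names.
#' @param y 0/1 labels.
#' @param drop Name of the predictor to remove.
#' @param ridge Penalty passed through to [loocv()].
#' @param ids Optional row identifiers.
#' @return A `classification_report` for the reduced model.
#' @export
ablate <- function(X, y, drop, ridge = 1e-3, ids = NULL) {
  X <- as.matrix(X)
  if (!drop %in% colnames(X)) {
    stop("unknown predictor '", drop, "'; available: ",
         paste(colnames(X), collapse = ", "), call. = FALSE)
  }
  loocv(X[, setdiff(colnames(X), drop), drop = FALSE], y, ridge = ridge,
        ids = ids)
}

#' Default predictor columns for the diagnostic classifier
#'
#' The six predictors of the picture-description diagnostic model: content-
#' word log frequency, mean utterance latency, relational word ratio, total
#' content units, and the theme ("picnic") and focus ("fisherman") mention
#' indicators.
#'
#' @return Character vector of feature-table column names.
#' @export
classifier_predictors <- function() {
  c("mean_log_frequency", "mean_utterance_latency", "relational_ratio",
    "total_content_units", "theme_mentioned", "focus_mentioned")
}

#' Run the diagnostic classifier on a feature table
#'
#' Convenience wrapper: selects the predictor columns, codes the group
#' (patients = 1), and runs [loocv()].
#'
#' @param features Feature table with a `group` column.
#' @param predictors Predictor column names (default
#'   [classifier_predictors()]).
#' @param positive Group label coded 1 (default `"PCA"`).
#' @param ridge Penalty (default `1e-3`).
#' @return A `classification_report`.
#' @export
classify_cohort <- function(features, predictors = classifier_predictors(),
                            positive = "PCA", ridge = 1e-3) {
  missing_cols <- setdiff(predictors, names(features))
  if (length(missing_cols)) {
    stop("feature table lacks predictor column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  X <- as.matrix(features[predictors])
  y <- as.integer(features$group == positive)
  loocv(X, y, ridge = ridge, ids = features$participant_id)
}
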
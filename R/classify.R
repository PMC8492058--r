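## Discriminative models over sequence features: an L2 logistic regression
## on predicted-occupancy features (C chosen on a 10^-4..10^4 grid by mean
## cross-validated F1), a linear SVM on canonical 6-mer counts, and a
## random-motif null distribution with a one-tailed Z-test. All models are
## evaluated by stratified k-fold cross-validation after shuffling with the
## configured seed, reporting AUROC and AUPR as mean +/- sd across folds.

C_GRID <- 10^seq(-4, 4)

## Stratified fold assignment: within each class the (shuffled) members are
## dealt round-robin, so per-fold class counts differ by at most one.
stratified_folds <- function(labels, k, seed) {
  with_seed(seed, {
    fold <- integer(length(labels))
    for (cls in unique(labels)) {
      idx <- sample(which(labels == cls))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    fold
  })
}

auroc <- function(labels, scores, positive) {
  r <- pROC::roc(
    response = labels == positive, predictor = scores,
    levels = c(FALSE, TRUE), direction = "<", quiet = TRUE
  )
  as.numeric(pROC::auc(r))
}

## Average-precision AUPR: precision at each positive, weighted by the
## recall step.
aupr <- function(labels, scores, positive) {
  ord <- order(scores, decreasing = TRUE)
  y <- (labels == positive)[ord]
  tp <- cumsum(y)
  precision <- tp / seq_along(y)
  recall <- tp / sum(y)
  sum(precision * diff(c(0, recall)))
}

f1_score <- function(labels, predicted, positive) {
  tp <- sum(predicted & labels == positive)
  fp <- sum(predicted & labels != positive)
  fn <- sum(!predicted & labels == positive)
  if (tp == 0) return(0)
  2 * tp / (2 * tp + fp + fn)
}

standardize_train_test <- function(x_train, x_test) {
  mu <- colMeans(x_train)
  sdev <- apply(x_train, 2, sd)
  sdev[sdev == 0] <- 1
  list(
    train = scale(x_train, center = mu, scale = sdev),
    test = scale(x_test, center = mu, scale = sdev)
  )
}

ridge_logistic <- function(x, y01, C) {
  ## glmnet's penalized deviance (1/n) sum loss + lambda ||b||^2 / 2 matches
  ## the sklearn objective sum loss + ||b||^2 / (2 C) at lambda = 1/(n C).
  ## glmnet needs >= 2 columns; a zero column is appended for single-feature
  ## models (it gets coefficient 0 and leaves predictions untouched).
  if (ncol(x) == 1) x <- cbind(x, .dummy = 0)
  glmnet::glmnet(x, y01,
    family = "binomial", alpha = 0,
    lambda = 1 / (nrow(x) * C), standardize = FALSE
  )
}

predict_ridge <- function(fit, x) {
  if (ncol(x) == 1) x <- cbind(x, .dummy = 0)
  as.numeric(predict(fit, newx = as.matrix(x), type = "response"))
}

as_feature_matrix <- function(features) {
  if (is.data.frame(features)) {
    features <- features[, setdiff(names(features), c("id", "total")), drop = FALSE]
    features <- as.matrix(features)
  }
  storage.mode(features) <- "double"
  features
}

cv_metrics <- function(x, labels, fold, positive, C) {
  purrr::map_dfr(sort(unique(fold)), function(f) {
    st <- standardize_train_test(x[fold != f, , drop = FALSE],
      x[fold == f, , drop = FALSE])
    fit <- ridge_logistic(st$train, labels[fold != f] == positive, C)
    prob <- predict_ridge(fit, st$test)
    truth <- labels[fold == f]
    tibble(
      fold = f,
      auroc = auroc(truth, prob, positive),
      aupr = aupr(truth, prob, positive),
      f1 = f1_score(truth, prob > 0.5, positive)
    )
  })
}

#' L2 logistic regression on occupancy (or other tabular) features
#'
#' Selects the regularization parameter C on the grid `10^-4 .. 10^4` by
#' mean F1 over stratified cross-validation folds (unless `C` is supplied,
#' e.g. to reuse the value chosen on a reference feature set), then reports
#' fold-wise AUROC and AUPR. Features are standardized on each training
#' fold. The final coefficients come from a fit on all data at the chosen C.
#'
#' @param features An [occupancy_profile()] tibble (the `id`/`total` columns
#'   are dropped) or a numeric matrix, rows aligned with `labels`.
#' @param labels A vector with exactly two distinct values.
#' @param config An [mpra_config()]; supplies `cv_folds` and `seed`.
#' @param positive The label value treated as the positive class (default:
#'   the larger of the two, so `TRUE`, or the later factor level).
#' @param C Optional fixed regularization parameter.
#' @return An object of class `"mpra_classifier"`: list with `cv` (fold
#'   metrics), `auroc`/`aupr` (mean), `auroc_sd`/`aupr_sd`, `C`, `grid`,
#'   `coefficients`, `positive`.
#' @export
fit_occupancy_logistic <- function(features, labels, config = mpra_config(),
                                   positive = NULL, C = NULL) {
  x <- as_feature_matrix(features)
  labels <- as.character(labels)
  if (length(unique(labels)) != 2) {
    abort("labels must contain exactly two classes", class = "mpraic_fit_error")
  }
  positive <- positive %||% max(unique(labels))
  fold <- stratified_folds(labels, config$cv_folds, config$seed)

  grid <- NULL
  if (is.null(C)) {
    grid <- purrr::map_dfr(C_GRID, function(cc) {
      m <- cv_metrics(x, labels, fold, positive, cc)
      tibble(C = cc, mean_f1 = mean(m$f1))
    })
    C <- grid$C[which.max(grid$mean_f1)]
  }
  cv <- cv_metrics(x, labels, fold, positive, C)

  st <- standardize_train_test(x, x)
  final <- ridge_logistic(st$train, labels == positive, C)
  coefs <- as.numeric(stats::coef(final))
  names(coefs) <- rownames(stats::coef(final))
  coefs <- coefs[names(coefs) != ".dummy"]

  structure(
    list(
      model = "logistic", cv = cv,
      auroc = mean(cv$auroc), auroc_sd = sd(cv$auroc),
      aupr = mean(cv$aupr), aupr_sd = sd(cv$aupr),
      C = C, grid = grid, coefficients = coefs,
      positive = positive, folds = fold
    ),
    class = "mpra_classifier"
  )
}

#' @export
print.mpra_classifier <- function(x, ...) {
  cat(sprintf(
    "<mpra_classifier: %s> AUROC %.3f +/- %.3f, AUPR %.3f +/- %.3f (C = %g)\n",
    x$model, x$auroc, x$auroc_sd, x$aupr, x$aupr_sd, x$C
  ))
  invisible(x)
}

#' Linear SVM on canonical 6-mer spectrum features
#'
#' A support-vector classifier on reverse-complement-collapsed k-mer counts
#' (2080 features at k = 6), evaluated with the same shuffled stratified
#' cross-validation protocol as the logistic models. Per-feature weights of
#' the final all-data fit are exposed for inspection.
#'
#' @param sequences A tibble with `id`/`sequence` columns or a character
#'   vector, aligned with `labels`.
#' @param labels A vector with exactly two distinct values.
#' @param config An [mpra_config()].
#' @param k k-mer length (default 6).
#' @param positive Positive class label (default: the larger value).
#' @param cost SVM cost parameter.
#' @return An `"mpra_classifier"` with `model = "svm"` and a `weights`
#'   vector named by canonical k-mer.
#' @export
fit_spectrum_svm <- function(sequences, labels, config = mpra_config(),
                             k = 6, positive = NULL, cost = 1) {
  x <- kmer_features(sequences, k = k)
  labels <- as.character(labels)
  if (length(unique(labels)) != 2) {
    abort("labels must contain exactly two classes", class = "mpraic_fit_error")
  }
  positive <- positive %||% max(unique(labels))
  fold <- stratified_folds(labels, config$cv_folds, config$seed)

  svm_scores <- function(train_idx, test_idx) {
    y <- factor(labels[train_idx] == positive, levels = c(FALSE, TRUE))
    fit <- e1071::svm(x[train_idx, , drop = FALSE], y,
      kernel = "linear", cost = cost, scale = FALSE
    )
    dv <- attr(
      predict(fit, x[test_idx, , drop = FALSE], decision.values = TRUE),
      "decision.values"
    )
    ## decision values are oriented toward the first class named in the
    ## "a/b" column label; flip so larger score = positive class
    oriented <- if (startsWith(colnames(dv)[1], "TRUE")) dv[, 1] else -dv[, 1]
    list(fit = fit, scores = oriented)
  }

  cv <- purrr::map_dfr(sort(unique(fold)), function(f) {
    sc <- svm_scores(which(fold != f), which(fold == f))
    truth <- labels[fold == f]
    tibble(
      fold = f,
      auroc = auroc(truth, sc$scores, positive),
      aupr = aupr(truth, sc$scores, positive)
    )
  })
  full <- svm_scores(seq_along(labels), seq_along(labels))
  w <- drop(t(full$fit$coefs) %*% full$fit$SV)
  if (!startsWith(colnames(full$fit$decision.values)[1], "TRUE")) w <- -w

  structure(
    list(
      model = "svm", cv = cv,
      auroc = mean(cv$auroc), auroc_sd = sd(cv$auroc),
      aupr = mean(cv$aupr), aupr_sd = sd(cv$aupr),
      C = cost, grid = NULL,
      coefficients = NULL, weights = w,
      positive = positive, folds = fold
    ),
    class = "mpra_classifier"
  )
}

#' Null model-performance distribution from random motif draws
#'
#' Repeatedly samples `n_tfs` motifs from a pool (without replacement within
#' a draw), recomputes occupancy features for the sequence set, refits the
#' logistic model at a fixed C, and records the cross-validated mean AUROC
#' and AUPR — the background against which the curated panel is judged.
#'
#' @param pwm_pool Named list of [motif_model()]s to draw from.
#' @param sequences Sequence tibble or character vector.
#' @param labels Two-class label vector aligned with `sequences`.
#' @param n_draws Number of draws (default 100).
#' @param n_tfs Motifs per draw (default 8).
#' @param config An [mpra_config()]; `config$seed` makes draws reproducible.
#' @param C Regularization strength reused from the curated-panel model.
#' @return A tibble with `draw`, `auroc`, `aupr` and the drawn TF names.
#' @export
null_feature_distribution <- function(pwm_pool, sequences, labels,
                                      n_draws = 100, n_tfs = 8,
                                      config = mpra_config(), C = 0.01) {
  if (length(pwm_pool) < n_tfs) {
    abort("motif pool smaller than n_tfs", class = "mpraic_parameter_error")
  }
  if (n_draws < 1) {
    abort("n_draws must be >= 1", class = "mpraic_parameter_error")
  }
  draws <- with_seed(config$seed, {
    lapply(seq_len(n_draws), function(i) sample(names(pwm_pool), n_tfs))
  })
  purrr::imap_dfr(draws, function(tfs, i) {
    occ <- occupancy_profile(sequences, pwm_pool[tfs], config)
    fit <- fit_occupancy_logistic(occ, labels, config, C = C)
    tibble(
      draw = i, auroc = fit$auroc, aupr = fit$aupr,
      tfs = paste(tfs, collapse = ",")
    )
  })
}

#' One-tailed Z-test of an observed statistic against a null sample
#'
#' @param observed Observed statistic (e.g. mean AUROC of the curated panel).
#' @param null_samples Numeric vector of null statistics.
#' @param tail `"upper"` (is the observed larger than the null?) or
#'   `"lower"`.
#' @return A one-row tibble with `z` and `p_value`.
#' @export
z_test_vs_null <- function(observed, null_samples, tail = c("upper", "lower")) {
  tail <- match.arg(tail)
  s <- sd(null_samples)
  if (!is.finite(s) || s == 0) {
    abort("null distribution has zero spread", class = "mpraic_fit_error")
  }
  z <- (observed - mean(null_samples)) / s
  p <- if (tail == "upper") 1 - pnorm(z) else pnorm(z)
  tibble(z = z, p_value = p)
}
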
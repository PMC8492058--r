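test_that("canonical k-mers collapse reverse complements", {
  expect_equal(canonical_kmers(1), c("A", "C"))
  expect_equal(length(canonical_kmers(2)), 10) # (16 + 4) / 2
  expect_equal(length(canonical_kmers(6)), 2080)
  ## every representative is the lexicographic minimum of its pair
  k3 <- canonical_kmers(3)
  expect_true(all(k3 <= reverse_complement(k3)))
})

test_that("k-mer features conserve window counts and collapse strands", {
  x <- kmer_features(c(s = "AAAAAA"), k = 6)
  expect_equal(sum(x), 1)
  expect_equal(unname(x[1, "AAAAAA"]), 1)

  set.seed(61)
  seqs <- vapply(1:20, function(i) random_seq(164), character(1))
  feats <- kmer_features(stats::setNames(seqs, paste0("s", 1:20)), k = 6)
  expect_equal(unname(rowSums(feats)), rep(159, 20))
  rc <- kmer_features(stats::setNames(
    reverse_complement(seqs), paste0("s", 1:20)), k = 6)
  expect_equal(unname(feats), unname(rc))
  expect_error(kmer_features(c(s = "ACG"), k = 6), class = "mpraic_input_error")
})

test_that("logistic model separates separable features and stratifies folds", {
  set.seed(62)
  n <- 120
  labels <- rep(c("neg", "pos"), c(45, 75))
  x <- cbind(f1 = ifelse(labels == "pos", 5, 0) + rnorm(n, 0, 0.2),
    f2 = rnorm(n))
  fit <- fit_occupancy_logistic(x, labels, mpra_config(seed = 3))
  expect_equal(fit$cv$auroc, rep(1, 5))
  expect_equal(fit$positive, "pos")
  expect_gt(fit$coefficients["f1"], 0)

  ## class proportions per fold within one sequence of global proportions
  per_fold <- table(fit$folds, labels)
  expect_lte(diff(range(per_fold[, "pos"])), 1)
  expect_lte(diff(range(per_fold[, "neg"])), 1)

  expect_error(fit_occupancy_logistic(x, rep("pos", n)),
    class = "mpraic_fit_error"
  )
})

test_that("shuffled labels drive the logistic model to chance", {
  set.seed(63)
  n <- 1000
  x <- matrix(rnorm(n * 4), ncol = 4,
    dimnames = list(NULL, paste0("f", 1:4)))
  labels <- sample(rep(c("a", "b"), n / 2))
  fit <- fit_occupancy_logistic(x, labels, mpra_config(seed = 4), C = 0.01)
  expect_lt(abs(fit$auroc - 0.5), 0.05)
})

test_that("single-feature models fit (information-content classifier)", {
  set.seed(64)
  bits <- c(rnorm(80, 2.4, 0.5), rnorm(80, 1.6, 0.5))
  labels <- rep(c("strong_enhancer", "silencer"), each = 80)
  fit <- fit_occupancy_logistic(cbind(bits = bits), labels,
    mpra_config(seed = 5),
    positive = "strong_enhancer", C = 0.01
  )
  expect_gt(fit$auroc, 0.75)
  expect_equal(names(fit$coefficients), c("(Intercept)", "bits"))
})

test_that("spectrum SVM finds a planted discriminative 6-mer", {
  set.seed(65)
  n <- 80
  has_planted <- function(s) {
    grepl("ACGTAC", s, fixed = TRUE) || grepl("GTACGT", s, fixed = TRUE)
  }
  neg <- vapply(1:n, function(i) {
    repeat {
      s <- random_seq(60)
      if (!has_planted(s)) return(s)
    }
  }, character(1))
  pos <- vapply(1:n, function(i) {
    s <- random_seq(60)
    p <- sample(54, 1)
    paste0(substr(s, 1, p - 1), "ACGTAC", substr(s, p + 6, 60))
  }, character(1))
  seqs <- stats::setNames(c(neg, pos), paste0("s", 1:(2 * n)))
  labels <- rep(c("silencer", "strong_enhancer"), each = n)
  fit <- fit_spectrum_svm(seqs, labels, mpra_config(seed = 6),
    positive = "strong_enhancer"
  )
  expect_equal(fit$cv$auroc, rep(1, 5))
  top <- tidy(fit)$term[1]
  expect_equal(top, min("ACGTAC", reverse_complement("ACGTAC")))
  expect_gt(tidy(fit)$weight[1], 0)

  ## reverse-complementing every sequence changes nothing (canonical features)
  fit_rc <- fit_spectrum_svm(
    stats::setNames(reverse_complement(seqs), names(seqs)),
    labels, mpra_config(seed = 6), positive = "strong_enhancer"
  )
  expect_equal(fit_rc$cv$auroc, fit$cv$auroc)
  expect_equal(glance(fit_rc)$aupr, glance(fit)$aupr)
})

test_that("the random-motif null distribution is reproducible and honest", {
  set.seed(66)
  pool <- make_toy_pwms(6, width = 6, sharpness = 0.9, seed = 7)
  seqs <- stats::setNames(
    vapply(1:100, function(i) random_seq(80), character(1)), paste0("s", 1:100)
  )
  labels <- rep(c("a", "b"), 50)
  cfg <- mpra_config(seed = 8, cv_folds = 3)
  null1 <- null_feature_distribution(pool, seqs, labels,
    n_draws = 3, n_tfs = 4, config = cfg
  )
  null2 <- null_feature_distribution(pool, seqs, labels,
    n_draws = 3, n_tfs = 4, config = cfg
  )
  expect_identical(null1, null2)
  expect_equal(nrow(null1), 3)
  ## random labels: null centred near chance (few draws, so a loose band)
  expect_lt(abs(mean(null1$auroc) - 0.5), 0.2)

  ## degenerate pool: the draw is forced, so the null equals the observed fit
  forced <- null_feature_distribution(pool[1:4], seqs, labels,
    n_draws = 1, n_tfs = 4, config = cfg
  )
  occ <- occupancy_profile(seqs, pool[forced$tfs |>
    strsplit(",") |> unlist()], cfg)
  obs <- fit_occupancy_logistic(occ, labels, cfg, C = 0.01)
  expect_equal(forced$auroc, obs$auroc)

  expect_error(
    null_feature_distribution(pool, seqs, labels, n_draws = 2, n_tfs = 10),
    class = "mpraic_parameter_error"
  )
})

test_that("Z-test against the null behaves like a one-tailed normal test", {
  null <- c(0.48, 0.5, 0.52, 0.49, 0.51)
  expect_equal(z_test_vs_null(mean(null), null)$p_value, 0.5)
  z <- z_test_vs_null(mean(null) + 1.645 * sd(null), null)
  expect_equal(z$z, 1.645)
  expect_equal(z$p_value, 1 - pnorm(1.645))
  expect_gt(z_test_vs_null(mean(null) - 0.1, null, tail = "upper")$p_value, 0.5)
  expect_equal(
    z_test_vs_null(0.6, null, tail = "lower")$p_value,
    pnorm(z_test_vs_null(0.6, null)$z)
  )
  expect_error(z_test_vs_null(0.6, rep(0.5, 5)), class = "mpraic_fit_error")
})

test_that("tidiers and plots return well-formed objects", {
  set.seed(67)
  x <- cbind(a = rnorm(60), b = rnorm(60))
  labels <- rep(c("x", "y"), 30)
  fit <- fit_occupancy_logistic(x, labels, mpra_config(seed = 9), C = 1)
  expect_named(glance(fit),
    c("model", "auroc", "auroc_sd", "aupr", "aupr_sd", "C", "n_folds"))
  expect_s3_class(tidy(fit), "tbl_df")
  expect_s3_class(autoplot(fit), "ggplot")

  calls <- tibble::tibble(
    construct = c("a", "b"), activity = c(2.5, 0.4),
    log2_activity = log2(c(2.5, 0.4)), q_value = c(0.01, 0.02),
    class = factor(c("strong_enhancer", "silencer"),
      levels = c("strong_enhancer", "weak_enhancer", "inactive",
        "silencer", "ambiguous"))
  )
  expect_s3_class(plot_activity_volcano(calls), "ggplot")
  expect_s3_class(plot_class_fractions(calls), "ggplot")
  expect_s3_class(
    plot_information_content(tibble::tibble(bits = c(1, 2), class = calls$class)),
    "ggplot"
  )
})
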
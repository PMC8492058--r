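test_that("rho-mode barcode filters apply the raw-count floors", {
  ## DNA = 9 -> removed entirely
  tab <- toy_counts(dna = c(9, 100, 100, 100))
  out <- filter_barcodes(tab, "rho")
  expect_false("b1" %in% out$barcode)
  expect_true(all(c("b2", "b3", "b4") %in% out$barcode))

  ## cDNA (4, 100, 100) -> zeroed in all three replicates
  cdna <- matrix(100, 4, 3)
  cdna[1, 1] <- 4
  out <- filter_barcodes(toy_counts(cdna = cdna), "rho")
  b1 <- out[out$barcode == "b1" & out$sample_type == "cDNA", ]
  expect_equal(b1$count, c(0, 0, 0))
  expect_equal(out$count[out$barcode == "b1" & out$sample == "DNA"], 100)

  ## boundary: DNA = 10 and all cDNA >= 5 pass untouched
  cdna <- matrix(5, 4, 3)
  out <- filter_barcodes(toy_counts(dna = rep(10, 4), cdna = cdna), "rho")
  expect_equal(sort(unique(out$barcode)), c("b1", "b2", "b3", "b4"))
  expect_true(all(out$count[out$sample_type == "cDNA"] == 5))

  no_dna <- dplyr::filter(toy_counts(), sample != "DNA")
  expect_error(filter_barcodes(no_dna, "rho"), class = "mpraic_input_error")
})

test_that("polylinker-mode filters use the 50-count and 8-RPM floors", {
  tab <- toy_counts(dna = c(49, 100, 100, 100))
  out <- filter_barcodes(tab, "polylinker")
  expect_false("b1" %in% out$barcode)

  ## equal counts: each surviving barcode sits at 2.5e5 RPM, far above 8;
  ## drop one barcode's cDNA low enough to fall under 8 RPM
  cdna <- matrix(1e6, 4, 3)
  cdna[2, 2] <- 1 # ~0.3 RPM
  out <- filter_barcodes(toy_counts(dna = rep(100, 4), cdna = cdna), "polylinker")
  b2 <- out[out$barcode == "b2" & out$sample_type == "cDNA", ]
  expect_equal(b2$count, c(0, 0, 0))
})

test_that("RPM normalization scales each sample to one million", {
  tab <- tibble::tibble(
    barcode = c("b1", "b2"), construct = c("x", "y"),
    sample = "DNA", count = c(1, 3), sample_type = "DNA"
  )
  out <- rpm_normalize(tab)
  expect_equal(out$rpm, c(250000, 750000))

  big <- toy_counts()
  rpm <- rpm_normalize(big)
  sums <- tapply(rpm$rpm, rpm$sample, sum)
  expect_equal(as.numeric(sums), rep(1e6, 4), tolerance = 1e-9)

  zero <- big
  zero$count[zero$sample == "cDNA_2"] <- 0
  expect_error(rpm_normalize(zero), class = "mpraic_normalization_error")
})

test_that("barcode expression is the cDNA/DNA RPM ratio", {
  cdna <- matrix(100, 4, 3)
  cdna[1, ] <- 200
  ratios <- toy_counts(cdna = cdna) |>
    rpm_normalize() |>
    barcode_expression()
  b1 <- ratios$expression[ratios$barcode == "b1"]
  b2 <- ratios$expression[ratios$barcode == "b2"]
  ## equal DNA shares; b1 has 200/500 of cDNA reads vs 100/500 for b2
  expect_equal(b1 / b2, rep(2, 3))
  expect_equal(ratios$expression[ratios$barcode == "b4"], b2)
})

test_that("construct aggregation averages surviving barcodes", {
  ratios <- tibble::tibble(
    barcode = c("b1", "b2", "b3", "b9"),
    construct = c("x", "x", "x", "y"),
    replicate = 1L,
    expression = c(1, 2, 3, 7)
  )
  agg <- aggregate_construct(ratios)
  expect_equal(agg$expression[agg$construct == "x"], 2)
  expect_equal(agg$expression[agg$construct == "y"], 7) # single barcode
  expect_equal(nrow(agg), 2) # no phantom rows for missing combinations
})

test_that("Welch test against basal matches the textbook formula", {
  a <- c(1, 2, 3, 4)
  b <- c(2, 3, 4, 5)
  pc <- 1e-3
  ratios <- tibble::tibble(
    barcode = paste0("b", 1:8),
    construct = rep(c("elem", "basal"), each = 4),
    replicate = 1L,
    expression = exp(c(a, b)) - pc # so log(e + pc) lands on a and b exactly
  )
  res <- test_vs_basal(ratios, "basal", pseudocount = pc)
  expect_equal(res$p_value, oracle_welch_p(a, b), tolerance = 1e-12)

  ## identical observation sets -> p = 1
  same <- ratios
  same$expression <- exp(rep(c(1, 2, 1.5, 2.5), 2)) - pc
  expect_equal(test_vs_basal(same, "basal", pseudocount = pc)$p_value, 1)

  ## constant groups get a floored variance, not NaN
  const <- ratios
  const$expression <- rep(c(0, 1), each = 4)
  p <- test_vs_basal(const, "basal", pseudocount = pc)$p_value
  expect_true(is.finite(p))
  expect_lt(p, 0.05)
})

test_that("BH q-values match a hand-computed step-up and are monotone", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_error(bh_fdr(c(0.5, 1.2)), class = "mpraic_validation_error")

  set.seed(31)
  for (i in 1:10) {
    p <- stats::runif(20)
    q <- bh_fdr(p)
    expect_equal(q, oracle_bh(p))
    expect_true(all(diff(q[order(p)]) >= -1e-15))
    expect_true(all(q <= 1))
  }
})

test_that("class assignment follows the twofold / FDR / percentile rules", {
  scrambled <- seq(0.5, 1.5, length.out = 100) # 95th percentile ~1.45
  act <- tibble::tibble(
    construct = letters[1:6],
    activity = c(2.5, 2.5, 1.2, 2.5, 0.4, 0.6),
    q_value = c(0.01, 0.01, 0.50, 0.20, 0.01, 0.01)
  )
  act$activity[2] <- 1.40 # enhancer fold fails -> ambiguous (q significant)
  out <- assign_classes(act, scrambled)
  expect_equal(
    as.character(out$class),
    c("strong_enhancer", "ambiguous", "inactive", "ambiguous", "silencer",
      "ambiguous")
  )
  ## weak enhancer: above twofold, q significant, below scrambled percentile
  weak <- assign_classes(
    tibble::tibble(construct = "w", activity = 2.1, q_value = 0.01),
    scrambled = c(rep(1, 50), rep(3, 50))
  )
  expect_equal(as.character(weak$class), "weak_enhancer")
  expect_error(assign_classes(act, numeric(0)), class = "mpraic_config_error")
})

test_that("autonomous calls use strictly positive replicate-mean log2 ratio", {
  make_poly <- function(a_cdna) {
    bcs <- c("a1", "f1")
    rows <- list(tibble::tibble(
      barcode = bcs, construct = c("x", "filler"), sample = "DNA",
      count = c(100, 100)
    ))
    for (r in 1:3) {
      rows[[r + 1]] <- tibble::tibble(
        barcode = bcs, construct = c("x", "filler"),
        sample = paste0("cDNA_", r), count = c(a_cdna, 200 - a_cdna)
      )
    }
    tab <- dplyr::bind_rows(rows)
    tab$sample_type <- ifelse(tab$sample == "DNA", "DNA", "cDNA")
    tab
  }
  ## totals equal across samples, so RPM ratio = count ratio
  calls <- call_autonomous(make_poly(200))                      # ratio 2
  expect_true(calls$autonomous[calls$construct == "x"])
  calls <- call_autonomous(make_poly(100))                      # ratio exactly 1
  expect_false(calls$autonomous[calls$construct == "x"])
  calls <- call_autonomous(make_poly(50))                       # ratio 0.5
  expect_false(calls$autonomous[calls$construct == "x"])
})

test_that("pipeline activities are RPM-scale invariant and basal-anchored", {
  design <- library_design(
    n_per_class = c(strong_enhancer = 10, weak_enhancer = 10,
      inactive = 10, silencer = 10),
    n_scrambled = 20, seed = 41
  )
  sim <- simulate_mpra(design, generative_params(seed = 42))
  ## zero sub-floor cDNA counts up front so the raw-count filter makes the
  ## same decisions before and after scaling (scale invariance is a property
  ## of the RPM stage, not of the raw-count floors)
  low <- sim$counts$sample_type == "cDNA" & sim$counts$count < 5
  sim$counts$count[low] <- 0
  calls <- call_activity(sim$counts, sim$annotation)

  scaled <- sim$counts
  idx <- scaled$sample == "cDNA_2"
  scaled$count[idx] <- scaled$count[idx] * 7
  calls2 <- call_activity(scaled, sim$annotation)
  expect_equal(calls2$activity, calls$activity, tolerance = 1e-9)
  expect_equal(calls2$q_value, calls$q_value, tolerance = 1e-9)

  ## classes are one per construct, exhaustive over called constructs
  expect_false(any(is.na(calls$class)))
  expect_equal(nrow(calls), dplyr::n_distinct(calls$construct))
  ## basal itself is excluded from calls (it is the reference)
  expect_false("basal" %in% calls$construct)
})

test_that("q-values are calibrated on null data with independent noise", {
  design <- library_design(
    n_per_class = c(strong_enhancer = 0, weak_enhancer = 0,
      inactive = 300, silencer = 0),
    n_scrambled = 100, seed = 43
  )
  ## noise_sd near zero: barcode-level Poisson sampling is the only noise,
  ## so the Welch observations are effectively independent
  params <- generative_params(noise_sd = 0.01, seed = 44)
  sim <- simulate_mpra(design, params)
  calls <- call_activity(sim$counts, sim$annotation)
  fp <- mean(calls$q_value < 0.05, na.rm = TRUE)
  n <- sum(!is.na(calls$q_value))
  expect_lte(fp, 0.05 + 3 * sqrt(0.05 * 0.95 / n))
})
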
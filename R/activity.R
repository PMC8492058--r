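## From barcode counts to activity classes. The processing chain follows the
## published retinal MPRA protocol: barcode count floors, reads-per-million
## normalization, cDNA/DNA expression ratios per barcode, barcode averaging
## per construct and replicate, Welch's t-test of each construct against the
## basal promoter on log expression, Benjamini-Hochberg FDR, then the
## twofold / q < 0.05 / scrambled-95th-percentile classification rules.

#' Apply barcode count filters
#'
#' In `rho` mode (basal-promoter assay) barcodes with a DNA raw count below
#' 10 are removed entirely, and barcodes with a cDNA raw count below 5 in
#' any cDNA sample have their cDNA counts set to zero in all cDNA samples
#' (present in the plasmid pool, below the detection limit). In
#' `polylinker` mode (promoterless assay) the DNA floor is 50 raw counts and
#' the cDNA floor is 8 on the RPM scale, computed after the DNA removal.
#'
#' @param counts A barcode count tibble (see [read_barcode_counts()]).
#' @param mode `"rho"` or `"polylinker"`.
#' @param config An [mpra_config()] holding the filter thresholds.
#' @return The filtered count tibble.
#' @export
filter_barcodes <- function(counts, mode = c("rho", "polylinker"),
                            config = mpra_config()) {
  mode <- match.arg(mode)
  counts <- validate_barcode_counts(counts)
  if (!any(counts$sample == "DNA")) {
    abort("count table has no DNA sample", class = "mpraic_input_error")
  }
  dna_floor <- if (mode == "rho") config$dna_floor_rho else config$dna_floor_polylinker
  keep <- counts %>%
    filter(.data$sample == "DNA", .data$count >= dna_floor) %>%
    pull("barcode")
  counts <- counts %>% filter(.data$barcode %in% keep)

  if (mode == "rho") {
    low <- counts %>%
      filter(.data$sample_type == "cDNA", .data$count < config$cdna_floor_rho) %>%
      pull("barcode") %>%
      unique()
  } else {
    rpm <- rpm_normalize(counts)
    low <- rpm %>%
      filter(.data$sample_type == "cDNA",
        .data$rpm < config$cdna_rpm_floor_polylinker) %>%
      pull("barcode") %>%
      unique()
  }
  counts %>%
    mutate(count = if_else(.data$sample_type == "cDNA" & .data$barcode %in% low,
      0, .data$count
    ))
}

#' Reads-per-million normalization
#'
#' Scales each sample to one million total counts. Totals are computed on
#' the table as given (i.e. after any barcode filtering), so DNA and cDNA
#' denominators reflect the same surviving barcodes.
#'
#' @param counts A barcode count tibble.
#' @return The tibble with an `rpm` column in place of raw counts.
#' @export
rpm_normalize <- function(counts) {
  totals <- counts %>%
    group_by(.data$sample) %>%
    summarise(total = sum(.data$count), .groups = "drop")
  if (any(totals$total <= 0)) {
    abort(paste0("sample with zero total counts: ",
      totals$sample[totals$total <= 0][1]), class = "mpraic_normalization_error")
  }
  counts %>%
    left_join(totals, by = "sample") %>%
    mutate(rpm = .data$count * 1e6 / .data$total) %>%
    select(-dplyr::all_of(c("count", "total")))
}

#' Per-barcode expression ratios
#'
#' Divides each cDNA replicate's RPM by the barcode's DNA RPM.
#'
#' @param rpm An [rpm_normalize()]d tibble.
#' @return A tibble with `barcode`, `construct`, `replicate`, `expression`.
#' @export
barcode_expression <- function(rpm) {
  dna <- rpm %>%
    filter(.data$sample_type == "DNA") %>%
    select(dplyr::all_of(c("barcode", "rpm"))) %>%
    rename(dna_rpm = "rpm")
  rpm %>%
    filter(.data$sample_type == "cDNA") %>%
    left_join(dna, by = "barcode") %>%
    mutate(
      replicate = as.integer(sub("^cDNA_", "", .data$sample)),
      expression = .data$rpm / .data$dna_rpm
    ) %>%
    select(dplyr::all_of(c("barcode", "construct", "replicate", "expression")))
}

#' Average barcodes per construct and replicate
#'
#' @param ratios A [barcode_expression()] tibble.
#' @return A tibble with `construct`, `replicate`, `expression` (arithmetic
#'   mean over the construct's surviving barcodes) and `n_barcodes`.
#'   Construct x replicate combinations with no surviving barcodes are
#'   simply absent (missing, not zero).
#' @export
aggregate_construct <- function(ratios) {
  ratios %>%
    group_by(.data$construct, .data$replicate) %>%
    summarise(
      expression = mean(.data$expression),
      n_barcodes = dplyr::n(), .groups = "drop"
    )
}

## Welch's unequal-variance t-test with a variance floor for degenerate
## groups. Regular two-sided t.test when both sample variances are positive;
## otherwise the textbook statistic with each variance floored at floor_var
## so constant groups yield a finite p instead of NaN.
welch_p <- function(x, y, floor_var = 0) {
  if (length(x) < 2 || length(y) < 2) return(NA_real_)
  v1 <- var(x)
  v2 <- var(y)
  if (v1 > 0 && v2 > 0) {
    return(t.test(x, y, var.equal = FALSE)$p.value)
  }
  v1 <- max(v1, floor_var)
  v2 <- max(v2, floor_var)
  se2 <- v1 / length(x) + v2 / length(y)
  tstat <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / (v1^2 / (length(x)^2 * (length(x) - 1)) +
    v2^2 / (length(y)^2 * (length(y) - 1)))
  2 * stats::pt(-abs(tstat), df)
}

#' Welch's t-test of each construct against basal expression
#'
#' The null hypothesis is that a construct's expression equals the basal
#' promoter's. Expression is approximately log-normal, so the test runs on
#' natural-log expression values; the observation unit is the barcode x
#' replicate expression value (up to 3 barcodes x 3 replicates per element
#' versus 18 x 3 for basal). A pseudocount is added before taking logs, and
#' a variance floor (the squared pseudocount) keeps degenerate all-zero
#' constructs finite.
#'
#' @param ratios A [barcode_expression()] tibble.
#' @param basal_construct Construct id of the basal promoter.
#' @param pseudocount Expression pseudocount.
#' @return A tibble with `construct`, `p_value`, `n_obs`.
#' @export
test_vs_basal <- function(ratios, basal_construct = "basal",
                          pseudocount = 1e-3) {
  if (!basal_construct %in% ratios$construct) {
    abort(paste0("basal construct '", basal_construct, "' absent"),
      class = "mpraic_input_error"
    )
  }
  logex <- ratios %>% mutate(obs = log(.data$expression + pseudocount))
  basal_obs <- logex %>%
    filter(.data$construct == basal_construct) %>%
    pull("obs")
  logex %>%
    filter(.data$construct != basal_construct) %>%
    group_by(.data$construct) %>%
    summarise(
      p_value = welch_p(.data$obs, basal_obs, floor_var = pseudocount^2),
      n_obs = dplyr::n(), .groups = "drop"
    )
}

#' Benjamini-Hochberg step-up q-values
#'
#' @param p Numeric vector of p-values in `[0, 1]` (NAs pass through).
#' @return q-values, monotone non-decreasing in sorted-p order, capped at 1.
#' @export
bh_fdr <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) {
    abort("p-values must lie in [0, 1]", class = "mpraic_validation_error")
  }
  p.adjust(p, method = "BH")
}

#' Assign activity classes
#'
#' Enhancer: activity at least `fold_cutoff` times basal and q below
#' `fdr_alpha`; silencer: at most `1/fold_cutoff` and q below `fdr_alpha`;
#' inactive: strictly within the twofold band and q at or above `fdr_alpha`;
#' anything else (including constructs whose test was undefined) is
#' ambiguous. Enhancers above the `strong_percentile`-th percentile of the
#' scrambled-control activities are strong, the rest weak.
#'
#' @param activity A tibble with `construct`, `activity` (basal-normalized,
#'   linear) and `q_value` columns.
#' @param scrambled_activities Numeric vector of basal-normalized activities
#'   of the scrambled controls.
#' @param config An [mpra_config()].
#' @return The tibble with a `class` factor column (levels strong_enhancer,
#'   weak_enhancer, inactive, silencer, ambiguous).
#' @export
assign_classes <- function(activity, scrambled_activities,
                           config = mpra_config()) {
  if (length(scrambled_activities) == 0 || all(is.na(scrambled_activities))) {
    abort("scrambled activity set is empty", class = "mpraic_config_error")
  }
  strong_cut <- quantile(scrambled_activities,
    probs = config$strong_percentile / 100, na.rm = TRUE, names = FALSE
  )
  up <- config$fold_cutoff
  dn <- 1 / config$fold_cutoff
  a <- activity$activity
  q <- activity$q_value
  cls <- dplyr::case_when(
    is.na(a) | is.na(q) ~ "ambiguous",
    a >= up & q < config$fdr_alpha & a > strong_cut ~ "strong_enhancer",
    a >= up & q < config$fdr_alpha ~ "weak_enhancer",
    a <= dn & q < config$fdr_alpha ~ "silencer",
    a > dn & a < up & q >= config$fdr_alpha ~ "inactive",
    TRUE ~ "ambiguous"
  )
  activity$class <- factor(cls, levels = ACTIVITY_CLASSES)
  activity
}

ACTIVITY_CLASSES <- c(
  "strong_enhancer", "weak_enhancer", "inactive", "silencer", "ambiguous"
)

#' Full activity-calling pipeline for the basal-promoter assay
#'
#' Runs filtering, RPM normalization, barcode expression, construct
#' aggregation, Welch tests against basal, BH FDR, replicate-specific basal
#' normalization and class assignment in one call.
#'
#' @param counts A barcode count tibble with one DNA sample and >= 2 cDNA
#'   replicates.
#' @param annotation A construct annotation tibble (`construct`, `group`,
#'   `category`); the `basal` group supplies the reference and the
#'   `scrambled` group the strong/weak split.
#' @param config An [mpra_config()].
#' @return A tibble of activity calls: `construct`, `group`, `activity`
#'   (basal-normalized linear mean), `log2_activity` (pseudocounted),
#'   `p_value`, `q_value`, `class`.
#' @export
call_activity <- function(counts, annotation, config = mpra_config()) {
  annotation <- annotation %>% distinct(.data$construct, .keep_all = TRUE)
  basal_ids <- annotation$construct[annotation$group == "basal"]
  if (length(basal_ids) != 1) {
    abort("annotation must contain exactly one basal construct",
      class = "mpraic_input_error"
    )
  }
  ratios <- counts %>%
    filter_barcodes(mode = "rho", config = config) %>%
    rpm_normalize() %>%
    barcode_expression()

  tests <- test_vs_basal(ratios, basal_ids,
    pseudocount = config$pseudocount_rho
  ) %>%
    mutate(q_value = bh_fdr(.data$p_value))

  expr <- aggregate_construct(ratios)
  basal_by_rep <- expr %>%
    filter(.data$construct == basal_ids) %>%
    select(dplyr::all_of(c("replicate", "expression"))) %>%
    rename(basal_expression = "expression")
  act <- expr %>%
    inner_join(basal_by_rep, by = "replicate") %>%
    mutate(norm = .data$expression / .data$basal_expression) %>%
    group_by(.data$construct) %>%
    summarise(activity = mean(.data$norm), .groups = "drop") %>%
    mutate(log2_activity = log2(.data$activity + config$pseudocount_rho))

  calls <- act %>%
    left_join(tests, by = "construct") %>%
    left_join(annotation[, c("construct", "group")], by = "construct")
  scrambled <- calls %>%
    filter(.data$group == "scrambled") %>%
    pull("activity")
  calls %>%
    filter(.data$construct != basal_ids) %>%
    assign_classes(scrambled, config) %>%
    select(dplyr::all_of(c(
      "construct", "group", "activity", "log2_activity",
      "p_value", "q_value", "class"
    )))
}

#' Autonomous-activity calls for the promoterless assay
#'
#' Processes a polylinker-mode count table (DNA floor 50, cDNA floor 8 RPM)
#' and calls a construct autonomous when its replicate-averaged
#' log2(RNA/DNA) is strictly positive. The reported `log2_expression` adds
#' the promoterless pseudocount; the autonomy decision itself uses the raw
#' ratio so that a ratio of exactly 1 is not autonomous.
#'
#' @param counts A polylinker-assay barcode count tibble.
#' @param config An [mpra_config()].
#' @return A tibble with `construct`, `log2_expression`, `autonomous`.
#' @export
call_autonomous <- function(counts, config = mpra_config()) {
  expr <- counts %>%
    filter_barcodes(mode = "polylinker", config = config) %>%
    rpm_normalize() %>%
    barcode_expression() %>%
    aggregate_construct()
  expr %>%
    group_by(.data$construct) %>%
    summarise(
      log2_expression = mean(log2(.data$expression + config$pseudocount_polylinker)),
      autonomous = mean(log2(.data$expression)) > 0,
      .groups = "drop"
    )
}
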
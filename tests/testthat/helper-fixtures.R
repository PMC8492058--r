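## Fixtures and independent oracles shared across the suite. Oracles here
## deliberately re-derive quantities from first principles (naive loops,
## textbook formulas) rather than calling the package's own code paths.

## -- tiny barcode count tables ------------------------------------------

## One construct (3 barcodes), one basal-like filler, 1 DNA + 3 cDNA samples.
toy_counts <- function(dna = c(100, 100, 100, 100),
                       cdna = matrix(100, nrow = 4, ncol = 3)) {
  bcs <- c("b1", "b2", "b3", "b4")
  constructs <- c("elemA", "elemA", "elemA", "basal")
  rows <- list(tibble::tibble(
    barcode = bcs, construct = constructs, sample = "DNA", count = dna
  ))
  for (r in 1:3) {
    rows[[r + 1]] <- tibble::tibble(
      barcode = bcs, construct = constructs,
      sample = paste0("cDNA_", r), count = cdna[, r]
    )
  }
  tab <- dplyr::bind_rows(rows)
  tab$sample_type <- ifelse(tab$sample == "DNA", "DNA", "cDNA")
  tab
}

## -- independent occupancy oracle ---------------------------------------

## Naive per-window enumeration on both strands, computed directly from the
## letter-probability matrix (no energy_matrix object involved).
oracle_occupancy <- function(seq, motif, mu = 9, rt_scale = 2.5,
                             pseudocount = 1e-4) {
  pwm <- motif$matrix + pseudocount
  pwm <- pwm / apply(pwm, 1, max)
  letters_of <- function(s) strsplit(s, "", fixed = TRUE)[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  scan_one <- function(s) {
    x <- letters_of(s)
    w <- nrow(pwm)
    total <- 0
    for (i in seq_len(length(x) - w + 1)) {
      e <- 0
      for (j in seq_len(w)) {
        e <- e - rt_scale * log(pwm[j, x[i + j - 1]])
      }
      total <- total + 1 / (1 + exp((e - mu) / rt_scale))
    }
    total
  }
  rc <- paste(rev(unname(comp[letters_of(seq)])), collapse = "")
  unname(scan_one(seq) + scan_one(rc))
}

## -- independent Welch oracle -------------------------------------------

oracle_welch_p <- function(x, y) {
  v1 <- stats::var(x) / length(x)
  v2 <- stats::var(y) / length(y)
  tstat <- (mean(x) - mean(y)) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (length(x) - 1) + v2^2 / (length(y) - 1))
  2 * stats::pt(-abs(tstat), df)
}

## -- independent BH step-up oracle --------------------------------------

oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  running <- 1
  for (i in rev(seq_len(m))) {
    running <- min(running, p[ord[i]] * m / i)
    q[ord[i]] <- running
  }
  q
}

random_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}
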
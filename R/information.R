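## Boltzmann-entropy motif information content. A sequence's bound TF
## molecules (predicted occupancies N_i, total N) can be arranged in
## W = Gamma(N+1) / prod_i Gamma(N_i + 1) distinguishable orders; the
## information content is I = log2(W) bits. Fractional occupancies pass
## through the Gamma continuation unrounded, and everything is computed in
## log-Gamma space so large occupancies never overflow.

#' Boltzmann-entropy information content of an occupancy vector
#'
#' `I = log2 Gamma(N + 1) - sum_i log2 Gamma(N_i + 1)` bits, where `N_i` is
#' the predicted occupancy of TF i and `N` their total. Zero when at most one
#' TF is bound: a sequence occupied by many copies of a single TF carries no
#' arrangement information, while diversity at the same total occupancy
#' raises I.
#'
#' @param occupancy Either a numeric vector of per-TF occupancies for one
#'   sequence, or an [occupancy_profile()] tibble (its `total` column is
#'   ignored; a `bits` column is appended).
#' @return A single number of bits, or the tibble with a `bits` column.
#' @export
#' @examples
#' information_content(c(1, 1, 0)) # 1 bit
#' information_content(c(2, 1, 0)) # log2(3) = 1.6 bits
information_content <- function(occupancy) {
  if (is.data.frame(occupancy)) {
    tf_cols <- setdiff(names(occupancy), c("id", "total"))
    mat <- as.matrix(occupancy[, tf_cols])
    occupancy$bits <- apply(mat, 1, ic_bits)
    return(occupancy)
  }
  ic_bits(occupancy)
}

ic_bits <- function(ni) {
  if (any(!is.finite(ni)) || any(ni < 0)) {
    abort("occupancies must be finite and non-negative",
      class = "mpraic_validation_error"
    )
  }
  n <- sum(ni)
  if (n == 0) return(0)
  (lgamma(n + 1) - sum(lgamma(ni + 1))) / log(2)
}

#' Residual information content, excluding one TF
#'
#' Information content recomputed with the named TF removed from the
#' occupancy vector — e.g. the information carried by non-CRX motifs in a
#' CRX-centered library.
#'
#' @param occupancy A named numeric occupancy vector, or an
#'   [occupancy_profile()] tibble (appends a `residual_bits` column).
#' @param excluded_tf Name of the TF to drop.
#' @return Bits, or the tibble with a `residual_bits` column.
#' @export
residual_information_content <- function(occupancy, excluded_tf) {
  if (is.data.frame(occupancy)) {
    tf_cols <- setdiff(names(occupancy), c("id", "total", "bits"))
    if (!excluded_tf %in% tf_cols) {
      abort(paste0("unknown TF: ", excluded_tf), class = "mpraic_validation_error")
    }
    mat <- as.matrix(occupancy[, setdiff(tf_cols, excluded_tf)])
    occupancy$residual_bits <- apply(mat, 1, ic_bits)
    return(occupancy)
  }
  if (!excluded_tf %in% names(occupancy)) {
    abort(paste0("unknown TF: ", excluded_tf), class = "mpraic_validation_error")
  }
  ic_bits(occupancy[setdiff(names(occupancy), excluded_tf)])
}

#' Expected number of genomic windows carrying k spurious motifs
#'
#' Under a Poisson model for spurious motif matches, a `w` bp window carries
#' `k` total motifs for `m` TFs with probability `Poisson(k; lambda)`,
#' `lambda = p * m * w`, where `p` is the per-bp spurious-motif probability;
#' the expected number of such windows in a genome of `N_genome` bp is
#' `Poisson(k; lambda) * N_genome`.
#'
#' @param p Spurious-motif probability per bp.
#' @param m Number of distinct TFs.
#' @param w Window width in bp.
#' @param n_genome Genome length in bp.
#' @param k Total motif count (non-negative integer).
#' @return A tibble with `lambda`, `p_k`, `expected_windows`.
#' @export
expected_kmotif_windows <- function(p, m, w, n_genome, k) {
  if (any(c(p, m, w, n_genome) <= 0)) {
    abort("p, m, w, n_genome must be positive", class = "mpraic_validation_error")
  }
  if (any(k < 0) || any(k != floor(k))) {
    abort("k must be a non-negative integer", class = "mpraic_validation_error")
  }
  lambda <- p * m * w
  p_k <- dpois(k, lambda)
  tibble(k = k, lambda = lambda, p_k = p_k, expected_windows = p_k * n_genome)
}
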
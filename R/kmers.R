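## Canonical k-mer spectrum features: a k-mer and its reverse complement
## are one feature, so features(seq) == features(reverse_complement(seq))
## by construction. For k = 6 there are (4^6 + 4^3) / 2 = 2080 features.

all_kmers <- function(k) {
  grid <- do.call(expand.grid, c(
    rep(list(DNA_LETTERS), k),
    stringsAsFactors = FALSE
  ))
  ## vary the first position slowest so output is lexicographically sorted
  sort(apply(grid, 1, paste, collapse = ""))
}

#' Canonical (reverse-complement-collapsed) k-mers
#'
#' One representative per reverse-complement equivalence class: the
#' lexicographically smaller of the k-mer and its reverse complement,
#' sorted. For even k the count is `(4^k + 4^(k/2)) / 2`; k = 6 gives 2080.
#'
#' @param k k-mer length (>= 1).
#' @return Character vector of canonical k-mers.
#' @export
#' @examples
#' canonical_kmers(1) # "A", "C"
#' length(canonical_kmers(6)) # 2080
canonical_kmers <- function(k) {
  stopifnot(k >= 1)
  kmers <- all_kmers(k)
  sort(unique(pmin(kmers, reverse_complement(kmers))))
}

canonical_map <- function(k) {
  kmers <- all_kmers(k)
  stats::setNames(pmin(kmers, reverse_complement(kmers)), kmers)
}

#' Canonical k-mer count features
#'
#' Counts every length-k window of each sequence into its canonical
#' reverse-complement class; counts sum to `L - k + 1` per sequence.
#'
#' @param sequences A tibble with `id`/`sequence` columns, or a character
#'   vector of ACGT strings.
#' @param k k-mer length.
#' @return A numeric matrix (sequences x canonical k-mers) with the
#'   sequence ids as row names.
#' @export
kmer_features <- function(sequences, k = 6) {
  sequences <- as_sequence_tbl(sequences)
  if (any(nchar(sequences$sequence) < k)) {
    abort("sequence shorter than k", class = "mpraic_input_error")
  }
  check_dna(sequences$sequence, sequences$id)
  map <- canonical_map(k)
  feats <- canonical_kmers(k)
  out <- matrix(0, nrow = nrow(sequences), ncol = length(feats),
    dimnames = list(sequences$id, feats)
  )
  for (i in seq_len(nrow(sequences))) {
    s <- sequences$sequence[i]
    n <- nchar(s) - k + 1
    windows <- substring(s, seq_len(n), seq_len(n) + k - 1)
    tab <- table(map[windows])
    out[i, names(tab)] <- as.numeric(tab)
  }
  out
}
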
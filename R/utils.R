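## Internal sequence helpers. All sequences are plain uppercase ACGT strings;
## the integer encoding A=1, C=2, G=3, T=4 is used by the occupancy scanner
## and the k-mer counter.

DNA_LETTERS <- c("A", "C", "G", "T")

encode_seq <- function(seq) {
  x <- match(strsplit(seq, "", fixed = TRUE)[[1]], DNA_LETTERS)
  if (anyNA(x)) {
    abort("sequence contains letters outside {A,C,G,T}", class = "mpraic_alphabet_error")
  }
  x
}

#' Reverse complement of a DNA string
#'
#' @param seq Character vector of ACGT strings.
#' @return Character vector of the same length.
#' @export
#' @examples
#' reverse_complement("ACGGT")
reverse_complement <- function(seq) {
  vapply(
    chartr("ACGT", "TGCA", seq),
    function(s) paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""),
    character(1),
    USE.NAMES = FALSE
  )
}

check_dna <- function(seq, id = NULL) {
  bad <- grepl("[^ACGT]", seq)
  if (any(bad)) {
    who <- if (is.null(id)) which(bad)[1] else id[bad][1]
    abort(
      paste0("non-ACGT characters in sequence ", who),
      class = "mpraic_alphabet_error"
    )
  }
  invisible(seq)
}

random_dna <- function(n, length) {
  vapply(
    seq_len(n),
    function(i) paste(sample(DNA_LETTERS, length, replace = TRUE), collapse = ""),
    character(1)
  )
}

## %||% for default arguments
`%||%` <- function(x, y) if (is.null(x)) y else x
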
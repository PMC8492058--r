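## Readers and writers for the plain-text formats the pipeline touches:
## FASTA sequence libraries, MEME minimal motif files, tab-separated barcode
## count tables and construct annotation tables. All readers are strict:
## malformed input raises a classed condition rather than propagating NAs.

SEQUENCE_GROUPS <- c("genomic", "crx_mutant", "scrambled", "basal")

#' Read a sequence library from FASTA
#'
#' The token before the first whitespace in each header becomes the sequence
#' id; any remaining `key=value` header fields populate the `group` and
#' `category` columns. Sequences are case-folded to upper case and must use
#' only A/C/G/T (ambiguity codes such as N are rejected because binding
#' energies are undefined for them).
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id`, `sequence`, `group`, `category`.
#' @export
read_fasta <- function(path) {
  seqs <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) abort(paste0("not readable as FASTA: ", conditionMessage(e)),
      class = "mpraic_format_error"
    )
  )
  if (length(seqs) == 0) {
    abort("empty FASTA file", class = "mpraic_format_error")
  }
  headers <- names(seqs)
  ids <- sub("\\s.*$", "", headers)
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate sequence id: ", ids[duplicated(ids)][1]),
      class = "mpraic_validation_error"
    )
  }
  rest <- sub("^\\S+\\s*", "", headers)
  parse_field <- function(txt, key) {
    m <- regmatches(txt, regexec(paste0("\\b", key, "=(\\S+)"), txt))
    vapply(m, function(x) if (length(x) == 2) x[2] else NA_character_, character(1))
  }
  group <- parse_field(rest, "group")
  group[is.na(group)] <- "genomic"
  bad_group <- !group %in% SEQUENCE_GROUPS
  if (any(bad_group)) {
    abort(paste0("unknown sequence group: ", group[bad_group][1]),
      class = "mpraic_validation_error"
    )
  }
  sequence <- toupper(as.character(seqs))
  check_dna(sequence, ids)
  tibble(
    id = ids,
    sequence = unname(sequence),
    group = group,
    category = parse_field(rest, "category")
  )
}

#' @rdname read_fasta
#' @param sequences A tibble with at least `id` and `sequence` columns;
#'   `group` and `category` are written as `key=value` header fields when
#'   present.
#' @export
write_fasta <- function(sequences, path) {
  stopifnot(all(c("id", "sequence") %in% names(sequences)))
  header <- sequences$id
  if ("group" %in% names(sequences)) {
    header <- paste0(header, " group=", sequences$group)
  }
  if ("category" %in% names(sequences)) {
    cat_part <- ifelse(is.na(sequences$category), "",
      paste0(" category=", sequences$category)
    )
    header <- paste0(header, cat_part)
  }
  writeLines(paste0(">", header, "\n", sequences$sequence), path)
  invisible(path)
}

#' Construct a motif model (letter-probability matrix)
#'
#' @param tf_name Transcription factor name.
#' @param matrix A width x 4 matrix of letter probabilities with columns
#'   A, C, G, T; each row must sum to 1 within 1e-6.
#' @param source Free-text provenance tag.
#' @return An object of class `"motif_model"`.
#' @export
motif_model <- function(tf_name, matrix, source = "") {
  matrix <- as.matrix(matrix)
  if (ncol(matrix) != 4 || nrow(matrix) < 1) {
    abort("motif matrix must be width x 4 with width >= 1",
      class = "mpraic_validation_error"
    )
  }
  colnames(matrix) <- DNA_LETTERS
  if (any(matrix < 0)) {
    abort("motif probabilities must be non-negative",
      class = "mpraic_validation_error"
    )
  }
  if (any(abs(rowSums(matrix) - 1) > 1e-6)) {
    abort(paste0("motif '", tf_name, "' has a row not summing to 1"),
      class = "mpraic_validation_error"
    )
  }
  structure(
    list(tf_name = tf_name, matrix = matrix, source = source),
    class = "motif_model"
  )
}

#' @export
print.motif_model <- function(x, ...) {
  cat("<motif_model>", x$tf_name, "width", nrow(x$matrix), "\n")
  print(round(x$matrix, 3))
  invisible(x)
}

#' Read motif models from a MEME minimal-format file
#'
#' Parses `MOTIF` blocks with their `letter-probability matrix` sections.
#' Rows whose probabilities sum to within 1e-3 of 1 (common with truncated
#' database matrices) are renormalized; larger deviations are format errors.
#'
#' @param path Path to a MEME minimal motif file over the ACGT alphabet.
#' @return A named list of [motif_model()] objects, in file order.
#' @export
read_meme_motifs <- function(path) {
  lines <- readLines(path, warn = FALSE)
  motif_starts <- grep("^MOTIF\\b", lines)
  if (length(motif_starts) == 0) {
    abort("no MOTIF blocks found", class = "mpraic_format_error")
  }
  ends <- c(motif_starts[-1] - 1, length(lines))
  motifs <- vector("list", length(motif_starts))
  for (i in seq_along(motif_starts)) {
    block <- lines[motif_starts[i]:ends[i]]
    name_fields <- strsplit(trimws(block[1]), "\\s+")[[1]]
    if (length(name_fields) < 2) {
      abort("MOTIF line without a name", class = "mpraic_format_error")
    }
    name <- name_fields[2]
    hdr <- grep("^letter-probability matrix", block)
    if (length(hdr) != 1) {
      abort(paste0("motif '", name, "': missing letter-probability matrix"),
        class = "mpraic_format_error"
      )
    }
    rows <- block[-seq_len(hdr)]
    rows <- rows[grepl("^\\s*[0-9.eE+-]", rows)]
    if (length(rows) == 0) {
      abort(paste0("motif '", name, "': empty matrix block"),
        class = "mpraic_format_error"
      )
    }
    mat <- do.call(rbind, lapply(strsplit(trimws(rows), "\\s+"), as.numeric))
    if (ncol(mat) != 4 || anyNA(mat)) {
      abort(paste0("motif '", name, "': malformed probability rows"),
        class = "mpraic_format_error"
      )
    }
    sums <- rowSums(mat)
    if (any(abs(sums - 1) > 1e-3)) {
      abort(paste0("motif '", name, "': row sum off by more than 1e-3"),
        class = "mpraic_format_error"
      )
    }
    mat <- mat / sums
    motifs[[i]] <- motif_model(name, mat, source = basename(path))
  }
  names(motifs) <- vapply(motifs, function(m) m$tf_name, character(1))
  motifs
}

#' @rdname read_meme_motifs
#' @param motifs A list of [motif_model()] objects.
#' @export
write_meme_motifs <- function(motifs, path) {
  out <- c(
    "MEME version 4", "",
    "ALPHABET= ACGT", "",
    "strands: + -", "",
    "Background letter frequencies",
    "A 0.25 C 0.25 G 0.25 T 0.25", ""
  )
  for (m in motifs) {
    out <- c(
      out,
      paste("MOTIF", m$tf_name),
      sprintf(
        "letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
        nrow(m$matrix)
      ),
      apply(m$matrix, 1, function(r) paste(sprintf("%.6f", r), collapse = " ")),
      ""
    )
  }
  writeLines(out, path)
  invisible(path)
}

#' Read a long-format barcode count table
#'
#' Expects a tab-separated file with header columns `barcode`, `construct`,
#' `sample`, `count`. Sample names must follow the `DNA` / `cDNA_<r>` naming
#' convention; a `sample_type` column tagging each row as `DNA` or `cDNA` is
#' added on read.
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `barcode`, `construct`, `sample`, `count`,
#'   `sample_type`.
#' @export
read_barcode_counts <- function(path) {
  tab <- readr::read_tsv(path,
    col_types = readr::cols(
      barcode = readr::col_character(),
      construct = readr::col_character(),
      sample = readr::col_character(),
      count = readr::col_double()
    )
  )
  validate_barcode_counts(tab)
}

validate_barcode_counts <- function(tab) {
  need <- c("barcode", "construct", "sample", "count")
  if (!all(need %in% names(tab))) {
    abort("count table must have columns barcode, construct, sample, count",
      class = "mpraic_format_error"
    )
  }
  if (anyNA(tab$count) || any(tab$count < 0) || any(tab$count != floor(tab$count))) {
    abort("counts must be non-negative integers", class = "mpraic_validation_error")
  }
  bad_sample <- !grepl("^(DNA|cDNA_[0-9]+)$", tab$sample)
  if (any(bad_sample)) {
    abort(paste0("sample names must be 'DNA' or 'cDNA_<r>'; got: ",
      tab$sample[bad_sample][1]), class = "mpraic_validation_error")
  }
  if (anyDuplicated(tab[, c("barcode", "sample")])) {
    abort("duplicated (barcode, sample) row", class = "mpraic_validation_error")
  }
  multi <- tab %>%
    distinct(.data$barcode, .data$construct) %>%
    dplyr::count(.data$barcode) %>%
    filter(.data$n > 1)
  if (nrow(multi) > 0) {
    abort(paste0("barcode mapped to two constructs: ", multi$barcode[1]),
      class = "mpraic_validation_error"
    )
  }
  tab %>%
    mutate(sample_type = if_else(.data$sample == "DNA", "DNA", "cDNA")) %>%
    as_tibble()
}

#' @rdname read_barcode_counts
#' @param counts A barcode count tibble.
#' @export
write_barcode_counts <- function(counts, path) {
  readr::write_tsv(counts[, c("barcode", "construct", "sample", "count")], path)
  invisible(path)
}

#' Read or write a construct annotation table
#'
#' Tab-separated with columns `construct`, `group`, `category`; `group` must
#' be one of genomic, crx_mutant, scrambled, basal.
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `construct`, `group`, `category`.
#' @export
read_annotation <- function(path) {
  tab <- readr::read_tsv(path,
    col_types = readr::cols(
      construct = readr::col_character(),
      group = readr::col_character(),
      category = readr::col_character()
    )
  )
  if (!all(c("construct", "group") %in% names(tab))) {
    abort("annotation must have columns construct, group",
      class = "mpraic_format_error"
    )
  }
  bad <- !tab$group %in% SEQUENCE_GROUPS
  if (any(bad)) {
    abort(paste0("unknown group in annotation: ", tab$group[bad][1]),
      class = "mpraic_validation_error"
    )
  }
  if (anyDuplicated(tab$construct)) {
    abort("duplicate construct in annotation", class = "mpraic_validation_error")
  }
  if (!"category" %in% names(tab)) tab$category <- NA_character_
  as_tibble(tab)
}

#' @rdname read_annotation
#' @param annotation An annotation tibble.
#' @export
write_annotation <- function(annotation, path) {
  readr::write_tsv(annotation[, c("construct", "group", "category")], path)
  invisible(path)
}
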
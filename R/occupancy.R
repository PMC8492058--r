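## Biophysical predicted occupancy. A motif's letter-probability matrix is
## turned into an energy weight matrix (consensus-normalized, negative log,
## scaled by RT = 2.5); each sequence window's energy feeds a Fermi-form
## binding probability with chemical potential mu, and the per-window
## probabilities over both strands sum to the expected number of bound
## molecules.

#' Convert a letter-probability matrix to an energy weight matrix
#'
#' Each probability column is normalized by its most probable letter, then
#' `E = -rt_scale * log(p_rel)`. The consensus letter has energy exactly 0 at
#' every position. A pseudocount keeps energies finite when database
#' matrices contain zeros.
#'
#' @param motif A [motif_model()].
#' @param pseudocount Probability pseudocount added before normalization.
#' @param rt_scale Energy scale (RT); default 2.5.
#' @return An object of class `"energy_matrix"`: list with `tf_name`,
#'   `width`, and `energies` (width x 4, non-negative, consensus = 0).
#' @export
pwm_to_energy <- function(motif, pseudocount = 1e-4, rt_scale = 2.5) {
  stopifnot(inherits(motif, "motif_model"), pseudocount >= 0)
  p <- motif$matrix + pseudocount
  p_max <- apply(p, 1, max)
  energies <- -rt_scale * log(p / p_max)
  structure(
    list(tf_name = motif$tf_name, width = nrow(energies), energies = energies),
    class = "energy_matrix"
  )
}

#' @export
print.energy_matrix <- function(x, ...) {
  cat("<energy_matrix>", x$tf_name, "width", x$width, "\n")
  print(round(x$energies, 2))
  invisible(x)
}

#' Fermi-form binding probability of a single site
#'
#' `p = 1 / (1 + exp((E - mu) / rt_scale))`. At `E = mu` the site is
#' half-occupied; with `mu = 9` and `rt_scale = 2.5` that corresponds to a
#' relative K_D of `exp(-9/2.5) ~ 0.03` of the optimal site.
#'
#' @param site_energy Site energy (sum of per-position energies), vectorized.
#' @param mu Chemical potential.
#' @param rt_scale Energy scale.
#' @return Binding probabilities in `[0, 1]`.
#' @export
#' @examples
#' site_occupancy(9)        # half occupied at E = mu
#' site_occupancy(0)        # consensus site
site_occupancy <- function(site_energy, mu = 9, rt_scale = 2.5) {
  1 / (1 + exp((site_energy - mu) / rt_scale))
}

## Per-window site energies of one strand; x is the integer-encoded sequence.
window_energies <- function(x, energies) {
  w <- nrow(energies)
  n <- length(x) - w + 1
  e <- numeric(n)
  for (j in seq_len(w)) {
    ej <- energies[j, ]
    e <- e + ej[x[j:(j + n - 1)]]
  }
  e
}

#' Predicted occupancy of one TF on a sequence
#'
#' Sums the Fermi-form binding probability over every window on the forward
#' strand and every window on the reverse complement (`2 * (L - w + 1)`
#' windows total; overlapping windows all count).
#'
#' @param sequence A single ACGT string.
#' @param energy_matrix An [pwm_to_energy()] result.
#' @param mu Chemical potential.
#' @param rt_scale Energy scale.
#' @return Expected number of bound molecules (non-negative scalar).
#' @export
predicted_occupancy <- function(sequence, energy_matrix, mu = 9, rt_scale = 2.5) {
  stopifnot(inherits(energy_matrix, "energy_matrix"), length(sequence) == 1)
  x <- encode_seq(sequence)
  w <- energy_matrix$width
  if (length(x) < w) {
    abort("sequence shorter than motif width", class = "mpraic_input_error")
  }
  xrc <- rev(5L - x) # A<->T, C<->G on the integer encoding
  e_fwd <- window_energies(x, energy_matrix$energies)
  e_rev <- window_energies(xrc, energy_matrix$energies)
  sum(site_occupancy(c(e_fwd, e_rev), mu = mu, rt_scale = rt_scale))
}

panel_energies <- function(tf_panel, config) {
  lapply(tf_panel, pwm_to_energy,
    pseudocount = config$pwm_pseudocount, rt_scale = config$rt_scale
  )
}

#' Per-TF predicted occupancy profile of a sequence library
#'
#' @param sequences A tibble with `id` and `sequence` columns (as returned by
#'   [read_fasta()]), or a named character vector of sequences.
#' @param tf_panel A named list of [motif_model()]s.
#' @param config An [mpra_config()].
#' @return A tibble with `id`, one occupancy column per TF, and `total`.
#' @export
occupancy_profile <- function(sequences, tf_panel, config = mpra_config()) {
  if (length(tf_panel) == 0) {
    abort("tf_panel must be non-empty", class = "mpraic_input_error")
  }
  sequences <- as_sequence_tbl(sequences)
  ems <- panel_energies(tf_panel, config)
  occ <- vapply(
    ems,
    function(em) {
      vapply(sequences$sequence, predicted_occupancy,
        numeric(1),
        energy_matrix = em, mu = config$mu, rt_scale = config$rt_scale,
        USE.NAMES = FALSE
      )
    },
    numeric(nrow(sequences))
  )
  occ <- matrix(occ, nrow = nrow(sequences),
    dimnames = list(NULL, names(tf_panel)))
  out <- as_tibble(occ)
  out$total <- rowSums(occ)
  dplyr::bind_cols(tibble(id = sequences$id), out)
}

as_sequence_tbl <- function(sequences) {
  if (is.character(sequences)) {
    ids <- names(sequences) %||% paste0("seq", seq_along(sequences))
    sequences <- tibble(id = ids, sequence = unname(sequences))
  }
  stopifnot(all(c("id", "sequence") %in% names(sequences)))
  sequences
}

#' Motif presence calls from an occupancy profile
#'
#' A TF's motifs are called present in a sequence when its predicted
#' occupancy is strictly above the threshold (default 0.5 molecules).
#'
#' @param occupancy An [occupancy_profile()] tibble.
#' @param threshold Occupancy threshold in molecules.
#' @return A tibble with `id` and one logical column per TF.
#' @export
motif_presence <- function(occupancy, threshold = 0.5) {
  stopifnot(threshold > 0)
  tf_cols <- setdiff(names(occupancy), c("id", "total"))
  occupancy %>%
    mutate(across(dplyr::all_of(tf_cols), ~ .x > threshold)) %>%
    select(dplyr::all_of(c("id", tf_cols)))
}

#' Occupied binding sites of a sequence library
#'
#' Lists every motif window whose single-site binding probability exceeds
#' the threshold. Forward- and reverse-strand hits covering overlapping
#' positions of the same TF are collapsed into one site (a physical site is
#' one locus); the reported occupancy is the maximum over merged windows and
#' positions are 1-based on the forward strand.
#'
#' @inheritParams occupancy_profile
#' @param threshold Per-site binding probability threshold (default 0.5).
#' @return A tibble with `id`, `tf`, `start`, `end`, `center`, `strand`,
#'   `occupancy`.
#' @export
occupied_sites <- function(sequences, tf_panel, config = mpra_config(),
                           threshold = 0.5) {
  sequences <- as_sequence_tbl(sequences)
  ems <- panel_energies(tf_panel, config)
  purrr::map_dfr(seq_len(nrow(sequences)), function(i) {
    x <- encode_seq(sequences$sequence[i])
    L <- length(x)
    purrr::map_dfr(ems, function(em) {
      w <- em$width
      if (L < w) return(tibble())
      xrc <- rev(5L - x)
      p_fwd <- site_occupancy(window_energies(x, em$energies),
        mu = config$mu, rt_scale = config$rt_scale)
      p_rev <- site_occupancy(window_energies(xrc, em$energies),
        mu = config$mu, rt_scale = config$rt_scale)
      n <- L - w + 1
      hits <- tibble(
        start = c(seq_len(n), rev(seq_len(n))),
        strand = rep(c("+", "-"), each = n),
        occupancy = c(p_fwd, p_rev)
      ) %>% filter(.data$occupancy > threshold)
      if (nrow(hits) == 0) return(tibble())
      hits <- hits %>%
        mutate(end = .data$start + w - 1) %>%
        arrange(.data$start)
      ## strand-collapsed merge of overlapping windows
      grp <- cumsum(c(1, as.integer(hits$start[-1] > cummax(hits$end)[-nrow(hits)])))
      hits %>%
        group_by(grp = grp) %>%
        summarise(
          start = min(.data$start), end = max(.data$end),
          strand = if (dplyr::n_distinct(.data$strand) > 1) "*" else .data$strand[1],
          occupancy = max(.data$occupancy), .groups = "drop"
        ) %>%
        mutate(
          id = sequences$id[i], tf = em$tf_name,
          center = (.data$start + .data$end) / 2
        ) %>%
        select(dplyr::all_of(c("id", "tf", "start", "end", "center",
                               "strand", "occupancy")))
    })
  })
}
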
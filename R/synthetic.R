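## Synthetic MPRA libraries. Sequences are uniform-random backgrounds with
## consensus motif sites planted at non-overlapping random positions; the
## generative link from motif content to expression is a deliberately
## minimal two-parameter rule (diversity activates, high centering-TF
## occupancy without partners silences) so that the downstream pipeline's
## recovery of planted structure is a meaningful test. Counts follow a
## negative-binomial plasmid pool and Poisson cDNA sampling around
## DNA * 2^(m + noise).

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit(
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  )
  set.seed(seed)
  force(code)
}

#' Generate toy position weight matrices
#'
#' Each TF gets a distinct uniform-random consensus; the consensus letter
#' carries `sharpness` probability mass per position and the remainder is
#' split equally over the other three letters. `sharpness = 1` gives
#' one-hot (consensus-only) motifs.
#'
#' @param n_tfs Number of motifs (>= 1).
#' @param width Motif width (>= 4).
#' @param sharpness Consensus probability mass per position, in (0, 1].
#' @param seed Integer seed; same seed, same models.
#' @return A named list of [motif_model()]s (`TF1`, `TF2`, ...).
#' @export
make_toy_pwms <- function(n_tfs, width = 8, sharpness = 0.95, seed = 1L) {
  if (n_tfs < 1 || width < 4) {
    abort("need n_tfs >= 1 and width >= 4", class = "mpraic_parameter_error")
  }
  if (sharpness <= 0 || sharpness > 1) {
    abort("sharpness must lie in (0, 1]", class = "mpraic_parameter_error")
  }
  with_seed(seed, {
    consensi <- character(0)
    motifs <- vector("list", n_tfs)
    for (i in seq_len(n_tfs)) {
      repeat {
        cons <- sample(4L, width, replace = TRUE)
        key <- paste(cons, collapse = "")
        if (!key %in% consensi) break
      }
      consensi <- c(consensi, key)
      mat <- matrix((1 - sharpness) / 3, nrow = width, ncol = 4)
      mat[cbind(seq_len(width), cons)] <- sharpness
      motifs[[i]] <- motif_model(paste0("TF", i), mat, source = "toy")
    }
    names(motifs) <- paste0("TF", seq_len(n_tfs))
    motifs
  })
}

consensus_seq <- function(motif) {
  paste(DNA_LETTERS[apply(motif$matrix, 1, which.max)], collapse = "")
}

#' Plant consensus motif sites into a random background
#'
#' Sites are placed at non-overlapping positions drawn uniformly over all
#' feasible non-overlapping arrangements, each on a uniform-random strand,
#' in a uniform-random ACGT background.
#'
#' @param length Sequence length in bp.
#' @param counts_per_tf Named integer vector: sites to plant per TF.
#' @param tf_panel Named list of [motif_model()]s covering those TFs.
#' @param seed Optional integer seed.
#' @return A list with `sequence` (string) and `sites` (tibble `tf`,
#'   `start`, `strand`; 1-based starts).
#' @export
plant_sequence <- function(length, counts_per_tf, tf_panel, seed = NULL) {
  counts_per_tf <- counts_per_tf[counts_per_tf > 0]
  widths <- vapply(tf_panel[names(counts_per_tf)], function(m) nrow(m$matrix), integer(1))
  if (sum(counts_per_tf * widths) > length) {
    abort("planted sites do not fit in the sequence",
      class = "mpraic_capacity_error"
    )
  }
  with_seed(seed, {
    background <- sample(DNA_LETTERS, length, replace = TRUE)
    tf_of_site <- rep(names(counts_per_tf), counts_per_tf)
    k <- length(tf_of_site)
    if (k == 0) {
      return(list(
        sequence = paste(background, collapse = ""),
        sites = tibble(tf = character(), start = integer(), strand = character())
      ))
    }
    tf_of_site <- sample(tf_of_site)
    w_of_site <- widths[tf_of_site]
    free <- length - sum(w_of_site)
    ## uniform composition of the free space into k + 1 gaps
    gaps <- if (free == 0) {
      rep(0L, k + 1)
    } else {
      dividers <- sort(sample.int(free + k, k))
      diff(c(0L, dividers, free + k + 1L)) - 1L
    }
    starts <- cumsum(c(1L, unname(w_of_site)[-k])) + cumsum(gaps[seq_len(k)])
    strands <- sample(c("+", "-"), k, replace = TRUE)
    for (i in seq_len(k)) {
      site <- consensus_seq(tf_panel[[tf_of_site[i]]])
      if (strands[i] == "-") site <- reverse_complement(site)
      background[starts[i]:(starts[i] + w_of_site[i] - 1)] <-
        strsplit(site, "", fixed = TRUE)[[1]]
    }
    list(
      sequence = paste(background, collapse = ""),
      sites = tibble(tf = tf_of_site, start = as.integer(starts), strand = strands) %>%
        arrange(.data$start)
    )
  })
}

#' Design of a synthetic MPRA library
#'
#' Defaults mirror the assayed retinal libraries: 164 bp elements with 3
#' barcodes each, a basal construct with 18 barcodes, 150 scrambled
#' controls, and a panel of one centering TF plus 7 partner TFs.
#'
#' @param n_per_class Named counts of intended constructs for
#'   strong_enhancer, weak_enhancer, inactive and silencer classes.
#' @param n_scrambled Number of scrambled control constructs.
#' @param n_basal_barcodes Barcodes on the basal construct.
#' @param barcodes_per_construct Barcodes per library element.
#' @param element_length Element length in bp.
#' @param tf_panel Named list of [motif_model()]s.
#' @param centering_tf Name of the centering TF (the panel member every
#'   genomic element is selected around; "CRX-like").
#' @param seed Integer seed for sequence generation.
#' @return A list with class `"library_design"`.
#' @export
library_design <- function(n_per_class = c(
                             strong_enhancer = 200, weak_enhancer = 200,
                             inactive = 200, silencer = 200
                           ),
                           n_scrambled = 150,
                           n_basal_barcodes = 18,
                           barcodes_per_construct = 3,
                           element_length = 164,
                           tf_panel = make_toy_pwms(8, width = 8, sharpness = 0.95),
                           centering_tf = names(tf_panel)[1],
                           seed = 1L) {
  stopifnot(
    all(n_per_class >= 0), n_scrambled >= 0,
    barcodes_per_construct >= 1, n_basal_barcodes >= 1,
    length(tf_panel) >= 1
  )
  need <- c("strong_enhancer", "weak_enhancer", "inactive", "silencer")
  if (!all(need %in% names(n_per_class))) {
    abort("n_per_class must name all four intended classes",
      class = "mpraic_parameter_error"
    )
  }
  if (!centering_tf %in% names(tf_panel)) {
    abort("centering_tf must be in the panel", class = "mpraic_parameter_error")
  }
  structure(
    list(
      n_per_class = n_per_class[need], n_scrambled = n_scrambled,
      n_basal_barcodes = n_basal_barcodes,
      barcodes_per_construct = barcodes_per_construct,
      element_length = element_length, tf_panel = tf_panel,
      centering_tf = centering_tf, seed = as.integer(seed)
    ),
    class = "library_design"
  )
}

#' Generative parameters for synthetic expression and counts
#'
#' `beta_act` is the log2-expression gain per distinct partner (non-centering)
#' TF present; `beta_sil` the log2 repression applied when the centering TF
#' is planted at two or more sites with no partner present; `noise_sd` the
#' per-construct, per-replicate log2 noise; `dna_depth_mean` and `dispersion`
#' parameterize the negative-binomial plasmid-pool counts.
#'
#' @param beta_act Activation gain (log2 per distinct partner TF).
#' @param beta_sil Silencing depth (log2).
#' @param noise_sd Replicate log2 noise SD (> 0).
#' @param dna_depth_mean Mean DNA count per barcode (>= 1).
#' @param dispersion Negative-binomial size parameter (> 0).
#' @param n_replicates Number of cDNA replicates.
#' @param seed Integer seed for count simulation.
#' @return A list with class `"generative_params"`.
#' @export
generative_params <- function(beta_act = 1.5, beta_sil = 2, noise_sd = 0.25,
                              dna_depth_mean = 500, dispersion = 4,
                              n_replicates = 3, seed = 1L) {
  if (noise_sd <= 0 || dispersion <= 0 || dna_depth_mean < 1) {
    abort("need noise_sd > 0, dispersion > 0, dna_depth_mean >= 1",
      class = "mpraic_parameter_error"
    )
  }
  structure(
    list(
      beta_act = beta_act, beta_sil = beta_sil, noise_sd = noise_sd,
      dna_depth_mean = dna_depth_mean, dispersion = dispersion,
      n_replicates = n_replicates, seed = as.integer(seed)
    ),
    class = "generative_params"
  )
}

true_log2_expression <- function(n_center, n_partner_distinct, params) {
  silenced <- n_center >= 2 & n_partner_distinct == 0
  params$beta_act * n_partner_distinct - params$beta_sil * as.numeric(silenced)
}

#' Simulate a motif-planted sequence library
#'
#' Intended silencers get 3-4 centering-TF sites and no partners; intended
#' strong enhancers get 1-2 centering sites plus one site for each of 2-3
#' distinct partners; weak enhancers one centering site plus one partner;
#' inactive at most one centering site; scrambled controls get no planted
#' sites. The true mean log2 expression of each construct is
#' `beta_act * D - beta_sil * [centering sites >= 2 and D = 0]` where `D`
#' is the number of distinct partner TFs planted; basal is 0.
#'
#' @param design A [library_design()].
#' @param params A [generative_params()].
#' @return A list with `sequences` (tibble `id`, `sequence`, `group`,
#'   `category`), `truth` (tibble `construct`, `intended_class`,
#'   `n_center`, `n_partner_distinct`, `true_m`), `sites` (planted
#'   ground-truth site tibble) and `annotation`.
#' @export
simulate_library <- function(design, params = generative_params()) {
  partners <- setdiff(names(design$tf_panel), design$centering_tf)
  with_seed(design$seed, {
    specs <- list()
    for (cls in names(design$n_per_class)) {
      n <- design$n_per_class[[cls]]
      if (n == 0) next
      for (i in seq_len(n)) {
        counts <- switch(cls,
          strong_enhancer = {
            d <- sample(2:min(3, length(partners)), 1)
            stats::setNames(
              c(sample(1:2, 1), rep(1, d)),
              c(design$centering_tf, sample(partners, d))
            )
          },
          weak_enhancer = stats::setNames(
            c(1, 1), c(design$centering_tf, sample(partners, 1))
          ),
          inactive = {
            n_c <- sample(0:1, 1)
            if (n_c == 0) integer(0) else stats::setNames(n_c, design$centering_tf)
          },
          silencer = stats::setNames(sample(3:4, 1), design$centering_tf)
        )
        specs[[paste0(cls, "_", sprintf("%03d", i))]] <- counts
      }
    }
    for (i in seq_len(design$n_scrambled)) {
      specs[[paste0("scrambled_", sprintf("%03d", i))]] <- integer(0)
    }

    planted <- purrr::imap(specs, function(counts, id) {
      plant_sequence(design$element_length, counts, design$tf_panel)
    })
    ids <- names(specs)
    intended <- sub("_[0-9]+$", "", ids)
    n_center <- unname(vapply(
      specs,
      function(cts) sum(cts[names(cts) == design$centering_tf]), numeric(1)
    ))
    n_partner <- unname(vapply(
      specs,
      function(cts) sum(names(cts) != design$centering_tf), numeric(1)
    ))
    truth <- tibble(
      construct = ids,
      intended_class = intended,
      n_center = n_center,
      n_partner_distinct = n_partner,
      true_m = true_log2_expression(n_center, n_partner, params)
    )
    truth$true_m[truth$intended_class == "scrambled"] <- 0
    sequences <- tibble(
      id = ids,
      sequence = unname(vapply(planted, function(p) p$sequence, character(1))),
      group = if_else(intended == "scrambled", "scrambled", "genomic"),
      category = "synthetic"
    )
    sites <- purrr::imap_dfr(planted, function(p, id) {
      if (nrow(p$sites) == 0) return(tibble())
      mutate(p$sites, id = id, .before = 1)
    })
    annotation <- sequences %>%
      select(construct = "id", "group", "category") %>%
      bind_rows(tibble(construct = "basal", group = "basal", category = "control"))
    truth <- bind_rows(truth, tibble(
      construct = "basal", intended_class = "basal",
      n_center = 0, n_partner_distinct = 0, true_m = 0
    ))
    list(
      sequences = sequences, truth = truth,
      sites = sites, annotation = annotation
    )
  })
}

#' Simulate barcode counts for a library
#'
#' DNA counts per barcode are negative-binomial with mean `dna_depth_mean`
#' and size `dispersion`; each cDNA replicate draws Poisson counts around
#' `DNA * 2^(m + eps)` with `eps ~ N(0, noise_sd)` per construct and
#' replicate.
#'
#' @param truth A truth tibble (`construct`, `true_m`) as from
#'   [simulate_library()].
#' @param design A [library_design()].
#' @param params A [generative_params()].
#' @return A long barcode count tibble (columns `barcode`, `construct`,
#'   `sample`, `count`, `sample_type`), deterministic given `params$seed`.
#' @export
simulate_counts <- function(truth, design, params = generative_params()) {
  with_seed(params$seed, {
    n_bc <- if_else(truth$construct == "basal",
      design$n_basal_barcodes, design$barcodes_per_construct
    )
    bc <- tibble(
      construct = rep(truth$construct, n_bc),
      true_m = rep(truth$true_m, n_bc)
    ) %>%
      group_by(.data$construct) %>%
      mutate(barcode = paste0(.data$construct, "_bc", dplyr::row_number())) %>%
      ungroup()
    bc$dna <- rnbinom(nrow(bc), mu = params$dna_depth_mean, size = params$dispersion)

    eps <- matrix(
      rnorm(nrow(truth) * params$n_replicates, 0, params$noise_sd),
      nrow = nrow(truth),
      dimnames = list(truth$construct, NULL)
    )
    cdna <- purrr::map_dfr(seq_len(params$n_replicates), function(r) {
      mu <- bc$dna * 2^(bc$true_m + eps[bc$construct, r])
      tibble(
        barcode = bc$barcode, construct = bc$construct,
        sample = paste0("cDNA_", r),
        count = as.numeric(rpois(nrow(bc), mu))
      )
    })
    dna <- tibble(
      barcode = bc$barcode, construct = bc$construct,
      sample = "DNA", count = as.numeric(bc$dna)
    )
    bind_rows(dna, cdna) %>%
      mutate(sample_type = if_else(.data$sample == "DNA", "DNA", "cDNA"))
  })
}

#' Simulate a complete synthetic MPRA experiment
#'
#' @inheritParams simulate_counts
#' @return A list with `sequences`, `truth`, `sites`, `annotation`, `counts`.
#' @export
simulate_mpra <- function(design = library_design(),
                          params = generative_params()) {
  lib <- simulate_library(design, params)
  lib$counts <- simulate_counts(lib$truth, design, params)
  lib
}
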
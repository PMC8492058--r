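## Motif grammar diagnostics: pairwise motif co-occurrence against the
## independence expectation, and the 5'/3' arrangement test that asks
## whether a partner motif shows a positional bias relative to the
## centering TF's site.

#' Observed and expected motif co-occurrence
#'
#' For every TF pair, the observed fraction of sequences containing both
#' motifs and the fraction expected if presence were independent (the
#' product of the marginals).
#'
#' @param presence A [motif_presence()] tibble (`id` plus logical TF
#'   columns), optionally pre-filtered to one activity class.
#' @return A tibble with `tf1`, `tf2`, `observed`, `expected` for all
#'   ordered pairs (symmetric).
#' @export
cooccurrence <- function(presence) {
  tf_cols <- setdiff(names(presence), "id")
  if (nrow(presence) == 0) {
    abort("empty sequence subset", class = "mpraic_input_error")
  }
  mat <- as.matrix(presence[, tf_cols])
  storage.mode(mat) <- "double"
  n <- nrow(mat)
  marg <- colMeans(mat)
  obs <- crossprod(mat) / n
  tidyr::expand_grid(tf1 = tf_cols, tf2 = tf_cols) %>%
    mutate(
      observed = unname(obs[cbind(.data$tf1, .data$tf2)]),
      expected = as.numeric(marg[.data$tf1]) * as.numeric(marg[.data$tf2])
    )
}

#' 5'/3' positional-bias test for a partner TF
#'
#' Restricts to sequences with exactly one occupied site for the centering
#' TF and exactly one for the partner, counts how often the partner site
#' lies 5' versus 3' of the centering site (by motif center), and applies a
#' two-sided exact binomial test against an even split.
#'
#' @param site_list An [occupied_sites()] tibble.
#' @param centering_tf,partner_tf TF names.
#' @return A one-row tibble `partner`, `n5`, `n3`, `n`, `p_value`
#'   (`p_value` is NA when no sequence qualifies).
#' @export
positional_bias_test <- function(site_list, centering_tf, partner_tf) {
  one_site <- site_list %>%
    filter(.data$tf %in% c(centering_tf, partner_tf)) %>%
    group_by(.data$id, .data$tf) %>%
    summarise(n_sites = dplyr::n(), center = .data$center[1], .groups = "drop")
  eligible <- one_site %>%
    group_by(.data$id) %>%
    filter(all(.data$n_sites == 1), dplyr::n() == 2) %>%
    ungroup()
  pos <- eligible %>%
    tidyr::pivot_wider(
      id_cols = "id", names_from = "tf", values_from = "center"
    )
  if (nrow(pos) == 0 || !all(c(centering_tf, partner_tf) %in% names(pos))) {
    return(tibble(
      partner = partner_tf, n5 = 0L, n3 = 0L, n = 0L, p_value = NA_real_
    ))
  }
  n5 <- sum(pos[[partner_tf]] < pos[[centering_tf]])
  n3 <- sum(pos[[partner_tf]] > pos[[centering_tf]])
  n <- n5 + n3
  p <- if (n == 0) NA_real_ else binom.test(n5, n, p = 0.5)$p.value
  tibble(partner = partner_tf, n5 = n5, n3 = n3, n = n, p_value = p)
}

#' Positional-bias scan over a panel of partner TFs
#'
#' Runs [positional_bias_test()] for every partner against the centering TF
#' and corrects the p-values by Benjamini-Hochberg FDR.
#'
#' @param site_list An [occupied_sites()] tibble.
#' @param centering_tf Name of the centering TF.
#' @param partners Character vector of partner TF names; defaults to every
#'   other TF in the site list.
#' @return A tibble with one row per partner and a `q_value` column.
#' @export
positional_bias_scan <- function(site_list, centering_tf, partners = NULL) {
  partners <- partners %||% setdiff(unique(site_list$tf), centering_tf)
  out <- purrr::map_dfr(partners, positional_bias_test,
    site_list = site_list, centering_tf = centering_tf
  )
  out$q_value <- bh_fdr(out$p_value)
  out
}
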
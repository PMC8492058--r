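#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted classifier
#'
#' @param x An `"mpra_classifier"`.
#' @param ... Unused.
#' @return For logistic fits, a tibble of `term`/`estimate` coefficients on
#'   the standardized feature scale; for the spectrum SVM, `term`/`weight`
#'   per canonical k-mer.
#' @method tidy mpra_classifier
#' @export
tidy.mpra_classifier <- function(x, ...) {
  if (x$model == "svm") {
    tibble(term = names(x$weights), weight = unname(x$weights)) %>%
      arrange(dplyr::desc(abs(.data$weight)))
  } else {
    tibble(term = names(x$coefficients), estimate = unname(x$coefficients))
  }
}

#' One-row performance summary of a fitted classifier
#'
#' @param x An `"mpra_classifier"`.
#' @param ... Unused.
#' @return A tibble with `model`, `auroc`, `auroc_sd`, `aupr`, `aupr_sd`,
#'   `C`, `n_folds`.
#' @method glance mpra_classifier
#' @export
glance.mpra_classifier <- function(x, ...) {
  tibble(
    model = x$model,
    auroc = x$auroc, auroc_sd = x$auroc_sd,
    aupr = x$aupr, aupr_sd = x$aupr_sd,
    C = x$C, n_folds = nrow(x$cv)
  )
}
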
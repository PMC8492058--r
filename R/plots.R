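## ggplot2 views of the main result types. Colors follow the convention of
## the retinal MPRA literature: strong enhancers dark blue, weak enhancers
## light blue, inactive green, silencers red, ambiguous grey.

CLASS_COLORS <- c(
  strong_enhancer = "#08306b", weak_enhancer = "#6baed6",
  inactive = "#41ab5d", silencer = "#cb181d", ambiguous = "grey60"
)

#' Volcano plot of activity calls
#'
#' log2 activity against -log10 q-value, colored by activity class, with
#' the fold-change and FDR cutoffs drawn in.
#'
#' @param calls A [call_activity()] tibble.
#' @param config An [mpra_config()] (for the cutoff guide lines).
#' @return A ggplot object.
#' @export
plot_activity_volcano <- function(calls, config = mpra_config()) {
  ggplot2::ggplot(
    dplyr::filter(calls, !is.na(.data$q_value)),
    ggplot2::aes(.data$log2_activity, -log10(.data$q_value), color = .data$class)
  ) +
    ggplot2::geom_point(size = 0.6, alpha = 0.7) +
    ggplot2::geom_hline(yintercept = -log10(config$fdr_alpha), linetype = 2) +
    ggplot2::geom_vline(
      xintercept = c(-log2(config$fold_cutoff), log2(config$fold_cutoff)),
      linetype = 2
    ) +
    ggplot2::scale_color_manual(values = CLASS_COLORS, drop = FALSE) +
    ggplot2::labs(
      x = "log2 activity (vs basal)", y = "-log10 q",
      color = "class"
    ) +
    ggplot2::theme_classic()
}

#' Bar plot of activity-class fractions
#'
#' @param calls A [call_activity()] tibble.
#' @return A ggplot object.
#' @export
plot_class_fractions <- function(calls) {
  frac <- calls %>%
    dplyr::count(.data$class, .drop = FALSE) %>%
    mutate(fraction = .data$n / sum(.data$n))
  ggplot2::ggplot(frac, ggplot2::aes(.data$class, .data$fraction, fill = .data$class)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = CLASS_COLORS, drop = FALSE) +
    ggplot2::labs(x = NULL, y = "fraction of constructs") +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_classic() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Information content by activity class
#'
#' @param ic A tibble with `bits` and `class` columns (e.g.
#'   [information_content()] output joined to activity calls).
#' @return A ggplot object.
#' @export
plot_information_content <- function(ic) {
  ggplot2::ggplot(ic, ggplot2::aes(.data$class, .data$bits, fill = .data$class)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::scale_fill_manual(values = CLASS_COLORS, drop = FALSE) +
    ggplot2::labs(x = NULL, y = "information content (bits)") +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_classic() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Fold-wise cross-validation metrics of a classifier
#'
#' @param object An `"mpra_classifier"`.
#' @param ... Unused.
#' @return A ggplot object showing per-fold AUROC and AUPR.
#' @method autoplot mpra_classifier
#' @export
autoplot.mpra_classifier <- function(object, ...) {
  long <- object$cv %>%
    tidyr::pivot_longer(dplyr::any_of(c("auroc", "aupr")),
      names_to = "metric", values_to = "value"
    )
  ggplot2::ggplot(long, ggplot2::aes(.data$metric, .data$value)) +
    ggplot2::geom_boxplot(width = 0.4, outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.08, height = 0) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 2, color = "grey50") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = "cross-validated value") +
    ggplot2::theme_classic()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
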
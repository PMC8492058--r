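#' Run configuration for the MPRA analysis pipeline
#'
#' Bundles the tunable constants of the pipeline. Defaults follow the
#' published retinal CRX MPRA protocol: a chemical potential of 9 on the
#' RT-scaled (2.5x natural log) energy axis, a motif-presence threshold of
#' 0.5 bound molecules, twofold activity cutoffs at FDR 0.05, the scrambled
#' 95th-percentile split for strong enhancers, expression pseudocounts of
#' 1e-3 (basal-promoter assay) and 1e-2 (promoterless assay), and barcode
#' count floors of 10 (DNA) / 5 (cDNA raw) for the basal-promoter assay and
#' 50 (DNA raw) / 8 (cDNA RPM) for the promoterless assay.
#'
#' @param mu Chemical potential (dimensionless, on the RT-scaled energy axis).
#' @param rt_scale Energy scale constant (RT at ~300 K in the units of the
#'   energy matrices).
#' @param presence_threshold Predicted occupancy (molecules) above which a
#'   TF's motifs are called present in a sequence.
#' @param fold_cutoff Fold-change versus basal separating enhancers/silencers
#'   from inactive sequences.
#' @param fdr_alpha Benjamini-Hochberg q-value cutoff.
#' @param strong_percentile Percentile of the scrambled-control activity
#'   distribution splitting strong from weak enhancers, in (0, 100).
#' @param pseudocount_rho Expression pseudocount for the basal-promoter assay.
#' @param pseudocount_polylinker Expression pseudocount for the promoterless
#'   assay.
#' @param dna_floor_rho,cdna_floor_rho Raw-count barcode filters for the
#'   basal-promoter assay.
#' @param dna_floor_polylinker Raw-count DNA filter for the promoterless assay.
#' @param cdna_rpm_floor_polylinker RPM-scale cDNA filter for the promoterless
#'   assay.
#' @param pwm_pseudocount Pseudocount added to letter probabilities before the
#'   energy transform, so database zeros stay finite.
#' @param cv_folds Number of stratified cross-validation folds.
#' @param seed Integer seed used wherever the pipeline draws random numbers.
#' @return A list with class `"mpra_config"`.
#' @export
#' @examples
#' cfg <- mpra_config(seed = 1)
#' cfg$mu
mpra_config <- function(mu = 9,
                        rt_scale = 2.5,
                        presence_threshold = 0.5,
                        fold_cutoff = 2,
                        fdr_alpha = 0.05,
                        strong_percentile = 95,
                        pseudocount_rho = 1e-3,
                        pseudocount_polylinker = 1e-2,
                        dna_floor_rho = 10,
                        cdna_floor_rho = 5,
                        dna_floor_polylinker = 50,
                        cdna_rpm_floor_polylinker = 8,
                        pwm_pseudocount = 1e-4,
                        cv_folds = 5,
                        seed = 1L) {
  cfg <- list(
    mu = mu, rt_scale = rt_scale,
    presence_threshold = presence_threshold,
    fold_cutoff = fold_cutoff, fdr_alpha = fdr_alpha,
    strong_percentile = strong_percentile,
    pseudocount_rho = pseudocount_rho,
    pseudocount_polylinker = pseudocount_polylinker,
    dna_floor_rho = dna_floor_rho, cdna_floor_rho = cdna_floor_rho,
    dna_floor_polylinker = dna_floor_polylinker,
    cdna_rpm_floor_polylinker = cdna_rpm_floor_polylinker,
    pwm_pseudocount = pwm_pseudocount,
    cv_folds = cv_folds, seed = as.integer(seed)
  )
  thresholds <- c(
    cfg$mu, cfg$rt_scale, cfg$presence_threshold, cfg$fold_cutoff,
    cfg$fdr_alpha, cfg$pseudocount_rho, cfg$pseudocount_polylinker,
    cfg$dna_floor_rho, cfg$cdna_floor_rho, cfg$dna_floor_polylinker,
    cfg$cdna_rpm_floor_polylinker, cfg$cv_folds
  )
  if (any(!is.finite(thresholds)) || any(thresholds <= 0)) {
    abort("all config thresholds must be positive and finite",
      class = "mpraic_config_error"
    )
  }
  if (cfg$strong_percentile <= 0 || cfg$strong_percentile >= 100) {
    abort("strong_percentile must lie in (0, 100)", class = "mpraic_config_error")
  }
  structure(cfg, class = "mpra_config")
}

#' @export
print.mpra_config <- function(x, ...) {
  cat("<mpra_config>\n")
  for (nm in names(x)) cat(sprintf("  %-26s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' Read or write a run configuration as YAML
#'
#' @param path File path.
#' @return `read_config()` returns an [mpra_config()]; `write_config()`
#'   returns `path` invisibly.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(mpra_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) {
    abort(paste0("unknown config fields: ", paste(unknown, collapse = ", ")),
      class = "mpraic_config_error"
    )
  }
  do.call(mpra_config, vals)
}

#' @rdname read_config
#' @param config An [mpra_config()].
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
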
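#' Run the two-level regulation analysis on preprocessed matrices
#'
#' Convenience wrapper over the model layer: computes RNA-level residuals
#' (constant precursor) and protein-level residuals (RNA precursor) for each
#' replicate, fits the change-point model per replicate, derives the
#' FDR-controlled CPS threshold per level x replicate, and collects the
#' significant events.
#'
#' @param rna_reps,protein_reps lists of log-scale [expr_matrix] objects,
#'   one per replicate, on a shared gene set and grid.
#' @param config a [peca_config].
#' @param target_fdr FDR level for the CPS thresholds.
#' @return list with `rna` and `protein`, each containing per-replicate
#'   `fits`, `thresholds` (with attained estFDR) and `events`.
#' @export
peca_pipeline <- function(rna_reps, protein_reps,
                          config = peca_config(), target_fdr = 0.05) {
  stopifnot(length(rna_reps) == length(protein_reps))
  run_level <- function(residual_fun) {
    fits <- lapply(seq_along(rna_reps), function(r)
      fit_peca(residual_fun(r), config))
    thr <- lapply(fits, function(f)
      fdr_threshold(as.vector(f$cps), target_fdr))
    ev <- lapply(seq_along(fits), function(r)
      significant_events(fits[[r]], thr[[r]]$threshold))
    list(fits = fits, thresholds = thr, events = ev)
  }
  list(rna = run_level(function(r) compute_residuals(rna_reps[[r]])),
       protein = run_level(function(r)
         compute_residuals(protein_reps[[r]], rna_reps[[r]])))
}
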
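#' Phase definition for an 8-point stress time course
#'
#' Interior time points are grouped into the response phases used to
#' summarize regulation: early (< 2 h), intermediate (2-8 h, both boundary
#' points included), late (> 8 h).
#'
#' @param time_grid ordered hours.
#' @return data frame with columns `time` (interior points) and `phase`.
#' @export
phase_definition <- function(time_grid = c(0, 0.5, 1, 2, 8, 16, 24, 30)) {
  ip <- interior_points(time_grid)
  phase <- ifelse(ip < 2, "early", ifelse(ip <= 8, "intermediate", "late"))
  if (any(!c("early", "intermediate", "late") %in% phase))
    stop("a phase has no interior points on this grid")
  data.frame(time = ip,
             phase = factor(phase, c("early", "intermediate", "late")))
}

#' Per-phase regulation calls from change point scores
#'
#' Summarizes a fitted replicate by the maximum CPS within each phase; a
#' gene is significantly regulated in a phase if that maximum reaches the
#' FDR-derived threshold. Direction is taken at the maximizing interior
#' point, ties broken toward the earlier time point.
#'
#' @param fit a `peca_fit` (one level, one replicate).
#' @param threshold CPS cutoff from [fdr_threshold] (`NA` = nothing
#'   significant).
#' @param phases a [phase_definition] on the fit's time grid.
#' @return data frame: `gene_id`, `level`, `phase`, `max_cps`, `time` (the
#'   maximizing interior point), `direction`, `significant`.
#' @export
phase_calls <- function(fit, threshold,
                        phases = phase_definition(fit$time_grid)) {
  stopifnot(inherits(fit, "peca_fit"))
  ip <- interior_points(fit$time_grid)
  out <- lapply(levels(phases$phase), function(ph) {
    cols <- which(ip %in% phases$time[phases$phase == ph])
    if (length(cols) == 0) stop("phase ", ph, " has no interior points")
    sub <- fit$cps[, cols, drop = FALSE]
    j <- max.col(sub, ties.method = "first")
    idx <- cbind(seq_len(nrow(sub)), j)
    data.frame(gene_id = rownames(fit$cps),
               level = fit$level,
               phase = ph,
               max_cps = sub[idx],
               time = ip[cols][j],
               direction = fit$direction[, cols, drop = FALSE][idx],
               row.names = NULL)
  })
  out <- do.call(rbind, out)
  out$phase <- factor(out$phase, levels(phases$phase))
  out$significant <- !is.na(threshold) & out$max_cps >= threshold
  out
}

direction_class <- function(calls) {
  ifelse(calls$significant, calls$direction, "none")
}

#' Joint RNA x protein direction table for one phase
#'
#' Cross-tabulates genes by their RNA-level and protein-level regulation
#' class (up / none / down) in a phase; a non-significant phase call counts
#' as "none". Each shared gene is counted exactly once.
#'
#' @param rna_calls,protein_calls [phase_calls] tables for the same
#'   replicate.
#' @param phase `"early"`, `"intermediate"` or `"late"`.
#' @return 3 x 3 contingency table (RNA up/none/down x protein up/none/down).
#' @export
contingency_table <- function(rna_calls, protein_calls, phase) {
  r <- rna_calls[rna_calls$phase == phase, , drop = FALSE]
  p <- protein_calls[protein_calls$phase == phase, , drop = FALSE]
  shared <- intersect(r$gene_id, p$gene_id)
  if (length(shared) < length(union(r$gene_id, p$gene_id)))
    warning("genes present at only one level were excluded")
  r <- r[match(shared, r$gene_id), ]
  p <- p[match(shared, p$gene_id), ]
  lv <- c("up", "none", "down")
  table(RNA = factor(direction_class(r), lv),
        protein = factor(direction_class(p), lv))
}

theta_anticorrelated <- function(theta_rna, theta_protein) {
  ok <- apply(theta_rna, 1, stats::sd) > 0 &
    apply(theta_protein, 1, stats::sd) > 0
  r <- rep(NA_real_, nrow(theta_rna))
  r[ok] <- sapply(which(ok), function(g)
    stats::cor(theta_rna[g, ], theta_protein[g, ]))
  !is.na(r) & r < 0
}

#' Genes with discordant RNA- and protein-level regulation
#'
#' A gene is discordant when its RNA-level and protein-level rate-ratio
#' trajectories are negatively correlated in *both* replicates, and it has
#' at least one significant regulatory event at each level (in at least one
#' replicate). Genes whose theta trajectory has zero variance in any
#' replicate are excluded (correlation undefined).
#'
#' @param rna_fits,protein_fits lists of `peca_fit` objects, one per
#'   replicate, same order.
#' @param rna_thresholds,protein_thresholds per-replicate CPS cutoffs from
#'   [fdr_threshold].
#' @return data frame of discordant genes with per-replicate theta
#'   correlations and the replicates in which each level had a significant
#'   event.
#' @export
discordant_genes <- function(rna_fits, protein_fits,
                             rna_thresholds, protein_thresholds) {
  stopifnot(length(rna_fits) == length(protein_fits))
  n_rep <- length(rna_fits)
  genes <- rownames(rna_fits[[1]]$theta_mean)
  cors <- vapply(seq_len(n_rep), function(r) {
    tr <- rna_fits[[r]]$theta_mean[genes, , drop = FALSE]
    tp <- protein_fits[[r]]$theta_mean[genes, , drop = FALSE]
    ok <- apply(tr, 1, stats::sd) > 0 & apply(tp, 1, stats::sd) > 0
    out <- rep(NA_real_, length(genes))
    out[ok] <- sapply(which(ok), function(g) stats::cor(tr[g, ], tp[g, ]))
    out
  }, numeric(length(genes)))
  cors <- matrix(cors, nrow = length(genes))
  anti <- rowSums(!is.na(cors) & cors < 0) == n_rep
  sig_in <- function(fits, thresholds) {
    hit <- vapply(seq_len(n_rep), function(r) {
      ev <- significant_events(fits[[r]], thresholds[[r]])
      genes %in% ev$gene_id
    }, logical(length(genes)))
    matrix(hit, nrow = length(genes))
  }
  rna_sig <- sig_in(rna_fits, rna_thresholds)
  prot_sig <- sig_in(protein_fits, protein_thresholds)
  keep <- anti & rowSums(rna_sig) >= 1 & rowSums(prot_sig) >= 1
  data.frame(gene_id = genes,
             theta_cor = I(cors),
             rna_sig_replicates = apply(rna_sig, 1, function(x)
               paste(which(x), collapse = ",")),
             protein_sig_replicates = apply(prot_sig, 1, function(x)
               paste(which(x), collapse = ",")),
             row.names = NULL)[keep, , drop = FALSE]
}

#' Buffered genes: discordant regulation with constant protein output
#'
#' Retains discordant genes whose protein concentration spans less than
#' `fold_cut`-fold (max/min over the time course) in both replicates —
#' mRNA-level changes counterbalanced so the protein stays flat.
#'
#' @param discordant data frame from [discordant_genes] (or a character
#'   vector of gene ids).
#' @param protein_reps list of protein [expr_matrix] objects per replicate
#'   (natural or log scale).
#' @param fold_cut maximum allowed fold span (default 1.5).
#' @return character vector of buffered gene ids.
#' @export
buffered_genes <- function(discordant, protein_reps, fold_cut = 1.5) {
  ids <- if (is.data.frame(discordant)) discordant$gene_id else discordant
  if (length(ids) == 0) return(character(0))
  spans <- sapply(protein_reps, function(m) {
    v <- unclass(m)[ids, , drop = FALSE]
    if (attr(m, "scale") == "log") v <- exp(v)
    apply(v, 1, function(x) max(x) / min(x))
  })
  spans <- matrix(spans, nrow = length(ids))
  ids[rowSums(spans < fold_cut) == ncol(spans)]
}

#' Divergence of the expression state from time zero
#'
#' For each time point: the squared Pearson correlation between the gene
#' expression vector at that time and at time 0 (how much the ranking of
#' absolute levels is preserved), and the mean and SD over genes of the
#' absolute base-10 log fold change relative to time 0 (how large the
#' relative changes are).
#'
#' @param x log-scale (natural log) [expr_matrix].
#' @return data frame: `time`, `r_squared`, `mean_abs_log10_fc`,
#'   `sd_abs_log10_fc`. `r_squared` is `NA` when a time point has zero
#'   variance across genes.
#' @export
divergence_curves <- function(x) {
  stopifnot_expr(x, scale = "log")
  v <- unclass(x)
  tg <- attr(x, "time_grid")
  base <- v[, 1]
  out <- lapply(seq_along(tg), function(j) {
    r2 <- if (stats::sd(v[, j]) == 0 || stats::sd(base) == 0) NA_real_
          else stats::cor(base, v[, j])^2
    lfc <- abs(v[, j] - base) / log(10)
    data.frame(time = tg[j], r_squared = r2,
               mean_abs_log10_fc = mean(lfc),
               sd_abs_log10_fc = stats::sd(lfc))
  })
  do.call(rbind, out)
}
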
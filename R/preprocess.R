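#' Natural-log transform
#'
#' @param x natural-scale [expr_matrix] with strictly positive observed
#'   values.
#' @return the matrix on the log scale.
#' @export
log_transform <- function(x) {
  stopifnot_expr(x, scale = "natural")
  bad <- which(x <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("non-positive value for gene %s at %s h: cannot log-transform",
                 rownames(x)[bad[1, 1]],
                 format(attr(x, "time_grid")[bad[1, 2]])))
  }
  expr_matrix(log(unclass(x)), attr(x, "time_grid"),
              level = attr(x, "level"), scale = "log")
}

#' Quantile normalization across time points
#'
#' Forces every column (time point) of a log-scale matrix onto the common
#' distribution given by the across-column mean of sorted values. Ties share
#' the mean of their rank positions' reference values. Delegates to
#' \code{limma::normalizeQuantiles}.
#'
#' @param x log-scale [expr_matrix] with at least two columns.
#' @return normalized matrix, same shape and metadata.
#' @export
quantile_normalize <- function(x) {
  stopifnot_expr(x, scale = "log")
  if (ncol(x) < 2) stop("need at least 2 columns")
  if (any(colSums(!is.na(unclass(x))) == 0)) stop("column with all values missing")
  out <- limma::normalizeQuantiles(unclass(x), ties = TRUE)
  dimnames(out) <- dimnames(x)
  expr_matrix(out, attr(x, "time_grid"),
              level = attr(x, "level"), scale = "log")
}

#' Sum normalization of LFQ intensities, excluding top intensities
#'
#' Divides each column (sample) of a natural-scale protein matrix by the sum
#' of its values after removing the `ceiling(top_fraction * n_genes)` largest
#' values of that column, so extremely abundant proteins cannot dominate the
#' normalizing factor.
#'
#' @param x natural-scale protein [expr_matrix].
#' @param top_fraction fraction of top intensities excluded per column.
#' @return normalized matrix (natural scale).
#' @export
lfq_sum_normalize <- function(x, top_fraction = 0.05) {
  stopifnot_expr(x, scale = "natural")
  n_excl <- ceiling(top_fraction * nrow(x))
  v <- unclass(x)
  norm <- apply(v, 2, function(col) {
    obs <- col[!is.na(col)]
    keep <- sort(obs, decreasing = TRUE)
    sum(keep[-seq_len(min(n_excl, length(keep) - 1L))])
  })
  if (any(norm <= 0)) stop("non-positive normalizing sum")
  expr_matrix(sweep(v, 2, norm, "/"), attr(x, "time_grid"),
              level = attr(x, "level"), scale = "natural")
}

#' Complete-case gene filter across all matrices
#'
#' Returns the genes present in every supplied matrix with no missing value
#' anywhere, i.e. complete time series at both molecular levels in all
#' replicates.
#'
#' @param matrices list of [expr_matrix] objects (all levels x replicates).
#' @return character vector of retained gene ids (possibly empty, with a
#'   warning).
#' @export
complete_case_filter <- function(matrices) {
  stopifnot(length(matrices) >= 1)
  ids <- Reduce(intersect, lapply(matrices, rownames))
  keep <- ids
  for (m in matrices) {
    ok <- rowSums(is.na(unclass(m)[keep, , drop = FALSE])) == 0
    keep <- keep[ok]
  }
  if (length(keep) == 0) warning("no gene passes the complete-case filter")
  keep
}

#' Jackknife TRV spikiness of a time series
#'
#' Deletes one point at a time and records the total range of variation
#' (max - min) of the remainder; spikiness is median(TRV) / min(TRV). A
#' single aberrant point inflates every TRV except the one where it was
#' deleted, driving the ratio up. Conventions: a constant series (all TRVs
#' zero) scores 1 (maximally clean); min(TRV) = 0 with median > 0 scores
#' `Inf` (flat except for one spike, maximally spiky).
#'
#' @param series numeric vector, length >= 3, no missing values.
#' @return list with `spikiness` and the jackknife `trv_values`.
#' @export
trv_spikiness <- function(series) {
  if (length(series) < 3) stop("series must have length >= 3")
  if (anyNA(series)) stop("series must be complete")
  n <- length(series)
  trv <- vapply(seq_len(n), function(j) {
    s <- series[-j]
    max(s) - min(s)
  }, numeric(1))
  med <- stats::median(trv)
  mn <- min(trv)
  spik <- if (med == 0 && mn == 0) 1 else if (mn == 0) Inf else med / mn
  list(spikiness = spik, trv_values = trv)
}

#' TRV spikiness filter
#'
#' Retains genes whose jackknife TRV spikiness is strictly below the
#' threshold (3 for RNA, 2 for protein by default — protein data are held to
#' the stricter standard).
#'
#' @param x log-scale [expr_matrix] without missing values.
#' @param threshold spikiness cutoff; genes with spikiness `< threshold` are
#'   retained. Defaults to 3 for RNA matrices and 2 for protein.
#' @return list with `matrix` (retained genes) and `report` (data frame with
#'   per-gene spikiness and retention flag; `trv_values` as a list column).
#' @export
trv_filter <- function(x, threshold = if (attr(x, "level") == "RNA") 3 else 2) {
  stopifnot_expr(x, scale = "log")
  res <- apply(unclass(x), 1, trv_spikiness)
  spik <- vapply(res, `[[`, numeric(1), "spikiness")
  retained <- spik < threshold
  report <- data.frame(gene_id = rownames(x), spikiness = spik,
                       retained = retained, row.names = NULL)
  report$trv_values <- lapply(res, `[[`, "trv_values")
  list(matrix = x[retained, , drop = FALSE], report = report)
}

#' Lowess smoothing on the hour axis
#'
#' Robust locally weighted regression of a gene's series against actual
#' hours (the grid is strongly uneven: gaps range from 0.5 h to 8 h), via
#' \code{stats::lowess} with its default span and robustifying iterations.
#'
#' @param series numeric vector on the time grid.
#' @param time_grid hours, same length.
#' @param span fraction of points entering each local fit.
#' @param iterations robustifying iterations.
#' @return smoothed series evaluated at the original time points.
#' @export
lowess_smooth <- function(series, time_grid, span = 2 / 3, iterations = 3) {
  if (length(series) < 4) stop("need >= 4 points")
  fit <- stats::lowess(time_grid, series, f = span, iter = iterations)
  # lowess returns sorted x; map back to original order
  fit$y[match(time_grid, fit$x)]
}

#' Smooth every gene of a matrix
#'
#' @param x log-scale [expr_matrix].
#' @inheritParams lowess_smooth
#' @return smoothed matrix.
#' @export
lowess_smooth_matrix <- function(x, span = 2 / 3, iterations = 3) {
  stopifnot_expr(x, scale = "log")
  tg <- attr(x, "time_grid")
  out <- t(apply(unclass(x), 1, lowess_smooth, time_grid = tg,
                 span = span, iterations = iterations))
  dimnames(out) <- dimnames(x)
  expr_matrix(out, tg, level = attr(x, "level"), scale = "log")
}

#' Replicate consistency measure
#'
#' Pearson correlation between the two replicates' time series for one gene,
#' with the two-sided p-value from the t transformation on n - 2 degrees of
#' freedom. At n = 8 points, r just above 0.7 corresponds to p just below
#' 0.05.
#'
#' @param series_rep1,series_rep2 equal-length (>= 3) complete series.
#' @return list with `correlation` and `p_value`; both `NA` when either
#'   series has zero variance.
#' @export
rcm <- function(series_rep1, series_rep2) {
  if (length(series_rep1) != length(series_rep2)) stop("unequal lengths")
  if (length(series_rep1) < 3) stop("need >= 3 points")
  if (anyNA(series_rep1) || anyNA(series_rep2)) stop("series must be complete")
  if (stats::sd(series_rep1) == 0 || stats::sd(series_rep2) == 0)
    return(list(correlation = NA_real_, p_value = NA_real_))
  ct <- stats::cor.test(series_rep1, series_rep2, method = "pearson")
  list(correlation = unname(ct$estimate), p_value = ct$p.value)
}

#' Full preprocessing for one molecular level
#'
#' Applies the level-appropriate normalization and filtering chain:
#' RNA: log transform, quantile normalization (per replicate), complete-case
#' filter, TRV filter, lowess smoothing. Protein: LFQ-sum normalization on
#' the natural scale, then log transform and the same chain with the protein
#' TRV threshold.
#'
#' @param replicates list of natural-scale [expr_matrix] objects, one per
#'   replicate, same level.
#' @param trv_threshold spikiness cutoff; default by level (RNA 3, protein 2).
#' @param smooth apply lowess smoothing (default TRUE).
#' @return list with `replicates` (processed log-scale matrices restricted
#'   to genes passing all filters in every replicate) and `reports` (TRV
#'   filter reports per replicate).
#' @export
preprocess_level <- function(replicates, trv_threshold = NULL, smooth = TRUE) {
  stopifnot(length(replicates) >= 1)
  level <- attr(replicates[[1]], "level")
  if (is.null(trv_threshold)) trv_threshold <- if (level == "RNA") 3 else 2
  if (level == "protein")
    replicates <- lapply(replicates, lfq_sum_normalize)
  logged <- lapply(replicates, log_transform)
  if (level == "RNA")
    logged <- lapply(logged, quantile_normalize)
  complete <- complete_case_filter(logged)
  logged <- lapply(logged, function(m) m[complete, , drop = FALSE])
  filtered <- lapply(logged, trv_filter, threshold = trv_threshold)
  keep <- Reduce(intersect, lapply(filtered, function(f) rownames(f$matrix)))
  out <- lapply(logged, function(m) m[keep, , drop = FALSE])
  if (smooth) out <- lapply(out, lowess_smooth_matrix)
  list(replicates = out, reports = lapply(filtered, `[[`, "report"))
}
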
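#' Combine RNA and protein profiles into one clustering matrix
#'
#' Concatenates each gene's RNA and protein time series across replicates
#' into one row and centers every row, so that correlation distance compares
#' profile shapes rather than absolute levels.
#'
#' @param rna_reps,protein_reps lists of log-scale [expr_matrix] objects per
#'   replicate, on a shared gene set.
#' @return numeric matrix, genes x concatenated time points, rows centered.
#' @export
combine_profiles <- function(rna_reps, protein_reps) {
  mats <- c(rna_reps, protein_reps)
  genes <- Reduce(intersect, lapply(mats, rownames))
  m <- do.call(cbind, lapply(mats, function(x)
    unclass(x)[genes, , drop = FALSE]))
  m - rowMeans(m)
}

#' Cluster combined expression profiles
#'
#' Agglomerative clustering with correlation distance (1 - Pearson
#' correlation between rows) and average linkage. `static_cut` cuts the
#' dendrogram at a fixed height (default 0.604). `dynamic_tree_cut` is a
#' simplified hybrid variant: the static cut is refined by reassigning every
#' cluster smaller than `min_size` to the large cluster whose mean profile
#' it correlates with best, yielding only clusters of at least `min_size`
#' genes. Cluster ids are assigned in decreasing order of size.
#'
#' @param x matrix of centered profiles (rows = genes), e.g. from
#'   [combine_profiles].
#' @param method `"static_cut"` or `"dynamic_tree_cut"`.
#' @param cut dendrogram height for the static cut.
#' @param min_size minimum cluster size for the dynamic mode.
#' @return data frame `gene_id`, `cluster_id`, `method`, with the `hclust`
#'   tree attached as attribute `"tree"`.
#' @export
cluster_profiles <- function(x, method = c("static_cut", "dynamic_tree_cut"),
                             cut = 0.604, min_size = 30L) {
  method <- match.arg(method)
  if (nrow(x) < 2) stop("need at least 2 genes to cluster")
  d <- stats::as.dist(1 - stats::cor(t(x)))
  tree <- stats::hclust(d, method = "average")
  cl <- stats::cutree(tree, h = cut)
  if (method == "dynamic_tree_cut") {
    sizes <- table(cl)
    big <- as.integer(names(sizes)[sizes >= min_size])
    if (length(big) > 0 && length(big) < length(sizes)) {
      centers <- sapply(big, function(k)
        colMeans(x[cl == k, , drop = FALSE]))
      small_genes <- which(!cl %in% big)
      best <- apply(stats::cor(t(x[small_genes, , drop = FALSE]),
                               centers), 1, which.max)
      cl[small_genes] <- big[best]
    }
  }
  # relabel by decreasing size, ties by first appearance
  sizes <- sort(table(cl), decreasing = TRUE)
  relab <- stats::setNames(seq_along(sizes), names(sizes))
  out <- data.frame(gene_id = rownames(x),
                    cluster_id = unname(relab[as.character(cl)]),
                    method = method, row.names = NULL)
  attr(out, "tree") <- tree
  out
}

#' Cluster-averaged rate-ratio trajectories
#'
#' Arithmetic mean of the posterior-mean log rate ratio per interval over
#' the members of each of the `top_k` largest clusters, for both levels.
#'
#' @param assignment data frame from [cluster_profiles].
#' @param theta_rna,theta_protein genes x intervals matrices of
#'   posterior-mean theta (e.g. `fit$theta_mean`, averaged over replicates
#'   if desired).
#' @param top_k number of largest clusters to report (default 6).
#' @return list with `RNA` and `protein`: cluster x interval matrices, and
#'   `sizes`, the member counts.
#' @export
cluster_rate_ratio_means <- function(assignment, theta_rna, theta_protein,
                                     top_k = 6L) {
  sizes <- sort(table(assignment$cluster_id), decreasing = TRUE)
  ks <- as.integer(names(sizes))[seq_len(min(top_k, length(sizes)))]
  avg <- function(theta) {
    out <- t(sapply(ks, function(k) {
      g <- assignment$gene_id[assignment$cluster_id == k]
      g <- intersect(g, rownames(theta))
      colMeans(theta[g, , drop = FALSE])
    }))
    rownames(out) <- paste0("cluster", ks)
    out
  }
  list(RNA = avg(theta_rna), protein = avg(theta_protein),
       sizes = stats::setNames(as.integer(sizes[as.character(ks)]),
                               paste0("cluster", ks)))
}

#' Heatmap-ready matrix: cluster-ordered, median-centered rows
#'
#' Orders genes by the clustering dendrogram (grouped by cluster), centers
#' every row at its median, and optionally rescales natural-log values to
#' base-10 logs for display.
#'
#' @param x matrix of profiles (rows = genes), natural-log scale.
#' @param assignment data frame from [cluster_profiles].
#' @param to_log10 divide by log(10) before centering (for concentration
#'   heatmaps).
#' @return reordered, row-median-centered matrix.
#' @export
export_heatmap_matrix <- function(x, assignment, to_log10 = FALSE) {
  tree <- attr(assignment, "tree")
  ord <- if (!is.null(tree)) tree$order else
    order(assignment$cluster_id)
  genes <- assignment$gene_id[ord]
  # group dendrogram order by cluster so blocks are contiguous
  genes <- genes[order(assignment$cluster_id[ord])]
  m <- x[genes, , drop = FALSE]
  if (to_log10) m <- m / log(10)
  m - apply(m, 1, stats::median)
}
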
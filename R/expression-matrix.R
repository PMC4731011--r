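#' Expression matrix for one molecular level and one replicate
#'
#' A thin S3 wrapper around a numeric gene x time matrix carrying the ordered
#' time grid (hours), the molecular level, and a scale flag so that operations
#' expecting natural-scale intensities or log values can check their inputs.
#'
#' @param values numeric matrix, genes in rows, time points in columns.
#'   Row names are the gene identifiers; if absent, "G000001"... are assigned.
#' @param time_grid strictly increasing numeric vector of sampling times in
#'   hours, one per column.
#' @param level `"RNA"` or `"protein"`.
#' @param scale `"natural"` (intensities, must be >= 0 where observed) or
#'   `"log"` (natural-log values).
#'
#' @return An object of class `expr_matrix`: the matrix with attributes
#'   `time_grid`, `level` and `scale`.
#' @export
expr_matrix <- function(values, time_grid,
                        level = c("RNA", "protein"),
                        scale = c("natural", "log")) {
  level <- match.arg(level)
  scale <- match.arg(scale)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (length(time_grid) != ncol(values))
    stop("time_grid length (", length(time_grid),
         ") does not match number of columns (", ncol(values), ")")
  if (any(diff(time_grid) <= 0))
    stop("time_grid must be strictly increasing")
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("G%06d", seq_len(nrow(values)))
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene identifiers")
  if (scale == "natural" && any(values < 0, na.rm = TRUE))
    stop("natural-scale values must be non-negative")
  colnames(values) <- fmt_num(time_grid)
  structure(values,
            time_grid = as.numeric(time_grid),
            level = level, scale = scale,
            class = c("expr_matrix", "matrix", "array"))
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d time points (%s, %s scale)\n",
              nrow(x), ncol(x), attr(x, "level"), attr(x, "scale")))
  cat("hours:", paste(attr(x, "time_grid"), collapse = ", "), "\n")
  n <- min(nrow(x), 5L)
  print(unclass(x)[seq_len(n), , drop = FALSE], ...)
  if (nrow(x) > n) cat("... and", nrow(x) - n, "more genes\n")
  invisible(x)
}

# keep attributes when subsetting rows/columns
#' @export
`[.expr_matrix` <- function(x, i, j, ..., drop = FALSE) {
  out <- unclass(x)[i, j, ..., drop = drop]
  if (!is.matrix(out)) return(out)
  grid <- attr(x, "time_grid")
  if (!missing(j)) grid <- grid[j]
  expr_matrix(out, grid, level = attr(x, "level"), scale = attr(x, "scale"))
}

is_expr_matrix <- function(x) inherits(x, "expr_matrix")

stopifnot_expr <- function(x, scale = NULL, arg = deparse(substitute(x))) {
  if (!is_expr_matrix(x)) stop(arg, " must be an expr_matrix")
  if (!is.null(scale) && attr(x, "scale") != scale)
    stop(arg, " must be on the ", scale, " scale (it is ",
         attr(x, "scale"), ")")
  invisible(x)
}

#' Read / write expression matrices as TSV
#'
#' Tab-delimited text with gene identifiers in the first column (`gene_id`)
#' and one column per time point, headed by the hour. Missing values are
#' written as `NA`.
#'
#' @param x an [expr_matrix].
#' @param path file path.
#' @param level,scale metadata for the matrix being read (TSV carries neither).
#' @return `write_expression_tsv` returns `path` invisibly;
#'   `read_expression_tsv` returns an [expr_matrix].
#' @export
write_expression_tsv <- function(x, path) {
  stopifnot_expr(x)
  df <- data.frame(gene_id = rownames(x), unclass(x), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path, level = c("RNA", "protein"),
                                scale = c("natural", "log")) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  expr_matrix(m, as.numeric(colnames(df)[-1]),
              level = match.arg(level), scale = match.arg(scale))
}

#' Interval and interior-point labels for a time grid
#'
#' An n-point grid has n-1 inter-timepoint intervals and n-2 interior points
#' (all sampling times except the first and last). The rate ratio is constant
#' within intervals; change points live at interior points.
#'
#' @param time_grid ordered hours.
#' @return character vectors labelling intervals ("0-0.5", ...) or interior
#'   points ("0.5", ...).
#' @keywords internal
fmt_num <- function(x) vapply(x, format, character(1), trim = TRUE)

interval_labels <- function(time_grid) {
  n <- length(time_grid)
  paste(fmt_num(time_grid[-n]), fmt_num(time_grid[-1]), sep = "-")
}

interior_points <- function(time_grid) {
  time_grid[-c(1L, length(time_grid))]
}
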
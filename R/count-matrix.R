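#' Construct a single-cell count matrix
#'
#' A thin container for a genes-by-cells matrix of non-negative integer
#' transcript counts, with optional per-cell capture depth metadata and a
#' cell-line label. All coexpression functions accept either a
#' `count_matrix` or a plain matrix with gene row names.
#'
#' @param counts genes x cells matrix (dense or `Matrix` sparse) of
#'   non-negative counts with unique row (gene) and column (cell) names.
#' @param depth optional numeric vector of per-cell depth multipliers or
#'   total counts, one per cell. When absent, column totals are used where
#'   a depth is needed.
#' @param line optional cell-line label (e.g. `"XN1"`).
#' @return An object of class `count_matrix`: a list with elements
#'   `counts`, `depth`, `line`.
#' @examples
#' m <- matrix(c(0L, 2L, 1L, 3L), 2, 2,
#'             dimnames = list(c("Otx2", "En2"), c("c1", "c2")))
#' count_matrix(m, line = "XN1")
#' @export
count_matrix <- function(counts, depth = NULL, line = NULL) {
  if (is.null(dim(counts)))
    stop("`counts` must be a matrix (genes x cells)")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("`counts` must have gene row names and cell column names")
  if (anyDuplicated(rownames(counts)))
    stop("gene names must be unique (see read_counts() for disambiguation)")
  if (anyDuplicated(colnames(counts)))
    stop("cell identifiers must be unique")
  if (min(counts) < 0)
    stop("counts must be non-negative")
  if (!is.null(depth)) {
    if (length(depth) != ncol(counts))
      stop("`depth` must have one entry per cell")
    if (any(depth <= 0))
      stop("per-cell depth must be positive")
    depth <- as.numeric(depth)
    names(depth) <- colnames(counts)
  }
  structure(list(counts = counts, depth = depth, line = line),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d cells%s\n",
              nrow(x$counts), ncol(x$counts),
              if (!is.null(x$line)) paste0(" (line ", x$line, ")") else ""))
  cat(sprintf("  genes: %s\n", paste(head(rownames(x$counts), 6L),
                                     collapse = ", ")))
  if (!is.null(x$depth))
    cat(sprintf("  per-cell depth: median %.3g\n",
                stats::median(x$depth)))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

# Accept either a count_matrix or a bare matrix everywhere downstream.
as_count_input <- function(x) {
  if (inherits(x, "count_matrix")) return(x)
  if (!is.null(dim(x))) return(count_matrix(as.matrix(x)))
  stop("expected a count_matrix or a genes x cells matrix")
}

# Per-cell depth: stored metadata if present, else column totals.
cell_depth <- function(x) {
  x <- as_count_input(x)
  if (!is.null(x$depth)) return(x$depth)
  d <- Matrix::colSums(x$counts)
  setNames(as.numeric(d), colnames(x$counts))
}
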
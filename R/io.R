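#' Read a single-cell count matrix
#'
#' Two on-disk layouts are supported: MatrixMarket (`matrix.mtx` with
#' `genes.tsv` and `barcodes.tsv` sidecars in one directory) and a wide
#' TSV (first column gene names, remaining columns cells). Duplicate gene
#' symbols are disambiguated with `make.unique()` suffixes and reported;
#' negative counts are a validation error.
#'
#' @param path directory (mtx) or file (tsv).
#' @param format `"mtx"` or `"tsv"`.
#' @param line optional cell-line label attached to the result.
#' @return A [count_matrix()].
#' @export
read_counts <- function(path, format = c("mtx", "tsv"), line = NULL) {
  format <- match.arg(format)
  if (format == "mtx") {
    mtx <- file.path(path, "matrix.mtx")
    for (f in c(mtx, file.path(path, c("genes.tsv", "barcodes.tsv"))))
      if (!file.exists(f)) stop("missing file: ", f)
    m <- tryCatch(Matrix::readMM(mtx),
                  error = function(e) stop("malformed MatrixMarket file '",
                                           mtx, "': ", conditionMessage(e)))
    genes <- readLines(file.path(path, "genes.tsv"))
    cells <- readLines(file.path(path, "barcodes.tsv"))
    if (length(genes) != nrow(m) || length(cells) != ncol(m))
      stop("sidecar gene/barcode counts do not match matrix dimensions")
    counts <- as.matrix(m)
  } else {
    if (file.size(path) == 0) stop("empty file: ", path)
    tab <- tryCatch(read.delim(path, check.names = FALSE,
                               stringsAsFactors = FALSE),
                    error = function(e) stop("malformed TSV '", path, "': ",
                                             conditionMessage(e)))
    if (ncol(tab) < 2L) stop("count TSV needs a gene column plus cells")
    genes <- as.character(tab[[1L]])
    counts <- as.matrix(tab[, -1L, drop = FALSE])
    cells <- colnames(counts)
  }
  if (anyDuplicated(genes)) {
    dup <- sum(duplicated(genes))
    genes <- make.unique(genes)
    message(sprintf("read_counts: %d duplicate gene symbol(s) suffixed", dup))
  }
  if (any(counts < 0)) stop("negative counts in ", path)
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(genes, cells)
  count_matrix(counts, line = line)
}

#' Write a single-cell count matrix
#'
#' Inverse of [read_counts()]; both layouts round-trip exactly.
#'
#' @param x a [count_matrix()] or matrix.
#' @param path output directory (mtx) or file (tsv).
#' @param format `"mtx"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_counts <- function(x, path, format = c("mtx", "tsv")) {
  format <- match.arg(format)
  x <- as_count_input(x)
  counts <- x$counts
  if (format == "mtx") {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    Matrix::writeMM(methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                            "generalMatrix"), "CsparseMatrix"),
                    file.path(path, "matrix.mtx"))
    writeLines(rownames(counts), file.path(path, "genes.tsv"))
    writeLines(colnames(counts), file.path(path, "barcodes.tsv"))
  } else {
    df <- data.frame(gene = rownames(counts), counts, check.names = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read / write a cell-track table
#'
#' CSV with the canonical header `cell_id,group,frame,t_min,x_um,y_um`.
#'
#' @param path file path.
#' @return `read_tracks`: a validated track `data.frame`.
#' @export
read_tracks <- function(path) {
  if (file.size(path) == 0) stop("empty file: ", path)
  tr <- read.csv(path, stringsAsFactors = FALSE)
  check_tracks(tr)
  tr
}

#' @param tracks track table.
#' @rdname read_tracks
#' @export
write_tracks <- function(tracks, path) {
  check_tracks(tracks)
  write.csv(tracks, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a bulk expression table
#'
#' TSV, genes in the first column, `sample_replicate` columns after.
#'
#' @param path file path.
#' @return `read_expression`: genes x columns numeric matrix.
#' @export
read_expression <- function(path) {
  if (file.size(path) == 0) stop("empty file: ", path)
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(m) <- as.character(tab[[1L]])
  if (any(m < 0)) stop("negative intensities in ", path)
  m
}

#' @param table genes x columns matrix.
#' @rdname read_expression
#' @export
write_expression <- function(table, path) {
  df <- data.frame(gene = rownames(table), table, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Remove ribosomal-protein and mitochondrial genes
#'
#' Drops genes whose symbol starts with any of the given prefixes
#' (case-insensitive), the standard preprocessing step before single-cell
#' detection analysis. Defaults remove mitochondrial (`mt-`) and
#' ribosomal-protein (`Rps`, `Rpl`) genes.
#'
#' @param x a [count_matrix()] or matrix.
#' @param drop_prefixes non-empty character vector of prefixes.
#' @return A [count_matrix()] without the matching genes.
#' @export
filter_genes <- function(x, drop_prefixes = c("mt-", "Rps", "Rpl")) {
  if (!length(drop_prefixes)) stop("prefix list must be non-empty")
  x <- as_count_input(x)
  genes <- rownames(x$counts)
  pat <- paste0("^(", paste(tolower(drop_prefixes), collapse = "|"), ")")
  drop <- grepl(pat, tolower(genes))
  if (all(drop)) stop("filter would remove every gene")
  if (any(drop))
    message(sprintf("filter_genes: removed %d gene(s)", sum(drop)))
  count_matrix(x$counts[!drop, , drop = FALSE],
               depth = x$depth, line = x$line)
}

#' Randomly subsample cells
#'
#' Uniform sampling without replacement of `n` cells (column order
#' preserved), deterministic under `seed`; the standard 4000-cell
#' subsample used for cross-line comparisons. When fewer than `n` cells
#' are available all cells are kept with a warning.
#'
#' @param x a [count_matrix()] or matrix.
#' @param n cells to keep (default 4000).
#' @param seed optional integer seed.
#' @return A [count_matrix()].
#' @export
sample_cells <- function(x, n = 4000, seed = NULL) {
  x <- as_count_input(x)
  total <- ncol(x$counts)
  if (n > total) {
    warning(sprintf("requested %d cells but only %d available; keeping all",
                    n, total))
    return(x)
  }
  if (!is.null(seed)) set.seed(seed)
  keep <- sort(sample.int(total, n))
  count_matrix(x$counts[, keep, drop = FALSE],
               depth = x$depth[keep], line = x$line)
}

#' Read a pipeline configuration
#'
#' YAML configuration for scripted runs: stage parameters (thresholds,
#' grid spacing, strata, seeds), input paths and an output directory.
#'
#' @param path YAML file.
#' @return Named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("missing config: ", path)
  yaml::read_yaml(path)
}

#' Write an analysis report as JSON
#'
#' @param report named list (profiles, partitions, fits, calls...).
#' @param path output file.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}
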
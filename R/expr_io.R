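#' Construct a validated cell-by-gene count matrix
#'
#' The substrate for all expression statistics: integer counts with cells
#' as rows and genes as columns.  Counts are stored sparse
#' (\link[Matrix]{dgCMatrix}) regardless of input representation.
#'
#' @param counts matrix-like, cells x genes, non-negative integers.
#' @param cell_ids,gene_ids unique label vectors; taken from `dimnames(counts)`
#'   when omitted.
#' @return an object of class `CountMatrix`.
#' @export
count_matrix <- function(counts, cell_ids = rownames(counts),
                         gene_ids = colnames(counts)) {
  if (is.null(cell_ids) || is.null(gene_ids)) {
    er_stop("cell and gene ids are required (dimnames or explicit arguments)")
  }
  cell_ids <- as.character(cell_ids)
  gene_ids <- as.character(gene_ids)
  if (nrow(counts) != length(cell_ids) || ncol(counts) != length(gene_ids)) {
    er_stop("dimension mismatch: counts is %dx%d but %d cell and %d gene ids given",
            nrow(counts), ncol(counts), length(cell_ids), length(gene_ids))
  }
  check_unique(cell_ids, "cell")
  check_unique(gene_ids, "gene")
  m <- if (methods::is(counts, "dgCMatrix")) counts else
    methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE), "generalMatrix"),
                "CsparseMatrix")
  v <- m@x
  if (any(v < 0)) er_stop("negative count encountered (min %s)", min(v))
  if (!is_wholenumber(v)) er_stop("non-integer count encountered")
  dimnames(m) <- list(cell_ids, gene_ids)
  structure(list(counts = m), class = "CountMatrix")
}

#' @export
print.CountMatrix <- function(x, ...) {
  cat(sprintf("CountMatrix: %d cells x %d genes, %d nonzero entries\n",
              nrow(x$counts), ncol(x$counts), length(x$counts@x)))
  invisible(x)
}

#' @rdname count_matrix
#' @param x a `CountMatrix` or `NormalizedMatrix`.
#' @export
cell_ids <- function(x) rownames(if (!is.null(x$counts)) x$counts else x$values)

#' @rdname count_matrix
#' @export
gene_ids <- function(x) colnames(if (!is.null(x$counts)) x$counts else x$values)

#' Read a count matrix from disk
#'
#' Two layouts are supported.  `mtx_triplet`: `path` is a directory holding
#' `matrix.mtx` (MatrixMarket triplet, rows = cells), `cells.tsv` and
#' `genes.tsv` (one label per line).  `dense_tsv`: `path` is a TSV whose
#' first column holds cell ids and whose header row holds gene ids.
#'
#' @param path file (dense_tsv) or directory (mtx_triplet).
#' @param layout `"mtx_triplet"` or `"dense_tsv"`.
#' @return a validated [count_matrix()].
#' @export
read_count_matrix <- function(path, layout = c("mtx_triplet", "dense_tsv")) {
  layout <- match.arg(layout)
  if (layout == "mtx_triplet") {
    mtx <- file.path(path, "matrix.mtx")
    cf <- file.path(path, "cells.tsv")
    gf <- file.path(path, "genes.tsv")
    for (f in c(mtx, cf, gf)) {
      if (!file.exists(f)) er_stop("missing file: %s", f)
    }
    m <- Matrix::readMM(mtx)
    cells <- readLines(cf)
    genes <- readLines(gf)
    if (nrow(m) != length(cells) || ncol(m) != length(genes)) {
      er_stop("label/matrix dimension mismatch: matrix %dx%d, %d cells, %d genes",
              nrow(m), ncol(m), length(cells), length(genes))
    }
    count_matrix(m, cells, genes)
  } else {
    if (!file.exists(path)) er_stop("missing file: %s", path)
    dt <- data.table::fread(path, sep = "\t", header = TRUE)
    cells <- as.character(dt[[1]])
    m <- as.matrix(dt[, -1, with = FALSE])
    rownames(m) <- cells
    count_matrix(m)
  }
}

#' Write a count matrix
#'
#' Emits the same dialects [read_count_matrix()] accepts, so round-trips
#' are identities.
#'
#' @param m a `CountMatrix`.
#' @param path target directory (mtx_triplet) or file (dense_tsv).
#' @inheritParams read_count_matrix
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(m, path, layout = c("mtx_triplet", "dense_tsv")) {
  layout <- match.arg(layout)
  stopifnot(inherits(m, "CountMatrix"))
  if (layout == "mtx_triplet") {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    Matrix::writeMM(m$counts, file.path(path, "matrix.mtx"))
    writeLines(cell_ids(m), file.path(path, "cells.tsv"))
    writeLines(gene_ids(m), file.path(path, "genes.tsv"))
  } else {
    dt <- data.table::data.table(cell_id = cell_ids(m))
    dt <- cbind(dt, data.table::as.data.table(as.matrix(m$counts)))
    data.table::fwrite(dt, path, sep = "\t")
  }
  invisible(path)
}

# normalization -------------------------------------------------------------

new_normalized <- function(values, scale, zero_cells = character()) {
  structure(list(values = values, scale = scale, zero_cells = zero_cells),
            class = "NormalizedMatrix")
}

#' @export
print.NormalizedMatrix <- function(x, ...) {
  cat(sprintf("NormalizedMatrix [%s]: %d cells x %d genes (%d zero-total cells)\n",
              x$scale, nrow(x$values), ncol(x$values), length(x$zero_cells)))
  invisible(x)
}

#' Counts-per-million normalization
#'
#' Every cell with a nonzero raw total is scaled to sum to 1e6.  Cells with
#' zero total are retained as all-zero rows and recorded in the result's
#' `zero_cells` field (a warning, not an error): CPM thresholds are
#' undefined for empty cells and downstream per-cell statistics exclude
#' them.
#'
#' @param m a `CountMatrix`.
#' @return a `NormalizedMatrix` with `scale = "cpm"`.
#' @export
to_cpm <- function(m) {
  stopifnot(inherits(m, "CountMatrix"))
  tot <- Matrix::rowSums(m$counts)
  zero <- cell_ids(m)[tot == 0]
  if (length(zero)) {
    er_log("warn", length(zero), " cell(s) with zero total counts retained as all-zero")
  }
  sf <- ifelse(tot > 0, 1e6 / tot, 0)
  vals <- as.matrix(m$counts * sf)
  new_normalized(vals, "cpm", zero)
}

#' Natural-log CPM normalization
#'
#' `ln(1 + CPM)`, the positivity scale used for marker co-expression
#' counting (a value of exactly 1 corresponds to CPM = e - 1 and counts as
#' positive at the default threshold).
#'
#' @inheritParams to_cpm
#' @return a `NormalizedMatrix` with `scale = "log1p_cpm"`.
#' @export
to_log1p_cpm <- function(m) {
  cpm <- if (inherits(m, "NormalizedMatrix")) {
    stopifnot(m$scale == "cpm"); m
  } else to_cpm(m)
  new_normalized(log1p(cpm$values), "log1p_cpm", cpm$zero_cells)
}

#' Log2 CPM normalization (display parity scale)
#'
#' `log2(1 + CPM)`; used for rank-correlation inputs and MDS, matching the
#' scale conventionally plotted for bulk comparisons.
#'
#' @inheritParams to_cpm
#' @return a `NormalizedMatrix` with `scale = "log2_cpm"`.
#' @export
to_log2_cpm <- function(m) {
  cpm <- if (inherits(m, "NormalizedMatrix")) {
    stopifnot(m$scale == "cpm"); m
  } else to_cpm(m)
  new_normalized(log2(1 + cpm$values), "log2_cpm", cpm$zero_cells)
}

# cell annotations -----------------------------------------------------------

#' Read a cell annotation table
#'
#' TSV with header columns `cell_id`, `cell_type`, `tissue`.  Annotations
#' for cells absent from a matrix are permitted (and logged as unused when
#' the matrix is supplied); duplicate `cell_id`s are an error.
#'
#' @param path TSV file.
#' @param matrix optional `CountMatrix`/`NormalizedMatrix` to cross-check.
#' @return a `data.frame` with class `CellAnnotation`.
#' @export
read_cell_annotations <- function(path, matrix = NULL) {
  if (!file.exists(path)) er_stop("missing file: %s", path)
  df <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE,
                                        colClasses = "character"))
  cell_annotation(df, matrix = matrix)
}

#' @rdname read_cell_annotations
#' @param df data.frame with `cell_id`, `cell_type`, `tissue` columns.
#' @export
cell_annotation <- function(df, matrix = NULL) {
  need <- c("cell_id", "cell_type", "tissue")
  miss <- setdiff(need, names(df))
  if (length(miss)) er_stop("annotation table lacks column(s): %s",
                            paste(miss, collapse = ", "))
  df <- as.data.frame(df)[, need]
  check_unique(df$cell_id, "cell")
  if (any(!nzchar(df$cell_type)) || any(!nzchar(df$tissue))) {
    er_stop("cell_type and tissue must be non-empty")
  }
  if (!is.null(matrix)) {
    unused <- setdiff(df$cell_id, cell_ids(matrix))
    if (length(unused)) {
      er_log("info", length(unused), " annotation(s) for cells absent from the matrix (unused)")
    }
    unann <- setdiff(cell_ids(matrix), df$cell_id)
    if (length(unann)) {
      er_log("info", length(unann),
             " matrix cell(s) without annotation; excluded from grouped statistics")
    }
  }
  class(df) <- c("CellAnnotation", "data.frame")
  df
}

#' @rdname read_cell_annotations
#' @param ann a `CellAnnotation`.
#' @export
write_cell_annotations <- function(ann, path) {
  data.table::fwrite(as.data.frame(ann), path, sep = "\t")
  invisible(path)
}

# grouped helper used by several modules
cells_of_group <- function(ann, group, universe = NULL) {
  ids <- ann$cell_id[ann$cell_type == group]
  if (!is.null(universe)) ids <- intersect(ids, universe)
  ids
}
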
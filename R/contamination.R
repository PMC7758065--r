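#' Top expressed genes of a profile
#'
#' The `n` highest-expression genes of a named expression vector, with
#' ties at the boundary broken lexicographically by gene id (the smaller
#' id wins) for determinism.  When `n` exceeds the number of genes, all
#' genes are returned and the shortfall logged.
#'
#' @param profile named numeric vector (gene -> expression).
#' @param n number of genes.
#' @return a `GeneSet`.
#' @export
top_expressed_genes <- function(profile, n = 300) {
  if (!length(profile)) er_stop("empty profile")
  if (n > length(profile)) {
    er_log("info", sprintf("top_expressed_genes: only %d genes for n=%d",
                           length(profile), n))
    n <- length(profile)
  }
  ord <- order(-profile, names(profile))
  gene_set(names(profile)[ord][seq_len(n)],
           provenance = sprintf("top %d expressed genes", n))
}

#' Kendall rank correlation (tau-b)
#'
#' Tie-corrected Kendall correlation:
#' \deqn{\tau_b = (n_c - n_d) / \sqrt{(n_0 - n_x)(n_0 - n_y)}}
#' with \eqn{n_c}/\eqn{n_d} concordant/discordant pairs, \eqn{n_0 =
#' n(n-1)/2}, and \eqn{n_x}, \eqn{n_y} the tied-pair counts within each
#' vector.  Defined (non-NaN) whenever each vector has at least one
#' non-tied pair.  O(n^2) pair counting, vectorized; adequate for the
#' few-hundred-gene universes used here.
#'
#' @param x,y numeric vectors of equal length >= 2.
#' @return tau-b in `[-1, 1]`.
#' @export
kendall_tau <- function(x, y) {
  n <- length(x)
  if (length(y) != n) er_stop("length mismatch: %d vs %d", n, length(y))
  if (n < 2) er_stop("need length >= 2")
  dx <- sign(outer(x, x, "-"))
  dy <- sign(outer(y, y, "-"))
  up <- upper.tri(dx)
  dx <- dx[up]; dy <- dy[up]
  n0 <- n * (n - 1) / 2
  nc <- sum(dx == dy & dx != 0)
  nd <- sum(dx == -dy & dx != 0)
  tx <- sum(dx == 0)
  ty <- sum(dy == 0)
  den <- sqrt((n0 - tx) * (n0 - ty))
  if (den == 0) er_stop("tau undefined: all pairs tied in one vector")
  (nc - nd) / den
}

#' Rank-correlation contamination test
#'
#' The contamination diagnostic: Kendall tau-b between two expression
#' profiles over the universe of the top-`n` expressed genes.  If the
#' transcripts shared between compartments arose by ambient contamination,
#' relative abundances in the target compartment should mirror the source
#' and tau should be high; cell-intrinsic transcription decouples the
#' ranks.  Which profile defines the top-`n` universe is explicit
#' (`ranking_reference`), defaulting to the source (whole-tissue) profile;
#' `"union"` takes the union of both top-`n` lists.  Values are correlated
#' on `log2(x+1)` by default; tau is rank-based, so the transform matters
#' only through tie structure.
#'
#' @param profile_target,profile_source named numeric vectors (gene ->
#'   expression, CPM-like scale).
#' @param n size of the top-expressed universe.
#' @param ranking_reference `"source"`, `"target"` or `"union"`.
#' @param log_scale correlate on `log2(x+1)` (default) or raw values.
#' @return a `TauResult`: list with `tau`, `n_genes`, `gene_universe`,
#'   `ranking_reference`.
#' @export
contamination_rank_test <- function(profile_target, profile_source, n = 300,
                                    ranking_reference = c("source", "target", "union"),
                                    log_scale = TRUE) {
  ranking_reference <- match.arg(ranking_reference)
  shared <- intersect(names(profile_target), names(profile_source))
  if (!length(shared)) er_stop("disjoint gene universes")
  if (length(shared) < n) {
    er_log("info", sprintf("only %d shared genes for n=%d; shrinking universe",
                           length(shared), n))
    n <- length(shared)
  }
  pt <- profile_target[shared]
  ps <- profile_source[shared]
  universe <- switch(ranking_reference,
    source = as.character(top_expressed_genes(ps, n)),
    target = as.character(top_expressed_genes(pt, n)),
    union = sort(union(as.character(top_expressed_genes(ps, n)),
                       as.character(top_expressed_genes(pt, n))))
  )
  xt <- pt[universe]; xs <- ps[universe]
  if (log_scale) { xt <- log2(xt + 1); xs <- log2(xs + 1) }
  structure(list(
    tau = kendall_tau(xt, xs),
    n_genes = length(universe),
    gene_universe = gene_set(universe,
      provenance = sprintf("top %d by %s profile", n, ranking_reference)),
    ranking_reference = ranking_reference
  ), class = "TauResult")
}

#' @export
print.TauResult <- function(x, ...) {
  cat(sprintf("TauResult: tau = %.4f over %d genes (ranking: %s)\n",
              x$tau, x$n_genes, x$ranking_reference))
  invisible(x)
}

#' Binary positivity matrix
#'
#' Entry `(cell, gene) = 1` iff the normalized value is `>=` the
#' threshold (inclusive: `ln(1+CPM)` of exactly 1.0, i.e. CPM = e-1, is
#' positive).  Requires the `log1p_cpm` scale so the threshold has one
#' meaning package-wide.
#'
#' @param norm `NormalizedMatrix`, scale `log1p_cpm`.
#' @param genes `GeneSet` (all must be present in the matrix).
#' @param threshold positivity threshold.
#' @return binary integer matrix, cells x genes.
#' @export
positivity_matrix <- function(norm, genes, threshold = 1.0) {
  stopifnot(inherits(norm, "NormalizedMatrix"))
  if (norm$scale != "log1p_cpm") {
    er_stop("positivity requires scale log1p_cpm, got '%s'", norm$scale)
  }
  genes <- as.character(genes)
  missing <- setdiff(genes, colnames(norm$values))
  if (length(missing)) {
    er_stop("gene(s) absent from matrix: %s", paste(missing, collapse = ", "))
  }
  v <- norm$values[, genes, drop = FALSE]
  p <- matrix(as.integer(positive_values(v, threshold)), nrow = nrow(v),
              dimnames = dimnames(v))
  attr(p, "zero_cells") <- norm$zero_cells
  p
}

#' Per-group marker co-expression distribution
#'
#' For each group: the histogram of the per-cell number of positive
#' markers (0..K), the fraction of cells positive for at least one
#' marker, and the median marker count among positive cells.  Under
#' ambient contamination all target cells sample the same pool and
#' positive cells carry many markers at once; under sporadic intrinsic
#' transcription most positive cells carry only one or two.  Zero-total
#' cells are excluded.
#'
#' @param p positivity matrix from [positivity_matrix()].
#' @param ann a `CellAnnotation`.
#' @param groups cell types to summarize.
#' @return a `MarkerCountDistribution`: per group, list with `histogram`
#'   (named 0..K), `n_cells`, `frac_ge1`, `median_positive`.
#' @export
marker_count_distribution <- function(p, ann, groups) {
  K <- ncol(p)
  usable <- setdiff(rownames(p), attr(p, "zero_cells"))
  out <- lapply(groups, function(g) {
    cells <- intersect(cells_of_group(ann, g), usable)
    if (!length(cells)) er_stop("empty group '%s'", g)
    k <- rowSums(p[cells, , drop = FALSE])
    hist <- table(factor(k, levels = 0:K))
    list(group = g,
         histogram = setNames(as.integer(hist), names(hist)),
         n_cells = length(cells),
         frac_ge1 = mean(k >= 1),
         median_positive = if (any(k >= 1)) median(k[k >= 1]) else NA_real_)
  })
  names(out) <- groups
  structure(out, K = K, class = "MarkerCountDistribution")
}

#' @export
print.MarkerCountDistribution <- function(x, ...) {
  for (g in names(x)) {
    cat(sprintf("%s: n=%d, frac_ge1=%.3f, median among positive=%s\n",
                g, x[[g]]$n_cells, x[[g]]$frac_ge1,
                format(x[[g]]$median_positive)))
  }
  invisible(x)
}

#' Classical MDS embedding of expression profiles
#'
#' Torgerson (classical) multidimensional scaling on Euclidean distances
#' over `log2(x+1)` values of the top variably-expressed genes
#' (cross-sample variance).  Classical MDS embeds a Euclidean distance
#' matrix exactly (up to rotation), so nearby profiles stay nearby;
#' output is centered at the origin.
#'
#' @param profiles numeric matrix, genes x samples (>= 3 samples), or a
#'   named list of equal-length named vectors.
#' @param top_variable number of genes to retain by variance.
#' @param log_scale transform to `log2(x+1)` before embedding.
#' @return samples x 2 coordinate matrix.
#' @export
mds_embed <- function(profiles, top_variable = 1000, log_scale = TRUE) {
  if (is.list(profiles) && !is.matrix(profiles)) {
    genes <- names(profiles[[1]])
    profiles <- vapply(profiles, function(p) p[genes], numeric(length(genes)))
    rownames(profiles) <- genes
  }
  if (ncol(profiles) < 3) er_stop("need >= 3 samples for MDS")
  x <- if (log_scale) log2(profiles + 1) else profiles
  if (top_variable < nrow(x)) {
    v <- apply(x, 1, var)
    keep <- order(-v, rownames(x))[seq_len(top_variable)]
    x <- x[keep, , drop = FALSE]
  } else if (top_variable > nrow(x)) {
    er_log("info", sprintf("only %d genes for top_variable=%d", nrow(x), top_variable))
  }
  d <- dist(t(x))
  coords <- cmdscale(d, k = 2)
  colnames(coords) <- c("dim1", "dim2")
  coords
}

# serialization --------------------------------------------------------------

#' Serialize a TauResult or MarkerCountDistribution
#'
#' @param x object to write.
#' @param path target file; `.json` or `.tsv` by `format`.
#' @param format `"json"` or `"tsv"`.
#' @export
write_result <- function(x, path, format = c("json", "tsv")) {
  format <- match.arg(format)
  if (format == "json") {
    obj <- if (inherits(x, "TauResult")) {
      list(tau = x$tau, n_genes = x$n_genes,
           ranking_reference = x$ranking_reference,
           gene_universe = as.character(x$gene_universe))
    } else if (inherits(x, "MarkerCountDistribution")) {
      lapply(unclass(x), function(g) g[c("group", "histogram", "n_cells",
                                         "frac_ge1", "median_positive")])
    } else x
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    df <- if (inherits(x, "TauResult")) {
      data.frame(tau = x$tau, n_genes = x$n_genes,
                 ranking_reference = x$ranking_reference)
    } else if (inherits(x, "MarkerCountDistribution")) {
      do.call(rbind, lapply(unclass(x), function(g)
        data.frame(group = g$group, n_positive = names(g$histogram),
                   n_cells = g$histogram)))
    } else as.data.frame(x)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
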
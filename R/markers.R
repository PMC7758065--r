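#' Gene sets with provenance
#'
#' An ordered, duplicate-free character vector of gene ids carrying a
#' `provenance` attribute recording the rule and parameters that produced
#' it.
#'
#' @param genes character vector of gene ids.
#' @param provenance one-line description of the selection rule.
#' @return a `GeneSet`.
#' @export
gene_set <- function(genes, provenance = "unspecified") {
  genes <- as.character(genes)
  check_unique(genes, "gene")
  structure(genes, provenance = provenance, class = c("GeneSet", "character"))
}

#' @export
print.GeneSet <- function(x, ...) {
  cat(sprintf("GeneSet (%d genes): %s\n", length(x), attr(x, "provenance")))
  if (length(x)) cat(" ", paste(head(x, 10), collapse = " "),
                     if (length(x) > 10) "...\n" else "\n")
  invisible(x)
}

#' Write / read a gene set as one-gene-per-line text
#'
#' The selection rule is recorded as a `#` header comment.
#'
#' @param gs a `GeneSet`.
#' @param path file path.
#' @export
write_gene_set <- function(gs, path) {
  writeLines(c(paste0("# ", attr(gs, "provenance")), as.character(gs)), path)
  invisible(path)
}

#' @rdname write_gene_set
#' @export
read_gene_set <- function(path) {
  ln <- readLines(path)
  prov <- sub("^#\\s*", "", ln[startsWith(ln, "#")][1])
  if (is.na(prov)) prov <- "unspecified"
  gene_set(ln[!startsWith(ln, "#") & nzchar(ln)], provenance = prov)
}

# positivity on the ln(1+CPM) scale: one definition used everywhere
positive_values <- function(values_log1p, threshold = 1.0) {
  values_log1p >= threshold
}

# per-group CPM means / positive fractions for marker statistics
marker_stats <- function(norm, ann, group, threshold = 1.0) {
  stopifnot(inherits(norm, "NormalizedMatrix"), norm$scale == "log1p_cpm")
  usable <- setdiff(rownames(norm$values), norm$zero_cells)
  in_cells <- intersect(cells_of_group(ann, group), usable)
  out_cells <- setdiff(intersect(ann$cell_id, usable), in_cells)
  if (!length(in_cells)) er_stop("group '%s' absent from annotations/matrix", group)
  vin <- norm$values[in_cells, , drop = FALSE]
  vout <- norm$values[out_cells, , drop = FALSE]
  cpm_in <- expm1(vin)
  cpm_out <- expm1(vout)
  list(
    in_cells = in_cells, out_cells = out_cells,
    vin = vin, vout = vout,
    frac_in = colMeans(positive_values(vin, threshold)),
    frac_out = if (length(out_cells)) colMeans(positive_values(vout, threshold)) else
      setNames(rep(NA_real_, ncol(vin)), colnames(vin)),
    mean_in = colMeans(cpm_in),
    mean_out = if (length(out_cells)) colMeans(cpm_out) else
      setNames(rep(0, ncol(vin)), colnames(vin))
  )
}

#' Rank cell-type marker genes
#'
#' Per-gene two-sided Wilcoxon rank-sum test of in-group versus all other
#' annotated cells on per-cell `ln(1+CPM)` values, with a pseudocounted
#' fold change on the CPM scale, `fold = (mean_in + 1) / (mean_out + 1)`,
#' and Benjamini-Hochberg adjustment across all genes.  Cells with zero
#' totals and unannotated cells are excluded.
#'
#' @param norm `NormalizedMatrix` with scale `log1p_cpm`.
#' @param ann a `CellAnnotation`.
#' @param group cell type to treat as in-group.
#' @param threshold positivity threshold on the `ln(1+CPM)` scale.
#' @return a `data.frame` of class `MarkerTable`: `gene_id`, `frac_in`,
#'   `frac_out`, `mean_in`, `mean_out`, `fold`, `rank_sum_p`, `adj_p`.
#' @export
rank_markers <- function(norm, ann, group, threshold = 1.0) {
  st <- marker_stats(norm, ann, group, threshold)
  if (length(st$in_cells) < 2 || length(st$out_cells) < 2) {
    er_stop("need >= 2 cells in and out of group '%s'", group)
  }
  p <- vapply(seq_len(ncol(st$vin)), function(j) {
    x <- st$vin[, j]; y <- st$vout[, j]
    if (all(x == x[1]) && all(y == x[1])) return(1.0)
    stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value
  }, numeric(1))
  p[is.na(p)] <- 1
  out <- data.frame(
    gene_id = colnames(st$vin),
    frac_in = st$frac_in, frac_out = st$frac_out,
    mean_in = st$mean_in, mean_out = st$mean_out,
    fold = (st$mean_in + 1) / (st$mean_out + 1),
    rank_sum_p = p,
    adj_p = p.adjust(p, method = "BH"),
    row.names = NULL
  )
  class(out) <- c("MarkerTable", "data.frame")
  out
}

#' Top positively-associated markers
#'
#' Genes with `fold > 1`, sorted by ascending p, then descending fold,
#' then lexicographic gene id; the first `n` are returned (fewer when
#' fewer qualify).
#'
#' @param t a `MarkerTable`.
#' @param n maximum number of genes.
#' @return a `GeneSet`.
#' @export
top_positive_markers <- function(t, n = 300) {
  if (n <= 0) er_stop("n must be positive")
  q <- t[t$fold > 1, , drop = FALSE]
  q <- q[order(q$rank_sum_p, -q$fold, q$gene_id), , drop = FALSE]
  gene_set(head(q$gene_id, n),
           provenance = sprintf("top_positive_markers n=%d (fold>1, by p asc, fold desc)", n))
}

#' Parenchymal (e.g. cardiomyocyte myofibril) marker selection
#'
#' The signature rule: genes positive (`ln(1+CPM) >=` threshold) in more
#' than `min_frac` of target-group cells AND with pseudocounted CPM fold
#' versus all other cells at least `min_fold`, ranked by fold descending
#' (ties broken by gene id) and truncated to `n`.  A shortfall (< n
#' qualifying genes) is logged, not an error.
#'
#' @inheritParams rank_markers
#' @param target_group the parenchymal cell type.
#' @param min_frac minimum in-group positive fraction (strict `>`).
#' @param min_fold minimum fold (inclusive `>=`).
#' @param n number of genes to keep.
#' @return a `GeneSet`.
#' @export
select_parenchymal_markers <- function(norm, ann, target_group,
                                       min_frac = 0.60, min_fold = 10,
                                       n = 15, threshold = 1.0) {
  st <- marker_stats(norm, ann, target_group, threshold)
  fold <- (st$mean_in + 1) / (st$mean_out + 1)
  ok <- st$frac_in > min_frac & fold >= min_fold
  ids <- names(fold)[ok]
  ids <- ids[order(-fold[ok], ids)]
  if (length(ids) < n) {
    er_log("info", sprintf("marker shortfall: %d qualify for n=%d", length(ids), n))
  }
  gene_set(head(ids, n),
           provenance = sprintf(
             "parenchymal markers: frac_in>%g & fold>=%g, top %d by fold, group=%s",
             min_frac, min_fold, n, target_group))
}

#' Drop mitochondrial genes from a set
#'
#' Mitochondrial genes are accessible in every cell type and are removed
#' from cell-type gene sets before chromatin-accessibility export.  The
#' filter is an id-prefix match (default `"mt-"`, the mouse convention).
#'
#' @param gs a `GeneSet`.
#' @param prefix id prefix identifying mitochondrial genes.
#' @return a filtered `GeneSet`.
#' @export
drop_mitochondrial <- function(gs, prefix = "mt-") {
  keep <- !startsWith(as.character(gs), prefix)
  gene_set(as.character(gs)[keep],
           provenance = paste0(attr(gs, "provenance"), sprintf(" | mito prefix '%s' removed", prefix)))
}
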
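#' Construct a gene model set
#'
#' Internal coordinates are 0-based half-open everywhere; GTF (1-based
#' inclusive) is converted at the boundary.  Exons are the union over all
#' transcripts of a gene ("spliced territory"); introns are the gaps
#' between merged exons.  The TSS is the gene start on `+` and the gene
#' end on `-`.
#'
#' @param genes data.frame with columns `gene_id`, `chrom`, `strand`
#'   (`+`/`-`), `start`, `end` (0-based half-open).
#' @param exons data.frame with columns `gene_id`, `start`, `end`
#'   (0-based half-open); merged per gene on construction.
#' @return an object of class `GeneModelSet`.
#' @export
gene_model_set <- function(genes, exons) {
  genes <- as.data.frame(genes)
  exons <- as.data.frame(exons)
  check_unique(genes$gene_id, "gene")
  bad <- setdiff(genes$strand, c("+", "-"))
  if (length(bad)) er_stop("unknown strand symbol(s): %s", paste(bad, collapse = ", "))
  if (any(genes$start >= genes$end)) er_stop("gene with start >= end")
  if (nrow(exons)) {
    if (any(exons$start >= exons$end)) er_stop("exon with start >= end")
    unknown <- setdiff(exons$gene_id, genes$gene_id)
    if (length(unknown)) er_stop("exon for unknown gene: %s", unknown[1])
    exons <- merge_exons(exons)
    gi <- match(exons$gene_id, genes$gene_id)
    if (any(exons$start < genes$start[gi] | exons$end > genes$end[gi])) {
      er_stop("exon outside gene span")
    }
  }
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end)
  rownames(genes) <- genes$gene_id
  structure(list(genes = genes, exons = exons), class = "GeneModelSet")
}

# union of possibly-overlapping exon intervals per gene (0-based half-open);
# one grouped reduce over an IRangesList keeps this O(n log n) overall
merge_exons <- function(exons) {
  irl <- S4Vectors::split(IRanges::IRanges(start = exons$start + 1L, end = exons$end),
                          factor(exons$gene_id))
  red <- IRanges::reduce(irl)
  flat <- unlist(red, use.names = FALSE)
  out <- data.frame(gene_id = rep(names(red), lengths(red)),
                    start = IRanges::start(flat) - 1L,
                    end = IRanges::end(flat))
  out[order(out$gene_id, out$start), , drop = FALSE]
}

#' @export
print.GeneModelSet <- function(x, ...) {
  cat(sprintf("GeneModelSet: %d genes, %d merged exons\n",
              nrow(x$genes), nrow(x$exons)))
  invisible(x)
}

#' Intron intervals of one gene
#'
#' Gaps between merged exons, 0-based half-open.  Gene territory outside
#' any exon but inside the gene span counts as intronic.
#'
#' @param models a `GeneModelSet`.
#' @param gene_id gene identifier.
#' @return data.frame with `start`, `end` (possibly 0 rows).
#' @export
gene_introns <- function(models, gene_id) {
  ex <- models$exons[models$exons$gene_id == gene_id, , drop = FALSE]
  g <- models$genes[gene_id, ]
  if (!nrow(ex)) return(data.frame(start = g$start, end = g$end))
  ex <- ex[order(ex$start), ]
  bounds <- c(g$start, as.vector(rbind(ex$start, ex$end)), g$end)
  s <- bounds[seq(1, length(bounds), by = 2)]
  e <- bounds[seq(2, length(bounds), by = 2)]
  keep <- s < e
  data.frame(start = s[keep], end = e[keep])
}

#' Read gene models from GTF
#'
#' Requires `gene` and `exon` features with a `gene_id` attribute
#' (GRCm38-style annotations satisfy this).  1-based inclusive GTF
#' coordinates are converted to the internal 0-based half-open convention
#' and transcript exons are merged per gene.
#'
#' @param path GTF file.
#' @return a [gene_model_set()].
#' @export
read_gene_models <- function(path) {
  if (!file.exists(path)) er_stop("missing file: %s", path)
  gr <- rtracklayer::import(path, format = "gtf")
  type <- as.character(gr$type)
  gg <- gr[type == "gene"]
  ee <- gr[type == "exon"]
  if (!length(gg)) er_stop("no gene features in %s", path)
  genes <- data.frame(
    gene_id = as.character(gg$gene_id),
    chrom = as.character(GenomicRanges::seqnames(gg)),
    strand = as.character(GenomicRanges::strand(gg)),
    start = GenomicRanges::start(gg) - 1L,
    end = GenomicRanges::end(gg)
  )
  exons <- data.frame(
    gene_id = as.character(ee$gene_id),
    start = GenomicRanges::start(ee) - 1L,
    end = GenomicRanges::end(ee)
  )
  gene_model_set(genes, exons)
}

#' Write gene models to GTF
#'
#' Emits `gene` and (merged) `exon` features; re-reading reproduces
#' `(gene_id, strand, TSS, merged exons)` exactly.
#'
#' @param models a `GeneModelSet`.
#' @param path target GTF file.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(models, path) {
  g <- models$genes
  e <- models$exons
  gi <- match(e$gene_id, g$gene_id)
  gr <- GenomicRanges::GRanges(
    seqnames = c(g$chrom, g$chrom[gi]),
    ranges = IRanges::IRanges(start = c(g$start, e$start) + 1L,
                              end = c(g$end, e$end)),
    strand = c(g$strand, g$strand[gi])
  )
  gr$source <- "echoRNA"
  gr$type <- c(rep("gene", nrow(g)), rep("exon", nrow(e)))
  gr$gene_id <- c(g$gene_id, e$gene_id)
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

# GRanges view of TSS windows / points, used by the accessibility module
tss_granges <- function(models, halfwidth = 0L) {
  g <- models$genes
  if (halfwidth > 0) {
    GenomicRanges::GRanges(g$chrom,
      IRanges::IRanges(start = g$tss - halfwidth + 1L, end = g$tss + halfwidth),
      gene_id = g$gene_id)
  } else {
    GenomicRanges::GRanges(g$chrom, IRanges::IRanges(start = g$tss + 1L, width = 1L),
      gene_id = g$gene_id)
  }
}
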
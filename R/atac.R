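#' TSS-window read density (RPKM)
#'
#' Counts reads overlapping the `[TSS - halfwidth, TSS + halfwidth)`
#' window of every gene by at least 1 bp (interval intersection, not read
#' midpoint) and converts to RPKM:
#' `rpkm = count / (window_kb * library_size / 1e6)` with
#' `window_kb = 2 * halfwidth / 1000`.  Genes on chromosomes without
#' reads get count 0, not an error.
#'
#' @param reads a `ReadSet`.
#' @param models a `GeneModelSet`.
#' @param halfwidth window half-width in bp (default 250, i.e. +/-250 bp).
#' @return an `AccessibilityTable` data.frame: `gene_id`, `chrom`,
#'   `window_start`, `window_end`, `count`, `rpkm`, `label`
#'   (all `"unset"`).
#' @export
tss_window_rpkm <- function(reads, models, halfwidth = 250) {
  stopifnot(inherits(reads, "ReadSet"))
  if (reads$library_size <= 0) er_stop("library_size must be positive")
  g <- models$genes
  win_gr <- tss_granges(models, halfwidth)
  # disjoint seqlevels are expected (gene chromosomes without reads count 0)
  cnt <- suppressWarnings(
    GenomicRanges::countOverlaps(win_gr, intervals_granges(reads$intervals),
                                 minoverlap = 1L))
  window_kb <- 2 * halfwidth / 1000
  out <- data.frame(gene_id = g$gene_id, chrom = g$chrom,
                    window_start = g$tss - halfwidth,
                    window_end = g$tss + halfwidth,
                    count = as.integer(cnt),
                    rpkm = cnt / (window_kb * reads$library_size / 1e6),
                    label = "unset",
                    row.names = g$gene_id)
  class(out) <- c("AccessibilityTable", "data.frame")
  out
}

#' Open/closed chromatin classification
#'
#' Labels each gene's TSS window: `closed` when the accessibility value
#' is below `closed_max`, `open` when above `open_min`, `indeterminate`
#' between.  The scale is a declared parameter because thresholds stated
#' on raw RPKM (closed < 1.5, open > 3; the defaults here) and on
#' log2-RPKM are both in circulation; with `scale = "log2_rpkm"` the
#' comparison value is `log2(rpkm)` and the thresholds are interpreted on
#' that scale.
#'
#' @param t an `AccessibilityTable`.
#' @param closed_max upper bound (strict) for `closed`.
#' @param open_min lower bound (strict) for `open`.
#' @param scale `"rpkm"` or `"log2_rpkm"`.
#' @return the table with `label` filled in.
#' @export
classify_accessibility <- function(t, closed_max = 1.5, open_min = 3.0,
                                   scale = c("rpkm", "log2_rpkm")) {
  scale <- match.arg(scale)
  if (closed_max >= open_min) er_stop("threshold inversion: closed_max >= open_min")
  v <- if (scale == "rpkm") t$rpkm else log2(t$rpkm)
  t$label <- ifelse(v < closed_max, "closed",
             ifelse(v > open_min, "open", "indeterminate"))
  t
}

#' TSS metaprofile of a gene set
#'
#' Strand-oriented read-start counts in bins of `binsize` bp from
#' `-flank` to `+flank` around each TSS (minus-strand genes flipped so
#' positive offsets are downstream), averaged over genes and scaled per
#' million library reads.
#'
#' @param reads a `ReadSet`.
#' @param genes a `GeneSet` restricting the profile.
#' @param models a `GeneModelSet`.
#' @param flank half-extent in bp.
#' @param binsize bin width in bp (must divide `2*flank`).
#' @return data.frame `bin_offset` (bin center, bp) and `mean_signal`
#'   (read starts per gene per million library reads).
#' @export
tss_metaprofile <- function(reads, genes, models, flank = 2000, binsize = 50) {
  genes <- as.character(genes)
  if (!length(genes)) er_stop("empty gene set")
  missing <- setdiff(genes, models$genes$gene_id)
  if (length(missing)) er_stop("gene(s) without model: %s", paste(missing, collapse = ", "))
  n_bins <- as.integer(2 * flank / binsize)
  if (n_bins * binsize != 2 * flank) er_stop("binsize must divide 2*flank")
  counts <- numeric(n_bins)
  g <- models$genes[genes, ]
  starts <- reads$intervals$start
  chroms <- reads$intervals$chrom
  for (i in seq_len(nrow(g))) {
    on_chr <- starts[chroms == g$chrom[i]]
    off <- if (g$strand[i] == "+") on_chr - g$tss[i] else g$tss[i] - on_chr
    off <- off[off >= -flank & off < flank]
    if (length(off)) {
      idx <- floor((off + flank) / binsize) + 1L
      tab <- tabulate(idx, nbins = n_bins)
      counts <- counts + tab
    }
  }
  data.frame(
    bin_offset = seq(-flank, flank - binsize, by = binsize) + binsize / 2,
    mean_signal = counts / length(genes) / (reads$library_size / 1e6))
}

#' Accessibility relative to housekeeping genes
#'
#' Gene RPKM divided by the geometric mean of the housekeeping genes'
#' RPKMs (classically `Rpsa` and `Tbp`).  A zero housekeeping RPKM is an
#' error: the reference is then undefined.
#'
#' @param t an `AccessibilityTable`.
#' @param gene gene id to normalize.
#' @param housekeeping `GeneSet` of housekeeping genes.
#' @return a non-negative real.
#' @export
relative_accessibility <- function(t, gene, housekeeping) {
  hk <- as.character(housekeeping)
  missing <- setdiff(c(gene, hk), t$gene_id)
  if (length(missing)) er_stop("gene(s) absent from table: %s", paste(missing, collapse = ", "))
  hk_rpkm <- t[hk, "rpkm"]
  if (any(hk_rpkm <= 0)) er_stop("zero housekeeping RPKM: reference undefined")
  t[gene, "rpkm"] / exp(mean(log(hk_rpkm)))
}

#' Tissue-enriched gene selection
#'
#' Genes with baseline expression of at least `min_expr` in the target
#' tissue and more than `min_fold` the maximum expression across the
#' other tissues (conservative reading of "fold versus brain or lung"),
#' with a small `eps` guarding zero denominators:
#' `expr_target / (max(expr_others) + eps) > min_fold`.
#'
#' @param expr numeric matrix, genes x tissues (CPM/TPM scale).
#' @param target_tissue column to select for.
#' @param others columns to compare against (non-empty).
#' @param min_expr baseline threshold (inclusive).
#' @param min_fold fold threshold (strict).
#' @param eps denominator guard.
#' @return a `GeneSet`.
#' @export
select_tissue_enriched <- function(expr, target_tissue, others,
                                   min_expr = 10, min_fold = 2, eps = 0.1) {
  if (!length(others)) er_stop("empty comparison tissue list")
  missing <- setdiff(c(target_tissue, others), colnames(expr))
  if (length(missing)) er_stop("tissue(s) absent: %s", paste(missing, collapse = ", "))
  tgt <- expr[, target_tissue]
  other_max <- apply(expr[, others, drop = FALSE], 1, max)
  keep <- tgt >= min_expr & tgt / (other_max + eps) > min_fold
  gene_set(sort(rownames(expr)[keep]),
           provenance = sprintf("%s-enriched: expr>=%g and fold>%g vs max(%s)",
                                target_tissue, min_expr, min_fold,
                                paste(others, collapse = ",")))
}

#' Compare two peak sets
#'
#' A peak is *shared* if it overlaps any peak of the other set by at
#' least `min_overlap_bp`; the shared/unique subsets partition each
#' input, and swapping the arguments swaps the labels exactly.
#'
#' @param a,b `PeakSet`s.
#' @param min_overlap_bp minimum overlap in bp.
#' @return list of `PeakSet`s: `unique_a`, `shared_a`, `unique_b`,
#'   `shared_b`.
#' @export
peak_set_compare <- function(a, b, min_overlap_bp = 1) {
  ga <- intervals_granges(a$peaks)
  gb <- intervals_granges(b$peaks)
  sa <- GenomicRanges::countOverlaps(ga, gb, minoverlap = min_overlap_bp) > 0
  sb <- GenomicRanges::countOverlaps(gb, ga, minoverlap = min_overlap_bp) > 0
  list(unique_a = peak_set(a$peaks[!sa, ]),
       shared_a = peak_set(a$peaks[sa, ]),
       unique_b = peak_set(b$peaks[!sb, ]),
       shared_b = peak_set(b$peaks[sb, ]))
}

#' Assign peaks to genes by TSS distance
#'
#' A peak is assigned to every gene whose TSS lies within `max_dist` bp
#' of the peak interval; the distance is 0 when the TSS falls inside the
#' peak, otherwise the gap to the nearest covered base.
#'
#' @param p a `PeakSet`.
#' @param models a `GeneModelSet`.
#' @param max_dist maximum distance in bp (inclusive).
#' @return data.frame `peak_idx`, `chrom`, `peak_start`, `peak_end`,
#'   `gene_id`, `distance`.
#' @export
annotate_peaks_to_genes <- function(p, models, max_dist = 2000) {
  pk <- p$peaks
  g <- models$genes
  out <- list()
  for (i in seq_len(nrow(pk))) {
    same <- g$chrom == pk$chrom[i]
    if (!any(same)) next
    tss <- g$tss[same]
    d <- ifelse(tss < pk$start[i], pk$start[i] - tss,
         ifelse(tss >= pk$end[i], tss - (pk$end[i] - 1L), 0L))
    hit <- d <= max_dist
    if (any(hit)) {
      out[[length(out) + 1L]] <- data.frame(
        peak_idx = i, chrom = pk$chrom[i],
        peak_start = pk$start[i], peak_end = pk$end[i],
        gene_id = g$gene_id[same][hit], distance = d[hit])
    }
  }
  if (!length(out)) {
    return(data.frame(peak_idx = integer(), chrom = character(),
                      peak_start = integer(), peak_end = integer(),
                      gene_id = character(), distance = integer()))
  }
  do.call(rbind, out)
}

#' Write an accessibility table as TSV
#'
#' @param t an `AccessibilityTable`.
#' @param path output file.
#' @export
write_accessibility <- function(t, path) {
  write.table(t, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
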
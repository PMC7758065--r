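#' Junction-split read alignments
#'
#' A read is a set of aligned blocks (0-based half-open intervals on one
#' chromosome, junction-split) plus a cell/group label.  Stored long:
#' `$reads` (one row per read: `read_id`, `chrom`, `strand`, `group`) and
#' `$blocks` (one row per block: `read_id`, `start`, `end`).
#'
#' @param reads data.frame with `read_id`, `chrom`, `group` (and
#'   optionally `strand`; `"*"` when unknown).
#' @param blocks data.frame with `read_id`, `start`, `end`.
#' @return an object of class `ReadAlignments`.
#' @export
read_alignments <- function(reads, blocks) {
  reads <- data.table::as.data.table(reads)
  blocks <- data.table::as.data.table(blocks)
  if (!"strand" %in% names(reads)) reads$strand <- "*"
  check_unique(reads$read_id, "read")
  if (any(blocks$start >= blocks$end)) er_stop("block with start >= end")
  unknown <- setdiff(blocks$read_id, reads$read_id)
  if (length(unknown)) er_stop("block for unknown read: %s", unknown[1])
  data.table::setorder(blocks, read_id, start)
  # blocks of one read must not overlap
  ov <- blocks[, any(start[-1] < end[-.N]), by = "read_id"]$V1
  if (any(ov)) er_stop("overlapping blocks within a read")
  structure(list(reads = reads, blocks = blocks), class = "ReadAlignments")
}

#' @export
print.ReadAlignments <- function(x, ...) {
  cat(sprintf("ReadAlignments: %d reads, %d blocks, %d group(s)\n",
              nrow(x$reads), nrow(x$blocks),
              length(unique(x$reads$group))))
  invisible(x)
}

# span (min start, max end) per read, joined with read metadata
read_spans <- function(alns) {
  sp <- alns$blocks[, list(span_start = min(start), span_end = max(end),
                           n_blocks = .N), by = "read_id"]
  merge(alns$reads, sp, by = "read_id")
}

#' Classify one read against one gene model
#'
#' Rule: *unspliced* if any block overlaps intronic territory of the gene
#' by at least 1 bp; *spliced* if all blocks lie within the exon union and
#' either the read is a single fully-exonic block or every inter-block gap
#' exactly matches an annotated intron; *ambiguous* otherwise (e.g. a gap
#' that matches no intron, or a block leaving the gene span).  Ambiguous
#' reads are excluded from fraction statistics rather than guessed.
#'
#' @param alns a `ReadAlignments` (the read is selected by `read_id`).
#' @param read_id id of the read to classify.
#' @param models a `GeneModelSet`.
#' @param gene_id the gene to classify against.
#' @return `"spliced"`, `"unspliced"` or `"ambiguous"`.
#' @export
classify_read_splice_state <- function(alns, read_id, models, gene_id) {
  g <- models$genes[gene_id, ]
  b <- alns$blocks[alns$blocks$read_id == read_id, ]
  if (!nrow(b)) er_stop("unknown read '%s'", read_id)
  chrom <- alns$reads$chrom[match(read_id, alns$reads$read_id)]
  if (chrom != g$chrom || max(b$end) <= g$start || min(b$start) >= g$end) {
    er_stop("read '%s' does not overlap gene '%s'", read_id, gene_id)
  }
  .classify_blocks(b$start, b$end, models, gene_id)
}

# core rule on one read's sorted blocks (0-based half-open)
.classify_blocks <- function(bs, be, models, gene_id) {
  introns <- gene_introns(models, gene_id)
  ex <- models$exons[models$exons$gene_id == gene_id, , drop = FALSE]
  if (nrow(introns)) {
    hit <- outer(bs, introns$end, "<") & outer(be, introns$start, ">")
    if (any(hit)) return("unspliced")
  }
  if (!nrow(ex)) return("ambiguous")
  contained <- vapply(seq_along(bs), function(i)
    any(bs[i] >= ex$start & be[i] <= ex$end), logical(1))
  if (!all(contained)) return("ambiguous")
  if (length(bs) == 1) return("spliced")
  gap_s <- be[-length(be)]
  gap_e <- bs[-1]
  key <- paste(introns$start, introns$end)
  if (all(paste(gap_s, gap_e) %in% key)) "spliced" else "ambiguous"
}

#' Count spliced/unspliced reads per gene per group
#'
#' Each read is assigned to every gene whose span its own span overlaps
#' (multi-gene reads are double-counted, with a logged tally) and
#' classified by [classify_read_splice_state()]'s rule.  Group labels are
#' taken from the reads directly, or mapped from cell id to cell type via
#' `ann` when supplied; reads with unresolvable labels are skipped and
#' counted in the log.
#'
#' @param alns a `ReadAlignments`.
#' @param models a `GeneModelSet`.
#' @param ann optional `CellAnnotation` mapping read `group` (cell id) to
#'   cell type.
#' @return a `SpliceCounts` data.frame: `gene_id`, `group`, `spliced`,
#'   `unspliced`, `ambiguous` (full gene x group grid, zero-filled).
#' @export
count_splice_states <- function(alns, models, ann = NULL) {
  spans <- read_spans(alns)
  if (!is.null(ann)) {
    idx <- match(spans$group, ann$cell_id)
    unknown <- sum(is.na(idx))
    if (unknown) er_log("warn", unknown, " read(s) with unknown cell label skipped")
    spans$group <- ann$cell_type[idx]
    spans <- spans[!is.na(spans$group), ]
  }
  groups <- sort(unique(spans$group))
  blocks <- data.table::copy(alns$blocks)
  data.table::setkey(blocks, read_id)
  res <- list()
  assigned_per_read <- integer(nrow(spans))
  for (gid in models$genes$gene_id) {
    g <- models$genes[gid, ]
    cand <- which(spans$chrom == g$chrom &
                  spans$span_start < g$end & spans$span_end > g$start)
    if (!length(cand)) next
    assigned_per_read[cand] <- assigned_per_read[cand] + 1L
    ids <- spans$read_id[cand]
    bl <- blocks[data.table::data.table(read_id = ids), on = "read_id",
                 allow.cartesian = TRUE]
    introns <- gene_introns(models, gid)
    ex <- models$exons[models$exons$gene_id == gid, , drop = FALSE]
    ir_b <- IRanges::IRanges(bl$start + 1L, bl$end)
    ih <- if (nrow(introns)) IRanges::overlapsAny(
      ir_b, IRanges::IRanges(introns$start + 1L, introns$end)) else
      rep(FALSE, nrow(bl))
    wi <- if (nrow(ex)) IRanges::overlapsAny(
      ir_b, IRanges::IRanges(ex$start + 1L, ex$end), type = "within") else
      rep(FALSE, nrow(bl))
    bl[, `:=`(ih = ih, wi = wi)]
    # vectorized gap check: rows 2..N of each read pair with their predecessor
    same <- bl$read_id == data.table::shift(bl$read_id)
    gkey <- paste(data.table::shift(bl$end), bl$start)
    ikey <- paste(introns$start, introns$end)
    bl[, gap_ok := TRUE]
    if (any(same, na.rm = TRUE)) {
      bl$gap_ok[which(same)] <- gkey[which(same)] %in% ikey
    }
    agg <- bl[, list(ih = any(ih), allw = all(wi), n = .N,
                     gaps = all(gap_ok)), by = "read_id"]
    state <- ifelse(agg$ih, "unspliced",
             ifelse(!agg$allw, "ambiguous",
             ifelse(agg$n == 1L | agg$gaps, "spliced", "ambiguous")))
    grp <- spans$group[cand][match(agg$read_id, ids)]
    tab <- table(factor(grp, levels = groups),
                 factor(state, levels = c("spliced", "unspliced", "ambiguous")))
    res[[gid]] <- data.frame(gene_id = gid, group = rownames(tab),
                             spliced = as.integer(tab[, "spliced"]),
                             unspliced = as.integer(tab[, "unspliced"]),
                             ambiguous = as.integer(tab[, "ambiguous"]))
  }
  multi_gene <- sum(assigned_per_read > 1L)
  if (multi_gene) er_log("info", multi_gene, " read(s) overlapped multiple genes (counted per gene)")
  unassigned <- sum(assigned_per_read == 0L)
  if (unassigned) er_log("info", unassigned, " read(s) overlapped no gene")
  grid <- expand.grid(gene_id = models$genes$gene_id, group = groups,
                      stringsAsFactors = FALSE)
  out <- merge(grid, do.call(rbind, res), by = c("gene_id", "group"), all.x = TRUE)
  out[is.na(out)] <- 0L
  out <- out[order(out$gene_id, out$group), ]
  rownames(out) <- NULL
  class(out) <- c("SpliceCounts", "data.frame")
  out
}

#' Merge splice counts across groups
#'
#' Component-wise sum; fractions computed after merging equal fractions
#' from summed counts by construction.
#'
#' @param counts a `SpliceCounts`.
#' @param groups groups to merge.
#' @param into name of the merged group.
#' @return a `SpliceCounts` with the merged group only.
#' @export
merge_splice_groups <- function(counts, groups, into = "merged") {
  sub <- counts[counts$group %in% groups, ]
  dt <- data.table::as.data.table(sub)[, list(
    spliced = sum(spliced), unspliced = sum(unspliced),
    ambiguous = sum(ambiguous)), by = "gene_id"]
  out <- data.frame(gene_id = dt$gene_id, group = into, dt[, -1])
  class(out) <- c("SpliceCounts", "data.frame")
  out
}

#' Unspliced/total fraction per gene per group
#'
#' `unspliced / (unspliced + spliced)`; ambiguous reads are excluded from
#' both numerator and denominator.  Genes with zero total are flagged
#' missing (`NA`), never reported as 0.
#'
#' @param counts a `SpliceCounts`.
#' @return data.frame `gene_id`, `group`, `spliced`, `unspliced`,
#'   `fraction` (`NA` when total = 0).
#' @export
unspliced_fraction <- function(counts) {
  tot <- counts$spliced + counts$unspliced
  data.frame(gene_id = counts$gene_id, group = counts$group,
             spliced = counts$spliced, unspliced = counts$unspliced,
             fraction = ifelse(tot > 0, counts$unspliced / tot, NA_real_))
}

#' Genes with detectable unspliced signal in a reference group
#'
#' Strictly greater than `min_frac` (default 1%) in the reference group;
#' genes with missing fractions never qualify.
#'
#' @param fractions output of [unspliced_fraction()].
#' @param reference_group group whose fraction is tested.
#' @param min_frac strict lower bound.
#' @return a `GeneSet`.
#' @export
filter_genes_by_unspliced <- function(fractions, reference_group, min_frac = 0.01) {
  sub <- fractions[fractions$group == reference_group, ]
  keep <- !is.na(sub$fraction) & sub$fraction > min_frac
  gene_set(sort(sub$gene_id[keep]),
           provenance = sprintf("unspliced fraction > %g in %s", min_frac, reference_group))
}

#' Median unspliced fraction of a gene set in one group
#'
#' Median over defined fractions; missing fractions are excluded with a
#' logged count (all-missing is an error).  Even-length medians use the
#' mean-of-middle rule (R's default).
#'
#' @inheritParams filter_genes_by_unspliced
#' @param genes a `GeneSet`.
#' @param group group to summarize.
#' @return a real in `[0, 1]`.
#' @export
median_unspliced <- function(fractions, genes, group) {
  sub <- fractions[fractions$group == group & fractions$gene_id %in% as.character(genes), ]
  n_missing <- sum(is.na(sub$fraction))
  if (n_missing) er_log("info", n_missing, " gene(s) with undefined fraction excluded")
  vals <- sub$fraction[!is.na(sub$fraction)]
  if (!length(vals)) er_stop("all fractions missing for group '%s'", group)
  median(vals)
}

#' Write splice counts as TSV
#'
#' @param counts a `SpliceCounts`.
#' @param path target file.
#' @export
write_splice_counts <- function(counts, path) {
  write.table(counts, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
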
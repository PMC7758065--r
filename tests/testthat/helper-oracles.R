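# Independent brute-force oracles.  Each is deliberately the dumbest
# correct implementation (loops, per-bp sets) so it shares no code path
# with the package functions it checks.

oracle_kendall <- function(x, y) {
  n <- length(x)
  nc <- 0L; nd <- 0L; tx <- 0L; ty <- 0L
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      a <- sign(x[i] - x[j]); b <- sign(y[i] - y[j])
      # a pair tied in x counts toward the x tie term, tied in y toward the
      # y term (a jointly tied pair counts toward both); only untied pairs
      # are concordant/discordant
      if (a == 0) tx <- tx + 1L
      if (b == 0) ty <- ty + 1L
      if (a != 0 && b != 0) {
        if (a == b) nc <- nc + 1L else nd <- nd + 1L
      }
    }
  }
  n0 <- n * (n - 1) / 2
  (nc - nd) / sqrt((n0 - tx) * (n0 - ty))
}

# reads overlapping [ws, we) by >= 1 bp, one window at a time
oracle_window_count <- function(ws, we, rs, re) {
  cnt <- 0L
  for (k in seq_along(rs)) if (rs[k] < we && re[k] > ws) cnt <- cnt + 1L
  cnt
}

# per-bp-set reimplementation of the splice classification rule
oracle_classify <- function(bs, be, gene_start, gene_end, ex_start, ex_end) {
  exon_bp <- unlist(mapply(function(s, e) s:(e - 1), ex_start, ex_end,
                           SIMPLIFY = FALSE))
  gene_bp <- gene_start:(gene_end - 1)
  intron_bp <- setdiff(gene_bp, exon_bp)
  read_bp <- unlist(mapply(function(s, e) s:(e - 1), bs, be, SIMPLIFY = FALSE))
  if (length(intersect(read_bp, intron_bp))) return("unspliced")
  if (length(setdiff(read_bp, exon_bp))) return("ambiguous")
  if (length(bs) == 1) return("spliced")
  intron_keys <- character(0)
  o <- order(ex_start)
  es <- ex_start[o]; ee <- ex_end[o]
  if (length(es) > 1) intron_keys <- paste(ee[-length(ee)], es[-1])
  gaps <- paste(be[-length(be)], bs[-1])
  if (all(gaps %in% intron_keys)) "spliced" else "ambiguous"
}

# distance from a TSS coordinate to an interval [s, e), 0 when inside
oracle_tss_distance <- function(tss, s, e) {
  if (tss < s) s - tss else if (tss >= e) tss - (e - 1) else 0L
}

# small dense CountMatrix with reproducible Poisson counts
random_count_matrix <- function(n_cells, n_genes, lambda = 5, seed = 1) {
  set.seed(seed)
  m <- matrix(rpois(n_cells * n_genes, lambda), nrow = n_cells,
              dimnames = list(sprintf("c%03d", seq_len(n_cells)),
                              sprintf("g%03d", seq_len(n_genes))))
  count_matrix(m)
}

# two-exon toy model used across velocity tests:
# exon1 [100,300), intron [300,500), exon2 [500,800)
two_exon_models <- function() {
  gene_model_set(
    data.frame(gene_id = "gA", chrom = "chr1", strand = "+",
               start = 100L, end = 800L),
    data.frame(gene_id = c("gA", "gA"), start = c(100L, 500L),
               end = c(300L, 800L)))
}

make_alignment <- function(read_id, blocks_start, blocks_end, group = "g1",
                           chrom = "chr1") {
  read_alignments(
    data.frame(read_id = read_id, chrom = chrom, group = group),
    data.frame(read_id = rep(read_id, length(blocks_start)),
               start = blocks_start, end = blocks_end))
}
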
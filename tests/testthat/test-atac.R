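make_read_set <- function(starts, len = 50, lib = NULL, chrom = "chrSim") {
  read_set(data.frame(chrom = chrom, start = starts, end = starts + len),
           library_size = lib)
}

test_that("TSS-window RPKM closed form and edge behavior", {
  models <- toy_tss_models(1, genome_size = 1e6, prefix = "g")
  tss <- models$genes$tss[1]
  rs <- make_read_set(rep(tss - 10, 10), len = 20, lib = 1e6)
  acc <- tss_window_rpkm(rs, models, halfwidth = 250)
  expect_equal(acc$count, 10L)
  expect_equal(acc$rpkm, 20)   # 10 / (0.5 kb * 1 M reads)

  # no reads on the gene's chromosome: count 0, not an error
  rs2 <- make_read_set(100, lib = 1e6, chrom = "other")
  expect_equal(tss_window_rpkm(rs2, models)$count, 0L)
  expect_equal(tss_window_rpkm(rs2, models)$rpkm, 0)

  # RPKM scales inversely with the declared library size
  accA <- tss_window_rpkm(make_read_set(rep(tss, 5), lib = 2e6), models)
  accB <- tss_window_rpkm(make_read_set(rep(tss, 5), lib = 1e6), models)
  expect_equal(accA$rpkm * 2, accB$rpkm)
})

test_that("window counts match the all-pairs overlap oracle", {
  set.seed(22)
  models <- toy_tss_models(80, genome_size = 5e5, prefix = "g")
  starts <- sample(0:(5e5 - 60), 600)
  rs <- make_read_set(starts, len = 60)
  acc <- tss_window_rpkm(rs, models, halfwidth = 250)
  for (i in seq_len(nrow(acc))) {
    expect_identical(acc$count[i],
                     oracle_window_count(acc$window_start[i], acc$window_end[i],
                                         starts, starts + 60))
  }
})

test_that("open/closed classification thresholds and scale switch", {
  t <- data.frame(gene_id = c("a", "b", "c"), chrom = "c",
                  window_start = 0, window_end = 500,
                  count = 1L, rpkm = c(1.2, 5.0, 2.0), label = "unset",
                  row.names = c("a", "b", "c"))
  got <- classify_accessibility(t)
  expect_identical(got$label, c("closed", "open", "indeterminate"))
  expect_error(classify_accessibility(t, closed_max = 3, open_min = 1.5),
               "inversion")
  # log2 scale: same thresholds now interpreted on log2(rpkm)
  got2 <- classify_accessibility(t, closed_max = 1, open_min = 2,
                                 scale = "log2_rpkm")
  # log2(1.2) < 1, log2(5) > 2, log2(2) = 1 sits exactly between
  expect_identical(got2$label, c("closed", "open", "indeterminate"))
})

test_that("metaprofile: spike at zero, minus-strand flipping, pooling identity", {
  models <- gene_model_set(
    data.frame(gene_id = c("gp", "gm"), chrom = "c", strand = c("+", "-"),
               start = c(10000L, 30000L), end = c(11000L, 31000L)),
    data.frame(gene_id = c("gp", "gm"), start = c(10000L, 30000L),
               end = c(11000L, 31000L)))
  # all reads starting exactly at each TSS -> single spike in the 0 bin
  rs <- make_read_set(c(rep(10000, 4), rep(31000, 4)), len = 50, lib = 1e6,
                      chrom = "c")
  prof <- tss_metaprofile(rs, gene_set(c("gp", "gm")), models,
                          flank = 500, binsize = 50)
  spike <- prof$bin_offset[prof$mean_signal > 0]
  expect_equal(spike, 25)   # the bin covering offset [0, 50)

  # minus-strand gene: read 100 bp downstream (genomic left) maps to +100
  rs2 <- make_read_set(31000 - 100, len = 50, lib = 1e6, chrom = "c")
  prof2 <- tss_metaprofile(rs2, gene_set("gm"), models, flank = 500, binsize = 50)
  expect_equal(prof2$bin_offset[prof2$mean_signal > 0], 125)

  # pooled reads give the read-count-weighted mean of per-set profiles
  set.seed(5)
  sA <- sample(5000:35000, 300); sB <- sample(5000:35000, 200)
  gg <- gene_set(c("gp", "gm"))
  pA <- tss_metaprofile(make_read_set(sA, chrom = "c"), gg, models)
  pB <- tss_metaprofile(make_read_set(sB, chrom = "c"), gg, models)
  pAB <- tss_metaprofile(make_read_set(c(sA, sB), chrom = "c"), gg, models)
  expect_equal(pAB$mean_signal * 500 / 1e6,
               pA$mean_signal * 300 / 1e6 + pB$mean_signal * 200 / 1e6,
               tolerance = 1e-12)
})

test_that("uniform reads give a flat metaprofile within Poisson bounds", {
  set.seed(30)
  models <- toy_tss_models(20, genome_size = 1e6, prefix = "g")
  n_reads <- 20000
  rs <- make_read_set(sample(0:(1e6 - 50), n_reads, replace = TRUE))
  prof <- tss_metaprofile(rs, gene_set(models$genes$gene_id), models,
                          flank = 1000, binsize = 100)
  # per-bin read-start counts across 20 genes ~ Poisson(20 * n * binsize / G)
  lambda <- 20 * n_reads * 100 / 1e6
  counts <- prof$mean_signal * 20 * (n_reads / 1e6)
  expect_true(all(abs(counts - lambda) < 4 * sqrt(lambda)))
})

test_that("housekeeping-relative accessibility uses the geometric mean", {
  t <- data.frame(gene_id = c("g", "hk1", "hk2", "z"), chrom = "c",
                  window_start = 0, window_end = 500, count = 1L,
                  rpkm = c(8, 4, 16, 0), label = "unset",
                  row.names = c("g", "hk1", "hk2", "z"))
  hk <- gene_set(c("hk1", "hk2"))
  expect_equal(relative_accessibility(t, "g", hk), 1.0)
  expect_equal(relative_accessibility(t, "z", hk), 0.0)
  expect_error(relative_accessibility(t, "g", gene_set(c("hk1", "z"))),
               "zero housekeeping")
  # random table against direct recomputation
  set.seed(12)
  t$rpkm <- runif(4, 1, 50)
  expect_equal(relative_accessibility(t, "g", hk),
               t["g", "rpkm"] / sqrt(t["hk1", "rpkm"] * t["hk2", "rpkm"]))
})

test_that("tissue-enriched selection applies baseline and fold gates", {
  expr <- matrix(c(20, 5, 8,
                   20, 15, 2,
                   9, 1, 1), nrow = 3, byrow = TRUE,
                 dimnames = list(c("gA", "gB", "gC"),
                                 c("heart", "brain", "lung")))
  got <- select_tissue_enriched(expr, "heart", c("brain", "lung"))
  expect_identical(as.character(got), "gA")   # gB fails fold, gC fails baseline
  expect_error(select_tissue_enriched(expr, "heart", character(0)), "empty")
})

test_that("peak set comparison: examples, symmetry, brute-force partition", {
  A <- peak_set(data.frame(chrom = "c", start = 0, end = 100))
  B <- peak_set(data.frame(chrom = "c", start = 50, end = 150))
  r <- peak_set_compare(A, B)
  expect_equal(nrow(r$shared_a$peaks), 1)
  expect_equal(nrow(r$unique_a$peaks), 0)

  B2 <- peak_set(data.frame(chrom = "c", start = 200, end = 300))
  r2 <- peak_set_compare(A, B2)
  expect_equal(nrow(r2$unique_a$peaks), 1)
  expect_equal(nrow(r2$unique_b$peaks), 1)

  set.seed(40)
  mk <- function(n) data.frame(chrom = sample(c("c1", "c2"), n, TRUE),
                               start = s <- sample(0:20000, n),
                               end = s + sample(50:500, n, TRUE))
  pa <- peak_set(mk(300)); pb <- peak_set(mk(300))
  res <- peak_set_compare(pa, pb)
  # partition property
  expect_equal(nrow(res$unique_a$peaks) + nrow(res$shared_a$peaks), 300)
  # symmetry
  swapped <- peak_set_compare(pb, pa)
  expect_equal(res$unique_a$peaks, swapped$unique_b$peaks)
  expect_equal(res$shared_b$peaks, swapped$shared_a$peaks)
  # brute force on set a
  shared_oracle <- vapply(seq_len(300), function(i) {
    any(pa$peaks$chrom[i] == pb$peaks$chrom &
        pa$peaks$start[i] < pb$peaks$end & pa$peaks$end[i] > pb$peaks$start)
  }, logical(1))
  expect_equal(nrow(res$shared_a$peaks), sum(shared_oracle))
})

test_that("peak-to-gene assignment respects the 2 kb TSS distance", {
  models <- gene_model_set(
    data.frame(gene_id = c("g1", "g2"), chrom = "c", strand = "+",
               start = c(1100L, 3300L), end = c(2000L, 4000L)),
    data.frame(gene_id = c("g1", "g2"), start = c(1100L, 3300L),
               end = c(2000L, 4000L)))
  p <- peak_set(data.frame(chrom = "c", start = 1000, end = 1200))
  got <- annotate_peaks_to_genes(p, models, max_dist = 2000)
  expect_identical(got$gene_id, "g1")        # TSS 1100 inside the peak
  expect_equal(got$distance, 0)              # g2 at distance 2101 excluded

  set.seed(41)
  models2 <- toy_tss_models(50, genome_size = 2e5, prefix = "g")
  pk <- peak_set(data.frame(chrom = "chrSim",
                            start = s <- sample(0:(2e5 - 500), 40),
                            end = s + sample(100:500, 40, TRUE)))
  got2 <- annotate_peaks_to_genes(pk, models2, max_dist = 2000)
  for (i in seq_len(40)) {
    want <- models2$genes$gene_id[vapply(models2$genes$tss, function(t)
      oracle_tss_distance(t, pk$peaks$start[i], pk$peaks$end[i]) <= 2000,
      logical(1))]
    expect_setequal(got2$gene_id[got2$peak_idx == i], want)
  }
})

test_that("BED and narrowPeak files round-trip through the interval readers", {
  d <- withr::local_tempdir()
  rs <- make_read_set(c(10, 20, 30))
  write_intervals_bed(rs, file.path(d, "reads.bed"))
  back <- read_intervals_bed(file.path(d, "reads.bed"), "reads")
  expect_equal(as.data.frame(back$intervals), as.data.frame(rs$intervals))
  expect_equal(back$library_size, 3)

  np <- peak_set(data.frame(chrom = "c1", start = 0L, end = 100L, name = "p1",
                            score = 100L, strand = ".", signalValue = 5.5,
                            pValue = 2.0, qValue = 1.5, peak = 50L))
  write_intervals_bed(np, file.path(d, "peaks.narrowPeak"))
  pback <- read_intervals_bed(file.path(d, "peaks.narrowPeak"), "peaks")
  expect_equal(as.data.frame(pback$peaks), as.data.frame(np$peaks))
})
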
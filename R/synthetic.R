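#' Scenario ground truth for the synthetic generators
#'
#' Encodes the two hypotheses the evidence chain contrasts, as a
#' generative stated world.  Under `"contamination"` a fraction `f` of
#' every target cell's library is resampled from the pooled parenchymal
#' profile (the standard ambient-RNA assumption) and the shared
#' transcripts are mature and chromatin-closed in the target population.
#' Under `"intrinsic"` each (cell, parenchymal gene) pair activates
#' independently with burst probability `p_on`, nascent fractions are
#' elevated in the target population, and marker-gene chromatin is open.
#' `"mixed"` applies both expression mechanisms.
#'
#' Default nascent fractions (target 0.054, parenchyma 0.024) mimic the
#' reported medians for the cardiac endothelial/cardiomyocyte contrast;
#' they are parameters, not constants.
#'
#' @param scenario `"contamination"`, `"intrinsic"` or `"mixed"`.
#' @param seed master seed; all generator randomness derives from it.
#' @param n_genes size of the toy gene universe.
#' @param n_parenchymal_genes number of parenchyma-exclusive genes.
#' @param contamination_fraction ambient fraction `f` (contamination/mixed).
#' @param ambient_sigma log-normal spread of the per-cell ambient fraction
#'   (mean-preserving; ambient load varies between cells, as it does in
#'   real dissociations).
#' @param p_on per-(cell,gene) burst probability (intrinsic/mixed).
#' @param burst_mean_cpm expected CPM of an active burst gene.
#' @param nascent_target,nascent_parenchyma pre-mRNA read fractions.
#' @return a `ScenarioTruth` list.
#' @export
scenario_truth <- function(scenario = c("intrinsic", "contamination", "mixed"),
                           seed = 1L,
                           n_genes = 2000L,
                           n_parenchymal_genes = 150L,
                           contamination_fraction = NULL,
                           ambient_sigma = 0.5,
                           p_on = NULL,
                           burst_mean_cpm = 50,
                           nascent_target = NULL,
                           nascent_parenchyma = 0.024) {
  scenario <- match.arg(scenario)
  f <- if (!is.null(contamination_fraction)) contamination_fraction else
    switch(scenario, contamination = 0.02, intrinsic = 0, mixed = 0.02)
  pon <- if (!is.null(p_on)) p_on else
    switch(scenario, contamination = 0, intrinsic = 0.08, mixed = 0.08)
  rho_t <- if (!is.null(nascent_target)) nascent_target else
    switch(scenario, contamination = 0.005, intrinsic = 0.054, mixed = 0.054)
  stopifnot(f >= 0, f <= 1, pon >= 0, pon <= 1,
            rho_t >= 0, rho_t <= 1, nascent_parenchyma >= 0, nascent_parenchyma <= 1)
  set.seed(derive_seed(seed, 7L))
  gene_ids <- sprintf("g%04d", seq_len(n_genes))
  parenchymal <- sort(sample(gene_ids, n_parenchymal_genes))
  structure(list(
    scenario = scenario,
    seed = as.integer(seed),
    n_genes = as.integer(n_genes),
    gene_ids = gene_ids,
    parenchymal_genes = parenchymal,
    contamination_fraction = f,
    ambient_sigma = ambient_sigma,
    p_on = pon,
    burst_mean_cpm = burst_mean_cpm,
    nascent = c(target = rho_t, parenchyma = nascent_parenchyma),
    marker_chromatin = if (scenario == "contamination") "closed" else "open",
    groups = c(target = "target", parenchyma = "parenchyma")
  ), class = "ScenarioTruth")
}

#' @export
print.ScenarioTruth <- function(x, ...) {
  cat(sprintf(
    "ScenarioTruth '%s' (seed %d): f=%g, p_on=%g, nascent=%g/%g, chromatin=%s\n",
    x$scenario, x$seed, x$contamination_fraction, x$p_on,
    x$nascent[["target"]], x$nascent[["parenchyma"]], x$marker_chromatin))
  invisible(x)
}

#' Write scenario truth as JSON
#'
#' @param truth a `ScenarioTruth`.
#' @param path output file.
#' @export
write_scenario_truth <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Simulate a two-population expression matrix
#'
#' Parenchymal cells draw counts multinomially from a log-normal
#' (sigma = 1) base profile in which the parenchyma-exclusive genes are
#' elevated 10-100x (log-uniform).  Target cells draw from an independent
#' log-normal base profile that is exactly zero on parenchymal genes,
#' then per scenario: *contamination* replaces a Binomial(depth, f)
#' portion of each cell's library with draws from the pooled empirical
#' parenchymal profile; *intrinsic* activates each (cell, parenchymal
#' gene) pair with probability `p_on`, adding log-normal expression for
#' that gene only (expected `burst_mean_cpm` CPM).  Identical seeds give
#' identical output.
#'
#' @param truth a [scenario_truth()].
#' @param n_parenchyma,n_target cell numbers.
#' @param depth per-cell library size.
#' @return list with `matrix` (`CountMatrix`), `annotation`
#'   (`CellAnnotation`), `truth`, and `ambient_reads` (per-target-cell
#'   contaminating read counts, all zero outside contamination/mixed).
#' @export
simulate_expression <- function(truth, n_parenchyma = 200, n_target = 500,
                                depth = 1e5) {
  stopifnot(inherits(truth, "ScenarioTruth"))
  if (depth <= 0) er_stop("depth must be positive")
  set.seed(derive_seed(truth$seed, 1L))
  ng <- truth$n_genes
  par_idx <- match(truth$parenchymal_genes, truth$gene_ids)

  w_par <- rlnorm(ng, 0, 1)
  w_par[par_idx] <- w_par[par_idx] * 10^runif(length(par_idx), 1, 2)
  w_tgt <- rlnorm(ng, 0, 1)
  w_tgt[par_idx] <- 0
  w_tgt <- w_tgt / sum(w_tgt)

  counts_par <- rmultinom(n_parenchyma, depth, w_par)   # genes x cells
  ambient_profile <- rowSums(counts_par)
  if (sum(ambient_profile) == 0) ambient_profile <- w_par

  f <- truth$contamination_fraction
  pon <- truth$p_on
  burst_share <- truth$burst_mean_cpm / 1e6 / exp(0.5)  # lognormal(0,1) mean
  counts_tgt <- matrix(0L, nrow = ng, ncol = n_target)
  ambient_reads <- integer(n_target)
  amb_n <- if (f > 0) {
    sig <- truth$ambient_sigma
    f_cell <- pmin(f * rlnorm(n_target, -sig^2 / 2, sig), 1)
    rbinom(n_target, depth, f_cell)
  } else integer(n_target)
  for (i in seq_len(n_target)) {
    w <- w_tgt
    if (pon > 0) {
      on <- par_idx[runif(length(par_idx)) < pon]
      if (length(on)) w[on] <- w[on] + burst_share * rlnorm(length(on), 0, 1)
    }
    own <- depth - amb_n[i]
    ci <- rmultinom(1, own, w)[, 1]
    if (amb_n[i] > 0) {
      ci <- ci + rmultinom(1, amb_n[i], ambient_profile)[, 1]
      ambient_reads[i] <- amb_n[i]
    }
    counts_tgt[, i] <- ci
  }

  cells <- c(sprintf("par_%04d", seq_len(n_parenchyma)),
             sprintf("tgt_%04d", seq_len(n_target)))
  counts <- t(cbind(counts_par, counts_tgt))
  dimnames(counts) <- list(cells, truth$gene_ids)
  ann <- cell_annotation(data.frame(
    cell_id = cells,
    cell_type = c(rep(truth$groups[["parenchyma"]], n_parenchyma),
                  rep(truth$groups[["target"]], n_target)),
    tissue = "sim_tissue"))
  names(ambient_reads) <- cells[(n_parenchyma + 1):length(cells)]
  list(matrix = count_matrix(counts), annotation = ann, truth = truth,
       ambient_reads = ambient_reads)
}

#' Toy multi-exon gene models
#'
#' Genes laid head-to-tail (5 kb gaps) on one toy chromosome, each with
#' 2-4 exons of 150-400 bp separated by introns of 200-1500 bp.  Exon
#' lengths exceed the default simulated read length, so a mature read
#' spans at most two exons.
#'
#' @param n_genes number of genes.
#' @param seed integer seed.
#' @param chrom chromosome name.
#' @return a `GeneModelSet`.
#' @export
toy_gene_models <- function(n_genes = 40, seed = 1L, chrom = "chrSim") {
  set.seed(seed)
  pos <- 1000L
  genes <- list(); exons <- list()
  for (i in seq_len(n_genes)) {
    gid <- sprintf("tg%03d", i)
    n_ex <- sample(2:4, 1)
    ex_len <- sample(150:400, n_ex, replace = TRUE)
    in_len <- sample(200:1500, n_ex - 1, replace = TRUE)
    s <- pos
    es <- integer(n_ex); ee <- integer(n_ex)
    for (j in seq_len(n_ex)) {
      es[j] <- s
      ee[j] <- s + ex_len[j]
      s <- ee[j] + if (j < n_ex) in_len[j] else 0L
    }
    genes[[i]] <- data.frame(gene_id = gid, chrom = chrom,
                             strand = sample(c("+", "-"), 1),
                             start = pos, end = ee[n_ex])
    exons[[i]] <- data.frame(gene_id = gid, start = es, end = ee)
    pos <- ee[n_ex] + 5000L
  }
  gene_model_set(do.call(rbind, genes), do.call(rbind, exons))
}

#' Intronless point-TSS toy models for accessibility simulation
#'
#' Single-exon genes with TSSs placed on a regular grid (with margin) on
#' one toy chromosome, used as accessibility targets.
#'
#' @param n_genes number of genes.
#' @param genome_size chromosome length in bp.
#' @param gene_length span of each toy gene.
#' @param prefix gene id prefix.
#' @param chrom chromosome name.
#' @return a `GeneModelSet`.
#' @export
toy_tss_models <- function(n_genes = 400, genome_size = 1e7,
                           gene_length = 1000L, prefix = "ag",
                           chrom = "chrSim") {
  margin <- 5000
  starts <- as.integer(round(seq(margin, genome_size - margin - gene_length,
                                 length.out = n_genes)))
  gene_model_set(
    data.frame(gene_id = sprintf("%s%04d", prefix, seq_len(n_genes)),
               chrom = chrom, strand = "+",
               start = starts, end = starts + gene_length),
    data.frame(gene_id = sprintf("%s%04d", prefix, seq_len(n_genes)),
               start = starts, end = starts + gene_length))
}

#' Simulate spliced/unspliced read mixtures
#'
#' For each population, each read comes from a mature transcript with
#' probability `1 - rho` (uniform placement along the spliced transcript,
#' mapped back to genomic blocks, junction-split) or from pre-mRNA with
#' probability `rho` (single block uniform over the gene span, introns
#' included), with `rho` the population's nascent fraction from the
#' truth.  Genes are sampled uniformly.  Note the pipeline-recovered
#' unspliced fraction is biased low relative to `rho` because pre-mRNA
#' reads that land fully inside an exon classify as spliced; the exact
#' expectation is [expected_unspliced_fraction()].
#'
#' @param truth a `ScenarioTruth`.
#' @param models optional `GeneModelSet`; defaults to
#'   [toy_gene_models()] under a derived seed.
#' @param reads_per_group reads simulated per population.
#' @param n_genes toy gene count when `models` is NULL.
#' @param read_length read length in bp.
#' @return list with `alignments` (`ReadAlignments`), `models`, `truth`.
#' @export
simulate_splice_reads <- function(truth, models = NULL, reads_per_group = 2e4,
                                  n_genes = 40, read_length = 100) {
  stopifnot(inherits(truth, "ScenarioTruth"))
  if (is.null(models)) {
    models <- toy_gene_models(n_genes, seed = derive_seed(truth$seed, 20L))
  }
  set.seed(derive_seed(truth$seed, 2L))
  rl <- as.integer(read_length)
  g <- models$genes
  ex_by_gene <- split(models$exons, models$exons$gene_id)

  all_reads <- list(); all_blocks <- list()
  for (pop in names(truth$nascent)) {
    grp <- truth$groups[[pop]]
    rho <- truth$nascent[[pop]]
    n <- reads_per_group
    gene_i <- sample(nrow(g), n, replace = TRUE)
    is_pre <- runif(n) < rho
    ids <- sprintf("%s_r%06d", grp, seq_len(n))
    bs <- vector("list", nrow(g))
    for (gi in sort(unique(gene_i))) {
      sel <- which(gene_i == gi)
      ex <- ex_by_gene[[g$gene_id[gi]]]
      ex <- ex[order(ex$start), ]
      elen <- ex$end - ex$start
      cum <- cumsum(c(0L, elen))          # transcript offsets of exon starts
      Lt <- cum[length(cum)]
      pre <- sel[is_pre[sel]]
      mat <- sel[!is_pre[sel]]
      blk <- list()
      if (length(pre)) {
        s0 <- g$start[gi] + floor(runif(length(pre)) * (g$end[gi] - g$start[gi] - rl + 1))
        blk$pre <- data.frame(read_id = ids[pre], start = as.integer(s0),
                              end = as.integer(s0 + rl))
      }
      if (length(mat)) {
        ts <- floor(runif(length(mat)) * (Lt - rl + 1))   # transcript start
        te <- ts + rl
        i1 <- findInterval(ts, cum[-length(cum)], rightmost.closed = FALSE)
        i2 <- findInterval(te - 1, cum[-length(cum)])
        if (any(i2 - i1 > 1L)) {
          er_stop("read length exceeds an exon: supply models with exons >= read_length")
        }
        gs1 <- ex$start[i1] + (ts - cum[i1])
        one <- i1 == i2
        if (any(one)) {
          blk$m1 <- data.frame(read_id = ids[mat][one],
                               start = as.integer(gs1[one]),
                               end = as.integer(gs1[one] + rl))
        }
        if (any(!one)) {
          two <- !one
          b1e <- ex$end[i1[two]]
          b2s <- ex$start[i2[two]]
          b2e <- b2s + (te[two] - cum[i2[two]])
          blk$m2 <- data.frame(
            read_id = rep(ids[mat][two], 2L),
            start = as.integer(c(gs1[two], b2s)),
            end = as.integer(c(b1e, b2e)))
        }
      }
      bs[[gi]] <- do.call(rbind, blk)
    }
    all_reads[[pop]] <- data.frame(read_id = ids, chrom = g$chrom[1],
                                   strand = "*", group = grp)
    all_blocks[[pop]] <- do.call(rbind, bs)
  }
  aln <- read_alignments(do.call(rbind, all_reads), do.call(rbind, all_blocks))
  list(alignments = aln, models = models, truth = truth)
}

#' Expected recovered unspliced fraction under the splice generator
#'
#' Closed-form enumeration of pre-mRNA read-placement classes: a pre-mRNA
#' read of length `L` placed uniformly over the `S`-bp gene span has
#' `S - L + 1` placements, of which `sum(max(0, exon_len - L + 1))` lie
#' fully within one exon (and classify as spliced); the rest overlap an
#' intron.  Mature reads always classify as spliced.  With reads
#' allocated uniformly across genes, the expected pooled recovered
#' fraction is `rho * mean_g P(intron overlap | gene g)`.
#'
#' @param models a `GeneModelSet`.
#' @param rho nascent (pre-mRNA) probability.
#' @param read_length read length in bp.
#' @return the expected pooled unspliced/total fraction.
#' @export
expected_unspliced_fraction <- function(models, rho, read_length = 100) {
  rl <- read_length
  p_int <- vapply(models$genes$gene_id, function(gid) {
    g <- models$genes[gid, ]
    ex <- models$exons[models$exons$gene_id == gid, ]
    n_placements <- g$end - g$start - rl + 1
    exonic <- sum(pmax(0, (ex$end - ex$start) - rl + 1))
    1 - exonic / n_placements
  }, numeric(1))
  rho * mean(p_int)
}

#' Simulate TSS-localized accessibility reads
#'
#' Reads fall either on a uniform toy-genome background or in pileups at
#' the TSSs of *open* genes, with the read-center displacement from the
#' TSS drawn from a symmetric double-exponential (Laplace) with the given
#' scale.  Each open gene's pileup weight is `open_enrichment` times a
#' 500-bp window of background, so `open_enrichment = 0` makes open and
#' closed genes indistinguishable.  Seed-deterministic.
#'
#' @param truth a `ScenarioTruth` (provides the seed).
#' @param models a `GeneModelSet` of accessibility target genes.
#' @param open_genes character vector of genes whose TSSs are open; all
#'   other model genes are closed.
#' @param reads_total total reads (= declared library size).
#' @param open_enrichment pileup density enrichment over background.  The
#'   default corresponds to a library almost entirely within peaks, which
#'   on a 10-Mb toy genome reproduces the background-vs-peak RPKM
#'   contrast that genome-scale ATAC libraries show.
#' @param read_length read length in bp.
#' @param laplace_scale Laplace displacement scale in bp.
#' @param genome_size toy genome length.
#' @return list with `reads` (`ReadSet`), `open_genes`, `truth`.
#' @export
simulate_atac_reads <- function(truth, models, open_genes,
                                reads_total = 1e5, open_enrichment = 1e4,
                                read_length = 50, laplace_scale = 150,
                                genome_size = 1e7) {
  stopifnot(inherits(truth, "ScenarioTruth"))
  set.seed(derive_seed(truth$seed, 3L))
  rl <- as.integer(read_length)
  open_genes <- intersect(open_genes, models$genes$gene_id)
  tss <- models$genes[open_genes, "tss"]
  w_open <- rep(open_enrichment * 500, length(open_genes))
  probs <- c(genome_size, w_open)
  assign <- sample.int(length(probs), reads_total, replace = TRUE, prob = probs) - 1L
  starts <- integer(reads_total)
  bg <- assign == 0L
  starts[bg] <- floor(runif(sum(bg)) * (genome_size - rl))
  if (any(!bg)) {
    d <- laplace_scale * (rexp(sum(!bg)) - rexp(sum(!bg)))
    s <- tss[assign[!bg]] + round(d) - rl %/% 2L
    starts[!bg] <- pmin(pmax(s, 0), genome_size - rl)
  }
  intervals <- data.frame(chrom = models$genes$chrom[1],
                          start = as.integer(starts),
                          end = as.integer(starts + rl))
  list(reads = read_set(intervals, library_size = reads_total),
       open_genes = open_genes, truth = truth)
}
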
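test_that("top_expressed_genes: ordering, boundary ties, brute-force agreement", {
  p <- c(a = 5, b = 9, c = 5)
  expect_identical(as.character(top_expressed_genes(p, 2)), c("b", "a"))

  set.seed(4)
  prof <- setNames(round(runif(1000) * 50), sprintf("g%04d", 1:1000))
  got <- as.character(top_expressed_genes(prof, 300))
  expected <- names(prof)[order(-prof, names(prof))][1:300]
  expect_identical(got, expected)

  expect_length(suppressMessages(top_expressed_genes(p, 10)), 3)
  expect_error(top_expressed_genes(numeric(0)), "empty")
})

test_that("kendall_tau: canonical values and error paths", {
  expect_equal(kendall_tau(1:4, 1:4), 1.0)
  expect_equal(kendall_tau(c(1, 2, 3), c(3, 2, 1)), -1.0)
  expect_error(kendall_tau(1:3, 1:4), "length mismatch")
  expect_error(kendall_tau(1, 1), "length >= 2")
  expect_error(kendall_tau(c(1, 1, 1), 1:3), "tied")
})

test_that("kendall_tau equals the pair-count oracle and stats::cor with ties", {
  set.seed(8)
  for (i in 1:50) {
    n <- sample(2:40, 1)
    x <- sample(1:8, n, replace = TRUE)   # heavy ties
    y <- sample(1:8, n, replace = TRUE)
    if (length(unique(x)) < 2 || length(unique(y)) < 2) next
    expect_equal(kendall_tau(x, y), oracle_kendall(x, y))
    expect_equal(kendall_tau(x, y), cor(x, y, method = "kendall"))
  }
})

test_that("kendall_tau is invariant under strictly increasing transforms", {
  set.seed(9)
  x <- rnorm(30); y <- rnorm(30)
  t0 <- kendall_tau(x, y)
  expect_equal(kendall_tau(exp(x), y), t0)
  expect_equal(kendall_tau(x, y^3 + 5 * y), t0)
  expect_equal(kendall_tau(rank(x), rank(y)), t0)
})

test_that("contamination_rank_test: identity, nulls, universe handling", {
  set.seed(10)
  prof <- setNames(rlnorm(800, 4, 2), sprintf("g%04d", 1:800))
  expect_equal(contamination_rank_test(prof, prof, n = 300)$tau, 1.0)

  # two independent permutations of the same values: tau near zero
  p1 <- setNames(sample(prof), names(prof))
  p2 <- setNames(sample(prof), names(prof))
  tau0 <- contamination_rank_test(p1, p2, n = 300)$tau
  expect_lt(abs(tau0), 0.1)

  expect_error(contamination_rank_test(c(a = 1, b = 2), c(x = 1, y = 2)),
               "disjoint")
  r <- suppressMessages(contamination_rank_test(prof[1:100], prof[1:100], n = 300))
  expect_equal(r$n_genes, 100)
  expect_equal(length(r$gene_universe), r$n_genes)
})

test_that("simulated scenarios separate in tau (frozen regression fixtures)", {
  pool <- function(sim, g) {
    cells <- sim$annotation$cell_id[sim$annotation$cell_type == g]
    v <- Matrix::colSums(sim$matrix$counts[cells, , drop = FALSE])
    v / sum(v) * 1e6
  }
  tr_c <- scenario_truth("contamination", seed = 1, contamination_fraction = 0.05)
  sim_c <- simulate_expression(tr_c, 100, 200, depth = 1e6)
  tau_c <- contamination_rank_test(pool(sim_c, "target"), pool(sim_c, "parenchyma"))$tau

  tr_i <- scenario_truth("intrinsic", seed = 1)
  sim_i <- simulate_expression(tr_i, 100, 200, depth = 1e6)
  tau_i <- contamination_rank_test(pool(sim_i, "target"), pool(sim_i, "parenchyma"))$tau

  # deterministic world: exact regression values, plus the ordering that matters
  expect_equal(tau_c, 0.0377039, tolerance = 1e-4)
  expect_equal(tau_i, -0.4627117, tolerance = 1e-4)
  expect_gt(tau_c, tau_i + 0.15)
})

test_that("positivity matrix: inclusive boundary and missing genes", {
  m <- count_matrix(matrix(c(5L, 0L, 3L, 2L), 2, 2,
                           dimnames = list(c("c1", "c2"), c("g1", "g2"))))
  norm <- to_log1p_cpm(m)
  # plant exact boundary values
  norm$values["c1", "g1"] <- 1.0
  norm$values["c1", "g2"] <- 0.99
  p <- positivity_matrix(norm, gene_set(c("g1", "g2")))
  expect_identical(p["c1", "g1"], 1L)   # >= 1 counts as positive
  expect_identical(p["c1", "g2"], 0L)

  expect_error(positivity_matrix(norm, gene_set("gX")), "absent.*gX")
  expect_error(positivity_matrix(to_cpm(m), gene_set("g1")), "log1p_cpm")

  # an all-zero cell is an all-negative row
  mz <- count_matrix(matrix(c(9L, 0L), 2, 1, dimnames = list(c("c1", "c2"), "g1")))
  pz <- positivity_matrix(suppressMessages(to_log1p_cpm(mz)), gene_set("g1"))
  expect_identical(unname(pz["c2", ]), 0L)
})

test_that("marker count distribution: histograms, medians, threshold monotonicity", {
  p <- matrix(c(0L, 0L, 0L,
                1L, 0L, 0L,
                1L, 1L, 0L), 3, 3, byrow = TRUE,
              dimnames = list(c("c1", "c2", "c3"), c("m1", "m2", "m3")))
  attr(p, "zero_cells") <- character()
  ann <- cell_annotation(data.frame(cell_id = rownames(p), cell_type = "EC",
                                    tissue = "t"))
  d <- marker_count_distribution(p, ann, "EC")
  expect_identical(unname(d$EC$histogram), c(1L, 1L, 1L, 0L))
  expect_equal(d$EC$frac_ge1, 2 / 3)
  expect_equal(d$EC$median_positive, 1.5)

  pfull <- p; pfull[] <- 1L; attr(pfull, "zero_cells") <- character()
  dfull <- marker_count_distribution(pfull, ann, "EC")
  expect_equal(dfull$EC$frac_ge1, 1)
  expect_equal(dfull$EC$median_positive, 3)

  expect_error(marker_count_distribution(p, ann, "missing_group"), "empty group")

  # frac_ge1 non-decreasing as the threshold decreases
  set.seed(2)
  m <- count_matrix(matrix(rpois(200 * 10, 3), 200,
                           dimnames = list(sprintf("c%03d", 1:200),
                                           sprintf("m%02d", 1:10))))
  norm <- to_log1p_cpm(m)
  ann2 <- cell_annotation(data.frame(cell_id = rownames(norm$values),
                                     cell_type = "EC", tissue = "t"))
  fracs <- sapply(c(2, 1.5, 1, 0.5), function(th) {
    pm <- positivity_matrix(norm, gene_set(sprintf("m%02d", 1:10)), threshold = th)
    marker_count_distribution(pm, ann2, "EC")$EC$frac_ge1
  })
  expect_true(all(diff(fracs) >= 0))
})

test_that("intrinsic-world frac_ge1 matches the independence expectation", {
  truth <- scenario_truth("intrinsic", seed = 21)
  sim <- simulate_expression(truth, n_parenchyma = 100, n_target = 600)
  norm <- to_log1p_cpm(sim$matrix)
  markers <- select_parenchymal_markers(norm, sim$annotation, "parenchyma", n = 15)
  p <- positivity_matrix(norm, markers)
  d <- marker_count_distribution(p, sim$annotation, "target")

  tcells <- sim$annotation$cell_id[sim$annotation$cell_type == "target"]
  p_eff <- colMeans(p[tcells, , drop = FALSE])       # per-gene detection rate
  expected <- 1 - prod(1 - p_eff)
  se <- sqrt(expected * (1 - expected) / length(tcells))
  expect_lt(abs(d$target$frac_ge1 - expected), 3 * se + 1e-3)
  # sporadic expression: most positive cells carry only one or two markers
  expect_lte(d$target$median_positive, 2)
})

test_that("classical MDS embeds distances faithfully", {
  # three profiles with pairwise Euclidean distances 3, 4, 5
  prof <- matrix(c(0, 0, 3, 0, 3, 4), nrow = 2,
                 dimnames = list(c("g1", "g2"), c("A", "B", "C")))
  xy <- mds_embed(prof, top_variable = 2, log_scale = FALSE)
  d <- as.matrix(dist(xy))
  expect_equal(d["A", "B"], 3, tolerance = 1e-6)
  expect_equal(d["B", "C"], 4, tolerance = 1e-6)
  expect_equal(d["A", "C"], 5, tolerance = 1e-6)
  expect_equal(colMeans(xy), c(dim1 = 0, dim2 = 0), tolerance = 1e-9)

  # identical profiles land on the same point
  set.seed(6)
  base <- matrix(rlnorm(200 * 4, 3, 1), 200,
                 dimnames = list(sprintf("g%03d", 1:200), c("s1", "s2", "s3", "s4")))
  base[, "s4"] <- base[, "s1"]
  xy2 <- mds_embed(base, top_variable = 100)
  expect_lt(sqrt(sum((xy2["s1", ] - xy2["s4", ])^2)), 1e-9)

  # rigid rotation leaves pairwise distances unchanged
  th <- 0.7; R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  expect_equal(as.matrix(dist(xy2 %*% R)), as.matrix(dist(xy2)), tolerance = 1e-9)

  expect_error(mds_embed(prof[, 1:2, drop = FALSE]), ">= 3 samples")
})

test_that("TauResult and distributions serialize to JSON and TSV", {
  prof <- setNames(rlnorm(400, 4, 1), sprintf("g%04d", 1:400))
  tau <- contamination_rank_test(prof, prof, n = 100)
  d <- withr::local_tempdir()
  write_result(tau, file.path(d, "tau.json"), "json")
  back <- jsonlite::read_json(file.path(d, "tau.json"), simplifyVector = TRUE)
  expect_equal(back$tau, 1.0)
  expect_equal(back$n_genes, 100)
  write_result(tau, file.path(d, "tau.tsv"), "tsv")
  expect_equal(read.delim(file.path(d, "tau.tsv"))$tau, 1.0)
})
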
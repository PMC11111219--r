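test_that("expression bins are rank-quantile cuts with matrix-order tie-breaking", {
  norm <- make_counts(cbind(c(1, 2, 9, 10), c(1, 2, 9, 10))) / 10
  expect_identical(unname(assign_expression_bins(norm, n_bins = 2)),
                   c(1L, 1L, 2L, 2L))
  # all means equal: first half of genes (matrix order) lands in bin 1
  tied <- make_counts(matrix(3L, 4, 2))
  expect_identical(unname(assign_expression_bins(tied, n_bins = 2)),
                   c(1L, 1L, 2L, 2L))
  # one bin per gene
  expect_identical(sort(unname(assign_expression_bins(tied, n_bins = 4))), 1:4)
  expect_error(assign_expression_bins(tied, n_bins = 0), "n_bins")
  expect_error(assign_expression_bins(tied, n_bins = 9), "genes")
})

test_that("module score matches the hand-computed small example", {
  # 4 genes x 2 cells, set = {g1}, one bin, full control pool {g2,g3,g4}
  norm <- make_counts(rbind(c(1, 2), c(1, 2), c(0, 0), c(0, 0)))
  sc <- score_module(norm, gene_set("s", "g1"), n_bins = 1, n_ctrl = 3, seed = 1)
  expect_equal(unname(sc$score), c(1 - 1 / 3, 2 - 2 / 3), tolerance = 1e-12)
  expect_setequal(sc$control_genes, c("g2", "g3", "g4"))
})

test_that("module scores are deterministic given a seed and shift with the set genes", {
  sim <- simulate_dataset(small_sim_config(), seed = 8)
  qc <- compute_cell_qc(sim$counts)
  norm <- log_normalize(filter_cells(sim$counts, qc)$counts)
  gs <- gene_set("mod", sim$truth$module$genes)
  a <- score_module(norm, gs, seed = 42)
  b <- score_module(norm, gs, seed = 42)
  expect_identical(a$score, b$score)
  c <- score_module(norm, gs, seed = 43)
  expect_false(identical(a$score, c$score))
  # same controls => scores differ only through control sampling
  expect_identical(a$genes_used, c$genes_used)

  # location equivariance: +delta on set genes shifts every score by exactly
  # delta (single bin keeps the control pool, and hence the draws, identical)
  delta <- 0.5
  shifted <- norm
  shifted[gs$genes, ] <- shifted[gs$genes, ] + delta
  a1 <- score_module(norm, gs, n_bins = 1, seed = 42)
  a2 <- score_module(shifted, gs, n_bins = 1, seed = 42)
  expect_identical(a2$control_genes, a1$control_genes)
  expect_equal(unname(a2$score - a1$score), rep(delta, length(a1$score)),
               tolerance = 1e-10)
})

test_that("permuting cells permutes scores identically", {
  norm <- random_norm(60, 20, seed = 9)
  gs <- gene_set("s", rownames(norm)[1:5])
  a <- score_module(norm, gs, n_bins = 4, seed = 1)
  set.seed(99)
  perm <- sample(ncol(norm))
  b <- score_module(norm[, perm], gs, n_bins = 4, seed = 1)
  expect_identical(unname(b$score), unname(a$score[perm]))
})

test_that("missing set genes are dropped and empty sets rejected", {
  norm <- random_norm(30, 10, seed = 4)
  gs <- gene_set("s", c(rownames(norm)[1:3], "NotAGene"))
  sc <- score_module(norm, gs, n_bins = 3, seed = 1)
  expect_identical(sc$genes_missing, "NotAGene")
  expect_length(sc$genes_used, 3)
  expect_error(score_module(norm, gene_set("none", "Nope"), n_bins = 3), "present")
})

test_that("group summaries match a brute-force groupby", {
  sim <- simulate_dataset(small_sim_config(), seed = 12)
  qc <- compute_cell_qc(sim$counts)
  norm <- log_normalize(filter_cells(sim$counts, qc)$counts)
  ann <- sim$annotation[sim$annotation$barcode %in% colnames(norm), ]
  sc <- score_module(norm, gene_set("mod", sim$truth$module$genes), seed = 2)
  summ <- summarize_module_by_group(sc, ann, keys = c("cluster", "condition"))
  # brute force on one group
  g <- summ[summ$cluster == "neut" & summ$condition == "control", ]
  cells <- ann$barcode[ann$cluster == "neut" & ann$condition == "control"]
  cells <- intersect(cells, names(sc$score))
  expect_equal(g$mean, mean(sc$score[cells]))
  expect_equal(g$median, median(sc$score[cells]))
  expect_identical(g$n_cells, length(cells))
  # single-cell group: quartiles collapse to the score
  one <- data.frame(barcode = names(sc$score)[1], cluster = "solo", condition = "x")
  ann2 <- rbind(ann[, c("barcode", "cluster", "condition")], one)
  ann2 <- ann2[!duplicated(ann2$barcode), ]
  ann2$cluster[ann2$barcode == one$barcode] <- "solo"
  s1 <- summarize_module_by_group(sc, ann2, keys = "cluster")
  solo <- s1[s1$cluster == "solo", ]
  expect_equal(solo$q25, solo$median)
  expect_equal(solo$q75, unname(sc$score[one$barcode]))
})
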
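test_that("simulation is deterministic given config and seed", {
  cfg <- small_sim_config()
  a <- simulate_dataset(cfg, seed = 5)
  b <- simulate_dataset(cfg, seed = 5)
  expect_identical(as.matrix(a$counts), as.matrix(b$counts))
  expect_identical(a$annotation, b$annotation)
  expect_identical(a$truth$planted_lr, b$truth$planted_lr)
  c <- simulate_dataset(cfg, seed = 6)
  expect_false(identical(as.matrix(a$counts), as.matrix(c$counts)))
})

test_that("bookkeeping: annotation rows equal matrix columns and truth dimensions", {
  cfg <- small_sim_config()
  sim <- simulate_dataset(cfg, seed = 2)
  n_real <- sum(vapply(cfg$conditions, `[[`, numeric(1), "n_cells"))
  n_junk <- sum(unlist(cfg$qc_failures))
  expect_equal(ncol(sim$counts), n_real + n_junk)
  expect_equal(nrow(sim$annotation), ncol(sim$counts))
  expect_identical(sim$annotation$barcode, colnames(sim$counts))
  expect_equal(nrow(sim$truth$qc_barcodes), n_junk)
  expect_true(all(startsWith(sim$truth$qc_barcodes$barcode, "JUNK-")))
  expect_equal(nrow(sim$truth$lr_table),
               length(cfg$planted_lr) + cfg$n_decoy_pairs)
})

test_that("default config is study-shaped and exercises every stage", {
  cfg <- default_sim_config()
  expect_length(cfg$conditions, 2)
  expect_length(cfg$clusters, 10)
  expect_gte(length(cfg$planted_lr), 1)
  expect_true(all(unlist(cfg$qc_failures) >= 1))
  sim <- simulate_dataset(cfg, seed = 1)
  expect_true(all(sim$truth$planted_lr$expected_score > 6))
  expect_gte(ncol(sim$counts), 2000)
  expect_gte(nrow(sim$counts), 2000)
})

test_that("counts follow the negative-binomial mean-variance relationship", {
  cfg <- sim_config(
    n_genes = 100,
    clusters = list(list(name = "only", n_markers = 2, marker_fold = 2)),
    conditions = list(list(name = "c", n_cells = 10000,
                           proportions = c(only = 1))),
    n_decoy_pairs = 0,
    qc_failures = list())
  sim <- simulate_dataset(cfg, seed = 3)
  x <- as.matrix(sim$counts)
  mu_hat <- rowMeans(x)
  var_hat <- apply(x, 1, var)
  keep <- mu_hat > 1   # variance estimates are stable for expressed genes
  expected <- mu_hat + mu_hat^2 / cfg$nb_dispersion
  rel_err <- abs(var_hat[keep] - expected[keep]) / expected[keep]
  expect_lt(median(rel_err), 0.05)
  expect_lt(mean(rel_err > 0.10), 0.10)
})

test_that("planted ligands dominate their source cluster's expression", {
  cfg <- small_sim_config(n_cells = 200, n_genes = 300)
  hits <- 0L; n_seeds <- 20L
  for (s in seq_len(n_seeds)) {
    sim <- simulate_dataset(cfg, seed = s)
    ann <- sim$annotation
    lig <- "LigA"
    means <- tapply(seq_len(nrow(ann))[!is.na(ann$cluster)],
                    ann$cluster[!is.na(ann$cluster)],
                    function(i) mean(sim$counts[lig, ann$barcode[i]]))
    if (names(which.max(means)) == "macA") hits <- hits + 1L
  }
  expect_gte(hits / n_seeds, 0.95)
})

test_that("ground truth round-trips through its writers", {
  sim <- simulate_dataset(small_sim_config(), seed = 4)
  dir <- withr::local_tempdir()
  write_sim_truth(sim$truth, dir)
  back <- read_sim_truth(dir)
  expect_equal(back$cells, sim$truth$cells)
  expect_equal(back$proportions, sim$truth$proportions)
  expect_equal(back$planted_lr, sim$truth$planted_lr, tolerance = 1e-12)
  expect_identical(back$module$genes, sim$truth$module$genes)
  expect_equal(back$module$multiplier, sim$truth$module$multiplier, tolerance = 1e-12)
  expect_identical(nrow(back$planted_lr), nrow(sim$truth$planted_lr))
})

test_that("invalid configurations are rejected", {
  cfg <- small_sim_config()
  bad <- cfg
  bad$conditions[[1]]$proportions["macA"] <- 0.9
  expect_error(simulate_dataset(bad, 1), "sum to 1")
  bad2 <- cfg
  bad2$planted_lr[[1]]$source <- "nonexistent"
  expect_error(simulate_dataset(bad2, 1), "unknown cluster")
  expect_error(sim_config(clusters = list(list(name = "a")), conditions = list()),
               "condition")
})
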
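test_that("per-cell QC metrics follow their definitions", {
  m <- make_counts(cbind(c(1, 9, 0, 0, 0), c(0, 2, 4, 4, 0), c(0, 0, 0, 0, 0)),
                   genes = c("mt-Nd1", "Actb", "Rps6", "Rpl7", "Gapdh"))
  expect_warning(qc <- compute_cell_qc(m), "zero total")
  expect_identical(qc$n_counts, c(10, 10, 0))
  expect_identical(qc$n_features, c(2L, 3L, 0L))
  expect_equal(qc$pct_mito, c(10, 0, 0))
  expect_equal(qc$pct_ribo, c(0, 80, 0))
})

test_that("filtering applies inclusive feature window and strict count/content cuts", {
  qc <- data.frame(
    barcode = sprintf("c%d", 1:6),
    n_features = c(150, 3000, 3000, 3000, 3000, 3000),
    n_counts = c(5000, 5000, 1000, 1001, 5000, 5000),
    pct_mito = c(5, 10, 5, 5, 15, 5),
    pct_ribo = c(10, 20, 10, 10, 10, 40))
  m <- make_counts(matrix(1L, 2, 6), barcodes = qc$barcode)
  res <- filter_cells(m, qc, qc_thresholds())
  # c1: 150 < 200 features; c3: exactly 1000 counts (strict >); c5: exactly 15
  # pct mito (strict <); c6: exactly 40 pct ribo (strict <)
  expect_identical(colnames(res$counts), c("c2", "c4"))
  expect_identical(res$report$n_failed[res$report$criterion == "any"], 4L)
})

test_that("filtering is monotone in the thresholds", {
  sim <- simulate_dataset(small_sim_config(), seed = 3)
  qc <- compute_cell_qc(sim$counts)
  kept <- function(t) sum(filter_cells(sim$counts, qc, t)$flags$pass)
  base <- kept(qc_thresholds())
  expect_lte(kept(qc_thresholds(min_features = 400)), base)
  expect_lte(kept(qc_thresholds(max_pct_mito = 8)), base)
  expect_lte(kept(qc_thresholds(min_counts = 2000)), base)
})

test_that("threshold validation rejects inconsistent windows", {
  expect_error(qc_thresholds(min_features = 7000, max_features = 6000), "max_features")
  expect_error(qc_thresholds(min_counts = -1), "non-negative")
})

test_that("log-normalization matches its formula and preserves zeros", {
  m <- make_counts(cbind(c(1, 1, 2)))
  norm <- log_normalize(m, scale_factor = 10000)
  # cell total 4: count 1 -> ln(1 + 2500), count 2 -> ln(1 + 5000)
  expect_equal(norm[1, 1], log1p(2500))
  expect_equal(norm[1, 1], 7.824446, tolerance = 1e-6)
  expect_equal(norm[3, 1], log1p(5000))
  m2 <- make_counts(cbind(c(0, 5, 5)))
  norm2 <- log_normalize(m2)
  expect_identical(norm2[1, 1], 0)
  # doubling the scale factor strictly increases every nonzero value
  norm2b <- log_normalize(m2, scale_factor = 20000)
  nz <- as.matrix(norm2) > 0
  expect_true(all(as.matrix(norm2b)[nz] > as.matrix(norm2)[nz]))
  # zero-total cells are refused
  expect_error(log_normalize(make_counts(cbind(c(0, 0)))), "filter_cells")
})

test_that("log-normalization agrees with the Seurat reference implementation", {
  skip_if_not_installed("Seurat")
  m <- random_counts(60, 30, seed = 11)
  m <- m[, Matrix::colSums(m) > 0]
  ours <- log_normalize(m)
  ref <- Seurat::LogNormalize(m, scale.factor = 10000, verbose = FALSE)
  expect_lt(max(abs(as.matrix(ours) - as.matrix(ref))), 1e-12)
})

test_that("cluster means equal the brute-force per-cell loop", {
  norm <- random_norm(20, 50, seed = 5)
  set.seed(6)
  labels <- sample(c("A", "B", "C"), 50, replace = TRUE)
  ann <- data.frame(barcode = colnames(norm), cluster = labels)
  prof <- cluster_means(norm, ann)
  oracle <- oracle_cluster_means(norm, labels)
  expect_lt(max(abs(prof$means[, colnames(oracle)] - oracle)), 1e-12)
  expect_identical(sum(prof$cells_per_cluster), 50L)
})

test_that("cluster means handle single-cell clusters and missing clusters", {
  norm <- random_norm(5, 3, seed = 2)
  ann <- data.frame(barcode = colnames(norm), cluster = c("A", "A", "B"))
  prof <- cluster_means(norm, ann)
  expect_equal(prof$means[, "B"], as.numeric(norm[, 3]), ignore_attr = TRUE)
  # cluster referenced in the annotation but with no cells present
  ann2 <- rbind(ann, data.frame(barcode = "ghost", cluster = "C"))
  expect_warning(prof2 <- cluster_means(norm[, 1:3], ann2), "omitted")
  expect_false("C" %in% colnames(prof2$means))
})
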
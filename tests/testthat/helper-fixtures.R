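suppressPackageStartupMessages(library(Matrix))

# dense integer matrix -> validated sparse counts with dimnames
make_counts <- function(values, genes = NULL, barcodes = NULL) {
  m <- as.matrix(values)
  rownames(m) <- genes %||% sprintf("g%d", seq_len(nrow(m)))
  colnames(m) <- barcodes %||% sprintf("c%d", seq_len(ncol(m)))
  as(Matrix::Matrix(m, sparse = TRUE), "CsparseMatrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random sparse integer count matrix
random_counts <- function(n_genes, n_cells, density = 0.3, max_count = 20, seed = 1) {
  set.seed(seed)
  m <- matrix(0L, n_genes, n_cells)
  nz <- round(density * n_genes * n_cells)
  idx <- sample(n_genes * n_cells, nz)
  m[idx] <- sample.int(max_count, nz, replace = TRUE)
  make_counts(m)
}

# random normalized-style matrix (non-negative reals, zeros preserved)
random_norm <- function(n_genes, n_cells, seed = 1) {
  set.seed(seed)
  m <- matrix(rexp(n_genes * n_cells), n_genes, n_cells)
  m[m < 0.5] <- 0
  make_counts(round(m * 100)) / 100  # keep dimnames, make values reproducible
}

# a small, fast simulation configuration exercising every feature; the higher
# per-gene baseline rate keeps per-cell totals ~3000 UMIs (well above the
# 1000-molecule QC cut) despite the reduced gene count
small_sim_config <- function(n_cells = 150, n_genes = 500, n_decoy_pairs = 10) {
  cl <- function(name) list(name = name, n_markers = 5, marker_fold = 8)
  clusters <- list(cl("macA"), cl("macB"), cl("neut"), cl("tcell"))
  p1 <- c(macA = 0.4, macB = 0.2, neut = 0.25, tcell = 0.15)
  p2 <- c(macA = 0.1, macB = 0.2, neut = 0.45, tcell = 0.25)
  sim_config(
    n_genes = n_genes,
    baseline_rate = 5,
    clusters = clusters,
    conditions = list(
      list(name = "control", n_cells = n_cells, proportions = p1),
      list(name = "mutant",  n_cells = n_cells, proportions = p2)
    ),
    planted_lr = list(
      list(ligand = "LigA", receptor = c("RecA1", "RecA2"),
           source = "macA", target = "neut", effect = 100),
      list(ligand = "LigB", receptor = "RecB",
           source = "neut", target = "macB", effect = 100)
    ),
    n_decoy_pairs = n_decoy_pairs,
    planted_module = list(name = "mod_sim", n_genes = 10,
                          condition = "mutant", delta = 0.5),
    qc_failures = list(low_feature = 2, low_count = 2, high_mito = 2, high_ribo = 2)
  )
}

# brute-force oracle for cluster means: per-cell loop
oracle_cluster_means <- function(norm, labels) {
  lvls <- unique(labels)
  out <- matrix(0, nrow(norm), length(lvls), dimnames = list(rownames(norm), lvls))
  for (cl in lvls) {
    cells <- which(labels == cl)
    acc <- numeric(nrow(norm))
    for (j in cells) acc <- acc + as.numeric(norm[, j])
    out[, cl] <- acc / length(cells)
  }
  out
}

# brute-force oracle for communication scores: double loop over clusters and pairs
oracle_comm_scores <- function(mu, pairs, complex_rule = "min") {
  comb <- function(rows) {
    v <- mu[rows, , drop = FALSE]
    switch(complex_rule,
           min = apply(v, 2, min),
           mean = colMeans(v),
           geomean = exp(colMeans(log(v))))
  }
  clusters <- colnames(mu)
  rows <- list(); k <- 0L
  for (a in clusters) for (b in clusters) {
    for (i in seq_len(nrow(pairs))) {
      k <- k + 1L
      s <- comb(pairs$ligand_subunits[[i]])[a] * comb(pairs$receptor_subunits[[i]])[b]
      rows[[k]] <- data.frame(source = a, target = b,
                              pair_id = pairs$pair_id[i], score = unname(s),
                              stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
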
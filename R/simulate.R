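#' Simulation configuration for synthetic single-cell datasets
#'
#' Describes a synthetic 10x-style study: negative-binomial UMI counts over a
#' set of immune clusters and conditions, with cluster-specific marker genes,
#' mitochondrial/ribosomal gene fractions, planted ligand-receptor
#' interactions between chosen cluster pairs, a planted gene-module shift in
#' one condition, and planted QC-failing junk cells. Everything downstream of
#' the generator treats the dataset like real data; the accompanying ground
#' truth makes every pipeline stage verifiable.
#'
#' @param n_genes Total number of genes (background plus special genes).
#' @param clusters List of cluster specs: `list(name=, n_markers=, marker_fold=)`.
#'   Marker genes are dedicated genes upregulated `marker_fold`-fold in their
#'   cluster.
#' @param conditions List of condition specs:
#'   `list(name=, n_cells=, proportions=)` where `proportions` is a named
#'   numeric vector over cluster names summing to 1.
#' @param baseline_rate Mean UMI rate per background gene per cell; per-gene
#'   rates are lognormal around this mean (sdlog 1), giving realistic skew.
#' @param nb_dispersion Negative-binomial size parameter shared across genes
#'   (variance = mu + mu^2/size).
#' @param n_mito,mito_share Number of `mt-` genes and their share of total
#'   expression in a normal cell.
#' @param n_ribo,ribo_share Number of `Rps`/`Rpl` genes and their share.
#' @param planted_lr List of planted interactions:
#'   `list(ligand=, receptor=, source=, target=, effect=)`. Ligand/receptor
#'   are dedicated gene symbols (receptor may be a vector of complex
#'   subunits); their baseline rate is `lr_base_rate`, multiplied by `effect`
#'   in the source (ligand) / target (receptor) cluster.
#' @param lr_base_rate Baseline NB mean of planted ligand/receptor genes
#'   outside their boosted cluster (near-silent).
#' @param n_decoy_pairs Decoy LR pairs over dedicated genes expressed at
#'   `decoy_rate` everywhere; their communication scores stay far below the
#'   aggregation threshold.
#' @param decoy_rate NB mean of decoy ligand/receptor genes.
#' @param planted_module `list(name=, n_genes=, condition=, delta=)`: a
#'   dedicated gene set whose NB means are scaled in `condition` so the
#'   induced mean log-normalized shift is `delta` (calibrated numerically; the
#'   multiplier is recorded in the truth).
#' @param module_base_rate NB mean of module genes before the shift.
#' @param qc_failures Named counts of planted junk cells:
#'   `low_feature`, `low_count`, `high_mito`, `high_ribo`.
#' @return An object of class `sim_config`.
#' @seealso [default_sim_config()], [simulate_dataset()]
#' @export
sim_config <- function(n_genes = 2000,
                       clusters = NULL,
                       conditions = NULL,
                       baseline_rate = 1.5,
                       nb_dispersion = 2,
                       n_mito = 13, mito_share = 0.05,
                       n_ribo = 40, ribo_share = 0.20,
                       planted_lr = list(),
                       lr_base_rate = 0.1,
                       n_decoy_pairs = 50,
                       decoy_rate = 0.5,
                       planted_module = NULL,
                       module_base_rate = 1.0,
                       qc_failures = list(low_feature = 4, low_count = 4,
                                          high_mito = 4, high_ribo = 4)) {
  cfg <- list(n_genes = n_genes, clusters = clusters, conditions = conditions,
              baseline_rate = baseline_rate, nb_dispersion = nb_dispersion,
              n_mito = n_mito, mito_share = mito_share,
              n_ribo = n_ribo, ribo_share = ribo_share,
              planted_lr = planted_lr, lr_base_rate = lr_base_rate,
              n_decoy_pairs = n_decoy_pairs, decoy_rate = decoy_rate,
              planted_module = planted_module, module_base_rate = module_base_rate,
              qc_failures = qc_failures)
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  if (is.null(cfg$clusters) || !length(cfg$clusters)) {
    stop_format("sim_config needs at least one cluster")
  }
  if (is.null(cfg$conditions) || !length(cfg$conditions)) {
    stop_format("sim_config needs at least one condition")
  }
  cluster_names <- vapply(cfg$clusters, `[[`, character(1), "name")
  if (anyDuplicated(cluster_names)) stop_format("duplicate cluster names")
  for (cond in cfg$conditions) {
    p <- cond$proportions
    if (!setequal(names(p), cluster_names)) {
      stop_format("condition '%s': proportions must be named by the cluster names", cond$name)
    }
    if (abs(sum(p) - 1) > 1e-8) {
      stop_format("condition '%s': cluster proportions must sum to 1", cond$name)
    }
    if (cond$n_cells < 1) stop_format("condition '%s': n_cells must be >= 1", cond$name)
  }
  if (cfg$baseline_rate <= 0 || cfg$nb_dispersion <= 0 ||
      cfg$lr_base_rate <= 0 || cfg$decoy_rate <= 0 || cfg$module_base_rate <= 0) {
    stop_format("all rates and the NB dispersion must be > 0")
  }
  if (cfg$mito_share + cfg$ribo_share >= 1) {
    stop_format("mito_share + ribo_share must be < 1")
  }
  for (pl in cfg$planted_lr) {
    if (!pl$source %in% cluster_names || !pl$target %in% cluster_names) {
      stop_format("planted LR interaction references unknown cluster")
    }
    if (pl$effect <= 0) stop_format("planted LR effect must be > 0")
  }
  # planted gene names must not collide across roles
  planted_genes <- c(unlist(lapply(cfg$planted_lr, function(p) c(p$ligand, p$receptor))))
  if (anyDuplicated(planted_genes)) {
    stop_format("planted ligand/receptor gene names collide across interactions")
  }
  invisible(cfg)
}

#' Default study-shaped simulation configuration
#'
#' Emulates the shape of a two-genotype cardiac immune-cell study: a control
#' condition with a full resident-macrophage compartment and a
#' macrophage-depleted condition (`dfire`), ~10 immune clusters, 1000 cells
#' per condition, ~2000 genes, three planted LR interactions between
#' macrophage/neutrophil/monocyte clusters, a 20-gene inflammasome-like module
#' shifted by +0.5 in the depleted condition, and four junk cells per QC
#' failure mode.
#'
#' @return A [sim_config()] object.
#' @export
default_sim_config <- function() {
  cl <- function(name) list(name = name, n_markers = 10, marker_fold = 8)
  clusters <- list(
    cl("homeostatic_mac"), cl("antigen_presenting_mac"), cl("ccr2hi_mac"),
    cl("ccr2lo_mac"), cl("neutrophils"), cl("classical_monocytes"),
    cl("b_cells"), cl("t_cells"), cl("nk_cells"), cl("dendritic_cells")
  )
  names_cl <- vapply(clusters, `[[`, character(1), "name")
  control_p <- setNames(c(0.20, 0.10, 0.08, 0.08, 0.15, 0.10, 0.08, 0.10, 0.06, 0.05), names_cl)
  dfire_p   <- setNames(c(0.04, 0.03, 0.12, 0.05, 0.25, 0.18, 0.09, 0.12, 0.07, 0.05), names_cl)
  sim_config(
    n_genes = 2000,
    clusters = clusters,
    conditions = list(
      list(name = "control", n_cells = 1000, proportions = control_p),
      list(name = "dfire",   n_cells = 1000, proportions = dfire_p)
    ),
    planted_lr = list(
      list(ligand = "Tgfb1", receptor = c("Tgfbr1", "Tgfbr2"),
           source = "homeostatic_mac", target = "neutrophils", effect = 100),
      list(ligand = "Il1b", receptor = "Il1r1",
           source = "neutrophils", target = "ccr2hi_mac", effect = 100),
      list(ligand = "Ccl2", receptor = "Ccr2",
           source = "antigen_presenting_mac", target = "classical_monocytes",
           effect = 100)
    ),
    planted_module = list(name = "inflammasome_sim", n_genes = 20,
                          condition = "dfire", delta = 0.5)
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0("<sim_config> %d genes; %d clusters; conditions: %s; ",
                     "%d planted LR, %d decoy pairs; module shift: %s\n"),
              x$n_genes, length(x$clusters),
              paste(vapply(x$conditions, function(c)
                sprintf("%s (%d cells)", c$name, c$n_cells), character(1)),
                collapse = ", "),
              length(x$planted_lr), x$n_decoy_pairs,
              if (is.null(x$planted_module)) "none" else
                sprintf("%s (+%.2f in %s)", x$planted_module$name,
                        x$planted_module$delta, x$planted_module$condition)))
  invisible(x)
}

# E[log1p(c * sf/total)] for c ~ NB(mu, size), summed over the bulk of the pmf.
expected_lognorm <- function(mu, size, total, sf = 10000) {
  if (mu <= 0) return(0)
  kmax <- max(10, qnbinom(1 - 1e-10, size = size, mu = mu))
  k <- 0:kmax
  sum(dnbinom(k, size = size, mu = mu) * log1p(k * sf / total))
}

# Multiplier f such that the mean log-normalized shift over `rates` equals delta.
calibrate_module_multiplier <- function(rates, size, total, delta, sf = 10000) {
  shift <- function(f) {
    mean(vapply(rates, function(r)
      expected_lognorm(f * r, size, total, sf) - expected_lognorm(r, size, total, sf),
      numeric(1))) - delta
  }
  uniroot(shift, lower = 1, upper = 1000, tol = 1e-6)$root
}

# Deterministic gene naming for the synthetic genome.
mito_gene_names <- function(n) {
  base <- c("mt-Nd1", "mt-Nd2", "mt-Co1", "mt-Co2", "mt-Atp8", "mt-Atp6",
            "mt-Co3", "mt-Nd3", "mt-Nd4l", "mt-Nd4", "mt-Nd5", "mt-Nd6", "mt-Cytb")
  if (n <= length(base)) base[seq_len(n)] else c(base, sprintf("mt-Sim%d", seq_len(n - length(base))))
}

ribo_gene_names <- function(n) {
  nm <- c(sprintf("Rps%d", 1:ceiling(n / 2)), sprintf("Rpl%d", 1:floor(n / 2)))
  nm[seq_len(n)]
}

#' Simulate a synthetic 10x-style dataset with ground truth
#'
#' Draws gene-wise negative-binomial UMI counts with cluster- and
#' condition-specific means: marker genes are multiplied by their fold-change
#' in their own cluster, planted ligand (receptor) genes by the interaction
#' effect in the source (target) cluster, and module genes by a numerically
#' calibrated multiplier in the shifted condition. Junk cells failing specific
#' QC criteria are appended with a `JUNK-` barcode prefix. Fully deterministic
#' given the seed.
#'
#' @param cfg A [sim_config()].
#' @param seed Integer RNG seed.
#' @return List with `counts` (dgCMatrix genes x cells), `annotation`
#'   (data.frame: barcode, sample, condition, cluster; junk cells have cluster
#'   `NA`), and `truth` (class `sim_truth`): per-cell truth, true cluster
#'   proportions, planted LR pairs with expected communication scores and
#'   margins versus the default threshold, the full planted-plus-decoy LR
#'   table, the planted module (genes, delta, calibrated multiplier), and the
#'   planted junk barcodes per failure mode.
#' @export
simulate_dataset <- function(cfg, seed = 1L) {
  validate_sim_config(cfg)
  with_seed(seed, simulate_dataset_impl(cfg, seed))
}

simulate_dataset_impl <- function(cfg, seed) {
  cluster_names <- vapply(cfg$clusters, `[[`, character(1), "name")
  n_clusters <- length(cluster_names)
  size <- cfg$nb_dispersion

  # --- gene layout -----------------------------------------------------------
  mito <- mito_gene_names(cfg$n_mito)
  ribo <- ribo_gene_names(cfg$n_ribo)
  markers <- lapply(cfg$clusters, function(cl)
    sprintf("Mk.%s.%d", cl$name, seq_len(cl$n_markers)))
  names(markers) <- cluster_names
  lig_genes <- vapply(cfg$planted_lr, `[[`, character(1), "ligand")
  rec_genes <- unlist(lapply(cfg$planted_lr, `[[`, "receptor"))
  decoy_lig <- sprintf("DecoyL%03d", seq_len(cfg$n_decoy_pairs))
  decoy_rec <- sprintf("DecoyR%03d", seq_len(cfg$n_decoy_pairs))
  module_genes <- if (!is.null(cfg$planted_module)) {
    sprintf("%s_g%d", cfg$planted_module$name, seq_len(cfg$planted_module$n_genes))
  } else character(0)
  special <- c(mito, ribo, unlist(markers), lig_genes, rec_genes,
               decoy_lig, decoy_rec, module_genes)
  if (anyDuplicated(special)) {
    stop_format("planted gene names collide across roles: %s",
                paste(unique(special[duplicated(special)]), collapse = ", "))
  }
  n_bg <- cfg$n_genes - length(special)
  if (n_bg < 1) {
    stop_format("n_genes (%d) too small for %d special genes", cfg$n_genes, length(special))
  }
  bg <- sprintf("Gene%04d", seq_len(n_bg))
  genes <- c(mito, ribo, unlist(markers), lig_genes, rec_genes,
             decoy_lig, decoy_rec, module_genes, bg)

  # --- baseline rates --------------------------------------------------------
  lognormal_rates <- function(n, mean_rate) {
    r <- rlnorm(n, meanlog = 0, sdlog = 1)
    r * mean_rate / mean(r)
  }
  rates <- setNames(numeric(length(genes)), genes)
  rates[bg] <- lognormal_rates(n_bg, cfg$baseline_rate)
  rates[unlist(markers)] <- 0.5
  rates[c(lig_genes, rec_genes)] <- cfg$lr_base_rate
  rates[c(decoy_lig, decoy_rec)] <- cfg$decoy_rate
  rates[module_genes] <- cfg$module_base_rate
  # mito/ribo genes: lognormal profiles rescaled so their expression shares hold
  other_sum <- sum(rates[setdiff(genes, c(mito, ribo))])
  total_target <- other_sum / (1 - cfg$mito_share - cfg$ribo_share)
  # uniform rates within the mito/ribo classes: keeps per-cell mito/ribo
  # percentages tightly concentrated, so background cells sit far from the
  # QC boundaries and planted failures are unambiguous
  rates[mito] <- cfg$mito_share * total_target / cfg$n_mito
  rates[ribo] <- cfg$ribo_share * total_target / cfg$n_ribo
  total_ref <- sum(rates)

  # --- module-shift calibration ---------------------------------------------
  module_mult <- NA_real_
  if (!is.null(cfg$planted_module)) {
    module_mult <- calibrate_module_multiplier(rates[module_genes], size,
                                               total_ref, cfg$planted_module$delta)
  }

  # --- per cluster/condition rate matrices -----------------------------------
  rate_matrix <- function(cluster, condition) {
    r <- rates
    cl <- cfg$clusters[[match(cluster, cluster_names)]]
    r[markers[[cluster]]] <- r[markers[[cluster]]] * cl$marker_fold
    for (pl in cfg$planted_lr) {
      if (cluster == pl$source) r[pl$ligand] <- r[pl$ligand] * pl$effect
      if (cluster == pl$target) r[pl$receptor] <- r[pl$receptor] * pl$effect
    }
    if (!is.null(cfg$planted_module) && condition == cfg$planted_module$condition) {
      r[module_genes] <- r[module_genes] * module_mult
    }
    r
  }

  # --- draw real cells -------------------------------------------------------
  blocks <- list(); ann_rows <- list()
  for (cond in cfg$conditions) {
    assign_cl <- sample(cluster_names, cond$n_cells, replace = TRUE,
                        prob = cond$proportions[cluster_names])
    barcodes <- sprintf("%s_cell%05d", cond$name, seq_len(cond$n_cells))
    cells <- matrix(0L, nrow = length(genes), ncol = cond$n_cells)
    for (cl in unique(assign_cl)) {
      idx <- which(assign_cl == cl)
      mu <- rate_matrix(cl, cond$name)
      cells[, idx] <- rnbinom(length(genes) * length(idx), size = size,
                              mu = rep(mu, length(idx)))
    }
    blocks[[cond$name]] <- cells
    ann_rows[[cond$name]] <- data.frame(
      barcode = barcodes,
      sample = sprintf("%s_s%d", cond$name, 1L + (seq_len(cond$n_cells) %% 2L)),
      condition = cond$name, cluster = assign_cl,
      stringsAsFactors = FALSE)
  }

  # --- junk cells (planted QC failures) --------------------------------------
  qc <- cfg$qc_failures
  junk_cols <- list(); junk_ann <- list()
  cond_cycle <- vapply(cfg$conditions, `[[`, character(1), "name")
  add_junk <- function(mode, n, rate_fun) {
    if (is.null(n) || n < 1) return()
    for (i in seq_len(n)) {
      mu <- rate_fun(i)
      counts_i <- rnbinom(length(genes), size = size, mu = mu)
      bc <- sprintf("JUNK-%s-%d", mode, i)
      junk_cols[[bc]] <<- counts_i
      cond_i <- cond_cycle[1L + (length(junk_ann) %% length(cond_cycle))]
      junk_ann[[bc]] <<- data.frame(barcode = bc, sample = paste0(cond_i, "_s1"),
                                    condition = cond_i, cluster = NA_character_,
                                    stringsAsFactors = FALSE)
    }
  }
  add_junk("low_feature", qc$low_feature, function(i) {
    mu <- setNames(numeric(length(genes)), genes)
    mu[sample(genes, 60)] <- 25  # few genes, healthy depth
    mu
  })
  add_junk("low_count", qc$low_count, function(i) rates * (400 / total_ref))
  add_junk("high_mito", qc$high_mito, function(i) {
    mu <- rates
    mu[mito] <- mu[mito] * (sum(mu[setdiff(genes, mito)]) / sum(mu[mito]))  # ~50% mito
    mu
  })
  add_junk("high_ribo", qc$high_ribo, function(i) {
    mu <- rates
    mu[ribo] <- mu[ribo] * (1.5 * sum(mu[setdiff(genes, ribo)]) / sum(mu[ribo]))  # ~60% ribo
    mu
  })

  counts <- cbind(do.call(cbind, blocks),
                  if (length(junk_cols)) do.call(cbind, junk_cols) else NULL)
  ann <- rbind(do.call(rbind, ann_rows),
               if (length(junk_ann)) do.call(rbind, junk_ann) else NULL)
  rownames(ann) <- NULL
  colnames(counts) <- ann$barcode
  rownames(counts) <- genes
  counts <- as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")

  # --- ground truth ----------------------------------------------------------
  planted_lr_truth <- do.call(rbind, lapply(cfg$planted_lr, function(pl) {
    mu_l <- expected_lognorm(rates[pl$ligand] * pl$effect, size, total_ref)
    mu_r <- min(vapply(pl$receptor, function(g)
      expected_lognorm(rates[g] * pl$effect, size, total_ref), numeric(1)))
    s <- mu_l * mu_r
    data.frame(pair_id = paste0(pl$ligand, "\u2192", paste(pl$receptor, collapse = "_")),
               ligand = pl$ligand, receptor = paste(pl$receptor, collapse = "_"),
               source = pl$source, target = pl$target, effect = pl$effect,
               expected_mu_ligand = unname(mu_l), expected_mu_receptor = unname(mu_r),
               expected_score = unname(s), margin_vs_tau = unname(s - 6),
               stringsAsFactors = FALSE)
  }))
  decoy_ids <- if (length(decoy_lig)) paste0(decoy_lig, "\u2192", decoy_rec) else character(0)
  lr_table <- data.frame(
    pair_id = c(if (!is.null(planted_lr_truth)) planted_lr_truth$pair_id,
                decoy_ids),
    ligand = c(if (!is.null(planted_lr_truth)) planted_lr_truth$ligand, decoy_lig),
    receptor = c(if (!is.null(planted_lr_truth)) planted_lr_truth$receptor, decoy_rec),
    is_planted = c(rep(TRUE, length(cfg$planted_lr)), rep(FALSE, cfg$n_decoy_pairs)),
    stringsAsFactors = FALSE)
  proportions <- do.call(rbind, lapply(cfg$conditions, function(cond)
    data.frame(condition = cond$name, cluster = cluster_names,
               true_prop = as.numeric(cond$proportions[cluster_names]),
               stringsAsFactors = FALSE)))
  qc_barcodes <- if (length(junk_ann)) {
    data.frame(barcode = names(junk_cols),
               mode = sub("^JUNK-([a-z_]+)-\\d+$", "\\1", names(junk_cols)),
               stringsAsFactors = FALSE)
  } else data.frame(barcode = character(0), mode = character(0))
  module_truth <- if (!is.null(cfg$planted_module)) {
    list(name = cfg$planted_module$name, genes = module_genes,
         condition = cfg$planted_module$condition,
         delta = cfg$planted_module$delta, multiplier = module_mult)
  }
  truth <- structure(list(
    cells = ann, proportions = proportions, planted_lr = planted_lr_truth,
    lr_table = lr_table, module = module_truth, qc_barcodes = qc_barcodes,
    seed = seed, total_rate = total_ref
  ), class = "sim_truth")
  list(counts = counts, annotation = ann, truth = truth)
}

#' LR pair table of a simulation's planted and decoy pairs
#'
#' @param truth A `sim_truth` from [simulate_dataset()].
#' @return An `lr_pair_table` ready for [resolve_pairs()] /
#'   [score_communication()].
#' @export
sim_lr_pair_table <- function(truth) {
  lr_pair_table(truth$lr_table$pair_id, truth$lr_table$ligand, truth$lr_table$receptor)
}

#' Write simulation ground truth to a directory
#'
#' Emits `cells.tsv`, `proportions.tsv`, `planted_lr.tsv`, `lr_table.tsv`,
#' `qc_barcodes.tsv` and `module.json`; all plain text, readable by
#' [read_sim_truth()].
#'
#' @param truth A `sim_truth`.
#' @param path Output directory, created if absent.
#' @return The directory, invisibly.
#' @export
write_sim_truth <- function(truth, path) {
  if (!is(truth, "sim_truth")) stop_format("'truth' must be a sim_truth object")
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  write_tsv_file(truth$cells, file.path(path, "cells.tsv"))
  write_tsv_file(truth$proportions, file.path(path, "proportions.tsv"))
  write_tsv_file(truth$planted_lr %||%
                   data.frame(pair_id = character(0), ligand = character(0),
                              receptor = character(0), source = character(0),
                              target = character(0), effect = numeric(0),
                              expected_mu_ligand = numeric(0),
                              expected_mu_receptor = numeric(0),
                              expected_score = numeric(0),
                              margin_vs_tau = numeric(0)),
                 file.path(path, "planted_lr.tsv"))
  write_tsv_file(truth$lr_table, file.path(path, "lr_table.tsv"))
  write_tsv_file(truth$qc_barcodes, file.path(path, "qc_barcodes.tsv"))
  jsonlite::write_json(
    list(module = truth$module, seed = truth$seed, total_rate = truth$total_rate),
    file.path(path, "module.json"), auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read simulation ground truth written by [write_sim_truth()]
#'
#' @param path Directory holding the truth files.
#' @return A `sim_truth` object.
#' @export
read_sim_truth <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "module.json"), simplifyVector = TRUE)
  module <- meta$module
  if (!is.null(module)) module <- as.list(module)
  planted <- read_tsv_file(file.path(path, "planted_lr.tsv"))
  structure(list(
    cells = read_tsv_file(file.path(path, "cells.tsv")),
    proportions = read_tsv_file(file.path(path, "proportions.tsv")),
    planted_lr = if (nrow(planted)) planted else NULL,
    lr_table = read_tsv_file(file.path(path, "lr_table.tsv")),
    module = module,
    qc_barcodes = read_tsv_file(file.path(path, "qc_barcodes.tsv")),
    seed = meta$seed, total_rate = meta$total_rate
  ), class = "sim_truth")
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf(paste0("<sim_truth> %d cells (%d junk); %d planted LR pairs ",
                     "(expected scores %s); module '%s' delta %s\n"),
              nrow(x$cells), nrow(x$qc_barcodes),
              if (is.null(x$planted_lr)) 0L else nrow(x$planted_lr),
              if (is.null(x$planted_lr)) "-" else
                paste(sprintf("%.1f", x$planted_lr$expected_score), collapse = ", "),
              if (is.null(x$module)) "none" else x$module$name,
              if (is.null(x$module)) "-" else format(x$module$delta)))
  invisible(x)
}
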
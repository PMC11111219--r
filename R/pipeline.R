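pipeline_schema <- list(
  top = c("counts", "annotation", "lr_pairs", "gene_sets", "seed", "skip",
          "qc", "normalization", "modules", "lr", "composition"),
  qc = c("min_features", "max_features", "min_counts", "max_pct_mito",
         "max_pct_ribo", "mito_prefixes", "ribo_prefixes"),
  normalization = c("scale_factor"),
  modules = c("n_bins", "n_ctrl", "seed"),
  lr = c("threshold", "complex_rule", "per_condition", "ligand_col",
         "receptor_col", "pair_id_col", "pathway_col"),
  composition = c("group_key", "cluster_key", "cond_a", "cond_b")
)

#' Validate and resolve a pipeline configuration
#'
#' Accepts a YAML/JSON file path or a plain list, checks every key against the
#' known schema (unknown keys are an error listing them), verifies that
#' referenced input paths exist, and fills defaults: QC thresholds at their
#' standard values, scale factor 10,000, module scoring with 24 bins and 100
#' controls, communication threshold tau = 6 with the `min` complex rule and
#' per-condition scoring, composition grouped by condition.
#'
#' @param config Path to a YAML/JSON config file, or a list with the same
#'   structure.
#' @return The fully resolved configuration, class `pipeline_config`.
#' @export
validate_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop_format("config file '%s' does not exist", config)
    config <- yaml::read_yaml(config)  # YAML superset: also parses JSON
  }
  if (!is.list(config)) stop_format("config must be a file path or a list")
  check_keys <- function(x, allowed, where) {
    unknown <- setdiff(names(x), allowed)
    if (length(unknown)) {
      stop_format("unknown config key(s) %s: %s", where,
                  paste(sQuote(unknown), collapse = ", "))
    }
  }
  check_keys(config, pipeline_schema$top, "at top level")
  for (sec in c("qc", "normalization", "modules", "lr", "composition")) {
    if (!is.null(config[[sec]])) {
      check_keys(config[[sec]], pipeline_schema[[sec]], sprintf("in section '%s'", sec))
    }
  }
  qc <- config$qc %||% list()
  thresholds <- qc_thresholds(
    min_features = qc$min_features %||% 200,
    max_features = qc$max_features %||% 6000,
    min_counts   = qc$min_counts %||% 1000,
    max_pct_mito = qc$max_pct_mito %||% 15,
    max_pct_ribo = qc$max_pct_ribo %||% 40,
    mito_prefixes = unlist(qc$mito_prefixes) %||% c("mt-", "MT-"),
    ribo_prefixes = unlist(qc$ribo_prefixes) %||% c("Rps", "Rpl")
  )
  mod <- config$modules %||% list()
  lr <- config$lr %||% list()
  comp <- config$composition %||% list()
  if (!is.null(lr$threshold) && lr$threshold < 0) {
    stop_format("lr.threshold must be >= 0")
  }
  resolved <- list(
    counts = config$counts, annotation = config$annotation,
    lr_pairs = config$lr_pairs,
    gene_sets = config$gene_sets,
    seed = config$seed %||% 1L,
    skip = unlist(config$skip) %||% character(0),
    qc = thresholds,
    normalization = list(scale_factor = config$normalization$scale_factor %||% 10000),
    modules = list(n_bins = mod$n_bins %||% 24, n_ctrl = mod$n_ctrl %||% 100,
                   seed = mod$seed %||% config$seed %||% 1L),
    lr = list(threshold = lr$threshold %||% 6,
              complex_rule = lr$complex_rule %||% "min",
              per_condition = lr$per_condition %||% TRUE,
              ligand_col = lr$ligand_col %||% "ligand",
              receptor_col = lr$receptor_col %||% "receptor",
              pair_id_col = lr$pair_id_col, pathway_col = lr$pathway_col),
    composition = list(group_key = comp$group_key %||% "condition",
                       cluster_key = comp$cluster_key %||% "cluster",
                       cond_a = comp$cond_a, cond_b = comp$cond_b)
  )
  stages <- c("qc", "normalize", "modules", "communication", "composition")
  bad <- setdiff(resolved$skip, stages)
  if (length(bad)) stop_format("unknown stage(s) in skip: %s", paste(bad, collapse = ", "))
  for (field in c("counts", "annotation", "lr_pairs")) {
    p <- resolved[[field]]
    if (!is.null(p) && !file.exists(p) && !dir.exists(p)) {
      stop_format("input path for '%s' does not exist: %s", field, p)
    }
  }
  for (p in unlist(resolved$gene_sets)) {
    if (!file.exists(p)) stop_format("gene set file does not exist: %s", p)
  }
  class(resolved) <- "pipeline_config"
  resolved
}

#' Run the full analysis pipeline
#'
#' Executes QC filtering, log-normalization, module scoring, communication
#' scoring and composition analysis on a 10x-style dataset, writing each
#' stage's tables into a fixed directory layout (`qc/`, `normalized/`,
#' `modules/`, `communication/`, `composition/`) plus a run manifest with the
#' resolved parameters and MD5 checksums of every emitted table. Reruns with
#' identical inputs and seed reproduce byte-identical tables.
#'
#' Stages listed in the config's `skip` are not run; stages whose required
#' annotation columns are missing (e.g. `cluster` for communication and
#' composition) are skipped with a warning, recorded in the manifest.
#' Communication scores are computed within each condition separately by
#' default (`lr.per_condition`), recorded in the manifest.
#'
#' @param config A [validate_pipeline_config()] result, config file path, or
#'   config list.
#' @param out_dir Output directory, created if needed.
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  cfg <- if (is(config, "pipeline_config")) config else validate_pipeline_config(config)
  if (is.null(cfg$counts) || is.null(cfg$annotation)) {
    stop_format("config must provide 'counts' and 'annotation' paths")
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  logfile <- file.path(out_dir, "run.log")
  cat(sprintf("commscore %s pipeline run\n", as.character(packageVersion("commscore"))),
      file = logfile)
  log_msg <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    message(msg)
    cat(msg, "\n", file = logfile, append = TRUE, sep = "")
  }
  skipped <- character(0)
  stage_on <- function(stage) !stage %in% c(cfg$skip, skipped)

  counts <- read_counts_10x(cfg$counts)
  ann <- read_cell_annotation(cfg$annotation)
  check_annotation(ann, counts)
  has_cluster <- "cluster" %in% names(ann)
  if (!has_cluster) {
    for (st in c("communication", "composition")) {
      if (stage_on(st)) {
        warning(sprintf("annotation has no 'cluster' column; skipping stage '%s'", st),
                call. = FALSE)
        skipped <- c(skipped, st)
      }
    }
  }

  emitted <- character(0)
  emit <- function(df, path) {
    write_tsv_file(df, path)
    emitted <<- c(emitted, path)
  }

  # --- qc ---------------------------------------------------------------
  if (stage_on("qc")) {
    qc_dir <- file.path(out_dir, "qc")
    dir.create(qc_dir, showWarnings = FALSE)
    qc_tab <- compute_cell_qc(counts, cfg$qc$mito_prefixes, cfg$qc$ribo_prefixes)
    filt <- filter_cells(counts, qc_tab, cfg$qc)
    emit(cbind(qc_tab, filt$flags[, -1, drop = FALSE]),
         file.path(qc_dir, "cell_metrics.tsv"))
    emit(filt$report, file.path(qc_dir, "filter_report.tsv"))
    write_counts_10x(filt$counts, file.path(qc_dir, "filtered"))
    counts <- filt$counts
    ann <- ann[ann$barcode %in% colnames(counts), , drop = FALSE]
    log_msg("qc: kept %d/%d cells (prefixes mito=%s ribo=%s; window [%s,%s] features; counts>%s; mito<%s%%; ribo<%s%%)",
            ncol(counts), nrow(qc_tab),
            paste(cfg$qc$mito_prefixes, collapse = "|"),
            paste(cfg$qc$ribo_prefixes, collapse = "|"),
            cfg$qc$min_features, cfg$qc$max_features, cfg$qc$min_counts,
            cfg$qc$max_pct_mito, cfg$qc$max_pct_ribo)
  }

  # --- normalize --------------------------------------------------------
  norm <- NULL
  if (stage_on("normalize")) {
    norm_dir <- file.path(out_dir, "normalized")
    dir.create(norm_dir, showWarnings = FALSE)
    norm <- log_normalize(counts, cfg$normalization$scale_factor)
    write_matrix_real(norm, norm_dir)
    jsonlite::write_json(list(scale_factor = cfg$normalization$scale_factor,
                              scheme = attr(norm, "normalization")),
                         file.path(norm_dir, "metadata.json"), auto_unbox = TRUE)
    log_msg("normalize: log1p(counts/total * %s) on %d cells",
            format(cfg$normalization$scale_factor), ncol(norm))
  }

  # --- module scoring ---------------------------------------------------
  if (stage_on("modules") && length(cfg$gene_sets)) {
    if (is.null(norm)) stop_format("module scoring requires the normalize stage")
    mod_dir <- file.path(out_dir, "modules")
    dir.create(mod_dir, showWarnings = FALSE)
    all_scores <- list(); all_summaries <- list()
    for (i in seq_along(cfg$gene_sets)) {
      sets <- read_gene_set(cfg$gene_sets[[i]])
      for (gs in sets) {
        sc <- score_module(norm, gs, n_bins = cfg$modules$n_bins,
                           n_ctrl = cfg$modules$n_ctrl, seed = cfg$modules$seed)
        all_scores[[gs$name]] <- data.frame(barcode = names(sc$score),
                                            set = gs$name, score = sc$score,
                                            stringsAsFactors = FALSE)
        summ <- summarize_module_by_group(sc, ann)
        summ <- cbind(set = gs$name, summ)
        all_summaries[[gs$name]] <- summ
        log_msg("modules: scored '%s' (%d/%d genes present)", gs$name,
                length(sc$genes_used), length(sc$genes_used) + length(sc$genes_missing))
      }
    }
    scores_df <- do.call(rbind, all_scores); rownames(scores_df) <- NULL
    emit(scores_df, file.path(mod_dir, "scores.tsv"))
    summ_df <- do.call(rbind, all_summaries); rownames(summ_df) <- NULL
    emit(summ_df, file.path(mod_dir, "summary.tsv"))
  }

  # --- communication ----------------------------------------------------
  if (stage_on("communication") && !is.null(cfg$lr_pairs)) {
    if (is.null(norm)) stop_format("communication scoring requires the normalize stage")
    comm_dir <- file.path(out_dir, "communication")
    dir.create(comm_dir, showWarnings = FALSE)
    lr <- read_lr_pairs(cfg$lr_pairs, ligand_col = cfg$lr$ligand_col,
                        receptor_col = cfg$lr$receptor_col,
                        pair_id_col = cfg$lr$pair_id_col,
                        pathway_col = cfg$lr$pathway_col)
    res <- resolve_pairs(lr, rownames(norm))
    if (nrow(res$dropped)) {
      emit(res$dropped, file.path(comm_dir, "dropped_pairs.tsv"))
      log_msg("communication: dropped %d unresolvable pair(s)", nrow(res$dropped))
    }
    groups <- if (isTRUE(cfg$lr$per_condition) && "condition" %in% names(ann)) {
      split(ann$barcode, ann$condition)
    } else {
      list(pooled = ann$barcode)
    }
    for (gname in names(groups)) {
      cells <- intersect(colnames(norm), groups[[gname]])
      sub_ann <- ann[ann$barcode %in% cells, , drop = FALSE]
      profile <- cluster_means(norm[, cells, drop = FALSE], sub_ann)
      scores <- score_communication(profile, res$pairs, cfg$lr$complex_rule)
      net <- build_network(scores, cfg$lr$threshold)
      outg <- outgoing_interaction_counts(net)
      emit(scores, file.path(comm_dir, sprintf("pair_scores_%s.tsv", gname)))
      emit(net, file.path(comm_dir, sprintf("network_%s.tsv", gname)))
      emit(outg, file.path(comm_dir, sprintf("outgoing_%s.tsv", gname)))
      log_msg("communication[%s]: %d clusters, %d pairs, %d supra-threshold interactions (tau=%s, rule=%s)",
              gname, ncol(profile$means), nrow(res$pairs), sum(net$n_interactions),
              format(cfg$lr$threshold), cfg$lr$complex_rule)
    }
  }

  # --- composition ------------------------------------------------------
  if (stage_on("composition")) {
    comp_dir <- file.path(out_dir, "composition")
    dir.create(comp_dir, showWarnings = FALSE)
    tab <- cluster_fractions(ann, cfg$composition$group_key, cfg$composition$cluster_key)
    emit(tab, file.path(comp_dir, "abundance.tsv"))
    conds <- unique(tab$condition)
    cond_a <- cfg$composition$cond_a %||% conds[1]
    cond_b <- cfg$composition$cond_b %||% if (length(conds) > 1) conds[2] else NULL
    if (!is.null(cond_b)) {
      diff <- abundance_difference(tab, cond_a, cond_b)
      emit(diff, file.path(comp_dir, "difference.tsv"))
      log_msg("composition: %s vs %s, max |delta| = %.2f pp",
              cond_a, cond_b, max(diff$abs_delta_pp))
    }
  }

  manifest <- list(
    package_version = as.character(packageVersion("commscore")),
    inputs = list(counts = cfg$counts, annotation = cfg$annotation,
                  lr_pairs = cfg$lr_pairs, gene_sets = cfg$gene_sets),
    parameters = list(
      qc = unclass(cfg$qc),
      normalization = cfg$normalization,
      modules = cfg$modules, lr = cfg$lr, composition = cfg$composition,
      seed = cfg$seed),
    skipped_stages = unique(c(cfg$skip, skipped)),
    table_checksums = as.list(tools::md5sum(sort(emitted)))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(manifest)
}
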
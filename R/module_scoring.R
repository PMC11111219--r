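#' Bin genes by average expression
#'
#' Ranks all genes by their mean normalized expression across cells and cuts
#' the ranking into `n_bins` equal-size bins. Ties are broken by gene order in
#' the matrix (stable ranking), so the binning is exactly deterministic even
#' on tied means. These bins supply expression-matched control genes for
#' module scoring.
#'
#' @param norm Normalized matrix (genes x cells).
#' @param n_bins Number of rank bins (default 24).
#' @return Integer vector of bin indices in 1..n_bins, named by gene, in
#'   matrix gene order.
#' @export
assign_expression_bins <- function(norm, n_bins = 24) {
  if (n_bins < 1) stop_format("n_bins must be >= 1")
  n <- nrow(norm)
  if (n < n_bins) stop_format("need at least n_bins (%d) genes, got %d", n_bins, n)
  means <- Matrix::rowMeans(norm)
  if (any(!is.finite(means))) stop_format("non-finite gene means")
  ord <- order(means, method = "radix")  # stable: ties keep matrix order
  ranks <- integer(n)
  ranks[ord] <- seq_len(n)
  bins <- as.integer(floor((ranks - 1) * n_bins / n) + 1L)
  setNames(bins, rownames(norm))
}

#' Score a gene module per cell with binned control genes
#'
#' For every cell, the module score M is the mean normalized expression of the
#' module's genes minus the mean normalized expression of a control gene set
#' matched for expression level: for each module gene, `n_ctrl` control genes
#' are drawn without replacement (seeded) from the gene's expression bin,
#' excluding all module genes; the sampled controls are pooled (duplicates
#' collapsed) and averaged. Scores may be negative; a score near 0 means the
#' module is expressed no higher than expression-matched background.
#'
#' @param norm Normalized matrix (genes x cells).
#' @param gs A [gene_set()]. Genes absent from the matrix are dropped and
#'   reported in the result; if none is present this is an error.
#' @param n_bins Number of expression bins (default 24).
#' @param n_ctrl Controls drawn per module gene (default 100), capped at the
#'   bin occupancy.
#' @param seed RNG seed for control sampling. Controls are sampled once per
#'   (matrix, gene set, seed) - not per cell - so scores are comparable across
#'   cells and bit-reproducible.
#' @return Object of class `module_scores`: list with `score` (named numeric,
#'   one per cell), `set_name`, `genes_used`, `genes_missing`,
#'   `control_genes`, and `params`.
#' @details If excluding module genes empties a bin, the nearest non-empty bin
#'   is used instead, with a warning (ties resolved toward lower bins).
#' @export
score_module <- function(norm, gs, n_bins = 24, n_ctrl = 100, seed = 1L) {
  if (!is(gs, "gene_set")) stop_format("'gs' must be a gene_set object")
  genes_used <- intersect(gs$genes, rownames(norm))
  genes_missing <- setdiff(gs$genes, rownames(norm))
  if (!length(genes_used)) {
    stop_format("no gene of set '%s' is present in the matrix", gs$name)
  }
  bins <- assign_expression_bins(norm, n_bins)
  pool_by_bin <- split(setdiff(rownames(norm), genes_used),
                       bins[setdiff(rownames(norm), genes_used)])
  occupied <- as.integer(names(pool_by_bin))
  controls <- with_seed(seed, {
    lapply(genes_used, function(g) {
      b <- bins[[g]]
      if (!b %in% occupied) {
        nearest <- occupied[which.min(abs(occupied - b))]
        warning(sprintf("bin %d empty after excluding set genes; using bin %d for '%s'",
                        b, nearest, g), call. = FALSE)
        b <- nearest
      }
      cand <- pool_by_bin[[as.character(b)]]
      k <- min(n_ctrl, length(cand))
      sample(cand, k)
    })
  })
  control_genes <- unique(unlist(controls))
  set_mean <- Matrix::colMeans(norm[genes_used, , drop = FALSE])
  ctrl_mean <- Matrix::colMeans(norm[control_genes, , drop = FALSE])
  structure(list(
    score = setNames(as.numeric(set_mean - ctrl_mean), colnames(norm)),
    set_name = gs$name,
    genes_used = genes_used,
    genes_missing = genes_missing,
    control_genes = control_genes,
    params = list(n_bins = n_bins, n_ctrl = n_ctrl, seed = seed)
  ), class = "module_scores")
}

#' @export
print.module_scores <- function(x, ...) {
  cat(sprintf("<module_scores> set '%s': %d cells; %d/%d set genes used; %d controls; seed %s\n",
              x$set_name, length(x$score), length(x$genes_used),
              length(x$genes_used) + length(x$genes_missing),
              length(x$control_genes), x$params$seed))
  invisible(x)
}

#' Summarize module scores by annotation groups
#'
#' @param scores A `module_scores` object from [score_module()].
#' @param ann Annotation data.frame with `barcode` and the grouping columns;
#'   must cover every scored cell.
#' @param keys Annotation columns defining the groups (default cluster and
#'   condition, when present).
#' @return A data.frame with one row per group: the key columns plus
#'   `n_cells`, `mean`, `median`, `q25`, `q75`.
#' @export
summarize_module_by_group <- function(scores, ann,
                                      keys = intersect(c("cluster", "condition"),
                                                       names(ann))) {
  if (!length(keys)) stop_format("no grouping keys available in the annotation")
  if (!all(keys %in% names(ann))) {
    stop_format("annotation lacks grouping column(s): %s",
                paste(setdiff(keys, names(ann)), collapse = ", "))
  }
  cells <- names(scores$score)
  idx <- match(cells, ann$barcode)
  if (anyNA(idx)) stop_format("annotation does not cover all scored cells")
  grp <- ann[idx, keys, drop = FALSE]
  key_str <- do.call(paste, c(grp, sep = "\r"))
  out_rows <- lapply(split(seq_along(cells), key_str), function(i) {
    s <- scores$score[i]
    cbind(grp[i[1], , drop = FALSE],
          data.frame(n_cells = length(s), mean = mean(s), median = median(s),
                     q25 = unname(quantile(s, 0.25)),
                     q75 = unname(quantile(s, 0.75))))
  })
  out <- do.call(rbind, out_rows)
  rownames(out) <- NULL
  out[order(do.call(paste, c(out[keys], sep = "\r"))), , drop = FALSE]
}
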
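#' Per-cell quality-control metrics
#'
#' Computes, for every cell, the number of detected genes, total UMI count,
#' and the percentage of UMIs falling on mitochondrial and ribosomal genes.
#' Gene classes are identified by prefix-anchored matching on the gene symbol.
#'
#' @param m Count matrix (genes x cells) with dimnames.
#' @param mito_prefixes Prefixes marking mitochondrial genes. The defaults
#'   cover both the mouse (`mt-`) and human (`MT-`) symbol conventions.
#' @param ribo_prefixes Prefixes marking ribosomal protein genes
#'   (`Rps`/`Rpl`; matching is case-sensitive).
#' @return A data.frame with one row per barcode, in barcode order: columns
#'   `barcode`, `n_features`, `n_counts`, `pct_mito`, `pct_ribo`. For an
#'   all-zero cell the percentages are defined as 0 (with a warning); such a
#'   cell fails the molecule-count filter regardless.
#' @export
compute_cell_qc <- function(m, mito_prefixes = c("mt-", "MT-"),
                            ribo_prefixes = c("Rps", "Rpl")) {
  m <- validate_counts(m)
  if (!length(mito_prefixes) || !length(ribo_prefixes)) {
    stop_format("mito_prefixes and ribo_prefixes must be non-empty")
  }
  genes <- rownames(m)
  is_pref <- function(prefixes) {
    hit <- rep(FALSE, length(genes))
    for (p in prefixes) hit <- hit | startsWith(genes, p)
    hit
  }
  n_counts <- Matrix::colSums(m)
  n_features <- Matrix::colSums(m > 0)
  mito <- Matrix::colSums(m[is_pref(mito_prefixes), , drop = FALSE])
  ribo <- Matrix::colSums(m[is_pref(ribo_prefixes), , drop = FALSE])
  zero <- n_counts == 0
  if (any(zero)) {
    warning(sprintf("%d cell(s) with zero total counts; pct_mito/pct_ribo set to 0",
                    sum(zero)), call. = FALSE)
  }
  denom <- ifelse(zero, 1, n_counts)
  data.frame(
    barcode = colnames(m),
    n_features = as.integer(n_features),
    n_counts = as.numeric(n_counts),
    pct_mito = 100 * mito / denom,
    pct_ribo = 100 * ribo / denom,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' QC filter thresholds
#'
#' Boundary semantics: the feature window is inclusive (`min_features <=
#' n_features <= max_features`), while the molecule count and the
#' mitochondrial/ribosomal percentages use strict inequalities
#' (`n_counts > min_counts`, `pct_mito < max_pct_mito`,
#' `pct_ribo < max_pct_ribo`). All thresholds are parameters, so alternative
#' boundary readings are one configuration change away.
#'
#' @param min_features,max_features Inclusive window on detected genes.
#' @param min_counts Cells must have strictly more total UMIs than this.
#' @param max_pct_mito,max_pct_ribo Cells must be strictly below these
#'   percentages.
#' @param mito_prefixes,ribo_prefixes Gene-symbol prefixes used to compute the
#'   percentages (recorded so QC reports are self-describing).
#' @return An object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_features = 200, max_features = 6000,
                          min_counts = 1000, max_pct_mito = 15,
                          max_pct_ribo = 40,
                          mito_prefixes = c("mt-", "MT-"),
                          ribo_prefixes = c("Rps", "Rpl")) {
  if (min_features > max_features) {
    stop_format("min_features (%s) must not exceed max_features (%s)",
                min_features, max_features)
  }
  vals <- c(min_features, max_features, min_counts, max_pct_mito, max_pct_ribo)
  if (any(vals < 0)) stop_format("QC thresholds must be non-negative")
  structure(list(min_features = min_features, max_features = max_features,
                 min_counts = min_counts, max_pct_mito = max_pct_mito,
                 max_pct_ribo = max_pct_ribo,
                 mito_prefixes = mito_prefixes, ribo_prefixes = ribo_prefixes),
            class = "qc_thresholds")
}

#' @export
print.qc_thresholds <- function(x, ...) {
  cat(sprintf(paste0("<qc_thresholds> %s <= n_features <= %s; n_counts > %s; ",
                     "pct_mito < %s; pct_ribo < %s\n  mito prefixes: %s; ribo prefixes: %s\n"),
              x$min_features, x$max_features, x$min_counts, x$max_pct_mito,
              x$max_pct_ribo, paste(x$mito_prefixes, collapse = ", "),
              paste(x$ribo_prefixes, collapse = ", ")))
  invisible(x)
}

#' Filter cells on QC metrics
#'
#' A cell is kept iff it passes all four criteria of [qc_thresholds()]. The
#' criteria are evaluated independently, so the surviving set does not depend
#' on any ordering, and the report counts how many cells fail each criterion
#' (a cell may fail several).
#'
#' @param m Count matrix (genes x cells).
#' @param qc QC table from [compute_cell_qc()]; rows must align with the
#'   matrix barcodes.
#' @param thresholds A [qc_thresholds()] object.
#' @return A list with `counts` (the filtered matrix), `report` (per-criterion
#'   removal counts) and `flags` (per-cell pass/fail logical table, one row per
#'   input cell).
#' @export
filter_cells <- function(m, qc, thresholds = qc_thresholds()) {
  m <- validate_counts(m)
  if (!is(thresholds, "qc_thresholds")) {
    stop_format("'thresholds' must be a qc_thresholds object")
  }
  if (!identical(qc$barcode, colnames(m))) {
    stop_format("QC table rows do not align with matrix barcodes")
  }
  t <- thresholds
  fail_features <- qc$n_features < t$min_features | qc$n_features > t$max_features
  fail_counts   <- !(qc$n_counts > t$min_counts)
  fail_mito     <- !(qc$pct_mito < t$max_pct_mito)
  fail_ribo     <- !(qc$pct_ribo < t$max_pct_ribo)
  keep <- !(fail_features | fail_counts | fail_mito | fail_ribo)
  flags <- data.frame(barcode = qc$barcode,
                      fail_features = fail_features, fail_counts = fail_counts,
                      fail_mito = fail_mito, fail_ribo = fail_ribo,
                      pass = keep, stringsAsFactors = FALSE)
  report <- data.frame(
    criterion = c("n_features", "n_counts", "pct_mito", "pct_ribo", "any"),
    n_failed = c(sum(fail_features), sum(fail_counts), sum(fail_mito),
                 sum(fail_ribo), sum(!keep)),
    stringsAsFactors = FALSE
  )
  list(counts = m[, keep, drop = FALSE], report = report, flags = flags)
}

#' Log-normalize a count matrix
#'
#' Standard single-cell log-normalization: each cell's counts are scaled to a
#' common total (`scale_factor`, default 10,000) and transformed with the
#' natural log of 1 + x:
#' \deqn{v_{g,i} = \ln(1 + c_{g,i} \cdot \mathrm{sf} / N_i)}
#' where \eqn{N_i} is cell i's total UMI count. Zero counts map exactly to 0,
#' so the sparsity pattern is preserved.
#'
#' @param m Count matrix (genes x cells); every cell must have a positive
#'   total (run [filter_cells()] first).
#' @param scale_factor Target per-cell total before the log transform.
#' @return A `dgCMatrix` of normalized values, with the scheme recorded in
#'   attributes `scale_factor` and `normalization`.
#' @export
log_normalize <- function(m, scale_factor = 10000) {
  m <- validate_counts(m)
  totals <- Matrix::colSums(m)
  if (any(totals == 0)) {
    stop_format("%d cell(s) have zero total counts; run filter_cells() before log_normalize()",
                sum(totals == 0))
  }
  out <- as(m, "CsparseMatrix")
  percol <- rep.int(totals, diff(out@p))
  out@x <- log1p(out@x / percol * scale_factor)
  attr(out, "scale_factor") <- scale_factor
  attr(out, "normalization") <- "log1p(counts/total * scale_factor)"
  out
}

#' Per-cluster mean normalized expression
#'
#' Computes \eqn{\mu_{g,c}}, the arithmetic mean of normalized expression of
#' gene g over all cells assigned to cluster c, zeros included (no dropout
#' exclusion). These cluster profiles are the sole input to communication
#' scoring.
#'
#' @param norm Normalized matrix (genes x cells) from [log_normalize()].
#' @param ann Annotation data.frame with `barcode` and the grouping column;
#'   every cell in `norm` must carry a label.
#' @param group_key Annotation column defining the groups (default
#'   `"cluster"`).
#' @return An object of class `cluster_profile`: list with `means` (dense
#'   genes x clusters matrix) and `cells_per_cluster` (named integer vector).
#'   Clusters with no cells in the matrix are omitted with a warning, never
#'   emitted as NaN.
#' @export
cluster_means <- function(norm, ann, group_key = "cluster") {
  if (!group_key %in% names(ann)) {
    stop_format("annotation lacks grouping column '%s'", group_key)
  }
  labels <- setNames(as.character(ann[[group_key]]), ann$barcode)
  cells <- colnames(norm)
  if (any(!cells %in% names(labels)) || anyNA(labels[cells])) {
    stop_format("every cell in the matrix must have a non-missing '%s' label", group_key)
  }
  f <- labels[cells]
  referenced <- unique(as.character(ann[[group_key]]))
  absent <- setdiff(referenced[!is.na(referenced)], unique(f))
  if (length(absent)) {
    warning(sprintf("cluster(s) with no cells in the matrix omitted: %s",
                    paste(absent, collapse = ", ")), call. = FALSE)
  }
  lvls <- unique(f)  # first-appearance order
  fac <- factor(f, levels = lvls)
  ind <- Matrix::sparseMatrix(i = seq_along(fac), j = as.integer(fac), x = 1,
                              dims = c(length(fac), length(lvls)))
  n <- as.integer(table(fac))
  means <- as.matrix(norm %*% ind)
  means <- sweep(means, 2, n, "/")
  dimnames(means) <- list(rownames(norm), lvls)
  structure(list(means = means, cells_per_cluster = setNames(n, lvls)),
            class = "cluster_profile")
}

#' @export
print.cluster_profile <- function(x, ...) {
  cat(sprintf("<cluster_profile> %d genes x %d clusters\n cells per cluster: %s\n",
              nrow(x$means), ncol(x$means),
              paste(sprintf("%s=%d", names(x$cells_per_cluster), x$cells_per_cluster),
                    collapse = ", ")))
  invisible(x)
}
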
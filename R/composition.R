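#' Cluster abundance per condition
#'
#' Counts cells per (condition, cluster) and converts to percentages of the
#' condition's total. The union of clusters across conditions is used for all
#' conditions, so a cluster absent from one condition appears with p = 0, not
#' as a missing row. Percentages sum to 100 within each condition.
#'
#' @param ann Annotation data.frame; every cell needs a `cluster` label and a
#'   label in `group_key`.
#' @param group_key Column defining the conditions (default `"condition"`).
#' @param cluster_key Column with cluster labels (default `"cluster"`).
#' @return A data.frame with columns `condition`, `cluster`, `n_cells`, `pct`.
#' @export
cluster_fractions <- function(ann, group_key = "condition", cluster_key = "cluster") {
  for (col in c(group_key, cluster_key)) {
    if (!col %in% names(ann)) stop_format("annotation lacks column '%s'", col)
  }
  if (!nrow(ann)) stop_format("annotation has no cells")
  cond <- as.character(ann[[group_key]])
  clus <- as.character(ann[[cluster_key]])
  if (anyNA(cond) || anyNA(clus)) {
    stop_format("every cell needs non-missing '%s' and '%s' labels", group_key, cluster_key)
  }
  conditions <- unique(cond)
  clusters <- unique(clus)
  tab <- table(factor(cond, conditions), factor(clus, clusters))
  totals <- rowSums(tab)
  if (any(totals == 0)) {
    stop_format("condition '%s' has no cells", conditions[totals == 0][1])
  }
  out <- expand.grid(condition = conditions, cluster = clusters,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$n_cells <- as.integer(tab[cbind(out$condition, out$cluster)])
  out$pct <- 100 * out$n_cells / totals[out$condition]
  out <- out[order(match(out$condition, conditions), match(out$cluster, clusters)), ]
  rownames(out) <- NULL
  out
}

#' Between-condition difference in cluster abundance
#'
#' Per cluster, the difference in abundance percentage between two conditions,
#' in percentage points: `delta = p(cond_a) - p(cond_b)` (signed), plus its
#' absolute value. Because each condition's percentages sum to 100, the signed
#' differences sum to 0 exactly.
#'
#' @param tab Abundance table from [cluster_fractions()].
#' @param cond_a,cond_b Condition labels to compare (a minus b).
#' @return A data.frame with columns `cluster`, `pct_a`, `pct_b`, `delta_pp`,
#'   `abs_delta_pp`, sorted by `abs_delta_pp` descending.
#' @export
abundance_difference <- function(tab, cond_a, cond_b) {
  for (cond in c(cond_a, cond_b)) {
    if (!cond %in% tab$condition) stop_format("unknown condition label '%s'", cond)
  }
  a <- tab[tab$condition == cond_a, ]
  b <- tab[tab$condition == cond_b, ]
  clusters <- unique(tab$cluster)
  pa <- setNames(a$pct, a$cluster)[clusters]
  pb <- setNames(b$pct, b$cluster)[clusters]
  out <- data.frame(cluster = clusters,
                    pct_a = as.numeric(pa), pct_b = as.numeric(pb),
                    delta_pp = as.numeric(pa - pb),
                    abs_delta_pp = abs(as.numeric(pa - pb)),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$abs_delta_pp), ]
  rownames(out) <- NULL
  out
}
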
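#' Resolve an LR pair table against a gene universe
#'
#' Drops every pair with any ligand or receptor subunit absent from the gene
#' universe (typically the matrix's gene list) and reports the dropped pairs.
#' Resolution is universe-insensitive: adding unrelated genes never changes
#' how existing pairs resolve.
#'
#' @param lr An `lr_pair_table` (see [read_lr_pairs()]).
#' @param gene_universe Character vector of available gene symbols.
#' @param case_sensitive Match symbols case-sensitively (default). The
#'   case-insensitive mode folds both sides to lower case before matching but
#'   reports the original symbols.
#' @return List with `pairs` (the resolved `lr_pair_table`, subunits rewritten
#'   to the universe's spelling when case-insensitive) and `dropped`
#'   (data.frame of pair_id and the missing subunits). An empty resolved table
#'   is an error: there is nothing to score.
#' @export
resolve_pairs <- function(lr, gene_universe, case_sensitive = TRUE) {
  if (!is(lr, "lr_pair_table")) stop_format("'lr' must be an lr_pair_table")
  key <- if (case_sensitive) gene_universe else tolower(gene_universe)
  lookup <- function(subunits) {
    q <- if (case_sensitive) subunits else tolower(subunits)
    gene_universe[match(q, key)]
  }
  res_l <- lapply(lr$ligand_subunits, lookup)
  res_r <- lapply(lr$receptor_subunits, lookup)
  ok <- !vapply(res_l, anyNA, logical(1)) & !vapply(res_r, anyNA, logical(1))
  dropped <- data.frame(
    pair_id = lr$pair_id[!ok],
    missing = vapply(which(!ok), function(i) {
      mis <- c(lr$ligand_subunits[[i]][is.na(res_l[[i]])],
               lr$receptor_subunits[[i]][is.na(res_r[[i]])])
      paste(mis, collapse = ",")
    }, character(1)),
    stringsAsFactors = FALSE
  )
  pairs <- lr[ok, , drop = FALSE]
  pairs$ligand_subunits <- res_l[ok]
  pairs$receptor_subunits <- res_r[ok]
  class(pairs) <- c("lr_pair_table", "data.frame")
  if (!nrow(pairs)) {
    stop_format("no LR pair could be resolved against the gene universe; nothing to score")
  }
  list(pairs = pairs, dropped = dropped)
}

combine_subunits <- function(mu_rows, rule) {
  # mu_rows: subunits x clusters matrix of cluster means for one complex
  switch(rule,
         min = apply(mu_rows, 2, min),
         mean = colMeans(mu_rows),
         geomean = exp(colMeans(log(mu_rows))),
         stop_format("unknown complex_rule '%s'", rule))
}

#' Cluster-to-cluster communication scores for LR pairs
#'
#' For every ordered pair of clusters (A, B), including A = B, and every
#' resolved ligand-receptor pair, the communication score is the expression
#' product of the cluster means:
#' \deqn{s = \mu_{ligand, A} \times \mu_{receptor, B}}
#' The direction is fixed from ligand (expressed by the source cluster) to
#' receptor (expressed by the target cluster). Low expression of either side
#' in its cluster drives the score toward 0; the score is exactly 0 whenever
#' either factor is 0. For multi-subunit complexes the factor is the
#' `complex_rule` combination of the subunit means (default: the minimum, i.e.
#' limiting-subunit logic).
#'
#' @param profile A [cluster_means()] profile.
#' @param lr Resolved `lr_pair_table` (from [resolve_pairs()]).
#' @param complex_rule How subunit means combine: `"min"` (default), `"mean"`,
#'   or `"geomean"`.
#' @return A data.frame of class `comm_scores` with one row per
#'   (source, target, pair): columns `source`, `target`, `pair_id`, `score`.
#' @export
score_communication <- function(profile, lr, complex_rule = c("min", "mean", "geomean")) {
  complex_rule <- match.arg(complex_rule)
  if (!is(profile, "cluster_profile")) stop_format("'profile' must be a cluster_profile")
  mu <- profile$means
  clusters <- colnames(mu)
  if (!length(clusters)) stop_format("cluster profile is empty")
  genes_needed <- unique(unlist(c(lr$ligand_subunits, lr$receptor_subunits)))
  if (!all(genes_needed %in% rownames(mu))) {
    stop_format("LR pairs are not resolved against this profile's genes; run resolve_pairs()")
  }
  # pairs x clusters factor matrices
  lig <- do.call(rbind, lapply(lr$ligand_subunits, function(su)
    combine_subunits(mu[su, , drop = FALSE], complex_rule)))
  rec <- do.call(rbind, lapply(lr$receptor_subunits, function(su)
    combine_subunits(mu[su, , drop = FALSE], complex_rule)))
  colnames(lig) <- colnames(rec) <- clusters
  grid <- expand.grid(source = clusters, target = clusters,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rows <- vector("list", nrow(grid))
  for (k in seq_len(nrow(grid))) {
    a <- grid$source[k]; b <- grid$target[k]
    rows[[k]] <- data.frame(source = a, target = b, pair_id = lr$pair_id,
                            score = lig[, a] * rec[, b],
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "complex_rule") <- complex_rule
  class(out) <- c("comm_scores", "data.frame")
  out
}

#' Aggregate per-pair scores into a communication network
#'
#' For each ordered cluster pair, sums the per-pair communication scores that
#' strictly exceed the threshold and counts them:
#' \deqn{S(A \to B) = \sum_{s > \tau} s, \qquad n(A \to B) = \#\{s > \tau\}}
#' The default threshold is 6, with strict inequality (a score of exactly 6 is
#' excluded). Cluster pairs with no supra-threshold interaction are emitted
#' with S = 0 and n = 0, never omitted.
#'
#' @param scores A `comm_scores` table from [score_communication()].
#' @param threshold Aggregation threshold tau (default 6); must be >= 0.
#' @return A data.frame of class `comm_network` with one row per ordered
#'   (source, target) cluster pair: `source`, `target`, `aggregated_score`,
#'   `n_interactions`; the threshold is recorded as an attribute.
#' @export
build_network <- function(scores, threshold = 6) {
  if (!is(scores, "comm_scores")) stop_format("'scores' must come from score_communication()")
  if (!is.numeric(threshold) || threshold < 0) {
    stop_format("threshold must be a non-negative number")
  }
  clusters <- unique(c(scores$source, scores$target))
  grid <- expand.grid(source = clusters, target = clusters,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  key_all <- paste(scores$source, scores$target, sep = "\r")
  pass <- scores$score > threshold
  key_pass <- key_all[pass]
  s_sum <- tapply(scores$score[pass], key_pass, sum)
  n_cnt <- tapply(scores$score[pass], key_pass, length)
  gkey <- paste(grid$source, grid$target, sep = "\r")
  out <- data.frame(
    source = grid$source, target = grid$target,
    aggregated_score = as.numeric(ifelse(is.na(s_sum[gkey]), 0, s_sum[gkey])),
    n_interactions = as.integer(ifelse(is.na(n_cnt[gkey]), 0L, n_cnt[gkey])),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "threshold") <- threshold
  class(out) <- c("comm_network", "data.frame")
  out
}

#' @export
print.comm_network <- function(x, ...) {
  cat(sprintf("<comm_network> %d ordered cluster pairs; threshold %s; %d with interactions\n",
              nrow(x), format(attr(x, "threshold")), sum(x$n_interactions > 0)))
  print.data.frame(utils::head(x[order(-x$aggregated_score), ], 10))
  invisible(x)
}

#' Outgoing interaction counts per source cluster
#'
#' For each requested source cluster, the number of supra-threshold LR
#' interactions it sends to other clusters (self-loops reported separately,
#' since crosstalk figures count interactions toward *other* cell clusters).
#'
#' @param net A `comm_network` from [build_network()].
#' @param sources Source clusters to report (default all); unknown clusters
#'   are an error.
#' @return A data.frame with columns `source`, `outgoing` (sum of
#'   `n_interactions` over targets != source) and `self` (the self-loop
#'   count).
#' @export
outgoing_interaction_counts <- function(net, sources = NULL) {
  if (!is(net, "comm_network")) stop_format("'net' must come from build_network()")
  clusters <- unique(c(net$source, net$target))
  sources <- sources %||% clusters
  unknown <- setdiff(sources, clusters)
  if (length(unknown)) {
    stop_format("unknown source cluster(s): %s", paste(unknown, collapse = ", "))
  }
  out <- data.frame(
    source = sources,
    outgoing = vapply(sources, function(a)
      sum(net$n_interactions[net$source == a & net$target != a]), numeric(1)),
    self = vapply(sources, function(a)
      sum(net$n_interactions[net$source == a & net$target == a]), numeric(1)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}
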
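make_profile <- function(mu) {
  structure(list(means = mu,
                 cells_per_cluster = setNames(rep(10L, ncol(mu)), colnames(mu))),
            class = "cluster_profile")
}

test_that("pair resolution drops pairs with absent subunits and reports them", {
  lr <- lr_pair_table(c("p1", "p2", "p3"),
                      c("Il1b", "Tgfb1", "Ccl2"),
                      c("Il1r1", "Tgfbr1_Tgfbr2", "Ccr2"))
  universe <- c("Il1b", "Il1r1", "Tgfb1", "Tgfbr1", "Ccl2", "Ccr2")  # no Tgfbr2
  res <- resolve_pairs(lr, universe)
  expect_identical(res$pairs$pair_id, c("p1", "p3"))
  expect_identical(res$dropped$pair_id, "p2")
  expect_match(res$dropped$missing, "Tgfbr2")
  # universe-insensitivity: unrelated genes change nothing
  res2 <- resolve_pairs(lr, c(universe, "Actb", "Gapdh"))
  expect_identical(res2$pairs$pair_id, res$pairs$pair_id)
  expect_error(resolve_pairs(lr, "Actb"), "resolved")
})

test_that("case-insensitive resolution maps to the universe's spelling", {
  lr <- lr_pair_table("p1", "IL1B", "IL1R1")
  res <- resolve_pairs(lr, c("Il1b", "Il1r1"), case_sensitive = FALSE)
  expect_identical(res$pairs$ligand_subunits[[1]], "Il1b")
  expect_error(resolve_pairs(lr, c("Il1b", "Il1r1"), case_sensitive = TRUE), "resolved")
})

test_that("communication scores are the expression product with fixed direction", {
  mu <- cbind(A = c(Lig = 2, Rec = 0.5, X = 1),
              B = c(Lig = 0.1, Rec = 3, X = 1))
  prof <- make_profile(mu)
  lr <- resolve_pairs(lr_pair_table("p", "Lig", "Rec"), rownames(mu))$pairs
  sc <- score_communication(prof, lr)
  s <- function(a, b) sc$score[sc$source == a & sc$target == b]
  expect_equal(s("A", "B"), 2 * 3)
  expect_equal(s("B", "A"), 0.1 * 0.5)
  expect_equal(s("A", "A"), 2 * 0.5)
  # zero annihilation
  mu0 <- mu; mu0["Lig", "A"] <- 0
  sc0 <- score_communication(make_profile(mu0), lr)
  expect_identical(sc0$score[sc0$source == "A" & sc0$target == "B"], 0)
})

test_that("complex rules combine subunit means as specified", {
  mu <- cbind(A = c(L = 4, R1 = 3, R2 = 1.5), B = c(L = 0, R1 = 3, R2 = 1.5))
  lr <- resolve_pairs(lr_pair_table("p", "L", "R1_R2"), rownames(mu))$pairs
  s_min <- score_communication(make_profile(mu), lr, "min")
  expect_equal(s_min$score[s_min$source == "A" & s_min$target == "B"], 4 * 1.5)
  s_mean <- score_communication(make_profile(mu), lr, "mean")
  expect_equal(s_mean$score[s_mean$source == "A" & s_mean$target == "B"], 4 * 2.25)
  s_geo <- score_communication(make_profile(mu), lr, "geomean")
  expect_equal(s_geo$score[s_geo$source == "A" & s_geo$target == "B"],
               4 * sqrt(3 * 1.5))
})

test_that("vectorized scoring equals the brute-force double loop", {
  set.seed(21)
  mu <- matrix(rexp(50 * 4), 50, 4,
               dimnames = list(sprintf("g%d", 1:50), LETTERS[1:4]))
  lig <- sample(rownames(mu), 12)
  rec <- setdiff(rownames(mu), lig)[1:12]
  rec[1:3] <- paste(rec[1:3], sample(setdiff(rownames(mu), c(lig, rec)), 3), sep = "_")
  lr <- resolve_pairs(lr_pair_table(sprintf("p%d", 1:12), lig, rec), rownames(mu))$pairs
  sc <- score_communication(make_profile(mu), lr)
  oracle <- oracle_comm_scores(mu, lr)
  merged <- merge(sc, oracle, by = c("source", "target", "pair_id"))
  expect_identical(nrow(merged), nrow(sc))
  expect_lt(max(abs(merged$score.x - merged$score.y)), 1e-12)
})

test_that("bilinearity: scaling a source cluster's means scales its outgoing scores", {
  set.seed(22)
  mu <- matrix(rexp(30 * 3), 30, 3,
               dimnames = list(sprintf("g%d", 1:30), c("A", "B", "C")))
  lr <- resolve_pairs(lr_pair_table(sprintf("p%d", 1:10),
                                    rownames(mu)[1:10], rownames(mu)[11:20]),
                      rownames(mu))$pairs
  sc1 <- score_communication(make_profile(mu), lr)
  k <- 3.7
  mu2 <- mu; mu2[, "A"] <- mu2[, "A"] * k
  sc2 <- score_communication(make_profile(mu2), lr)
  from_a <- sc1$source == "A" & sc1$target != "A"
  expect_equal(sc2$score[from_a], k * sc1$score[from_a], tolerance = 1e-12)
})

test_that("network aggregation uses a strict threshold and keeps empty pairs", {
  mu <- cbind(A = c(L1 = 1, L2 = 1, L3 = 1, R1 = 0, R2 = 0, R3 = 0),
              B = c(L1 = 0, L2 = 0, L3 = 0, R1 = 7, R2 = 6, R3 = 10))
  lr <- resolve_pairs(lr_pair_table(c("p1", "p2", "p3"),
                                    c("L1", "L2", "L3"), c("R1", "R2", "R3")),
                      rownames(mu))$pairs
  sc <- score_communication(make_profile(mu), lr)
  net <- build_network(sc, threshold = 6)
  ab <- net[net$source == "A" & net$target == "B", ]
  expect_equal(ab$aggregated_score, 17)     # 7 + 10; the 6.0 pair excluded
  expect_identical(ab$n_interactions, 2L)
  ba <- net[net$source == "B" & net$target == "A", ]
  expect_identical(ba$n_interactions, 0L)
  expect_identical(ba$aggregated_score, 0)
  expect_identical(nrow(net), 4L)           # all ordered pairs emitted
  # degenerate threshold: everything positive survives
  net0 <- build_network(sc, threshold = 0)
  expect_equal(sum(net0$aggregated_score), sum(sc$score[sc$score > 0]))
  expect_error(build_network(sc, threshold = -1), "non-negative")
})

test_that("aggregate equals the sum of its surviving per-pair scores", {
  sim <- simulate_dataset(small_sim_config(), seed = 17)
  qc <- compute_cell_qc(sim$counts)
  norm <- log_normalize(filter_cells(sim$counts, qc)$counts)
  ann <- sim$annotation[sim$annotation$barcode %in% colnames(norm), ]
  prof <- cluster_means(norm, ann)
  lr <- resolve_pairs(sim_lr_pair_table(sim$truth), rownames(norm))$pairs
  sc <- score_communication(prof, lr)
  net <- build_network(sc, threshold = 6)
  for (i in seq_len(nrow(net))) {
    sub <- sc$score[sc$source == net$source[i] & sc$target == net$target[i]]
    expect_equal(net$aggregated_score[i], sum(sub[sub > 6]))
    expect_true(net$aggregated_score[i] == 0 || net$n_interactions[i] > 0)
    if (net$n_interactions[i] > 0) {
      expect_gt(net$aggregated_score[i], net$n_interactions[i] * 6)
    }
  }
})

test_that("outgoing counts separate self-loops and conserve the total", {
  net <- structure(data.frame(
    source = c("A", "A", "A", "B", "B", "C", "B", "C", "C"),
    target = c("B", "C", "A", "A", "B", "C", "C", "A", "B"),
    aggregated_score = c(20, 15, 7, 0, 8, 9, 0, 0, 0),
    n_interactions = c(3L, 2L, 1L, 0L, 1L, 1L, 0L, 0L, 0L)),
    threshold = 6, class = c("comm_network", "data.frame"))
  out <- outgoing_interaction_counts(net, c("A", "B"))
  expect_equal(out$outgoing[out$source == "A"], 5)
  expect_equal(out$self[out$source == "A"], 1)
  expect_equal(out$outgoing[out$source == "B"], 0)
  all_out <- outgoing_interaction_counts(net)
  expect_equal(sum(all_out$outgoing + all_out$self), sum(net$n_interactions))
  expect_error(outgoing_interaction_counts(net, "Z"), "unknown")
})
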
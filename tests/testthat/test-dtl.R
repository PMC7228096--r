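test_that("a congruent single-copy family reconciles at zero cost", {
  st <- simulate_species_tree(15, seed = 2)
  h <- simulate_gene_history(st, event_rates(0, 0), seed = 1)
  expect_equal(dtl_reconciliation_cost(h$tree, st$phy), 0)
  res <- dtl_root(unroot_tree(h$tree), st$phy)
  expect_equal(res$score, 0)
  expect_equal(rf_rooted(pick_rooting(res, unroot_tree(h$tree)), h$tree), 0)
})

test_that("a single transfer explains the classic discordant triplet", {
  S <- parse_newick("((A:1,B:1):1,C:1);")
  G <- parse_newick("((A_1:1,C_1:1):1,B_1:1);")
  expect_equal(dtl_reconciliation_cost(G, S), 3)   # one transfer at cost 3
  expect_equal(dtl_brute_force(G, S,
                               c(A_1 = "A", C_1 = "C", B_1 = "B"),
                               c(1, 2, 3)), 3)
})

test_that("the dynamic program equals brute-force enumeration", {
  set.seed(202)
  for (rep in 1:60) {
    inst <- random_dtl_instance()
    costs <- sample(0:5, 3, replace = TRUE)
    expect_equal(
      dtl_reconciliation_cost(inst$gtree, inst$stree, inst$mapping, costs),
      dtl_brute_force(inst$gtree, inst$stree, inst$mapping, costs))
  }
})

test_that("per-edge rooting costs equal independent single-rooting costs", {
  set.seed(33)
  for (rep in 1:25) {
    st <- ape::rtree(sample(3:6, 1)); st$tip.label <- paste0("S", seq_along(st$tip.label))
    ng <- sample(4:7, 1)
    gt <- ape::rtree(ng)
    sp <- sample(st$tip.label, ng, replace = TRUE)
    gt$tip.label <- paste0(sp, "_", seq_len(ng))
    u <- unroot_tree(gt)
    res <- dtl_root(u, st)
    for (i in seq_len(nrow(u$edge))) {
      r <- root_at(u, root_position(u, u$edge[i, ], 0.5))
      expect_equal(res$edge_scores$score[i], dtl_reconciliation_cost(r, st))
    }
    expect_equal(res$score, min(res$edge_scores$score))
    expect_equal(res$tie_count, sum(res$edge_scores$is_optimal))
  }
})

test_that("brute force fixes the optimal tie set", {
  per_edge_brute <- function(u, S) {
    vapply(seq_len(nrow(u$edge)), function(i) {
      r <- root_at(u, root_position(u, u$edge[i, ], 0.5))
      dtl_brute_force(r, S, stats::setNames(sub("_[0-9]+$", "", r$tip.label),
                                            r$tip.label), c(1, 2, 3))
    }, numeric(1))
  }
  # the symmetric duplication family has a *unique* optimal edge (one
  # duplication, cost 2, on the internal edge); every pendant rooting needs
  # an extra event
  S <- parse_newick("(A:1,B:1);")
  u <- unroot_tree(parse_newick("((A_1:1,B_1:1):1,(A_2:1,B_2:1):1);"))
  res <- dtl_root(u, S)
  brute <- per_edge_brute(u, S)
  expect_equal(res$edge_scores$score, brute)
  expect_equal(res$score, 2)
  expect_equal(res$tie_count, 1L)
  expect_equal(res$tie_count, sum(brute == min(brute)))

  # a two-copy mixed family where three rootings tie at the optimum
  S2 <- parse_newick("((S1:1,S2:1):1,S3:1);")
  u2 <- parse_newick("((S2_1:1,S1_2:1):1,S1_3:1,(S1_4:1,S2_5:1):1);")
  res2 <- dtl_root(u2, S2)
  brute2 <- per_edge_brute(u2, S2)
  expect_equal(res2$edge_scores$score, brute2)
  expect_equal(res2$tie_count, sum(brute2 == min(brute2)))
  expect_gt(res2$tie_count, 1L)
  # every reported position re-evaluates to the reported optimum
  for (p in res2$positions)
    expect_equal(dtl_reconciliation_cost(root_at(u2, p), S2), res2$score)
})

test_that("optimal cost is nondecreasing in each unit cost", {
  set.seed(404)
  for (rep in 1:20) {
    inst <- random_dtl_instance()
    base <- c(1, 2, 3)
    c0 <- dtl_reconciliation_cost(inst$gtree, inst$stree, inst$mapping, base)
    for (k in 1:3) {
      up <- base; up[k] <- up[k] + 2
      expect_gte(dtl_reconciliation_cost(inst$gtree, inst$stree,
                                         inst$mapping, up), c0)
    }
  }
})

test_that("unmapped or unknown leaves are rejected", {
  S <- parse_newick("((A:1,B:1):1,C:1);")
  G <- parse_newick("((A_1:1,X_1:1):1,B_1:1);")
  expect_error(dtl_reconciliation_cost(G, S), "unknown species")
  expect_error(dtl_reconciliation_cost(G, S, mapping = c(A_1 = "A")),
               "unmapped")
})
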
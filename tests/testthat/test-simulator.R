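test_that("species trees are ultrametric with the requested size and height", {
  st <- simulate_species_tree(100, seed = 5)
  expect_length(st$phy$tip.label, 100)
  expect_true(ape::is.ultrametric(st$phy, tol = 1e-8))
  expect_equal(max(ape::node.depth.edgelength(st$phy)), 1, tolerance = 1e-12)
  expect_equal(unname(st$times[101]), 0)      # root at time 0

  st2 <- simulate_species_tree(2, seed = 5)
  expect_equal(sort(st2$phy$edge.length), c(1, 1))

  # determinism: same seed, byte-identical newick; different seeds differ
  a <- write_newick(simulate_species_tree(20, seed = 9)$phy)
  b <- write_newick(simulate_species_tree(20, seed = 9)$phy)
  c <- write_newick(simulate_species_tree(20, seed = 10)$phy)
  expect_identical(a, b)
  expect_false(identical(a, c))
  expect_error(simulate_species_tree(10, birth = 1, death = 2), "birth")
})

test_that("the loss rate is derived from duplication and additive transfer", {
  expect_equal(rate_preset("low")$loss, 0.8 * (0.13 + 0.3 * 0.27))
  expect_equal(rate_preset("low")$loss, 0.1688)
  expect_equal(rate_preset("medium")$loss, 0.8 * (0.3 + 0.3 * 0.6))
  expect_equal(rate_preset("high", additive_fraction = 1)$loss,
               0.8 * (0.6 + 1.2))
  for (p in c("low", "medium", "high", "very_high_2", "very_high_3",
              "very_high_4")) {
    r <- rate_preset(p)
    expect_equal(r$loss, 0.8 * (r$duplication + r$additive_fraction * r$transfer))
  }
})

test_that("a family with zero event rates reproduces the species tree", {
  st <- simulate_species_tree(40, seed = 3)
  h <- simulate_gene_history(st, event_rates(0, 0), seed = 1)
  expect_equal(h$n_leaves, 40)
  expect_false(h$extinct)
  expect_equal(unname(unlist(h$counts[-1])), rep(0, 4))
  relabeled <- h$tree
  relabeled$tip.label <- sub("_1$", "", relabeled$tip.label)
  expect_equal(rf_rooted(relabeled, st$phy), 0)
  expect_equal(unname(h$leaf_map), sub("_1$", "", names(h$leaf_map)))
})

test_that("gene histories are deterministic and unscaled trees ultrametric", {
  st <- simulate_species_tree(30, seed = 8)
  h1 <- simulate_gene_family(st, rate_preset("medium"), seed = 21)
  h2 <- simulate_gene_family(st, rate_preset("medium"), seed = 21)
  expect_identical(write_newick(h1$tree), write_newick(h2$tree))
  expect_true(ape::is.ultrametric(h1$tree, tol = 1e-8))
  # every gene leaf maps to a species leaf
  expect_true(all(h1$leaf_map %in% st$phy$tip.label))
  # the event log agrees with the reported surviving counts
  expect_equal(sum(h1$events$kind == "duplication"),
               unname(h1$counts["Duplications"]))
  expect_equal(sum(h1$events$kind == "replacing_transfer"),
               unname(h1$counts["Replacing Transfers"]))
})

test_that("surviving event counts match the reference medium-rate row", {
  # reference means per family (averaged over 100 families in the source
  # table): leaves 108.89, dup 5.73, losses 8.35, additive 3.38,
  # replacing 7.98; asserted within 3 standard errors of our sample mean
  nfam <- 100
  hs <- lapply(seq_len(nfam), function(i) {
    st <- simulate_species_tree(100, seed = derive_seed("t1check", i))
    simulate_gene_family(st, rate_preset("medium"),
                         seed = derive_seed("t1fam", i))
  })
  cm <- do.call(rbind, lapply(hs, function(h) h$counts))
  expect_identical(colnames(cm), c("Leaves", "Duplications", "Losses",
                                   "Additive Transfers",
                                   "Replacing Transfers"))
  ref <- c(108.89, 5.73, 8.35, 3.38, 7.98)
  m <- colMeans(cm); se <- apply(cm, 2, sd) / sqrt(nfam)
  for (k in seq_along(ref))
    expect_lt(abs(m[k] - ref[k]), 3 * se[k] + 1e-9,
              label = sprintf("%s: |%.2f - %.2f|", colnames(cm)[k], m[k], ref[k]))
})

test_that("raising the transfer rate raises surviving transfer counts", {
  tcount <- function(preset) {
    mean(sapply(1:30, function(i) {
      st <- simulate_species_tree(60, seed = derive_seed("mono", i))
      h <- simulate_gene_family(st, rate_preset(preset),
                                seed = derive_seed("monofam", preset, i))
      sum(h$counts[c("Additive Transfers", "Replacing Transfers")])
    }))
  }
  t2 <- tcount("very_high_2"); t3 <- tcount("very_high_3")
  t4 <- tcount("very_high_4")
  expect_lt(t2, t3)
  expect_lt(t3, t4)
})

test_that("branch scaling respects its bounds and degenerate settings", {
  set.seed(44)
  tr <- random_rooted_tree(20)
  expect_equal(scale_branches(tr, scaling_scheme("uniform", lo = 1, hi = 1),
                              seed = 2)$edge.length, tr$edge.length)
  s0 <- scale_branches(tr, scaling_scheme("autocorrelated", sigma2 = 0,
                                          start_rate = 2), seed = 2)
  expect_equal(sort(s0$edge.length), sort(2 * tr$edge.length),
               tolerance = 1e-12)
  for (i in 1:100) {
    tr <- random_rooted_tree(10)
    sc <- scale_branches(tr, scheme_preset("uniform_0.3_3"), seed = i)
    ratio <- sc$edge.length / ape::reorder.phylo(tr, "cladewise")$edge.length
    expect_true(all(ratio >= 0.3 - 1e-9 & ratio <= 3 + 1e-9))
  }
  # scaling never changes the topology
  sc <- scale_branches(tr, scheme_preset("auto_0.25"), seed = 1)
  expect_equal(rf_unrooted(sc, tr), 0)
})

test_that("NNI perturbation changes at most one split per move", {
  set.seed(91)
  tr <- random_rooted_tree(12)
  p0 <- perturb_topology(tr, 0, seed = 4)
  expect_equal(rf_unrooted(p0, tr), 0)
  p1 <- perturb_topology(tr, 1, seed = 4)
  expect_lte(rf_unrooted(p1, tr), 1)
  for (i in 1:50) {
    k <- sample(0:6, 1)
    tr <- random_rooted_tree(sample(6:15, 1))
    p <- perturb_topology(tr, k, seed = i)
    expect_setequal(p$tip.label, tr$tip.label)
    expect_lte(rf_unrooted(p, tr), k)
  }
})

test_that("family summaries are exact on a hand-built fixture", {
  mk <- function(leaves, d, l, at, rt) {
    structure(list(counts = c(Leaves = leaves, Duplications = d, Losses = l,
                              `Additive Transfers` = at,
                              `Replacing Transfers` = rt)),
              class = "gene_family_history")
  }
  s <- summarize_families(list(mk(100, 0, 0, 0, 0), mk(120, 4, 2, 3, 7)))
  expect_identical(names(s), c("Leaves", "Duplications", "Losses",
                               "Additive Transfers", "Replacing Transfers"))
  expect_equal(unname(unlist(s)), c(110, 2, 1, 1.5, 3.5))
})
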
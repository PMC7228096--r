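test_that("rooting error counts root displacement in RF units", {
  set.seed(55)
  u <- random_unrooted_tree(10)
  E <- nrow(u$edge)
  e1 <- u$edge[1, ]
  t1 <- root_at(u, root_position(u, e1, 0.5))
  expect_equal(rooting_error(t1, t1),
               list(absolute = 0, normalized = 0, correct = TRUE))
  # a rooting two intermediate nodes away errs by (2, 0.2)
  far <- which(vapply(seq_len(E), function(i)
    root_path_distance(u, e1, u$edge[i, ]), integer(1)) == 2L)[1]
  t2 <- root_at(u, root_position(u, u$edge[far, ], 0.5))
  err <- rooting_error(t1, t2)
  expect_equal(err$absolute, 2)
  expect_equal(err$normalized, 0.2)
  expect_false(err$correct)
  # every edge-pair rooting agrees with rf_rooted
  for (i in sample(E, 4)) for (j in sample(E, 4)) {
    ti <- root_at(u, root_position(u, u$edge[i, ], 0.5))
    tj <- root_at(u, root_position(u, u$edge[j, ], 0.5))
    expect_equal(rooting_error(ti, tj)$absolute, rf_rooted(ti, tj))
  }
  # differing topologies are rejected
  other <- random_unrooted_tree(10)
  other$tip.label <- u$tip.label
  t3 <- root_at(other, root_position(other, other$edge[1, ], 0.5))
  if (rf_unrooted(t1, t3) > 0) expect_error(rooting_error(t1, t3), "adjusted_rf")
})

test_that("adjusted RF isolates rooting error from topological error", {
  set.seed(66)
  tr <- random_rooted_tree(12)
  expect_equal(adjusted_rf(tr, tr), 0)
  # same topology, different root: adjusted RF equals rooted RF
  u <- unroot_tree(tr)
  t2 <- root_at(u, root_position(u, u$edge[5, ], 0.5))
  expect_equal(adjusted_rf(tr, t2), rf_rooted(tr, t2))
  # NNI-perturbed topology: rooting at the best edge beats a distant edge,
  # and adjusted RF is never negative
  p <- unroot_tree(perturb_topology(tr, 3, seed = 2))
  arfs <- vapply(seq_len(nrow(p$edge)), function(i)
    adjusted_rf(tr, root_at(p, root_position(p, p$edge[i, ], 0.5))),
    numeric(1))
  expect_true(all(arfs >= 0))
  expect_lt(min(arfs), max(arfs))
})

test_that("root balance is the smaller over larger root-clade size", {
  expect_equal(root_balance(parse_newick("((A:1,B:1):1,(C:1,D:1):1);")), 1)
  cat10 <- "(((((((((A:1,B:1):1,C:1):1,D:1):1,E:1):1,F:1):1,G:1):1,H:1):1,I:1):1,J:1);"
  expect_equal(root_balance(parse_newick(cat10)), 1 / 9)
  # a 504-leaf tree split 406 vs 98 at the root
  set.seed(4)
  a <- ape::rtree(98); a$tip.label <- paste0("c", 1:98)
  b <- ape::rtree(406); b$tip.label <- paste0("p", 1:406)
  nw <- paste0("(", sub(";$", "", write_newick(a)), ":1,",
               sub(";$", "", write_newick(b)), ":1);")
  expect_equal(root_balance(parse_newick(nw)), 98 / 406)
})

test_that("balance squared error behaves like a mean squared error", {
  expect_equal(balance_squared_error(c(0.3, 0.3), 0.3), 0)
  expect_equal(balance_squared_error(0, 0.2413), 0.2413^2)
  set.seed(9)
  b <- runif(50)
  grid <- seq(0, 1, by = 0.01)
  mses <- vapply(grid, function(e) balance_squared_error(b, e), numeric(1))
  expect_equal(grid[which.min(mses)], round(mean(b), 2), tolerance = 0.011)
})

test_that("aggregation reports exact means and quartiles", {
  rec <- data.frame(method = "mad", preset = "low",
                    rf = c(0, 0, 2, 6), norm_rf = c(0, 0, 0.2, 0.6),
                    correct = c(TRUE, TRUE, FALSE, FALSE))
  s <- aggregate_accuracy(rec)
  expect_equal(s$pct_correct, 50)
  expect_equal(s$mean_rf, 2)
  expect_equal(s$mean_norm_rf, 0.2)
  expect_equal(c(s$rf_q1, s$rf_q2, s$rf_q3),
               unname(quantile(c(0, 0, 2, 6), c(.25, .5, .75), type = 7)))
  expect_true(all(c("rf_q1", "rf_q2", "rf_q3") %in% names(s)))

  allcor <- data.frame(method = "x", rf = c(0, 0), norm_rf = c(0, 0),
                       correct = c(TRUE, TRUE))
  s2 <- aggregate_accuracy(allcor)
  expect_equal(s2$pct_correct, 100)
  expect_equal(s2$mean_rf, 0)
})

test_that("rooting error is invariant under consistent leaf relabeling", {
  set.seed(77)
  u <- random_unrooted_tree(8)
  t1 <- root_at(u, root_position(u, u$edge[2, ], 0.5))
  t2 <- root_at(u, root_position(u, u$edge[6, ], 0.5))
  base <- rooting_error(t1, t2)$absolute
  perm <- sample(u$tip.label)
  relab <- function(tr) {
    tr$tip.label <- perm[match(tr$tip.label, u$tip.label)]
    tr
  }
  expect_equal(rooting_error(relab(t1), relab(t2))$absolute, base)
})

test_that("expected random-rooting RF equals the mean root-path distance", {
  set.seed(88)
  u <- random_unrooted_tree(8)
  E <- nrow(u$edge)
  true_edge <- u$edge[3, ]
  truth <- root_at(u, root_position(u, true_edge, 0.5))
  closed <- mean(vapply(seq_len(E), function(i)
    root_path_distance(u, true_edge, u$edge[i, ]), integer(1)))
  sampled <- mean(vapply(1:2000, function(s) {
    r <- pick_rooting(random_root(u, seed = s), u)
    rf_rooted(truth, r)
  }, numeric(1)))
  expect_equal(sampled, closed, tolerance = 0.1)
})
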
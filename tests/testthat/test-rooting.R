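test_that("midpoint rooting halves the longest leaf-to-leaf path", {
  # star with pendant lengths 1, 2, 5: diameter B-C of length 7, midpoint
  # 3.5 from C, i.e. 1.5 into C's pendant edge from the hub
  s <- parse_newick("(A:1,B:2,C:5);")
  m <- midpoint_root(s)
  expect_equal(m$score, 3.5)
  expect_equal(m$tie_count, 1L)
  p <- m$positions[[1]]
  expect_equal(sort(p$edge), c(3, 4))            # C's pendant edge
  r <- root_at(s, p)
  d <- ape::node.depth.edgelength(r)
  expect_equal(max(d[1:3][r$tip.label != "C"]), d[which(r$tip.label == "C")],
               tolerance = 1e-12)
})

test_that("midpoint balances the two deepest leaves on random trees", {
  set.seed(12)
  for (i in 1:100) {
    u <- random_unrooted_tree(sample(4:15, 1))
    m <- midpoint_root(u)
    r <- root_at(u, m$positions[[1]])
    d <- ape::node.depth.edgelength(r)[seq_along(r$tip.label)]
    root <- length(r$tip.label) + 1L
    kids <- r$edge[r$edge[, 1] == root, 2]
    below <- rootbench:::descendant_tips(r)
    side1 <- max(d[below[[kids[1]]]])
    side2 <- max(d[below[[kids[2]]]])
    expect_equal(side1, side2, tolerance = 1e-9)
    expect_equal(max(d), m$score, tolerance = 1e-9)
  }
})

test_that("all-zero branch lengths make every edge a midpoint tie", {
  u <- parse_newick("(A:0,B:0,(C:0,D:0):0);")
  m <- midpoint_root(u)
  expect_equal(m$score, 0)
  expect_equal(m$tie_count, nrow(u$edge))
})

test_that("clock-like trees are rooted exactly by all branch-length methods", {
  set.seed(19)
  for (i in 1:20) {
    rt <- ape::rcoal(sample(5:25, 1))
    rt$tip.label <- paste0("s", seq_along(rt$tip.label))
    u <- unroot_tree(rt)
    for (fn in list(mad_root, mv_root)) {
      res <- fn(u)
      expect_lt(res$score, 1e-6)   # zero deviation/variance at the true root
      expect_equal(rf_rooted(pick_rooting(res, u), rt), 0)
    }
    expect_equal(rf_rooted(pick_rooting(midpoint_root(u), u), rt), 0)
  }
})

test_that("MAD matches a frozen grid-search fixture on a clock-violating tree", {
  u <- parse_newick("(A:1,B:3,(C:2,D:0.5):2);")
  m <- mad_root(u)
  # frozen from a 1e-5-step direct grid search over all edges
  expect_equal(m$score, 0.3732319179, tolerance = 1e-8)
  expect_equal(m$tie_count, 1L)
  expect_equal(sort(m$positions[[1]]$edge), c(5, 6))   # the internal edge
  expect_equal(m$positions[[1]]$fraction, 0.35169916, tolerance = 1e-6)
})

test_that("MAD and MV closed forms match dense grid search", {
  set.seed(77)
  for (i in 1:12) {
    u <- random_unrooted_tree(sample(5:8, 1))
    gm <- grid_search_mad(u, step = 1e-3)
    m <- mad_root(u)
    expect_equal(m$score, gm$score, tolerance = 1e-5)
    gv <- grid_search_mv(u, step = 1e-3)
    v <- mv_root(u)
    expect_equal(v$score, gv$score, tolerance = 1e-5)
  }
})

test_that("MV reports symmetric ties on a uniform star", {
  u <- parse_newick("(A:1,B:1,C:1);")
  v <- mv_root(u)
  expect_lt(v$score, 1e-12)            # variance 0 at the hub
  expect_equal(v$tie_count, 3L)        # reachable from all three edges
})

test_that("random rooting is seeded and uniform over edges", {
  u <- random_unrooted_tree(3)
  expect_identical(random_root(u, seed = 5)$positions[[1]]$edge_row,
                   random_root(u, seed = 5)$positions[[1]]$edge_row)
  draws <- vapply(1:3000, function(s)
    random_root(u, seed = s)$positions[[1]]$edge_row, integer(1))
  expect_setequal(unique(draws), 1:3)
  p <- chisq.test(table(draws))$p.value
  expect_gt(p, 0.01)
})

test_that("MAD skips coincident leaf pairs with a warning", {
  u <- parse_newick("((A:0,B:0):1,C:2,D:1);")
  expect_warning(res <- mad_root(u), "zero distance")
  expect_s3_class(res, "rooting_result")
})
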
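# random tree fixtures (built in code) and independent scoring oracles

random_rooted_tree <- function(n, min_len = 0.1, max_len = 2) {
  tr <- ape::rtree(n)
  tr$edge.length <- stats::runif(nrow(tr$edge), min_len, max_len)
  tr
}

random_unrooted_tree <- function(n, min_len = 0.1, max_len = 2) {
  unroot_tree(random_rooted_tree(n, min_len, max_len))
}

trees_isomorphic <- function(t1, t2) {
  isTRUE(ape::all.equal.phylo(t1, t2, use.edge.length = TRUE))
}

# dense grid evaluation of the MAD score: for each edge, the score at every
# grid point is computed directly from the pair-deviation definition
grid_search_mad <- function(tree, step = 1e-4) {
  n <- length(tree$tip.label)
  D <- ape::dist.nodes(tree)
  below <- rootbench:::descendant_tips(tree)
  rhos <- seq(0, 1, by = step)
  best <- Inf; best_edge <- NA
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  for (i in seq_len(nrow(tree$edge))) {
    s <- rootbench:::edge_sides(tree, i, below)
    dbc <- D[cbind(pairs[, 1L], pairs[, 2L])]
    keep <- dbc > 0
    # d(alpha, b) at rho = 0 plus its slope in rho, from the path definition
    dab0 <- numeric(nrow(pairs)); slope <- numeric(nrow(pairs))
    for (k in seq_len(nrow(pairs))) {
      b <- pairs[k, 1L]; c2 <- pairs[k, 2L]
      inA_b <- b %in% s$aside; inA_c <- c2 %in% s$aside
      if (inA_b != inA_c) {
        bb <- if (inA_b) b else c2
        dab0[k] <- D[s$a, bb]; slope[k] <- s$len
      } else if (inA_b) {
        dab0[k] <- (D[s$a, b] + D[b, c2] - D[s$a, c2]) / 2
      } else {
        dab0[k] <- (D[s$b, b] + D[b, c2] - D[s$b, c2]) / 2
      }
    }
    dev2 <- (2 * outer(dab0[keep], rep(1, length(rhos))) +
               2 * outer(slope[keep], rhos)) / dbc[keep] - 1
    sc <- sqrt(colMeans(dev2^2))
    m <- min(sc)
    if (m < best) { best <- m; best_edge <- i }
  }
  list(score = best, edge = best_edge)
}

# dense grid evaluation of the root-to-leaf distance variance
grid_search_mv <- function(tree, step = 1e-4) {
  n <- length(tree$tip.label)
  D <- ape::dist.nodes(tree)
  below <- rootbench:::descendant_tips(tree)
  best <- Inf; best_edge <- NA
  for (i in seq_len(nrow(tree$edge))) {
    s <- rootbench:::edge_sides(tree, i, below)
    ys <- seq(0, s$len, length.out = max(2L, ceiling(1 / step) + 1L))
    base <- numeric(n); sgn <- numeric(n)
    base[s$aside] <- D[s$a, s$aside]; sgn[s$aside] <- 1
    base[s$bside] <- D[s$b, s$bside] + s$len; sgn[s$bside] <- -1
    dmat <- outer(base, rep(1, length(ys))) + outer(sgn, ys)
    v <- colMeans(dmat^2) - colMeans(dmat)^2
    m <- min(v)
    if (m < best) { best <- m; best_edge <- i }
  }
  list(score = best, edge = best_edge)
}

# definitional DTL recursion with explicit enumeration over species-node
# placements (independent of the in/out-table dynamic program)
dtl_brute_force <- function(gtree, stree, mapping, costs) {
  ns <- length(stree$tip.label); ms <- ns + stree$Nnode
  kids <- lapply(seq_len(ms), function(v) stree$edge[stree$edge[, 1L] == v, 2L])
  getdesc <- function(v) {
    if (!length(kids[[v]])) return(v)
    c(v, unlist(lapply(kids[[v]], getdesc)))
  }
  desc <- lapply(seq_len(ms), getdesc)
  par_of <- function(v) {
    p <- stree$edge[stree$edge[, 2L] == v, 1L]
    if (length(p)) p else NA_integer_
  }
  depth_below <- function(s, x) {
    d <- 0L; cur <- x
    while (cur != s) { cur <- par_of(cur); d <- d + 1L }
    d
  }
  Dmat <- matrix(NA_real_, ms, ms)
  for (s in seq_len(ms)) for (x in desc[[s]]) Dmat[s, x] <- depth_below(s, x)
  ancestors <- function(s) {
    a <- s
    repeat { p <- par_of(a[length(a)]); if (is.na(p)) break; a <- c(a, p) }
    a
  }
  incomp <- lapply(seq_len(ms), function(s)
    setdiff(seq_len(ms), union(ancestors(s), desc[[s]])))
  ng <- length(gtree$tip.label); mg <- ng + gtree$Nnode
  gkids <- lapply(seq_len(mg), function(v) gtree$edge[gtree$edge[, 1L] == v, 2L])
  smap <- match(mapping[gtree$tip.label], stree$tip.label)
  L <- costs[1L]; Dc <- costs[2L]; Tc <- costs[3L]
  memo <- matrix(NA_real_, mg, ms)
  cost <- function(g, s) {
    if (!is.na(memo[g, s])) return(memo[g, s])
    if (!length(gkids[[g]])) {
      v <- if (smap[g] == s) 0 else Inf
      memo[g, s] <<- v; return(v)
    }
    g1 <- gkids[[g]][1L]; g2 <- gkids[[g]][2L]
    best <- Inf
    if (length(kids[[s]]) == 2L) {
      sl <- kids[[s]][1L]; sr <- kids[[s]][2L]
      for (x in desc[[sl]]) for (y in desc[[sr]])
        best <- min(best,
                    cost(g1, x) + L * Dmat[sl, x] + cost(g2, y) + L * Dmat[sr, y],
                    cost(g2, x) + L * Dmat[sl, x] + cost(g1, y) + L * Dmat[sr, y])
    }
    for (x in desc[[s]]) for (y in desc[[s]])
      best <- min(best, Dc + cost(g1, x) + L * Dmat[s, x] +
                          cost(g2, y) + L * Dmat[s, y])
    for (x in desc[[s]]) for (y in incomp[[s]])
      best <- min(best, Tc + cost(g1, x) + L * Dmat[s, x] + cost(g2, y),
                        Tc + cost(g2, x) + L * Dmat[s, x] + cost(g1, y))
    memo[g, s] <<- best
    best
  }
  min(vapply(seq_len(ms), function(s) cost(ng + 1L, s), numeric(1)))
}

# random small DTL instance: species tree + gene tree with leaves mapped to
# random species
random_dtl_instance <- function(max_species = 5, max_gene_leaves = 6) {
  ns <- sample(2:max_species, 1L)
  ng <- sample(3:max_gene_leaves, 1L)
  st <- ape::rtree(ns); st$tip.label <- paste0("S", seq_len(ns))
  gt <- ape::rtree(ng)
  sp <- sample(st$tip.label, ng, replace = TRUE)
  gt$tip.label <- paste0(sp, "_", seq_len(ng))
  list(gtree = gt, stree = st, mapping = stats::setNames(sp, gt$tip.label))
}
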
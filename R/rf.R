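# Robinson-Foulds machinery: rooted (clade-set) RF, unrooted (bipartition) RF,
# and the root-path distance that links RF between alternative rootings of one
# unrooted tree to the number of intermediate nodes between the two root edges.

# sorted tip-label key for a set of tip ids
tipset_key <- function(labels, ids) paste(sort(labels[ids]), collapse = "\r")

# list of tip-id vectors below every node (tips included), indexed by node id
descendant_tips <- function(phy) {
  n <- n_tips(phy); m <- n_nodes(phy)
  phy <- ape::reorder.phylo(phy, "postorder")
  below <- vector("list", m)
  for (i in seq_len(n)) below[[i]] <- i
  e <- phy$edge
  for (i in seq_len(nrow(e))) {
    p <- e[i, 1L]; ch <- e[i, 2L]
    below[[p]] <- c(below[[p]], below[[ch]])
  }
  below
}

# clade keys of a rooted tree: one per internal node (root included);
# trivial single-leaf clades are excluded
clade_keys <- function(phy) {
  n <- n_tips(phy)
  below <- descendant_tips(phy)
  vapply((n + 1L):n_nodes(phy), function(v) tipset_key(phy$tip.label, below[[v]]),
         character(1))
}

# nontrivial bipartition keys of an unrooted tree; each split keyed by the
# side not containing the lexicographically smallest label
bipartition_keys <- function(phy) {
  n <- n_tips(phy)
  below <- descendant_tips(phy)
  ref <- order(phy$tip.label)[1L]  # tip id carrying the smallest label
  keys <- character(0)
  e <- phy$edge
  for (i in seq_len(nrow(e))) {
    ch <- e[i, 2L]
    if (ch <= n) next                      # pendant edge: trivial split
    side <- below[[ch]]
    if (ref %in% side) side <- setdiff(seq_len(n), side)
    if (length(side) < 2L || length(side) > n - 2L) next
    keys <- c(keys, tipset_key(phy$tip.label, side))
  }
  unique(keys)
}

check_same_leafset <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label))
    stop("trees have different leaf sets")
}

#' Rooted Robinson-Foulds distance
#'
#' Half the size of the symmetric difference between the clade sets of two
#' rooted trees on the same leaves, where a clade is the leaf set below an
#' internal node. Zero exactly when the rooted topologies agree. For two
#' rootings of the same unrooted tree this equals the number of intermediate
#' nodes on the path between the two root edges (see
#' [root_path_distance()]).
#'
#' @param t1,t2 rooted binary trees with identical leaf sets.
#' @return a nonnegative number (integer-valued).
#' @export
rf_rooted <- function(t1, t2) {
  validate_rooted_tree(t1); validate_rooted_tree(t2)
  check_same_leafset(t1, t2)
  k1 <- clade_keys(t1); k2 <- clade_keys(t2)
  (sum(!(k1 %in% k2)) + sum(!(k2 %in% k1))) / 2
}

#' Unrooted Robinson-Foulds distance
#'
#' Half the symmetric-difference count over nontrivial bipartitions. Rooted
#' input is unrooted first, so the distance depends only on the unrooted
#' topologies.
#'
#' @param t1,t2 trees (rooted or unrooted) with identical leaf sets.
#' @return a nonnegative number (integer-valued).
#' @export
rf_unrooted <- function(t1, t2) {
  t1 <- unroot_tree(t1); t2 <- unroot_tree(t2)
  check_same_leafset(t1, t2)
  k1 <- bipartition_keys(t1); k2 <- bipartition_keys(t2)
  (sum(!(k1 %in% k2)) + sum(!(k2 %in% k1))) / 2
}

#' Distance between two root edges of an unrooted tree
#'
#' Counts the internal nodes strictly between two edges, i.e. on the path
#' connecting their farthest endpoints, excluding the endpoints of the edges
#' themselves. Rooting the tree on the two edges yields rooted trees whose
#' rooted RF distance equals exactly this count; the equivalence is the basis
#' for measuring rooting error in RF units.
#'
#' @param tree an unrooted tree.
#' @param e1,e2 edges of `tree` as unordered node pairs.
#' @return a nonnegative integer; 0 iff `e1` and `e2` are the same edge.
#' @export
root_path_distance <- function(tree, e1, e2) {
  validate_unrooted_tree(tree)
  i1 <- edge_row(tree, e1); i2 <- edge_row(tree, e2)
  if (i1 == i2) return(0L)
  adj <- adjacency_list(tree)
  # BFS hop counts from a source node
  hops_from <- function(src) {
    d <- rep(NA_integer_, n_nodes(tree)); d[src] <- 0L
    queue <- src
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      for (nb in adj$nbr[[v]]) if (is.na(d[nb])) {
        d[nb] <- d[v] + 1L; queue <- c(queue, nb)
      }
    }
    d
  }
  u <- sort(as.integer(e1)); v <- sort(as.integer(e2))
  du1 <- hops_from(u[1L]); du2 <- hops_from(u[2L])
  longest <- max(du1[v[1L]], du1[v[2L]], du2[v[1L]], du2[v[2L]])
  longest - 1L
}
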
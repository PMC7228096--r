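#' @useDynLib rootbench, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# ---- internal helpers -------------------------------------------------------

n_tips <- function(phy) length(phy$tip.label)

# all node ids: tips 1..n, internals n+1..n+Nnode
n_nodes <- function(phy) n_tips(phy) + phy$Nnode

# neighbor lists of the (undirected) tree graph: for each node a matrix-free
# list with integer vectors $nbr and $edge (row index into phy$edge)
adjacency_list <- function(phy) {
  m <- n_nodes(phy)
  e <- phy$edge
  nbr <- vector("list", m)
  erow <- vector("list", m)
  for (i in seq_len(nrow(e))) {
    a <- e[i, 1L]; b <- e[i, 2L]
    nbr[[a]] <- c(nbr[[a]], b); erow[[a]] <- c(erow[[a]], i)
    nbr[[b]] <- c(nbr[[b]], a); erow[[b]] <- c(erow[[b]], i)
  }
  list(nbr = nbr, edge = erow)
}

# row of phy$edge holding the unordered node pair `edge`; error if absent
edge_row <- function(phy, edge) {
  edge <- as.integer(edge)
  if (length(edge) != 2L || anyNA(edge))
    stop("an edge must be an unordered pair of node ids")
  e <- phy$edge
  hit <- which((e[, 1L] == edge[1L] & e[, 2L] == edge[2L]) |
               (e[, 1L] == edge[2L] & e[, 2L] == edge[1L]))
  if (length(hit) != 1L)
    stop("edge (", edge[1L], ",", edge[2L], ") is not an edge of the tree")
  hit
}

node_degrees <- function(phy) {
  tabulate(c(phy$edge[, 1L], phy$edge[, 2L]), nbins = n_nodes(phy))
}

# ---- validation -------------------------------------------------------------

#' Test or assert tree validity
#'
#' A *rooted* tree here is a binary rooted `phylo`: every internal node,
#' including the root, has exactly two children. An *unrooted* tree is the
#' unrooted form of such a tree: stored with a basal trifurcation, every
#' internal node of the underlying graph has degree three. Both require unique
#' leaf labels and nonnegative branch lengths; zero-length branches are
#' allowed.
#'
#' @param phy a `phylo` object.
#' @return `is_rooted_tree()`/`is_unrooted_tree()` return a logical scalar;
#'   the `validate_*` variants return `phy` invisibly or raise an error
#'   describing the violated invariant.
#' @export
is_rooted_tree <- function(phy) {
  inherits(phy, "phylo") && ape::is.rooted(phy) && ape::is.binary(phy)
}

#' @rdname is_rooted_tree
#' @export
is_unrooted_tree <- function(phy) {
  if (!inherits(phy, "phylo") || ape::is.rooted(phy)) return(FALSE)
  deg <- node_degrees(phy)
  n <- n_tips(phy)
  n >= 3L && all(deg[seq_len(n)] == 1L) && all(deg[-seq_len(n)] == 3L)
}

validate_lengths_labels <- function(phy) {
  if (is.null(phy$edge.length))
    stop("tree has no branch lengths")
  if (anyNA(phy$edge.length) || any(phy$edge.length < 0))
    stop("branch lengths must be nonnegative reals")
  if (anyDuplicated(phy$tip.label))
    stop("duplicate leaf labels: ",
         paste(unique(phy$tip.label[duplicated(phy$tip.label)]), collapse = ", "))
  invisible(phy)
}

#' @rdname is_rooted_tree
#' @export
validate_rooted_tree <- function(phy) {
  if (!inherits(phy, "phylo")) stop("not a phylo object")
  if (!ape::is.rooted(phy)) stop("tree is not rooted (basal node is not bifurcating)")
  if (!ape::is.binary(phy)) stop("rooted tree must be binary (no multifurcations)")
  validate_lengths_labels(phy)
}

#' @rdname is_rooted_tree
#' @export
validate_unrooted_tree <- function(phy) {
  if (!inherits(phy, "phylo")) stop("not a phylo object")
  if (n_tips(phy) < 3L) stop("an unrooted tree needs at least 3 leaves")
  if (ape::is.rooted(phy)) stop("tree is rooted; expected a basal trifurcation")
  deg <- node_degrees(phy)
  internal <- (n_tips(phy) + 1L):n_nodes(phy)
  if (any(deg[internal] != 3L))
    stop("multifurcation: internal nodes of an unrooted binary tree must have degree 3")
  validate_lengths_labels(phy)
}

# ---- newick I/O -------------------------------------------------------------

#' Read a newick string
#'
#' Parses a single newick tree. A basal bifurcation is returned as a rooted
#' binary tree; a basal trifurcation as an unrooted tree. Branch lengths
#' missing from the string default to 1, so topology-only inputs (as consumed
#' by DTL rooting) parse cleanly. Multifurcations other than the basal
#' trifurcation of an unrooted tree are rejected, as are duplicate leaf
#' labels.
#'
#' @param text a newick string (quoted labels supported; no comments).
#' @param rooted_hint optional logical; if given, the parsed tree must be of
#'   the stated rootedness or an error is raised.
#' @return a `phylo` object passing [validate_rooted_tree()] or
#'   [validate_unrooted_tree()].
#' @examples
#' parse_newick("((A:1,B:1):1,C:2);")  # rooted
#' parse_newick("(A:1,B:1,C:2);")      # unrooted
#' @export
parse_newick <- function(text, rooted_hint = NULL) {
  stopifnot(is.character(text), length(text) == 1L)
  open <- gregexpr("(", text, fixed = TRUE)[[1L]]
  close <- gregexpr(")", text, fixed = TRUE)[[1L]]
  n_open <- sum(open > 0L); n_close <- sum(close > 0L)
  if (n_open != n_close) {
    at <- if (n_open > n_close) open[n_close + 1L] else close[n_open + 1L]
    stop("malformed newick: unbalanced parenthesis at character offset ", at)
  }
  phy <- tryCatch(ape::read.tree(text = text),
                  error = function(e) NULL, warning = function(w) NULL)
  if (is.null(phy) || !inherits(phy, "phylo"))
    stop("malformed newick string (offset unknown): ", substr(text, 1L, 60L))
  if (is.null(phy$edge.length)) {
    phy$edge.length <- rep(1, nrow(phy$edge))
  } else {
    phy$edge.length[is.na(phy$edge.length)] <- 1
  }
  rooted <- ape::is.rooted(phy)
  if (!is.null(rooted_hint) && rooted != rooted_hint)
    stop("tree is ", if (rooted) "rooted" else "unrooted",
         " but rooted_hint = ", rooted_hint)
  if (rooted) validate_rooted_tree(phy) else validate_unrooted_tree(phy)
  phy
}

#' Write a tree as a newick string
#'
#' Round-trips through [parse_newick()]: rooted trees are written with a basal
#' bifurcation, unrooted trees with a basal trifurcation.
#'
#' @param phy a valid rooted or unrooted tree.
#' @return a newick string.
#' @export
write_newick <- function(phy) {
  stopifnot(inherits(phy, "phylo"))
  ape::write.tree(phy)
}

# ---- root positions ---------------------------------------------------------

#' Construct a root position on an unrooted tree
#'
#' A root position names an edge of an unrooted tree (an unordered node pair)
#' and a fraction in (0, 1) locating the root along that edge. The fraction is
#' measured from the endpoint with the smaller node id, a fixed convention so
#' positions serialize deterministically. Topology-only methods (DTL, random
#' rooting) set `topology_only = TRUE`; their fraction is conventional.
#'
#' @param tree the unrooted tree the position refers to.
#' @param edge an unordered pair of node ids forming an edge of `tree`.
#' @param fraction position along the edge in (0, 1), measured from the
#'   smaller-id endpoint.
#' @param topology_only logical; `TRUE` when the fraction carries no metric
#'   meaning.
#' @return an object of class `root_position` with fields `edge` (sorted node
#'   pair), `edge_row` (row of `tree$edge`), `fraction`, `topology_only`.
#' @export
root_position <- function(tree, edge, fraction = 0.5, topology_only = FALSE) {
  validate_unrooted_tree(tree)
  i <- edge_row(tree, edge)
  edge <- sort(as.integer(edge))
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      !(fraction > 0 && fraction < 1))
    stop("fraction must lie strictly inside (0, 1)")
  structure(list(edge = edge, edge_row = i, fraction = fraction,
                 topology_only = isTRUE(topology_only)),
            class = "root_position")
}

#' @export
print.root_position <- function(x, ...) {
  cat(sprintf("root position: edge (%d,%d), fraction %.6g%s\n",
              x$edge[1L], x$edge[2L], x$fraction,
              if (x$topology_only) " [topology only]" else ""))
  invisible(x)
}

as_root_position <- function(tree, pos) {
  if (inherits(pos, "root_position")) {
    # re-resolve against this tree so stale positions error out
    root_position(tree, pos$edge, pos$fraction, pos$topology_only)
  } else if (is.numeric(pos) && length(pos) == 2L) {
    root_position(tree, pos)
  } else stop("pos must be a root_position or a node pair")
}

# ---- rerooting --------------------------------------------------------------

#' Root an unrooted tree at a point on an edge
#'
#' Introduces a new root node subdividing the chosen edge: the two daughter
#' branches carry `fraction * len` (toward the smaller-id endpoint) and
#' `(1 - fraction) * len` of the original edge length `len`. All other branch
#' lengths, and the leaf set, are unchanged.
#'
#' @param tree an unrooted tree.
#' @param pos a [root_position()] on `tree` (or a node pair, rooted at its
#'   midpoint).
#' @return a rooted binary tree.
#' @export
root_at <- function(tree, pos) {
  validate_unrooted_tree(tree)
  pos <- as_root_position(tree, pos)
  n <- n_tips(tree)
  adj <- adjacency_list(tree)
  a <- pos$edge[1L]; b <- pos$edge[2L]
  len <- tree$edge.length[pos$edge_row]

  m_new <- n_nodes(tree) + 1L           # nodes incl. the new root
  new_id <- integer(m_new)              # old id (0 = virtual root) -> new id
  # tips keep their ids; internals renumbered in preorder, root first
  next_internal <- n + 1L
  assign_id <- function(old) {
    if (old <= n) return(old)
    id <- next_internal; next_internal <<- next_internal + 1L
    id
  }
  root_new <- n + 1L; next_internal <- n + 2L

  parent <- integer(0); child <- integer(0); blen <- numeric(0)
  # stack entries: old node, its new id already assigned? we assign on push
  push <- function(old, from_old, new_parent, length) {
    id <- assign_id(old)
    parent <<- c(parent, new_parent); child <<- c(child, id); blen <<- c(blen, length)
    list(old = old, from = from_old, new = id)
  }
  stack <- list(push(a, -1L, root_new, pos$fraction * len),
                push(b, -2L, root_new, (1 - pos$fraction) * len))
  # mark so DFS from a does not cross the split edge to b and vice versa
  stack[[1L]]$from <- b; stack[[2L]]$from <- a
  while (length(stack)) {
    top <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    nbrs <- adj$nbr[[top$old]]; erows <- adj$edge[[top$old]]
    for (k in seq_along(nbrs)) {
      nb <- nbrs[k]
      if (nb == top$from) next
      # skip the split edge itself (relevant only at a and b)
      if ((top$old == a && nb == b) || (top$old == b && nb == a)) next
      stack[[length(stack) + 1L]] <-
        push(nb, top$old, top$new, tree$edge.length[erows[k]])
    }
  }
  out <- list(edge = cbind(parent, child, deparse.level = 0),
              edge.length = blen,
              Nnode = tree$Nnode + 1L,
              tip.label = tree$tip.label)
  class(out) <- "phylo"
  out <- ape::reorder.phylo(out, "cladewise")
  validate_rooted_tree(out)
}

#' Remove the root of a rooted tree
#'
#' Suppresses the root node and merges its two incident branches into a single
#' edge, yielding the unrooted form. Unrooted input is returned unchanged
#' (the operation is idempotent).
#'
#' @param tree a rooted binary tree with at least 3 leaves, or an unrooted
#'   tree.
#' @return an unrooted tree.
#' @export
unroot_tree <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.rooted(tree)) return(validate_unrooted_tree(tree))
  if (n_tips(tree) < 3L) stop("cannot unroot a tree with fewer than 3 leaves")
  validate_rooted_tree(tree)
  validate_unrooted_tree(ape::unroot(tree))
}
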
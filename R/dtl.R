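# Parsimonious DTL reconciliation and DTL rooting. The species tree is used
# as an undated topology: a transfer may move a lineage to any species node
# incomparable to the donor (neither ancestor nor descendant), and one loss is
# charged per species edge a surviving lineage skips over. Branch lengths of
# both trees are ignored.

#' DTL event costs
#'
#' Unit costs for losses, duplications, and transfers used by parsimonious
#' DTL reconciliation. The defaults, 1/2/3, are the costs commonly used for
#' DTL parsimony; higher transfer costs (e.g. 4 or 5) are worth sweeping, as
#' rooting accuracy tends to improve with them.
#'
#' @param loss,duplication,transfer nonnegative unit costs.
#' @return an `event_costs` object.
#' @export
event_costs <- function(loss = 1, duplication = 2, transfer = 3) {
  v <- c(loss = loss, duplication = duplication, transfer = transfer)
  if (any(!is.finite(v)) || any(v < 0)) stop("event costs must be nonnegative")
  structure(as.list(v), class = "event_costs")
}

#' @export
print.event_costs <- function(x, ...) {
  cat(sprintf("DTL event costs <loss %g, duplication %g, transfer %g>\n",
              x$loss, x$duplication, x$transfer))
  invisible(x)
}

as_event_costs <- function(costs) {
  if (inherits(costs, "event_costs")) return(costs)
  if (is.numeric(costs) && length(costs) == 3L)
    return(event_costs(costs[1L], costs[2L], costs[3L]))
  stop("costs must be an event_costs object or a numeric <loss, dup, transfer>")
}

# 0-based left/right child arrays of a rooted binary phylo, root index
rooted_arrays <- function(phy) {
  m <- n_nodes(phy)
  left <- rep(-1L, m); right <- rep(-1L, m)
  e <- phy$edge
  for (i in seq_len(nrow(e))) {
    p <- e[i, 1L]
    if (left[p] == -1L) left[p] <- e[i, 2L] - 1L else right[p] <- e[i, 2L] - 1L
  }
  root <- n_tips(phy) + 1L
  po <- ape::reorder.phylo(phy, "postorder")$edge
  post <- c(po[, 2L], root) - 1L         # children in postorder, then root
  list(left = left, right = right, root = root - 1L, post = post)
}

#' Resolve the gene-leaf to species-leaf mapping
#'
#' By default gene leaves are named `<species>_<copy>` and the species is
#' recovered by stripping the final underscore-number suffix. Alternatively an
#' explicit mapping may be given as a named character vector
#' (`names` = gene leaves) or a two-column data frame / TSV file
#' (gene leaf, species leaf).
#'
#' @param gtree a gene tree (rooted or unrooted).
#' @param stree the species tree.
#' @param mapping `NULL` for the naming convention, a named character vector,
#'   a two-column data frame, or the path of a two-column TSV file.
#' @return a named character vector mapping every gene leaf to a species leaf.
#' @export
leaf_species_map <- function(gtree, stree, mapping = NULL) {
  tips <- gtree$tip.label
  if (is.null(mapping)) {
    sp <- sub("_[0-9]+$", "", tips)
    names(sp) <- tips
  } else {
    if (is.character(mapping) && length(mapping) == 1L && file.exists(mapping))
      mapping <- utils::read.table(mapping, sep = "\t", header = FALSE,
                                   col.names = c("gene", "species"),
                                   colClasses = "character")
    if (is.data.frame(mapping)) {
      sp <- as.character(mapping[[2L]]); names(sp) <- as.character(mapping[[1L]])
    } else if (is.character(mapping) && !is.null(names(mapping))) {
      sp <- mapping
    } else stop("mapping must be a named vector, two-column table, or TSV path")
    if (!all(tips %in% names(sp)))
      stop("unmapped gene leaves: ",
           paste(setdiff(tips, names(sp)), collapse = ", "))
    sp <- sp[tips]
  }
  bad <- !(sp %in% stree$tip.label)
  if (any(bad))
    stop("gene leaves map to unknown species: ",
         paste(unique(sp[bad]), collapse = ", "))
  sp
}

#' Minimum DTL reconciliation cost of a rooted gene tree
#'
#' Computes, by dynamic programming over (gene node, species node) states, the
#' minimum total cost over all DTL reconciliations of the rooted gene tree
#' with the (undated) rooted species tree: each duplication, transfer, and
#' loss is charged its unit cost; speciations are free. Both trees are used as
#' topologies only.
#'
#' @param gtree a rooted binary gene tree.
#' @param stree a rooted binary species tree.
#' @param mapping see [leaf_species_map()].
#' @param costs an [event_costs()] object or numeric `<loss, dup, transfer>`.
#' @return the minimum reconciliation cost (a nonnegative number; exact
#'   integer arithmetic when all unit costs are integers).
#' @export
dtl_reconciliation_cost <- function(gtree, stree, mapping = NULL,
                                    costs = event_costs()) {
  validate_rooted_tree(gtree); validate_rooted_tree(stree)
  costs <- as_event_costs(costs)
  sp <- leaf_species_map(gtree, stree, mapping)
  sarr <- rooted_arrays(stree)
  garr <- rooted_arrays(gtree)
  gmap <- rep(-1L, n_nodes(gtree))
  gmap[seq_len(n_tips(gtree))] <- match(sp, stree$tip.label) - 1L
  cpp_dtl_cost(garr$left, garr$right, garr$post, gmap,
               sarr$left, sarr$right, sarr$root,
               costs$loss, costs$duplication, costs$transfer)
}

#' DTL rooting of an unrooted gene tree
#'
#' Roots the gene tree on each of its edges in turn, computes the minimum DTL
#' reconciliation cost of every rooting against the undated species tree, and
#' returns all cost-minimizing edges. Each edge's cost is an independent
#' recomputation, so the per-edge costs equal single-rooting calls to
#' [dtl_reconciliation_cost()].
#'
#' @inheritParams dtl_reconciliation_cost
#' @param gtree an unrooted gene tree (branch lengths ignored).
#' @return a `rooting_result` with topology-only positions; `score` is the
#'   minimum cost and `edge_scores` the per-edge costs.
#' @export
dtl_root <- function(gtree, stree, mapping = NULL, costs = event_costs()) {
  validate_unrooted_tree(gtree); validate_rooted_tree(stree)
  costs <- as_event_costs(costs)
  sp <- leaf_species_map(gtree, stree, mapping)
  sarr <- rooted_arrays(stree)
  leaf_map <- match(sp, stree$tip.label) - 1L
  edges0 <- gtree$edge - 1L
  storage.mode(edges0) <- "integer"
  cost_vec <- cpp_dtl_all_rootings(edges0, n_tips(gtree), leaf_map,
                                   sarr$left, sarr$right, sarr$root,
                                   costs$loss, costs$duplication,
                                   costs$transfer)
  best <- min(cost_vec)
  opt <- which(cost_vec <= best + SCORE_TIE_RTOL * max(1, abs(best)))
  positions <- lapply(opt, function(i)
    root_position(gtree, gtree$edge[i, ], 0.5, topology_only = TRUE))
  edge_scores <- data.frame(edge_row = seq_along(cost_vec),
                            node1 = gtree$edge[, 1L], node2 = gtree$edge[, 2L],
                            score = cost_vec,
                            is_optimal = seq_along(cost_vec) %in% opt)
  new_rooting_result("dtl", positions, best, edge_scores)
}
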
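# Synthetic-data stage: birth-death species trees (ultrametric, height 1),
# gene families evolving inside them under duplication, additive/replacing
# horizontal transfer, and loss, branch-scaling schemes emulating
# substitution-rate variation, and an NNI perturbation utility standing in
# for phylogenetic reconstruction error.

#' Deterministic seed derivation
#'
#' Folds an arbitrary sequence of tokens (collection names, set and family
#' indices, a master seed) into a positive integer below 2^31, so every
#' simulated family is independently reproducible from the master seed.
#'
#' @param ... tokens coerced to character.
#' @return a positive integer scalar.
#' @export
derive_seed <- function(...) {
  tokens <- unlist(lapply(list(...), as.character))
  h <- 0
  for (tok in tokens) for (b in utf8ToInt(tok)) h <- (h * 131 + b) %% 2147480009
  as.integer(h) + 1L
}

#' Event-rate settings for gene family simulation
#'
#' Rates are expected numbers of events per unit branch length on the species
#' tree (whose height is 1). The loss rate is derived, not free:
#' `0.8 * (duplication + additive_fraction * transfer)`, which models slowly
#' expanding gene families. `additive_fraction` is the probability that a
#' transfer is additive (adds a copy) rather than replacing (displaces a
#' resident copy, which is simultaneously lost).
#'
#' @param duplication duplication rate (events per unit branch length).
#' @param transfer total transfer rate.
#' @param additive_fraction probability a transfer is additive, in `[0, 1]`;
#'   0.3 reproduces the 3:7 additive:replacing ratio, 1 makes all transfers
#'   additive.
#' @return an `event_rates` object with the derived `loss` rate.
#' @export
event_rates <- function(duplication, transfer, additive_fraction = 0.3) {
  stopifnot(duplication >= 0, transfer >= 0,
            additive_fraction >= 0, additive_fraction <= 1)
  structure(list(duplication = duplication, transfer = transfer,
                 additive_fraction = additive_fraction,
                 loss = 0.8 * (duplication + additive_fraction * transfer)),
            class = "event_rates")
}

#' @export
print.event_rates <- function(x, ...) {
  cat(sprintf(
    "event rates: dup %g, transfer %g (additive fraction %g), loss %g\n",
    x$duplication, x$transfer, x$additive_fraction, x$loss))
  invisible(x)
}

#' Named event-rate presets
#'
#' The study grid: `low` (dup 0.13, transfer 0.27), `medium` (0.3, 0.6),
#' `high` (0.6, 1.2), and the very-high-transfer settings `very_high_2/3/4`
#' (dup 0.6, transfer 2/3/4). All use the derived loss rate.
#'
#' @param name one of `"low"`, `"medium"`, `"high"`, `"very_high_2"`,
#'   `"very_high_3"`, `"very_high_4"`.
#' @param additive_fraction see [event_rates()].
#' @return an `event_rates` object.
#' @export
rate_preset <- function(name, additive_fraction = 0.3) {
  par <- switch(name,
    low = c(0.13, 0.27), medium = c(0.3, 0.6), high = c(0.6, 1.2),
    very_high_2 = c(0.6, 2), very_high_3 = c(0.6, 3), very_high_4 = c(0.6, 4),
    stop("unknown rate preset: ", name))
  event_rates(par[1L], par[2L], additive_fraction)
}

#' Branch-scaling schemes
#'
#' `uniform` multiplies each branch by an independent Uniform(lo, hi) draw.
#' `autocorrelated` assigns each node a rate: the root gets `start_rate`, each
#' child's log-rate is a mean-preserving normal step around its parent's
#' (variance `sigma2 * branch duration` when `time_scaled`, else `sigma2` per
#' edge), and each branch is multiplied by its child's rate -- a relaxed
#' lognormal clock with rates autocorrelated along lineages. `none` leaves the
#' tree untouched.
#'
#' @param kind `"none"`, `"uniform"`, or `"autocorrelated"`.
#' @param lo,hi uniform bounds, `0 < lo <= hi`.
#' @param start_rate root rate of the autocorrelated process.
#' @param sigma2 variance parameter of the lognormal steps.
#' @param time_scaled logical; scale the step variance by branch duration
#'   (the default, matching the relaxed-clock model the scheme emulates) or
#'   use a constant variance per edge.
#' @return a `scaling_scheme` object.
#' @export
scaling_scheme <- function(kind = c("none", "uniform", "autocorrelated"),
                           lo = 0.3, hi = 3, start_rate = 1, sigma2 = 0.05,
                           time_scaled = TRUE) {
  kind <- match.arg(kind)
  if (kind == "uniform") stopifnot(lo > 0, hi >= lo)
  if (kind == "autocorrelated") stopifnot(start_rate > 0, sigma2 >= 0)
  structure(list(kind = kind, lo = lo, hi = hi, start_rate = start_rate,
                 sigma2 = sigma2, time_scaled = time_scaled),
            class = "scaling_scheme")
}

#' @rdname scaling_scheme
#' @param name preset name: `"none"`, `"uniform_0.3_3"`, `"uniform_0.2_5"`,
#'   `"auto_0.05"`, `"auto_0.25"`.
#' @export
scheme_preset <- function(name) {
  switch(name,
    none = scaling_scheme("none"),
    uniform_0.3_3 = scaling_scheme("uniform", lo = 0.3, hi = 3),
    uniform_0.2_5 = scaling_scheme("uniform", lo = 0.2, hi = 5),
    auto_0.05 = scaling_scheme("autocorrelated", sigma2 = 0.05),
    auto_0.25 = scaling_scheme("autocorrelated", sigma2 = 0.25),
    stop("unknown scaling scheme preset: ", name))
}

#' Simulate an ultrametric species tree
#'
#' Draws a birth-death tree conditioned on exactly `n` extant species
#' (extinct lineages pruned) and rescales it to height exactly 1, recording
#' node times (root 0, leaves 1). The stage on which gene families evolve and
#' the (undated) topology DTL rooting reconciles against.
#'
#' @param n number of extant species (>= 2).
#' @param birth,death per-lineage rates, `birth > death >= 0`. The defaults
#'   were calibrated once so that surviving event counts of simulated gene
#'   families match the study's reference table; see the package vignette.
#' @param seed integer seed; the same seed yields a byte-identical tree.
#' @return a `species_tree` object: `$phy` (rooted binary ultrametric
#'   `phylo`), `$times` (node times in [0, 1] indexed by node id).
#' @export
simulate_species_tree <- function(n = 100, birth = 3, death = 1, seed = 1) {
  stopifnot(n >= 2, birth > death, death >= 0)
  phy <- withr::with_seed(as.integer(seed),
                          ape::rphylo(n, birth, death, fossils = FALSE))
  depth <- ape::node.depth.edgelength(phy)
  h <- max(depth)
  phy$edge.length <- phy$edge.length / h
  times <- depth / h
  times[seq_len(n)] <- 1  # leaves exactly at the present
  validate_rooted_tree(phy)
  structure(list(phy = phy, times = times, n = n, birth = birth,
                 death = death, seed = as.integer(seed)),
            class = "species_tree")
}

#' @export
print.species_tree <- function(x, ...) {
  cat(sprintf("species tree: %d taxa, height 1, birth %g, death %g, seed %d\n",
              x$n, x$birth, x$death, x$seed))
  invisible(x)
}

# ---- gene family simulation -------------------------------------------------

#' Simulate one gene family inside a species tree
#'
#' A single gene lineage enters at the species root and evolves down the tree.
#' Along each species branch, events arrive as a Poisson process with total
#' rate duplication + transfer + loss (per unit branch length):
#' a duplication bifurcates the lineage in place, a loss terminates it, and a
#' transfer copies it onto a recipient species branch chosen uniformly among
#' the branches alive at the event time (donor excluded). With probability
#' `additive_fraction` the transfer is additive; otherwise it is replacing and
#' one uniformly chosen gene lineage resident in the recipient branch is
#' removed (with no resident the transfer degrades to additive, which is
#' logged). Lineages split at speciations and the sampled copies reach the
#' present at time 1. Extinct subtrees are then pruned and unary nodes
#' suppressed.
#'
#' @param stree a [simulate_species_tree()] result.
#' @param rates an [event_rates()] object.
#' @param seed integer seed.
#' @return a `gene_family_history`: `$tree` (rooted ultrametric gene tree,
#'   `NULL` if fewer than 2 copies survive), `$extinct` flag (fewer than 3
#'   leaves), `$leaf_map` (named vector gene leaf -> species), `$counts`
#'   (surviving event counts), `$events` (surviving event log),
#'   `$events_all` (full log), `$degraded` (replacing transfers degraded to
#'   additive).
#' @export
simulate_gene_history <- function(stree, rates, seed = 1) {
  stopifnot(inherits(stree, "species_tree"), inherits(rates, "event_rates"))
  withr::with_seed(as.integer(seed), sim_gene_history_impl(stree, rates, seed))
}

sim_gene_history_impl <- function(stree, rates, seed) {
  phy <- stree$phy; times <- stree$times
  nsp <- n_tips(phy)
  sedge <- phy$edge                      # species branches
  s_t0 <- times[sedge[, 1L]]; s_t1 <- times[sedge[, 2L]]
  child_edges <- lapply(seq_len(n_nodes(phy)), function(v) which(sedge[, 1L] == v))
  sroot <- nsp + 1L

  lambda <- rates$duplication + rates$transfer + rates$loss
  probs <- c(rates$duplication, rates$transfer, rates$loss)

  # gene nodes, appended as created (children always after parents)
  NN <- 256L
  n_type <- character(NN); n_time <- numeric(NN)
  n_parent <- integer(NN); n_kid1 <- integer(NN); n_kid2 <- integer(NN)
  n_species <- integer(NN)               # species tip for leaves
  n_flag <- character(NN)                # transfer kind
  n_count <- 0L
  grow <- function() {
    NN <<- NN * 2L
    length(n_type) <<- NN; length(n_time) <<- NN; length(n_parent) <<- NN
    length(n_kid1) <<- NN; length(n_kid2) <<- NN; length(n_species) <<- NN
    length(n_flag) <<- NN
  }
  new_node <- function(type, time, parent, species = 0L, flag = "") {
    n_count <<- n_count + 1L
    if (n_count > NN) grow()
    i <- n_count
    n_type[i] <<- type; n_time[i] <<- time; n_parent[i] <<- parent
    n_kid1[i] <<- 0L; n_kid2[i] <<- 0L; n_species[i] <<- species
    n_flag[i] <<- flag
    if (parent > 0L) {
      if (n_kid1[parent] == 0L) n_kid1[parent] <<- i else n_kid2[parent] <<- i
    }
    i
  }

  # active lineages
  LN <- 256L
  l_parent <- integer(LN); l_sedge <- integer(LN)
  l_next <- numeric(LN); l_arrive <- logical(LN); l_alive <- logical(LN)
  l_count <- 0L
  spawn <- function(parent_node, se, t) {
    l_count <<- l_count + 1L
    if (l_count > LN) {
      LN <<- LN * 2L
      length(l_parent) <<- LN; length(l_sedge) <<- LN; length(l_next) <<- LN
      length(l_arrive) <<- LN; length(l_alive) <<- LN
    }
    i <- l_count
    l_parent[i] <<- parent_node; l_sedge[i] <<- se; l_alive[i] <<- TRUE
    te <- s_t1[se]
    wait <- if (lambda > 0) stats::rexp(1L, lambda) else Inf
    if (t + wait < te) {
      l_next[i] <<- t + wait; l_arrive[i] <<- FALSE
    } else {
      l_next[i] <<- te; l_arrive[i] <<- TRUE
    }
    i
  }

  log_kind <- character(0); log_time <- numeric(0)
  log_donor <- integer(0); log_recip <- integer(0); log_node <- integer(0)
  add_log <- function(kind, time, donor, recip, node) {
    log_kind <<- c(log_kind, kind); log_time <<- c(log_time, time)
    log_donor <<- c(log_donor, donor); log_recip <<- c(log_recip, recip)
    log_node <<- c(log_node, node)
  }
  degraded <- 0L

  # the root speciation at time 0
  root_node <- new_node("speciation", 0, 0L)
  for (se in child_edges[[sroot]]) spawn(root_node, se, 0)

  while (TRUE) {
    act <- which(l_alive[seq_len(l_count)])
    if (!length(act)) break
    li <- act[which.min(l_next[act])]
    t <- l_next[li]; se <- l_sedge[li]
    l_alive[li] <- FALSE
    if (l_arrive[li]) {                      # reached the end of the branch
      v <- sedge[se, 2L]
      if (v <= nsp) {
        new_node("leaf", 1, l_parent[li], species = v)
      } else {
        nd <- new_node("speciation", t, l_parent[li])
        for (ce in child_edges[[v]]) spawn(nd, ce, t)
      }
      next
    }
    kind <- sample.int(3L, 1L, prob = probs)
    if (kind == 1L) {                        # duplication
      nd <- new_node("duplication", t, l_parent[li])
      spawn(nd, se, t); spawn(nd, se, t)
      add_log("duplication", t, se, NA_integer_, nd)
    } else if (kind == 3L) {                 # loss
      nd <- new_node("loss", t, l_parent[li])
      add_log("loss", t, se, NA_integer_, nd)
    } else {                                 # transfer
      alive_edges <- which(s_t0 < t & t < s_t1)
      recips <- setdiff(alive_edges, se)
      if (!length(recips)) {                 # no contemporaneous branch
        spawn(l_parent[li], se, t)           # lineage continues unaffected
        next
      }
      additive <- stats::runif(1L) < rates$additive_fraction
      if (!additive) {
        # a replacing transfer needs a resident copy to displace: recipients
        # are the contemporaneous branches currently carrying the gene
        occupied <- unique(l_sedge[which(l_alive[seq_len(l_count)])])
        recips_r <- intersect(recips, occupied)
        if (length(recips_r)) recips <- recips_r
        else { additive <- TRUE; degraded <- degraded + 1L }
      }
      recip <- recips[sample.int(length(recips), 1L)]
      if (!additive) {
        victims <- which(l_alive[seq_len(l_count)] &
                           l_sedge[seq_len(l_count)] == recip)
        vic <- victims[sample.int(length(victims), 1L)]
        l_alive[vic] <- FALSE
        new_node("replaced", t, l_parent[vic])
      }
      nd <- new_node("transfer", t, l_parent[li],
                     flag = if (additive) "additive" else "replacing")
      spawn(nd, se, t)                       # donor copy continues
      spawn(nd, recip, t)                    # transferred copy
      add_log(if (additive) "additive_transfer" else "replacing_transfer",
              t, se, recip, nd)
    }
  }

  build_gene_family(stree, seed, rates, degraded,
                    list(type = n_type[seq_len(n_count)],
                         time = n_time[seq_len(n_count)],
                         parent = n_parent[seq_len(n_count)],
                         kid1 = n_kid1[seq_len(n_count)],
                         kid2 = n_kid2[seq_len(n_count)],
                         species = n_species[seq_len(n_count)],
                         flag = n_flag[seq_len(n_count)]),
                    data.frame(kind = log_kind, time = log_time,
                               donor = log_donor, recipient = log_recip,
                               node = log_node))
}

# prune extinct subtrees, suppress unary nodes, assemble the phylo and the
# surviving-event counts
build_gene_family <- function(stree, seed, rates, degraded, nodes, full_log) {
  m <- length(nodes$type)
  ext <- integer(m)                            # extant leaves below each node
  for (i in m:1) {
    ext[i] <- if (nodes$type[i] == "leaf") 1L else 0L
    if (nodes$kid1[i] > 0L) ext[i] <- ext[i] + ext[nodes$kid1[i]]
    if (nodes$kid2[i] > 0L) ext[i] <- ext[i] + ext[nodes$kid2[i]]
  }
  n_extant <- ext[1L]

  # a branching survives if both its children have extant descendants
  k1 <- nodes$kid1; k2 <- nodes$kid2
  both_survive <- k1 > 0L & k2 > 0L
  both_survive[both_survive] <- ext[k1[both_survive]] > 0L &
    ext[k2[both_survive]] > 0L

  counts <- c(
    Leaves = n_extant,
    Duplications = sum(nodes$type == "duplication" & both_survive),
    Losses = sum(nodes$type == "loss" & ext[pmax(nodes$parent, 1L)] > 0L &
                   nodes$parent > 0L),
    `Additive Transfers` = sum(nodes$type == "transfer" &
                                 nodes$flag == "additive" & both_survive),
    `Replacing Transfers` = sum(nodes$type == "transfer" &
                                  nodes$flag == "replacing" & both_survive))
  surv_nodes <- which(
    (nodes$type %in% c("duplication", "transfer") & both_survive) |
      (nodes$type == "loss" & nodes$parent > 0L & ext[pmax(nodes$parent, 1L)] > 0L))
  events <- full_log[full_log$node %in% surv_nodes, , drop = FALSE]
  sp_lab <- function(e) {
    v <- stree$phy$edge[e, 2L]
    n <- n_tips(stree$phy)
    if (is.na(e)) NA_character_
    else if (v <= n) stree$phy$tip.label[v] else paste0("node", v)
  }
  if (nrow(events)) {
    events$donor <- vapply(events$donor, sp_lab, character(1))
    events$recipient <- vapply(events$recipient, sp_lab, character(1))
  }

  out <- list(tree = NULL, extinct = n_extant < 3L, n_leaves = n_extant,
              leaf_map = character(0), counts = counts, events = events,
              events_all = full_log, degraded = degraded, seed = seed,
              rates = rates)
  class(out) <- "gene_family_history"
  if (n_extant < 2L) return(out)

  # assemble the pruned binary tree
  nsp_lab <- stree$phy$tip.label
  copy_counter <- integer(length(nsp_lab))
  tip_label <- character(0); tip_species <- character(0); tip_node <- integer(0)
  # surviving bifurcations in creation order; map to phylo ids later
  keep_int <- which(nodes$type %in% c("speciation", "duplication", "transfer") &
                      both_survive)
  # descend from node i to its surviving representative (bifurcation or leaf)
  represent <- function(i) {
    repeat {
      if (nodes$type[i] == "leaf") return(i)
      kk <- c(nodes$kid1[i], nodes$kid2[i])
      kk <- kk[kk > 0L]
      kk <- kk[ext[kk] > 0L]
      if (length(kk) >= 2L) return(i)
      i <- kk[1L]
    }
  }
  top <- represent(1L)
  if (nodes$type[top] == "leaf") return(out)   # single survivor: no tree

  n_tip_new <- n_extant
  tip_id <- integer(m); int_id <- integer(m)
  next_tip <- 0L; next_int <- n_tip_new + 1L
  parent_v <- integer(0); child_v <- integer(0); len_v <- numeric(0)
  # iterative preorder from top
  stack <- list(list(node = top, parent_new = 0L, parent_time = NA_real_))
  while (length(stack)) {
    fr <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    i <- fr$node
    if (nodes$type[i] == "leaf") {
      next_tip <- next_tip + 1L
      sp <- nodes$species[i]
      copy_counter[sp] <- copy_counter[sp] + 1L
      tip_label <- c(tip_label, paste0(nsp_lab[sp], "_", copy_counter[sp]))
      tip_species <- c(tip_species, nsp_lab[sp])
      id <- next_tip
    } else {
      id <- next_int; next_int <- next_int + 1L
    }
    if (fr$parent_new > 0L) {
      parent_v <- c(parent_v, fr$parent_new); child_v <- c(child_v, id)
      len_v <- c(len_v, nodes$time[i] - fr$parent_time)
    }
    if (nodes$type[i] != "leaf") {
      kk <- c(nodes$kid1[i], nodes$kid2[i])
      kk <- kk[kk > 0L]; kk <- kk[ext[kk] > 0L]
      for (k in kk)
        stack[[length(stack) + 1L]] <-
          list(node = represent(k), parent_new = id, parent_time = nodes$time[i])
    }
  }
  phy <- list(edge = cbind(parent_v, child_v, deparse.level = 0),
              edge.length = len_v, Nnode = next_int - n_tip_new - 1L,
              tip.label = tip_label)
  class(phy) <- "phylo"
  phy <- ape::reorder.phylo(phy, "cladewise")
  out$tree <- validate_rooted_tree(phy)
  out$leaf_map <- stats::setNames(tip_species, tip_label)
  out
}

#' @export
print.gene_family_history <- function(x, ...) {
  cat(sprintf(
    "gene family: %d leaves%s; D %d, L %d, T+ %d, Tr %d (surviving)\n",
    x$n_leaves, if (x$extinct) " [extinct]" else "",
    x$counts[["Duplications"]], x$counts[["Losses"]],
    x$counts[["Additive Transfers"]], x$counts[["Replacing Transfers"]]))
  invisible(x)
}

#' Simulate a gene family, resimulating extinct ones
#'
#' Families surviving with fewer than `min_leaves` copies (rooting is
#' undefined below 3 leaves) are resimulated with the next seed; the number of
#' attempts is recorded in the `retries` field.
#'
#' @inheritParams simulate_gene_history
#' @param min_leaves minimum surviving copies to accept (default 3).
#' @param max_retries bound on resimulation attempts.
#' @return a `gene_family_history` with at least `min_leaves` leaves.
#' @export
simulate_gene_family <- function(stree, rates, seed = 1, min_leaves = 3L,
                                 max_retries = 1000L) {
  for (k in 0:max_retries) {
    h <- simulate_gene_history(stree, rates, seed + k)
    if (h$n_leaves >= min_leaves) {
      h$retries <- k
      return(h)
    }
  }
  stop("family extinct after ", max_retries, " resimulations")
}

# ---- branch scaling ---------------------------------------------------------

#' Scale gene tree branches to emulate rate variation
#'
#' Applies a [scaling_scheme()]: independent uniform multipliers, or
#' autocorrelated lognormal node rates (mean-preserving; root at
#' `start_rate`), multiplying each branch by its child node's rate. Topology
#' is unchanged.
#'
#' @param gtree a rooted gene tree.
#' @param scheme a [scaling_scheme()].
#' @param seed integer seed.
#' @return the tree with scaled branch lengths.
#' @export
scale_branches <- function(gtree, scheme, seed = 1) {
  validate_rooted_tree(gtree)
  stopifnot(inherits(scheme, "scaling_scheme"))
  if (scheme$kind == "none") return(gtree)
  withr::with_seed(as.integer(seed), {
    E <- nrow(gtree$edge)
    if (scheme$kind == "uniform") {
      gtree$edge.length <- gtree$edge.length *
        stats::runif(E, scheme$lo, scheme$hi)
    } else {
      gtree <- ape::reorder.phylo(gtree, "cladewise")  # parents before kids
      rate <- numeric(n_nodes(gtree))
      rate[n_tips(gtree) + 1L] <- scheme$start_rate
      for (i in seq_len(E)) {
        p <- gtree$edge[i, 1L]; ch <- gtree$edge[i, 2L]
        s2 <- scheme$sigma2 *
          (if (scheme$time_scaled) gtree$edge.length[i] else 1)
        rate[ch] <- exp(stats::rnorm(1L, log(rate[p]) - s2 / 2, sqrt(s2)))
        gtree$edge.length[i] <- gtree$edge.length[i] * rate[ch]
      }
    }
    gtree
  })
}

#' Perturb a gene tree topology with random NNI moves
#'
#' Applies `k` random nearest-neighbor interchanges to the unrooted topology
#' and reroots at a random edge: a generic stand-in for phylogenetic
#' reconstruction error (each NNI changes at most one bipartition, so the
#' unrooted RF distance to the input is at most `k`).
#'
#' @param gtree a rooted gene tree (>= 4 leaves for an NNI to exist).
#' @param k number of NNI moves, >= 0.
#' @param seed integer seed.
#' @return a rooted tree on the same leaves.
#' @export
perturb_topology <- function(gtree, k, seed = 1) {
  validate_rooted_tree(gtree)
  stopifnot(k >= 0)
  u <- unroot_tree(gtree)
  withr::with_seed(as.integer(seed), {
    if (k > 0) {
      u <- phangorn::rNNI(u, moves = k, n = 1)
      if (is.null(u$edge.length)) u$edge.length <- rep(1, nrow(u$edge))
      u <- unroot_tree(u)
    }
    i <- sample.int(nrow(u$edge), 1L)
    root_at(u, root_position(u, u$edge[i, ], 0.5))
  })
}

#' Summarize simulated gene family sets
#'
#' Per-family surviving counts averaged over a list of histories: mean leaf
#' count and mean numbers of duplications, losses, additive and replacing
#' transfers.
#'
#' @param histories a nonempty list of `gene_family_history` objects.
#' @return a one-row data frame with columns `Leaves`, `Duplications`,
#'   `Losses`, `Additive Transfers`, `Replacing Transfers`.
#' @export
summarize_families <- function(histories) {
  stopifnot(length(histories) > 0)
  counts <- do.call(rbind, lapply(histories, function(h) h$counts))
  out <- as.data.frame(t(colMeans(counts)), check.names = FALSE)
  rownames(out) <- NULL
  out
}
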
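# Branch-length based rooting methods (midpoint, MAD, MV) and the random
# rooting baseline. All four consume an unrooted binary tree; the first three
# use branch lengths, random rooting ignores them. Each returns a
# `rooting_result` listing every optimal root position (ties included).

SCORE_TIE_RTOL <- 1e-9
FRACTION_EPS <- 1e-9

new_rooting_result <- function(method, positions, score = NA_real_,
                               edge_scores = NULL) {
  stopifnot(length(positions) >= 1L)
  structure(list(method = method, positions = positions, score = score,
                 tie_count = length(positions), edge_scores = edge_scores),
            class = "rooting_result")
}

#' @export
print.rooting_result <- function(x, ...) {
  cat(sprintf("%s rooting: %d optimal position%s, score %s\n", x$method,
              x$tie_count, if (x$tie_count > 1L) "s (tied)" else "",
              if (is.na(x$score)) "-" else format(x$score)))
  for (p in x$positions) print(p)
  invisible(x)
}

#' Apply one optimal root position of a rooting result
#'
#' Roots `tree` at one of the optimal positions stored in `result`. With a
#' single optimum the choice is forced; among ties, one is picked uniformly at
#' random under `seed` (the seeded "arbitrary" tie pick used when scoring
#' simulated families).
#'
#' @param result a `rooting_result`.
#' @param tree the unrooted tree the result was computed on.
#' @param seed integer seed for the tie pick (ignored when there is a single
#'   optimum).
#' @return a rooted binary tree.
#' @export
pick_rooting <- function(result, tree, seed = 1L) {
  stopifnot(inherits(result, "rooting_result"))
  k <- length(result$positions)
  i <- if (k == 1L) 1L else withr::with_seed(seed, sample.int(k, 1L))
  root_at(tree, result$positions[[i]])
}

clamp_fraction <- function(f) min(max(f, FRACTION_EPS), 1 - FRACTION_EPS)

# tips on the side of each canonical endpoint of edge row i; returns list(
# a, b, aside, bside, len) with a < b node ids
edge_sides <- function(tree, i, below) {
  n <- n_tips(tree)
  parent <- tree$edge[i, 1L]; child <- tree$edge[i, 2L]
  childside <- below[[child]]
  a <- min(parent, child); b <- max(parent, child)
  aside <- if (a == child) childside else setdiff(seq_len(n), childside)
  list(a = a, b = b, aside = aside, bside = setdiff(seq_len(n), aside),
       len = tree$edge.length[i])
}

#' Midpoint rooting
#'
#' Roots at the midpoint of a longest leaf-to-leaf path, i.e. the point
#' equidistant (at half the tree diameter) from the two farthest leaves. When
#' several leaf pairs attain the diameter, every distinct midpoint is
#' reported; when all branch lengths are zero every edge ties with score 0.
#'
#' @param tree an unrooted tree with nonnegative branch lengths.
#' @return a `rooting_result`; `score` is half the diameter.
#' @export
midpoint_root <- function(tree) {
  validate_unrooted_tree(tree)
  n <- n_tips(tree)
  E <- nrow(tree$edge)
  if (sum(tree$edge.length) == 0) {
    pos <- lapply(seq_len(E), function(i)
      root_position(tree, tree$edge[i, ], 0.5))
    return(new_rooting_result("midpoint", pos, 0))
  }
  D <- ape::dist.nodes(tree)
  tipD <- D[seq_len(n), seq_len(n), drop = FALSE]
  mx <- max(tipD)
  tol <- 1e-12 * max(1, mx)
  hits <- which(tipD >= mx - tol & upper.tri(tipD), arr.ind = TRUE)
  adj <- adjacency_list(tree)
  positions <- list(); seen <- character(0)
  for (h in seq_len(nrow(hits))) {
    bleaf <- hits[h, 1L]; cleaf <- hits[h, 2L]
    path <- node_path(adj, bleaf, cleaf)
    target <- mx / 2
    cum <- 0
    for (k in seq_len(length(path) - 1L)) {
      u <- path[k]; v <- path[k + 1L]
      len <- D[u, v]
      if (cum + len >= target - tol) {
        f <- if (len > 0) (target - cum) / len else 0.5
        a <- min(u, v)
        f_can <- if (a == u) f else 1 - f
        p <- root_position(tree, c(u, v), clamp_fraction(f_can))
        key <- sprintf("%d|%.9f", p$edge_row, p$fraction)
        if (!key %in% seen) {
          seen <- c(seen, key); positions[[length(positions) + 1L]] <- p
        }
        break
      }
      cum <- cum + len
    }
  }
  new_rooting_result("midpoint", positions, mx / 2)
}

# node path between two nodes via DFS parent pointers
node_path <- function(adj, from, to) {
  m <- length(adj$nbr)
  parent <- rep(NA_integer_, m); parent[from] <- 0L
  stack <- from
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    if (v == to) break
    for (nb in adj$nbr[[v]]) if (is.na(parent[nb])) {
      parent[nb] <- v; stack <- c(stack, nb)
    }
  }
  path <- to
  while (path[1L] != from) path <- c(parent[path[1L]], path)
  path
}

#' Minimal ancestor deviation (MAD) rooting
#'
#' For every candidate root point, each leaf pair (b, c) is assigned its
#' ancestor alpha: the node where the two root-to-leaf paths diverge, or the
#' candidate point itself for pairs spanning the root edge. The pair's
#' relative deviation from a clock is `|2 d(alpha, b) / d(b, c) - 1|`, and the
#' candidate's score is the root-mean-square deviation over all pairs.
#' Restricted to one edge, the squared deviations of spanning pairs are
#' quadratic in the root's position, so the within-edge optimum has a closed
#' form (clamped to the edge); the tree is rooted at the global minimum, ties
#' reported. Leaf pairs at zero distance are skipped with a warning.
#'
#' @param tree an unrooted tree with branch lengths, not all zero.
#' @return a `rooting_result`; `score` is the minimal RMS relative deviation.
#'   `edge_scores` holds the per-edge minima.
#' @export
mad_root <- function(tree) {
  validate_unrooted_tree(tree)
  if (sum(tree$edge.length) == 0)
    stop("MAD rooting is undefined when all branch lengths are zero")
  n <- n_tips(tree)
  D <- ape::dist.nodes(tree)
  below <- descendant_tips(tree)
  E <- nrow(tree$edge)
  warned <- FALSE

  # per-side sum of squared deviations for pairs not spanning the root edge:
  # ((d(end, x) - d(end, y)) / d(x, y))^2 over unordered pairs
  same_side_ss <- function(end, side) {
    if (length(side) < 2L) return(0)
    dxy <- D[side, side, drop = FALSE]
    dend <- D[end, side]
    num <- outer(dend, dend, "-")
    up <- upper.tri(dxy)
    bad <- dxy == 0 & up
    if (any(bad)) warned <<- TRUE
    ok <- up & dxy > 0
    sum((num[ok] / dxy[ok])^2)
  }

  res <- vapply(seq_len(E), function(i) {
    s <- edge_sides(tree, i, below)
    dbc <- D[s$aside, s$bside, drop = FALSE]
    da <- D[s$a, s$aside]
    ok <- dbc > 0
    if (!all(ok)) warned <<- TRUE
    A <- ifelse(ok, 2 * s$len / dbc, 0)
    B <- ifelse(ok, 2 * outer(da, rep(1, length(s$bside))) / dbc - 1, 0)
    sumA2 <- sum(A * A); sumAB <- sum(A * B); sumB2 <- sum(B * B)
    rho <- if (sumA2 > 0) -sumAB / sumA2 else 0.5
    rho <- min(max(rho, 0), 1)
    # the quadratic is a sum of squares; guard tiny negative rounding at a
    # perfect-clock optimum
    ss_span <- max(sumA2 * rho^2 + 2 * sumAB * rho + sumB2, 0)
    ss <- ss_span + same_side_ss(s$a, s$aside) + same_side_ss(s$b, s$bside)
    npairs <- sum(ok) +
      sum(upper.tri(D[s$aside, s$aside, drop = FALSE]) &
            D[s$aside, s$aside, drop = FALSE] > 0) +
      sum(upper.tri(D[s$bside, s$bside, drop = FALSE]) &
            D[s$bside, s$bside, drop = FALSE] > 0)
    c(score = sqrt(ss / npairs), rho = rho)
  }, numeric(2))
  if (warned)
    warning("leaf pairs at zero distance were skipped in the MAD score")
  finish_length_method(tree, "mad", res["score", ], res["rho", ])
}

#' Minimum variance (MV) rooting
#'
#' Scores a candidate root by the variance of its distances to all leaves.
#' On each edge the variance is quadratic in the root's position, minimized in
#' closed form and clamped to the edge; the global minimum over edges is
#' returned with ties.
#'
#' @param tree an unrooted tree with branch lengths.
#' @return a `rooting_result`; `score` is the minimal root-to-leaf distance
#'   variance (population form).
#' @export
mv_root <- function(tree) {
  validate_unrooted_tree(tree)
  n <- n_tips(tree)
  D <- ape::dist.nodes(tree)
  below <- descendant_tips(tree)
  E <- nrow(tree$edge)
  res <- vapply(seq_len(E), function(i) {
    s <- edge_sides(tree, i, below)
    base <- numeric(n); sgn <- numeric(n)
    base[s$aside] <- D[s$a, s$aside]; sgn[s$aside] <- 1
    base[s$bside] <- D[s$b, s$bside] + s$len; sgn[s$bside] <- -1
    ms <- mean(sgn)
    a2 <- 1 - ms^2
    a1 <- 2 * (mean(base * sgn) - mean(base) * ms)
    a0 <- mean(base^2) - mean(base)^2
    y <- if (a2 > 0) -a1 / (2 * a2) else 0
    y <- min(max(y, 0), s$len)
    c(score = max(a2 * y^2 + a1 * y + a0, 0),  # variance; guard rounding
      rho = if (s$len > 0) y / s$len else 0.5)
  }, numeric(2))
  finish_length_method(tree, "mv", res["score", ], res["rho", ])
}

# shared tail of MAD/MV: pick global min over per-edge optima, report ties
finish_length_method <- function(tree, method, scores, rhos) {
  best <- min(scores)
  tol <- SCORE_TIE_RTOL * max(1, abs(best))
  opt <- which(scores <= best + tol)
  positions <- lapply(opt, function(i)
    root_position(tree, tree$edge[i, ], clamp_fraction(rhos[i])))
  edge_scores <- data.frame(edge_row = seq_along(scores),
                            node1 = tree$edge[, 1L], node2 = tree$edge[, 2L],
                            score = scores, fraction = rhos,
                            is_optimal = seq_along(scores) %in% opt)
  new_rooting_result(method, positions, best, edge_scores)
}

#' Random rooting baseline
#'
#' Roots at a uniformly chosen edge of the unrooted tree (fraction 0.5,
#' topology only). Deterministic given `seed`.
#'
#' @param tree an unrooted tree.
#' @param seed integer seed.
#' @return a `rooting_result` with a single position and no score.
#' @export
random_root <- function(tree, seed = 1L) {
  validate_unrooted_tree(tree)
  E <- nrow(tree$edge)
  i <- withr::with_seed(seed, sample.int(E, 1L))
  pos <- root_position(tree, tree$edge[i, ], 0.5, topology_only = TRUE)
  new_rooting_result("random", list(pos), NA_real_)
}
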
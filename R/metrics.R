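# Rooting-accuracy measures: RF error against the true rooting, adjusted RF
# for trees with topological (reconstruction) error, and root balance.

#' RF rooting error against the true rooted tree
#'
#' For an inferred rooting of the *same* unrooted topology as the truth:
#' absolute error is the rooted RF distance (= number of intermediate nodes
#' between the two root edges), normalized error divides by the leaf count,
#' and the rooting is correct iff the absolute error is 0.
#'
#' @param true_tree the true rooted tree.
#' @param inferred an inferred rooted tree on the same unrooted topology.
#' @return a list with `absolute`, `normalized`, `correct`.
#' @seealso [adjusted_rf()] when the topologies differ.
#' @export
rooting_error <- function(true_tree, inferred) {
  if (rf_unrooted(true_tree, inferred) != 0)
    stop("trees differ in unrooted topology; use adjusted_rf() instead")
  ab <- rf_rooted(true_tree, inferred)
  list(absolute = ab, normalized = ab / length(true_tree$tip.label),
       correct = ab == 0)
}

#' Adjusted RF distance
#'
#' `RF(T1, T2) - URF(T1, T2)`: the rooted minus the unrooted RF distance.
#' Always nonnegative, and zero exactly when the (possibly erroneous) tree is
#' rooted "correctly" in the sense that rooting contributes no disagreement
#' beyond the topological error. The measure of rooting accuracy for
#' reconstructed trees, whose unrooted topology need not match the truth.
#'
#' @param true_tree the true rooted tree.
#' @param recon_tree a rooted tree on the same leaves (topology may differ).
#' @return a nonnegative number.
#' @export
adjusted_rf <- function(true_tree, recon_tree) {
  rf_rooted(true_tree, recon_tree) - rf_unrooted(true_tree, recon_tree)
}

#' Root balance ratio
#'
#' Leaves in the smaller root-child clade divided by leaves in the larger:
#' 1 for a perfectly balanced root, near 0 for a root above a single leaf.
#'
#' @param tree a rooted tree with >= 2 leaves.
#' @return a ratio in (0, 1].
#' @export
root_balance <- function(tree) {
  validate_rooted_tree(tree)
  root <- length(tree$tip.label) + 1L
  below <- descendant_tips(tree)
  sizes <- vapply(tree$edge[tree$edge[, 1L] == root, 2L],
                  function(ch) length(below[[ch]]), integer(1))
  min(sizes) / max(sizes)
}

#' Mean squared error of root balances around an expected ratio
#'
#' @param balances numeric vector of root balance ratios.
#' @param expected the expected balance (e.g. the species-level split ratio).
#' @return mean of `(balance - expected)^2`.
#' @export
balance_squared_error <- function(balances, expected) {
  stopifnot(length(balances) > 0)
  mean((balances - expected)^2)
}

#' Score one rooting result against the truth
#'
#' Builds an accuracy record for a method's result on one family: the seeded
#' arbitrary tie pick is scored (as in the simulated study), and the tie
#' closest to the truth is additionally reported as `rf_best` (a non-study
#' best-case diagnostic).
#'
#' @param result a `rooting_result` on `utree`.
#' @param utree the unrooted gene tree the result was computed on.
#' @param true_tree the true rooted gene tree.
#' @param tie_seed seed for the arbitrary tie pick.
#' @return a one-row data frame: `method`, `rf`, `norm_rf`, `correct`,
#'   `balance`, `ties`, `rf_best`, `n_leaves`.
#' @export
score_rooting <- function(result, utree, true_tree, tie_seed = 1L) {
  stopifnot(inherits(result, "rooting_result"))
  picked <- pick_rooting(result, utree, seed = tie_seed)
  err <- rooting_error(true_tree, picked)
  rf_best <- err$absolute
  if (result$tie_count > 1L)
    rf_best <- min(vapply(result$positions, function(p)
      rf_rooted(true_tree, root_at(utree, p)), numeric(1)))
  data.frame(method = result$method, rf = err$absolute,
             norm_rf = err$normalized, correct = err$correct,
             balance = root_balance(picked), ties = result$tie_count,
             rf_best = rf_best, n_leaves = length(true_tree$tip.label))
}

#' Aggregate accuracy records
#'
#' Per (method, data set): percent of families rooted correctly, mean
#' absolute and normalized RF, and the three quartiles of the absolute RF
#' distribution (linear-interpolation convention, `quantile` type 7, so
#' supplement-style tables are deterministic).
#'
#' @param records a data frame of accuracy records (as produced by
#'   [score_rooting()] plus grouping columns).
#' @param by names of grouping columns present in `records` (default
#'   `"method"` plus any of collection/preset/scheme that are present).
#' @return a data frame with one row per group.
#' @export
aggregate_accuracy <- function(records, by = NULL) {
  stopifnot(is.data.frame(records), nrow(records) > 0)
  if (is.null(by))
    by <- intersect(c("collection", "preset", "scheme", "method"),
                    names(records))
  key <- interaction(records[by], drop = TRUE, lex.order = TRUE)
  rows <- lapply(split(records, key), function(g) {
    q <- stats::quantile(g$rf, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    cbind(g[1L, by, drop = FALSE],
          data.frame(n = nrow(g), pct_correct = 100 * mean(g$correct),
                     mean_rf = mean(g$rf), mean_norm_rf = mean(g$norm_rf),
                     rf_q1 = q[1L], rf_q2 = q[2L], rf_q3 = q[3L]))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
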
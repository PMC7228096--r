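# Experiment orchestration: build the simulated collections, root every
# family with every configured method (and DTL cost vector), score, and
# aggregate. Fully deterministic under a master seed: every random draw uses
# a seed derived from (master seed, collection, preset, scheme, family).

#' Configure a rooting-accuracy experiment
#'
#' The default grid mirrors the full study design: the `baseline` collection
#' crosses three event-rate presets (low/medium/high, additive:replacing 3:7)
#' with four branch-scaling schemes, 100 families per set; `additive` uses the
#' same presets with all transfers additive; `very_high` uses the
#' very-high-transfer presets. `perturbed` applies NNI perturbation to the
#' baseline families before rooting (a stand-in for reconstruction error,
#' scored by adjusted RF).
#'
#' @param collections subset of `"baseline"`, `"additive"`, `"very_high"`,
#'   `"perturbed"`.
#' @param presets event-rate preset names (see [rate_preset()]); defaults to
#'   low/medium/high for baseline-like collections, the very-high presets for
#'   `very_high`.
#' @param schemes branch-scaling preset names (see [scheme_preset()]).
#' @param families_per_set families per (collection, preset, scheme) set.
#' @param methods subset of `"midpoint"`, `"mad"`, `"mv"`, `"dtl"`,
#'   `"random"`.
#' @param cost_vectors named list of `<loss, dup, transfer>` cost triples for
#'   the DTL sweep.
#' @param master_seed integer master seed.
#' @param n_species,birth,death species-tree parameters.
#' @param perturb_nni NNI moves for the `perturbed` collection.
#' @return an `experiment_config` object.
#' @export
experiment_config <- function(collections = "baseline",
                              presets = NULL,
                              schemes = c("uniform_0.3_3", "uniform_0.2_5",
                                          "auto_0.05", "auto_0.25"),
                              families_per_set = 100L,
                              methods = c("midpoint", "mad", "mv", "dtl",
                                          "random"),
                              cost_vectors = list(default = c(1, 2, 3)),
                              master_seed = 1L,
                              n_species = 100L, birth = 3, death = 1,
                              perturb_nni = 5L) {
  known <- c("baseline", "additive", "very_high", "perturbed")
  stopifnot(all(collections %in% known), families_per_set >= 1,
            all(methods %in% c("midpoint", "mad", "mv", "dtl", "random")),
            length(cost_vectors) >= 1)
  for (s in schemes) scheme_preset(s)   # validate early
  structure(list(collections = collections, presets = presets,
                 schemes = schemes,
                 families_per_set = as.integer(families_per_set),
                 methods = methods, cost_vectors = cost_vectors,
                 master_seed = as.integer(master_seed),
                 n_species = as.integer(n_species), birth = birth,
                 death = death, perturb_nni = as.integer(perturb_nni)),
            class = "experiment_config")
}

collection_presets <- function(config, collection) {
  if (!is.null(config$presets)) return(config$presets)
  if (collection == "very_high") c("very_high_2", "very_high_3", "very_high_4")
  else c("low", "medium", "high")
}

#' Run a configured experiment
#'
#' For each (collection, preset, scheme) set: simulates the families (one
#' species tree per family index, shared across presets; one gene family per
#' (preset, family index), shared across schemes with scalings redrawn per
#' scheme), roots every family with every configured method and DTL cost
#' vector, and scores each rooting against the true rooted tree. Branch-length
#' methods see the scaled tree; DTL and random rooting ignore branch lengths.
#'
#' @param config an [experiment_config()].
#' @param progress logical; print per-set progress lines.
#' @return an `experiment_result`: `$records` (one row per family x method),
#'   `$summary` (per-set aggregates from [aggregate_accuracy()]), and
#'   `$manifest` (seeds, resimulation counts, config echo).
#' @export
run_experiment <- function(config, progress = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  ms <- config$master_seed
  records <- list()
  resim <- 0L
  for (collection in config$collections) {
    af <- if (collection == "additive") 1 else 0.3
    base_collection <- if (collection == "perturbed") "baseline" else collection
    for (preset in collection_presets(config, collection)) {
      rates <- rate_preset(preset, additive_fraction = af)
      fams <- lapply(seq_len(config$families_per_set), function(i) {
        st <- simulate_species_tree(config$n_species, config$birth,
                                    config$death,
                                    seed = derive_seed(ms, "stree", i))
        h <- simulate_gene_family(st, rates,
                                  seed = derive_seed(ms, base_collection,
                                                     preset, "fam", i))
        resim <<- resim + h$retries
        list(st = st, h = h)
      })
      for (scheme in config$schemes) {
        sch <- scheme_preset(scheme)
        for (i in seq_along(fams)) {
          st <- fams[[i]]$st; h <- fams[[i]]$h
          true_tree <- h$tree
          scaled <- scale_branches(true_tree, sch,
                                   seed = derive_seed(ms, collection, preset,
                                                      scheme, "scale", i))
          if (collection == "perturbed") {
            # reconstruction-error stand-in: perturbed topology, scored below
            # by adjusted RF through the same record fields
            scaled <- perturb_topology(scaled, config$perturb_nni,
                                       seed = derive_seed(ms, "nni", preset,
                                                          scheme, i))
          }
          utree <- unroot_tree(scaled)
          for (method in config$methods) {
            results <- rooting_results(method, utree, st, config,
                                       derive_seed(ms, "m", method, preset,
                                                   scheme, i))
            for (mname in names(results)) {
              rec <- score_family(results[[mname]], utree, true_tree,
                                  tie_seed = derive_seed(ms, "tie", mname,
                                                         preset, scheme, i),
                                  perturbed = collection == "perturbed")
              rec$method <- mname
              rec <- cbind(data.frame(collection = collection,
                                      preset = preset, scheme = scheme,
                                      family = i), rec)
              records[[length(records) + 1L]] <- rec
            }
          }
        }
        if (progress)
          message(sprintf("[%s/%s/%s] %d families done", collection, preset,
                          scheme, length(fams)))
      }
    }
  }
  records <- do.call(rbind, records)
  summary <- aggregate_accuracy(records)
  manifest <- list(master_seed = ms, resimulations = resim,
                   families_per_set = config$families_per_set,
                   n_species = config$n_species, birth = config$birth,
                   death = config$death,
                   seed_scheme = "derive_seed(master, role, ...indices)",
                   package_version = as.character(utils::packageVersion("rootbench")))
  structure(list(records = records, summary = summary, manifest = manifest,
                 config = config),
            class = "experiment_result")
}

# run one named method, returning a named list of rooting_results (DTL
# expands into one entry per configured cost vector)
rooting_results <- function(method, utree, st, config, seed) {
  if (method == "dtl") {
    out <- lapply(config$cost_vectors, function(cv)
      dtl_root(utree, st$phy, costs = cv))
    names(out) <- if (length(out) == 1L) "dtl"
      else paste0("dtl_", vapply(config$cost_vectors, paste, character(1),
                                 collapse = "_"))
    return(out)
  }
  res <- switch(method,
    midpoint = midpoint_root(utree),
    mad = mad_root(utree),
    mv = mv_root(utree),
    random = random_root(utree, seed = seed))
  stats::setNames(list(res), method)
}

# score with rooting_error when topologies agree, adjusted RF otherwise
score_family <- function(result, utree, true_tree, tie_seed, perturbed) {
  if (!perturbed)
    return(score_rooting(result, utree, true_tree, tie_seed = tie_seed))
  picked <- pick_rooting(result, utree, seed = tie_seed)
  arf <- adjusted_rf(true_tree, picked)
  data.frame(method = result$method, rf = arf,
             norm_rf = arf / length(true_tree$tip.label), correct = arf == 0,
             balance = root_balance(picked), ties = result$tie_count,
             rf_best = arf, n_leaves = length(true_tree$tip.label))
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("experiment: %d records, %d sets, master seed %d\n",
              nrow(x$records), nrow(x$summary), x$manifest$master_seed))
  print(x$summary)
  invisible(x)
}

#' Sweep DTL event costs
#'
#' Runs the configured sets with DTL rooting under each cost vector and
#' tabulates percent correct and mean RF per (cost vector, set), enabling the
#' transfer-cost comparison (accuracy typically improves as the transfer cost
#' rises above its default).
#'
#' @param config an [experiment_config()] with >= 1 entries in
#'   `cost_vectors` (e.g. `list(c(1,2,3), c(1,1,2), c(1,2,4), c(1,2,5))`).
#' @return a data frame: one row per cost vector x set.
#' @export
event_cost_sweep <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  config$methods <- "dtl"
  res <- run_experiment(config)
  out <- res$summary
  out$cost_vector <- sub("^dtl_?", "", out$method)
  out$cost_vector[out$cost_vector == ""] <-
    paste(config$cost_vectors[[1L]], collapse = "_")
  out
}

#' Write experiment outputs
#'
#' Writes `accuracy.tsv` (one row per family x method), `summary.tsv` (one
#' row per method x set), and `manifest.yaml` under `dir`.
#'
#' @param result an `experiment_result`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_experiment <- function(result, dir) {
  stopifnot(inherits(result, "experiment_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(result$records, file.path(dir, "accuracy.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(result$summary, file.path(dir, "summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(yaml::as.yaml(result$manifest), file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' Write one simulated gene family set to disk
#'
#' Per-family files as plain text: the species tree, the true rooted and the
#' unrooted gene tree newicks, the surviving event log, and the leaf-species
#' mapping.
#'
#' @param stree a `species_tree`.
#' @param histories list of `gene_family_history` objects simulated in it.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_family_set <- function(stree, histories, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeLines(write_newick(stree$phy), file.path(dir, "species_tree.nwk"))
  for (i in seq_along(histories)) {
    h <- histories[[i]]
    if (is.null(h$tree)) next
    writeLines(write_newick(h$tree),
               file.path(dir, sprintf("genetree_%d.true.nwk", i)))
    writeLines(write_newick(unroot_tree(h$tree)),
               file.path(dir, sprintf("genetree_%d.unrooted.nwk", i)))
    utils::write.table(h$events,
                       file.path(dir, sprintf("genetree_%d.events.tsv", i)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(data.frame(gene = names(h$leaf_map),
                                  species = unname(h$leaf_map)),
                       file.path(dir, sprintf("mapping_%d.tsv", i)),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  }
  invisible(dir)
}
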
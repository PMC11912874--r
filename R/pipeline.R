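#' Full module-detection pipeline
#'
#' Convenience wrapper chaining [build_multilayer()],
#' [rewire_regulators()], [weight_edges()], [enumerate_units()],
#' [high_level_search()], and [finalize_assignment()]. All randomness is
#' confined to the shared permutation null, so a fixed `seed` makes the
#' whole run reproducible.
#'
#' @param expr Expression matrix (genes x samples).
#' @param sets One [interaction_set()] or a list of them.
#' @param layer_order Optional layer order, see [build_multilayer()].
#' @param B,seed Permutation-null parameters.
#' @param gamma Discount factor of the high-level controller.
#' @param split_threshold Correlation-score split threshold.
#' @param max_partners Combined-unit partner cap.
#' @param strict Use the asymmetric softmax denominator variant, see
#'   [weight_edges()].
#' @return Object of class `modnet_result` with the intermediate objects
#'   `mln`, `rewired`, `network`, `units`, `state` and the final
#'   `modules` (`module_set`).
#' @export
detect_modules <- function(expr, sets, layer_order = NULL, B = 1000L,
                           seed = 7L, gamma = 0.995, split_threshold = 0.4,
                           max_partners = 10L, strict = FALSE) {
  null <- corr_null(ncol(expr), B = B, seed = seed)
  mln <- build_multilayer(expr, sets, layer_order = layer_order)
  rewired <- rewire_regulators(mln, expr)
  network <- weight_edges(rewired, expr, null = null, strict = strict)
  units <- enumerate_units(network, expr, max_partners = max_partners)
  state <- high_level_search(units, gamma = gamma,
                             split_threshold = split_threshold, null = null)
  modules <- finalize_assignment(state, units)
  structure(list(mln = mln, rewired = rewired, network = network,
                 units = units, state = state, modules = modules,
                 null = null),
            class = "modnet_result")
}

#' @export
print.modnet_result <- function(x, ...) {
  cat(sprintf(
    "<modnet_result> %d modules from %d units (%d genes, %d samples); V = %.3f\n",
    length(x$modules$modules), nrow(x$units$units),
    length(x$units$genes), x$units$n, x$state$value))
  invisible(x)
}

# ---- recovery metrics --------------------------------------------------

jaccard <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0) return(0)
  length(intersect(a, b)) / u
}

#' Compare recovered modules against a planted truth
#'
#' For every planted module, finds the recovered module with the highest
#' Jaccard index over gene sets (best match from the planted side).
#' Overlap recovery asks whether each planted two-module gene is a member
#' of at least two recovered modules.
#'
#' @param modules `module_set` or list of gene id vectors (recovered).
#' @param truth A `planted_truth`.
#' @return List with `per_module` (data frame `planted, best_match,
#'   jaccard`), `mean_jaccard`, `n_recovered`, `n_planted`,
#'   `overlap_recovered` (logical per overlap gene).
#' @export
module_recovery <- function(modules, truth) {
  rec <- module_gene_sets(modules)
  planted <- truth$module_genes
  per <- data.frame(planted = names(planted),
                    best_match = NA_character_, jaccard = 0,
                    stringsAsFactors = FALSE)
  for (i in seq_along(planted)) {
    js <- vapply(rec, jaccard, numeric(1), b = planted[[i]])
    if (length(js)) {
      per$best_match[i] <- names(rec)[which.max(js)]
      per$jaccard[i] <- max(js)
    }
  }
  ov <- truth$overlap_genes
  ov_rec <- vapply(ov, function(g) {
    sum(vapply(rec, function(m) g %in% m, logical(1))) >= 2
  }, logical(1))
  list(per_module = per, mean_jaccard = mean(per$jaccard),
       n_recovered = length(rec), n_planted = length(planted),
       overlap_recovered = ov_rec)
}

#' Seeded end-to-end module-recovery benchmark
#'
#' For each seed, generates a planted cohort and its interaction sets,
#' runs the full detection pipeline, and scores recovery. Cohort sizes
#' cycle deterministically with the seed across the stated ranges so that
#' a multi-seed run covers different module counts and sizes.
#'
#' @param seeds Integer vector of seeds.
#' @param n_samples Samples per cohort.
#' @param within_r Planted member-factor correlation.
#' @param decoy_frac Decoy interaction fraction.
#' @param regulator_expressed_frac Fraction of regulators present in the
#'   expression matrix.
#' @param B Permutation-null size.
#' @param n_modules,genes_per_module Optional fixed sizes; by default
#'   `n_modules` cycles over 3..6 and `genes_per_module` over 20..40 with
#'   the seed.
#' @return Data frame, one row per seed: `seed, n_planted,
#'   genes_per_module, n_recovered, mean_jaccard, count_within_1,
#'   overlap_any, overlap_all` (whether any / every planted two-module
#'   gene was recovered in at least two output modules).
#' @export
run_recovery_benchmark <- function(seeds = 1:10, n_samples = 100L,
                                   within_r = 0.8, decoy_frac = 0.1,
                                   regulator_expressed_frac = 0.5,
                                   B = 1000L, n_modules = NULL,
                                   genes_per_module = NULL) {
  rows <- lapply(seeds, function(s) {
    nm <- n_modules %||% (3L + (s %% 4L))
    gpm <- genes_per_module %||% (20L + 5L * (s %% 5L))
    cohort <- generate_module_cohort(n_modules = nm,
                                     genes_per_module = gpm,
                                     n_samples = n_samples,
                                     within_r = within_r, seed = s)
    gi <- generate_interactions(cohort$truth, decoy_frac = decoy_frac,
                                regulator_expressed_frac =
                                  regulator_expressed_frac,
                                seed = s)
    res <- detect_modules(cohort$expr, gi$sets, B = B, seed = s)
    rec <- module_recovery(res$modules, gi$truth)
    data.frame(seed = s, n_planted = nm, genes_per_module = gpm,
               n_recovered = length(res$modules$modules),
               mean_jaccard = rec$mean_jaccard,
               count_within_1 = abs(length(res$modules$modules) - nm) <= 1,
               overlap_any = any(rec$overlap_recovered),
               overlap_all = all(rec$overlap_recovered),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Seeded survival-scan benchmark
#'
#' For each replicate, generates a survival cohort at the given hazard
#' ratio, builds the coregulatory network and consensus from the planted
#' module sets with regulator provenance, runs [scan_network()], and
#' reports the number of significant relations and whether the planted
#' broken relation was among them. With `hazard_ratio = 1` this measures
#' the false-relation rate of the scan; with a real hazard ratio it
#' measures power.
#'
#' @param n_reps Number of replicate cohorts.
#' @param hazard_ratio,broken_frac,censor_rate,n_patients Passed to
#'   [generate_survival_cohort()].
#' @param fdr Scan FDR threshold.
#' @param seed Base seed; replicate `i` uses `seed + i`.
#' @param n_modules,genes_per_module Planted structure of the underlying
#'   cohort.
#' @return Data frame, one row per replicate: `rep, n_tested, n_hits,
#'   planted_hit`.
#' @export
run_survival_benchmark <- function(n_reps = 100L, hazard_ratio = 3,
                                   broken_frac = 0.5, censor_rate = 0.3,
                                   n_patients = 200L, fdr = 0.05,
                                   seed = 1L, n_modules = 2L,
                                   genes_per_module = 8L) {
  base <- generate_module_cohort(n_modules = n_modules,
                                 genes_per_module = genes_per_module,
                                 overlap_frac = 0, n_noise_genes = 5L,
                                 seed = seed)
  gi <- generate_interactions(base$truth, decoy_frac = 0,
                              n_regulators = 1L, target_frac = 1,
                              seed = seed)
  rows <- lapply(seq_len(n_reps), function(i) {
    sc <- generate_survival_cohort(gi$truth, hazard_ratio = hazard_ratio,
                                   broken_frac = broken_frac,
                                   censor_rate = censor_rate,
                                   n_patients = n_patients,
                                   seed = seed + i)
    mln <- build_multilayer(sc$expr, gi$sets)
    rewired <- rewire_regulators(mln, sc$expr)
    cons <- build_consensus(list(sc$truth$module_genes),
                            networks = list(rewired))
    scan <- scan_network(cons, sc$expr, sc$survival, fdr = fdr)
    br <- sc$truth$broken_relation
    planted_hit <- any(scan$hit & scan$regulator == br[["regulator"]] &
                         scan$target == br[["target"]])
    data.frame(rep = i, n_tested = sum(!scan$untestable),
               n_hits = sum(scan$hit), planted_hit = planted_hit)
  })
  do.call(rbind, rows)
}
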
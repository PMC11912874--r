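# ---- internal state helpers -------------------------------------------

# module feature matrix (K x n): componentwise mean of assigned unit patterns
feature_matrix <- function(fu, assignment, K = max(assignment)) {
  counts <- tabulate(assignment, nbins = K)
  if (any(counts == 0)) stop("feature_matrix: empty module")
  rowsum(fu$patterns, assignment) / counts
}

# Pearson correlation of every gene's z-row with every feature (genes x K)
gene_cor_mat <- function(Z, features) {
  n <- ncol(Z)
  fc <- features - rowMeans(features)
  s <- sqrt(rowMeans(fc^2))
  C <- Z %*% t(fc)
  C <- sweep(C, 2, n * pmax(s, 1e-300), "/")
  C[, s < 1e-12] <- 0   # degenerate (cancelled) feature attracts nothing
  C
}

# unit x module probability / score matrices
prob_units_mat <- function(fu, features, null) {
  rg <- gene_cor_mat(fu$Z, features)
  pg <- matrix(prob_from_r(abs(rg), null), nrow = nrow(rg))
  fu$A %*% pg
}

score_units_mat <- function(fu, features) {
  fu$A %*% abs(gene_cor_mat(fu$Z, features))
}

row_max_sum <- function(m) {
  sum(m[cbind(seq_len(nrow(m)), max.col(m, ties.method = "first"))])
}

#' Probability of correlation between a functional unit and a module
#'
#' A single-gene unit's probability is the correlation probability of its
#' anchor z-row with the module feature vector; a combined unit's
#' probability is the weight-averaged probability of its partners,
#' `sum_i w_i * P(partner_i, feature)`.
#'
#' @param fu A [enumerate_units()] result.
#' @param unit Unit id or index.
#' @param feature Module feature vector (length `fu$n`).
#' @param null A [corr_null()] for `fu$n` samples.
#' @return Scalar in \[0, 1\].
#' @export
unit_module_probability <- function(fu, unit, feature, null) {
  if (popsd(feature) < 1e-12) stop("empty or degenerate module feature")
  if (is.character(unit)) unit <- match(unit, fu$units$unit_id)
  P <- prob_units_mat(fu, rbind(feature), null)
  unname(P[unit, 1])
}

#' Correlation score between a functional unit and a module
#'
#' The absolute Pearson correlation of the anchor z-row with the module
#' feature for a single-gene unit, and the weighted average
#' `sum_i w_i * |r(partner_i, feature)|` for a combined unit. With
#' `strict = TRUE` the absolute value is applied to the first partner term
#' only, an asymmetric variant of the combined score kept for comparison.
#'
#' @inheritParams unit_module_probability
#' @param strict Apply `|.|` to the first term only.
#' @return Scalar (in \[0, 1\] unless `strict` lets a negative term in).
#' @export
correlation_score <- function(fu, unit, feature, strict = FALSE) {
  if (popsd(feature) < 1e-12) stop("zero-variance module feature")
  if (is.character(unit)) unit <- match(unit, fu$units$unit_id)
  if (!strict || fu$units$kind[unit] == "single") {
    return(unname(score_units_mat(fu, rbind(feature))[unit, 1]))
  }
  w <- fu$partners[[unit]]
  r <- vapply(names(w), function(p) {
    stats::cor(fu$Z[p, ], feature)
  }, numeric(1))
  r[1] <- abs(r[1])
  sum(w * r)
}

#' Low-level controller: greedy assignment of units to modules
#'
#' Repeats: assign every functional unit to the module with the highest
#' probability of correlation; recompute every module's feature vector
#' (the mean pattern of its assigned units); compute the cumulative
#' probability `CP = sum_i max_j P(u_i, M_j)`. The reward of an assignment
#' round is `R_t = CP_t - CP_{t-1}`; when `R_t <= 0` the controller stops
#' and returns the state achieving the best CP, whose CP is the value
#' function `V` handed back to the high-level controller. Modules emptied
#' by reassignment are dropped for the remainder of the run. Ties in the
#' argmax go to the lowest module index, so reruns are identical.
#'
#' @param fu A [enumerate_units()] result.
#' @param init Either an integer assignment vector (one module index per
#'   unit) or a K x n feature matrix from which the first assignment pass
#'   starts.
#' @param null A [corr_null()] for `fu$n` samples.
#' @param max_iter Safety cap on assignment rounds.
#' @return List with `assignment`, `features`, `value` (best CP), `K`,
#'   and a per-round `trace` data frame.
#' @export
low_level_assign <- function(fu, init, null, max_iter = 50L) {
  if (is.matrix(init)) {
    features <- init
    assignment <- max.col(prob_units_mat(fu, features, null),
                          ties.method = "first")
    present <- sort(unique(assignment))
    assignment <- match(assignment, present)
    features <- feature_matrix(fu, assignment)
  } else {
    assignment <- as.integer(init)
    stopifnot(length(assignment) == nrow(fu$units))
    present <- sort(unique(assignment))
    assignment <- match(assignment, present)
    features <- feature_matrix(fu, assignment)
  }
  P <- prob_units_mat(fu, features, null)
  cp <- row_max_sum(P)
  best <- list(assignment = assignment, features = features, value = cp)
  trace <- data.frame(iter = 0L, K = nrow(features), CP = cp)
  cp_prev <- cp

  for (t in seq_len(max_iter)) {
    assignment <- max.col(P, ties.method = "first")
    present <- sort(unique(assignment))
    if (length(present) < nrow(features)) {
      mn_log("low-level: %d module(s) emptied and dropped",
             nrow(features) - length(present))
    }
    assignment <- match(assignment, present)
    features <- feature_matrix(fu, assignment)
    P <- prob_units_mat(fu, features, null)
    cp <- row_max_sum(P)
    trace <- rbind(trace, data.frame(iter = t, K = nrow(features), CP = cp))
    if (cp > best$value) {
      best <- list(assignment = assignment, features = features, value = cp)
    }
    if (cp - cp_prev <= 1e-12) break
    cp_prev <- cp
  }
  list(assignment = best$assignment, features = best$features,
       value = best$value, K = nrow(best$features), trace = trace)
}

#' Split a module at the correlation-score threshold
#'
#' Units with correlation score >= `threshold` against the module's
#' feature go to the first submodule, units below it to the second (ties
#' at the threshold are assigned to the high side). An empty side makes
#' the split infeasible, which is signaled by returning `NULL` rather than
#' an error.
#'
#' @param fu A [enumerate_units()] result.
#' @param module List with `unit_ids` (indices into `fu`) and `feature`.
#' @param threshold Correlation-score split threshold (default 0.4).
#' @return `list(high = indices, low = indices, scores = numeric)` or
#'   `NULL` when infeasible.
#' @export
split_module <- function(fu, module, threshold = 0.4) {
  members <- module$unit_ids
  if (length(members) < 2) return(NULL)
  s <- score_units_mat(fu, rbind(module$feature))[members, 1]
  hi <- s >= threshold
  if (!any(hi) || all(hi)) return(NULL)
  list(high = members[hi], low = members[!hi], scores = s)
}

#' High-level controller: discounted split / removal search over module
#' counts
#'
#' Starts from a single module holding every functional unit and
#' alternates two actions. SPLIT: each current module is split at the
#' correlation-score threshold, every candidate state is re-optimized by
#' the low-level controller, and the best candidate is accepted when the
#' discounted reward `gamma * max V(s_{n+1}) - V(s_n)` is positive.
#' REMOVE: each module in turn is deleted (its units reassigned by the
#' low-level controller) and the best deletion is accepted when
#' `max V(s'_{n-1}) - value_store[n-1] > 0`, i.e. when it beats the best
#' value previously recorded for that module count. Removal is attempted
#' after every split round, accepted or not: deleting a module forces its
#' units through fresh greedy re-assignment, so the search backtracks out
#' of locally optimal partitions (typically fused module pairs that the
#' threshold split cannot bisect) and re-splits them along better lines.
#' The search terminates when neither action yields a positive reward.
#'
#' @param fu A [enumerate_units()] result.
#' @param gamma Discount factor limiting overfitting (default 0.995).
#' @param split_threshold Correlation-score threshold (default 0.4).
#' @param null Optional [corr_null()]; built from `B`, `seed` when `NULL`.
#' @param B,seed Permutation-null parameters.
#' @param max_rounds Safety cap on accepted actions.
#' @return Object of class `module_state`: `assignment`, `features`,
#'   `value`, `K`, `value_store` (best V per module count), and an action
#'   `trace`.
#' @export
high_level_search <- function(fu, gamma = 0.995, split_threshold = 0.4,
                              null = NULL, B = 1000L, seed = 1L,
                              max_rounds = NULL) {
  null <- null %||% corr_null(fu$n, B = B, seed = seed)
  n_units <- nrow(fu$units)
  max_rounds <- max_rounds %||% (4L * n_units)

  state <- low_level_assign(fu, rep(1L, n_units), null)
  vs <- list()
  vs[[as.character(state$K)]] <- state$value
  trace <- data.frame(step = 0L, action = "init", K = state$K,
                      V = state$value, stringsAsFactors = FALSE)
  step <- 0L

  repeat {
    step <- step + 1L
    if (step > max_rounds) break
    advanced <- FALSE
    K <- state$K

    # SPLIT: candidate states from splitting each module.  Each module
    # contributes its correlation-score threshold split and, as a second
    # candidate, a median-score split: a module holding two strongly
    # correlated sub-blocks can have every score above the threshold, and
    # only a bisecting initialization lets the low-level controller pull
    # the blocks apart.  The discounted reward still decides acceptance,
    # so spurious bisections (e.g. of a homogeneous module) are rejected.
    best_cand <- NULL
    if (K < n_units) {
      for (m in seq_len(K)) {
        members <- which(state$assignment == m)
        if (length(members) < 2) next
        sc <- score_units_mat(fu, rbind(state$features[m, ]))[members, 1]
        lows <- list()
        hi <- sc >= split_threshold
        if (any(hi) && !all(hi)) lows$threshold <- members[!hi]
        med <- sc < stats::median(sc)
        if (any(med)) lows$median <- members[med]
        for (low in lows) {
          cand <- state$assignment
          cand[low] <- K + 1L
          res <- low_level_assign(fu, cand, null)
          if (is.null(best_cand) || res$value > best_cand$value) {
            best_cand <- res
          }
        }
      }
    }
    if (!is.null(best_cand) &&
        gamma * best_cand$value - state$value > 0) {
      state <- best_cand
      k <- as.character(state$K)
      vs[[k]] <- max(vs[[k]] %||% -Inf, state$value)
      trace <- rbind(trace, data.frame(step = step, action = "split",
                                       K = state$K, V = state$value,
                                       stringsAsFactors = FALSE))
      advanced <- TRUE
    }

    # REMOVE: backtrack when deleting a module beats the stored value at
    # the lower module count
    K <- state$K
    if (K > 1) {
      best_rm <- NULL
      for (m in seq_len(K)) {
        res <- low_level_assign(fu,
                                state$features[-m, , drop = FALSE], null)
        if (is.null(best_rm) || res$value > best_rm$value) best_rm <- res
      }
      prev <- vs[[as.character(K - 1L)]] %||% -Inf
      if (best_rm$value - prev > 0) {
        state <- best_rm
        k <- as.character(state$K)
        vs[[k]] <- max(vs[[k]] %||% -Inf, state$value)
        step <- step + 1L
        trace <- rbind(trace, data.frame(step = step, action = "remove",
                                         K = state$K, V = state$value,
                                         stringsAsFactors = FALSE))
        advanced <- TRUE
      }
    }
    if (!advanced) break
  }
  structure(list(assignment = state$assignment, features = state$features,
                 value = state$value, K = state$K, value_store = vs,
                 trace = trace, null = null, gamma = gamma,
                 split_threshold = split_threshold),
            class = "module_state")
}

#' @export
print.module_state <- function(x, ...) {
  cat(sprintf("<module_state> %d modules over %d units, V = %.3f (%d actions)\n",
              x$K, length(x$assignment), x$value, nrow(x$trace) - 1L))
  invisible(x)
}

#' Value of an explicit unit-to-module assignment
#'
#' Computes the cumulative probability `CP = sum_i max_j P(u_i, M_j)` of a
#' state defined by an assignment vector, with module features recomputed
#' from the assignment. Useful for auditing the controllers against
#' exhaustive enumeration on small instances.
#'
#' @inheritParams low_level_assign
#' @param assignment Integer module index per unit (empty indices are
#'   compacted).
#' @return List with `value` (CP) and `features`.
#' @export
state_value <- function(fu, assignment, null) {
  assignment <- match(assignment, sort(unique(assignment)))
  features <- feature_matrix(fu, assignment)
  list(value = row_max_sum(prob_units_mat(fu, features, null)),
       features = features)
}

#' Final overlapping gene-level module assignment
#'
#' After the controllers terminate, every functional unit is placed in the
#' module with the highest correlation probability (ties to the lowest
#' module id, logged). A module's gene membership is the set of anchor
#' genes of its units: a gene acts through its functional units, and when
#' its single-gene and combined units land in different modules the gene
#' belongs to all of them — module overlap is a feature, not an error.
#' The union of the units' partner genes is kept alongside
#' (`partner_genes`) for network assembly, but a partner reference alone
#' does not make a gene a member: combined units of boundary genes
#' routinely cite partners from a neighboring module, and counting those
#' would systematically inflate every module.
#'
#' @param state A [high_level_search()] result.
#' @param fu The [enumerate_units()] result the search ran on.
#' @return Object of class `module_set`; each module holds `module_id`,
#'   `unit_ids`, `genes`, `anchor_genes`, `partner_genes`, `feature`, and
#'   per-gene absolute correlations `gene_scores`.
#' @export
finalize_assignment <- function(state, fu) {
  null <- state$null
  P <- prob_units_mat(fu, state$features, null)
  assign <- max.col(P, ties.method = "first")
  if (ncol(P) > 1) {
    mx <- P[cbind(seq_len(nrow(P)), assign)]
    nties <- sum(rowSums(abs(P - mx) < 1e-12) > 1)
    if (nties > 0) mn_log("final assignment: %d tie(s) broken to lowest module id", nties)
  }
  present <- sort(unique(assign))
  rg_abs <- abs(gene_cor_mat(fu$Z, state$features))

  mods <- list()
  for (j in seq_along(present)) {
    k <- present[j]
    uid <- which(assign == k)
    genes <- sort(unique(fu$units$anchor[uid]))
    partners <- sort(unique(unlist(lapply(fu$partners[uid], names))))
    scores <- rg_abs[genes, k]
    names(scores) <- genes
    mods[[sprintf("M%d", j)]] <- list(
      module_id = sprintf("M%d", j), unit_ids = uid, genes = genes,
      anchor_genes = genes, partner_genes = partners,
      feature = state$features[k, ], gene_scores = scores)
  }
  structure(list(modules = mods, n_samples = fu$n,
                 assignment = assign), class = "module_set")
}

#' @export
print.module_set <- function(x, ...) {
  cat(sprintf("<module_set> %d overlapping gene modules\n",
              length(x$modules)))
  for (m in x$modules) {
    cat(sprintf("  %-4s %4d genes (%d units)\n", m$module_id,
                length(m$genes), length(m$unit_ids)))
  }
  invisible(x)
}
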
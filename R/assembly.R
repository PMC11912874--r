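#' Assemble the typed interaction network of one module
#'
#' Collects every multilayer-network interaction whose two endpoints are
#' members of the module (the original typed edges, pre-rewiring). Member
#' genes left without any known in-module interaction are connected by
#' coexpression instead: edges to every in-module partner with
#' `|r| >= coexpr_threshold`, or to the single best partner when none
#' passes, so each measured member of a module of two or more genes ends
#' with degree at least 1.
#'
#' @param module A module from [finalize_assignment()], or a character
#'   vector of gene ids.
#' @param mln The [build_multilayer()] network.
#' @param expr Expression matrix.
#' @param coexpr_threshold Absolute-correlation threshold for fallback
#'   coexpression edges (default 0.6).
#' @return Object of class `module_network` with `module_id` and an
#'   `edges` data frame (`source, target, itype, weight, sign`).
#' @export
assemble_module_network <- function(module, mln, expr,
                                    coexpr_threshold = 0.6) {
  genes <- if (is.character(module)) module else module$genes
  module_id <- if (is.character(module)) "module" else module$module_id
  if (length(genes) == 0) stop("empty module")
  if (length(genes) == 1) {
    warning("single-gene module '", module_id, "': empty network")
    return(structure(list(module_id = module_id,
                          edges = data.frame(source = character(0),
                                             target = character(0),
                                             itype = character(0),
                                             weight = numeric(0),
                                             sign = integer(0))),
                     class = "module_network"))
  }
  e <- mln$edges
  keep <- e$node_a %in% genes & e$node_b %in% genes
  known <- e[keep, , drop = FALSE]
  edges <- data.frame(source = character(0), target = character(0),
                      itype = character(0), weight = numeric(0),
                      sign = integer(0), stringsAsFactors = FALSE)
  measured <- intersect(genes, rownames(expr))
  Z <- if (length(measured) >= 2)
    zscore_rows(expr[measured, , drop = FALSE]) else NULL
  edge_sign <- function(a, b) {
    if (!is.null(Z) && a %in% measured && b %in% measured) {
      ifelse(mean(Z[a, ] * Z[b, ]) >= 0, 1L, -1L)
    } else NA_integer_
  }
  if (nrow(known)) {
    key <- pair_key(known$node_a, known$node_b)
    known <- known[!duplicated(key), , drop = FALSE]
    edges <- data.frame(source = known$node_a, target = known$node_b,
                        itype = known$itype, weight = known$score,
                        sign = mapply(edge_sign, known$node_a, known$node_b),
                        stringsAsFactors = FALSE)
  }
  deg <- table(factor(c(edges$source, edges$target), levels = genes))
  lonely <- intersect(names(deg)[deg == 0], measured)
  for (g in lonely) {
    others <- setdiff(measured, g)
    if (length(others) == 0) next
    r <- vapply(others, function(o) mean(Z[g, ] * Z[o, ]), numeric(1))
    pass <- names(r)[abs(r) >= coexpr_threshold]
    if (length(pass) == 0) pass <- names(r)[order(-abs(r), names(r))][1]
    edges <- rbind(edges, data.frame(
      source = g, target = pass, itype = "coexpression",
      weight = abs(r[pass]), sign = ifelse(r[pass] >= 0, 1L, -1L),
      stringsAsFactors = FALSE))
  }
  key <- pair_key(edges$source, edges$target)
  edges <- edges[!duplicated(key), , drop = FALSE]
  edges <- edges[order(edges$source, edges$target), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(module_id = module_id, edges = edges),
            class = "module_network")
}

#' Cross-condition consensus network of co-moduled gene pairs
#'
#' A gene pair is connected in the consensus iff, in every condition
#' (e.g. every tumor stage), some module contains both genes; with
#' `min_conditions` the strict intersection is relaxed to pairs co-moduled
#' in at least that many conditions. When per-condition coregulatory
#' networks are supplied, each consensus edge is annotated with the union
#' of their regulator provenances — required by [scan_network()].
#'
#' @param module_sets List over conditions; each element a `module_set`
#'   or list of gene id vectors.
#' @param networks Optional list (recycled if length 1) of edge data
#'   frames with `source`, `target`, `provenance` columns, e.g. from
#'   [rewire_regulators()] or [weight_edges()].
#' @param min_conditions Minimum co-membership count (default: all).
#' @return Object of class `consensus_network`: `edges` data frame
#'   (`gene_a, gene_b, n_conditions`, per-condition module ids, and
#'   `provenance` when networks are given).
#' @export
build_consensus <- function(module_sets, networks = NULL,
                            min_conditions = NULL) {
  stopifnot(length(module_sets) >= 1)
  conds <- names(module_sets) %||% sprintf("condition%d",
                                           seq_along(module_sets))
  names(module_sets) <- conds
  need <- min_conditions %||% length(module_sets)

  per_cond <- lapply(module_sets, function(ms) {
    sets <- module_gene_sets(ms)
    keys <- list(); mods <- list()
    for (id in names(sets)) {
      g <- sort(unique(sets[[id]]))
      if (length(g) < 2) next
      pr <- utils::combn(g, 2)
      keys[[id]] <- paste(pr[1, ], pr[2, ], sep = "\r")
      mods[[id]] <- rep(id, ncol(pr))
    }
    k <- unlist(keys, use.names = FALSE)
    m <- unlist(mods, use.names = FALSE)
    tapply(m, k, paste, collapse = ";")
  })

  counts <- table(unlist(lapply(per_cond, names), use.names = FALSE))
  keys <- sort(names(counts)[counts >= need])
  if (length(keys) == 0) {
    warning("no gene pair is co-moduled in ", need, " condition(s)")
    return(structure(list(edges = data.frame(gene_a = character(0),
                                             gene_b = character(0)),
                          conditions = conds),
                     class = "consensus_network"))
  }
  ab <- do.call(rbind, strsplit(keys, "\r", fixed = TRUE))
  edges <- data.frame(gene_a = ab[, 1], gene_b = ab[, 2],
                      n_conditions = as.integer(counts[keys]),
                      stringsAsFactors = FALSE)
  for (cn in conds) {
    edges[[paste0("modules_", cn)]] <-
      unname(ifelse(keys %in% names(per_cond[[cn]]),
                    per_cond[[cn]][keys], NA_character_))
  }
  if (!is.null(networks)) {
    if (length(networks) == 1) networks <- rep(networks, length(conds))
    prov <- rep(NA_character_, nrow(edges))
    pm <- list()
    for (nw in networks) {
      nd <- as_edge_df(nw)
      if (is.null(nd$provenance)) next
      k <- pair_key(nd$source, nd$target)
      for (i in seq_len(nrow(nd))) {
        pm[[k[i]]] <- union(pm[[k[i]]],
                            strsplit(nd$provenance[i], ";",
                                     fixed = TRUE)[[1]])
      }
    }
    hit <- keys %in% names(pm)
    prov[hit] <- vapply(keys[hit],
                        function(k) paste(sort(pm[[k]]), collapse = ";"),
                        character(1))
    edges$provenance <- prov
  }
  rownames(edges) <- NULL
  structure(list(edges = edges, conditions = conds),
            class = "consensus_network")
}

#' @export
print.consensus_network <- function(x, ...) {
  cat(sprintf("<consensus_network> %d edges across %d condition(s): %s\n",
              nrow(x$edges), length(x$conditions),
              paste(x$conditions, collapse = ", ")))
  invisible(x)
}

#' Assemble a two-cell-type ligand-mediated crosstalk network
#'
#' Joins a sender-cell TF-to-ligand network, a ligand-to-receptor/TF
#' bridge set, and a receiver-cell TF-to-target network into the
#' three-tier structure sender TF -> ligand -> receiver TF/receptor ->
#' target. A bridge edge is retained only when its ligand has at least one
#' upstream sender TF and its receiver endpoint has at least one
#' downstream target, so the assembled network carries no dangling bridge.
#'
#' @param sender_net Edge data frame (`source` = sender TF, `target` =
#'   ligand) or `module_network`.
#' @param receiver_net Edge data frame (`source` = receiver TF, `target`
#'   = target gene) or `module_network`.
#' @param bridge_set [interaction_set()] (typically `ligand_receptor` or
#'   `ligand_tf`) or edge data frame, `source` = ligand, `target` =
#'   receiver endpoint.
#' @return Object of class `crosstalk_network` with `sender_edges`,
#'   `bridge_edges`, `receiver_edges`, and a `nodes` data frame with tier
#'   labels.
#' @export
assemble_crosstalk <- function(sender_net, receiver_net, bridge_set) {
  snd <- as_edge_df(sender_net)
  rcv <- as_edge_df(receiver_net)
  brd <- as_edge_df(bridge_set)

  keep <- brd$source %in% snd$target & brd$target %in% rcv$source
  if (!any(keep)) {
    warning("no bridge edge survives; empty crosstalk network")
  }
  brd <- brd[keep, , drop = FALSE]
  snd <- snd[snd$target %in% brd$source, , drop = FALSE]
  rcv <- rcv[rcv$source %in% brd$target, , drop = FALSE]

  tier_df <- function(nodes, tier) {
    data.frame(node = nodes, tier = rep(tier, length(nodes)),
               stringsAsFactors = FALSE)
  }
  nodes <- rbind(tier_df(unique(snd$source), "sender_tf"),
                 tier_df(unique(brd$source), "ligand"),
                 tier_df(unique(brd$target), "receiver_tf"),
                 tier_df(unique(rcv$target), "target"))
  nodes <- nodes[!duplicated(paste(nodes$node, nodes$tier)), , drop = FALSE]
  rownames(snd) <- rownames(brd) <- rownames(rcv) <- rownames(nodes) <- NULL
  structure(list(sender_edges = snd, bridge_edges = brd,
                 receiver_edges = rcv, nodes = nodes),
            class = "crosstalk_network")
}

#' @export
print.crosstalk_network <- function(x, ...) {
  cat(sprintf(
    "<crosstalk_network> %d sender, %d bridge, %d receiver edges\n",
    nrow(x$sender_edges), nrow(x$bridge_edges), nrow(x$receiver_edges)))
  invisible(x)
}

#' Hypergeometric enrichment of modules in user-supplied gene sets
#'
#' One-sided hypergeometric tail `P(X >= overlap)` of each (module, gene
#' set) pair against a background universe, with Benjamini-Hochberg
#' adjustment across all pairs. Gene sets with no background overlap are
#' skipped.
#'
#' @param modules `module_set` or (named) list of gene id vectors.
#' @param gene_sets Named list of gene id vectors, e.g. [read_gmt()].
#' @param background Character vector of background genes, or an
#'   expression matrix whose rownames define the universe.
#' @return Data frame `module, set, overlap, module_size, set_size,
#'   background_size, p, adjusted_p`, ordered by `p`.
#' @export
enrich_modules <- function(modules, gene_sets, background) {
  mods <- module_gene_sets(modules)
  if (is.matrix(background)) background <- rownames(background)
  background <- unique(as.character(background))
  N <- length(background)
  rows <- list()
  for (sname in names(gene_sets)) {
    set_bg <- intersect(gene_sets[[sname]], background)
    if (length(set_bg) == 0) {
      mn_log("gene set '%s' has no background overlap; skipped", sname)
      next
    }
    for (mname in names(mods)) {
      mod_bg <- intersect(mods[[mname]], background)
      k <- length(intersect(mod_bg, set_bg))
      p <- stats::phyper(k - 1, length(set_bg), N - length(set_bg),
                         length(mod_bg), lower.tail = FALSE)
      rows[[length(rows) + 1]] <- data.frame(
        module = mname, set = sname, overlap = k,
        module_size = length(mod_bg), set_size = length(set_bg),
        background_size = N, p = p, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) stop("no testable (module, set) pair")
  out <- do.call(rbind, rows)
  out$adjusted_p <- stats::p.adjust(out$p, method = "BH")
  out <- out[order(out$p, out$module, out$set), , drop = FALSE]
  rownames(out) <- NULL
  out
}
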
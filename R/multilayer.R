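#' Build a (k+1)-layer network from expression data and interaction sets
#'
#' Stacks gene layers (node set = the genes of `expr`) and functional
#' layers (regulators such as TFs, miRNAs, or ligands that may be absent
#' from the expression matrix) in the order given, with interactions only
#' between adjacent layers. Undirected gene-gene sets (`ppi`, undirected
#' `custom`) link two consecutive gene layers; directed regulatory sets
#' insert a functional layer holding the set's source molecules, followed
#' by a fresh gene layer holding their measured targets. Interactions whose
#' endpoints fall outside the relevant layers are dropped and counted.
#'
#' @param expr Expression matrix (genes x samples).
#' @param sets A single [interaction_set()] or (named) list of them.
#' @param layer_order Character vector naming each set once, outermost
#'   first; defaults to the order of `sets`.
#' @return Object of class `multilayer_network` with elements `layers`
#'   (list of `list(kind, name, nodes)`), `edges` (data frame
#'   `layer_a, node_a, layer_b, node_b, score, itype, set`), `drops`
#'   (per-set dropped/kept counts), and `genes`.
#' @export
build_multilayer <- function(expr, sets, layer_order = NULL) {
  if (inherits(sets, "interaction_set")) sets <- list(sets)
  if (is.null(names(sets)) || any(names(sets) == "")) {
    names(sets) <- vapply(sets, `[[`, character(1), "name")
  }
  if (anyDuplicated(names(sets))) stop("interaction set names must be unique")
  layer_order <- layer_order %||% names(sets)
  if (!setequal(layer_order, names(sets)) ||
      length(layer_order) != length(sets)) {
    stop("layer_order must name each interaction set exactly once")
  }

  genes <- rownames(expr)
  layers <- list(list(kind = "gene", name = "genes_1", nodes = genes))
  edge_rows <- list()
  drops <- data.frame(set = character(0), kept = integer(0),
                      dropped = integer(0), stringsAsFactors = FALSE)

  for (sname in layer_order) {
    s <- sets[[sname]]
    e <- s$edges
    regulatory <- s$directed
    top <- length(layers)
    if (!regulatory) {
      keep <- e$source %in% genes & e$target %in% genes
      layers[[top + 1]] <- list(kind = "gene",
                                name = sprintf("genes_%d", top + 1),
                                nodes = genes)
      if (any(keep)) {
        edge_rows[[length(edge_rows) + 1]] <- data.frame(
          layer_a = top, node_a = e$source[keep],
          layer_b = top + 1, node_b = e$target[keep],
          score = e$score[keep], itype = s$itype, set = sname,
          stringsAsFactors = FALSE)
      }
    } else {
      keep <- e$target %in% genes
      regs <- sort(unique(e$source[keep]))
      layers[[top + 1]] <- list(kind = "functional",
                                name = sprintf("%s_regulators", sname),
                                nodes = regs)
      layers[[top + 2]] <- list(kind = "gene",
                                name = sprintf("genes_%d", top + 2),
                                nodes = genes)
      if (any(keep)) {
        edge_rows[[length(edge_rows) + 1]] <- data.frame(
          layer_a = top + 1, node_a = e$source[keep],
          layer_b = top + 2, node_b = e$target[keep],
          score = e$score[keep], itype = s$itype, set = sname,
          stringsAsFactors = FALSE)
      }
    }
    drops <- rbind(drops, data.frame(set = sname, kept = sum(keep),
                                     dropped = sum(!keep),
                                     stringsAsFactors = FALSE))
    if (any(!keep)) {
      mn_log("set '%s': dropped %d interaction(s) outside the layers",
             sname, sum(!keep))
    }
  }
  edges <- if (length(edge_rows)) do.call(rbind, edge_rows) else
    data.frame()
  if (nrow(edges) == 0) {
    stop("no interaction survives layer restriction; empty multilayer network")
  }
  rownames(edges) <- NULL
  structure(list(layers = layers, edges = edges, drops = drops,
                 genes = genes),
            class = "multilayer_network")
}

#' @export
print.multilayer_network <- function(x, ...) {
  cat(sprintf("<multilayer_network> %d layers, %d interlayer edges\n",
              length(x$layers), nrow(x$edges)))
  for (i in seq_along(x$layers)) {
    l <- x$layers[[i]]
    cat(sprintf("  [%d] %-12s %-18s %d nodes\n", i, l$kind, l$name,
                length(l$nodes)))
  }
  invisible(x)
}

#' Rewire regulator-target interactions into coregulatory edges
#'
#' Removes every functional layer and connects the gene layers on its two
#' sides: each regulator `R` with measured targets `t1..tm` contributes the
#' complete graph of coregulatory edges `ti - tj` with provenance `R` and
#' prior score `min(S(R, ti), S(R, tj))` (conservative combination of the
#' two regulator-target priors). Direct gene-layer-gene-layer edges pass
#' through unchanged with provenance `direct:<set>`. A regulator that is
#' itself measured additionally keeps its own regulator-target edges as
#' direct gene-level edges, so it participates both as a node and through
#' the coregulation it induces. Edges arising from several sources are
#' collapsed to one row per gene pair (maximum score, all provenances
#' recorded, `;`-separated).
#'
#' @param mln A [build_multilayer()] result.
#' @param expr Expression matrix the network was built against.
#' @return Data frame `source, target, score, itype, provenance`
#'   (undirected gene-level edges).
#' @export
rewire_regulators <- function(mln, expr) {
  stopifnot(inherits(mln, "multilayer_network"))
  genes <- rownames(expr)
  e <- mln$edges
  kinds <- vapply(mln$layers, `[[`, character(1), "kind")
  out <- list()

  direct <- kinds[e$layer_a] == "gene" & kinds[e$layer_b] == "gene"
  if (any(direct)) {
    d <- e[direct, , drop = FALSE]
    out[[length(out) + 1]] <- data.frame(
      source = d$node_a, target = d$node_b, score = d$score,
      itype = d$itype, provenance = paste0("direct:", d$set),
      stringsAsFactors = FALSE)
  }

  func_edges <- e[kinds[e$layer_a] == "functional", , drop = FALSE]
  if (nrow(func_edges)) {
    by_reg <- split(seq_len(nrow(func_edges)),
                    paste(func_edges$layer_a, func_edges$node_a, sep = "\r"))
    for (idx in by_reg) {
      reg <- func_edges$node_a[idx[1]]
      set <- func_edges$set[idx[1]]
      ity <- func_edges$itype[idx[1]]
      tgt <- func_edges$node_b[idx]
      sc <- func_edges$score[idx]
      keep <- !duplicated(tgt)
      tgt <- tgt[keep]
      sc <- sc[keep]
      o <- order(tgt)
      tgt <- tgt[o]
      sc <- sc[o]
      if (reg %in% genes) {
        # measured regulator: keep its own regulator-target edges too
        out[[length(out) + 1]] <- data.frame(
          source = reg, target = tgt, score = sc, itype = ity,
          provenance = paste0("direct:", set), stringsAsFactors = FALSE)
      }
      if (length(tgt) >= 2) {
        pr <- utils::combn(length(tgt), 2)
        out[[length(out) + 1]] <- data.frame(
          source = tgt[pr[1, ]], target = tgt[pr[2, ]],
          score = pmin(sc[pr[1, ]], sc[pr[2, ]]),
          itype = "coreg", provenance = reg, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) stop("rewiring produced no gene-level edges")
  edges <- do.call(rbind, out)
  edges <- edges[edges$source != edges$target, , drop = FALSE]

  key <- pair_key(edges$source, edges$target)
  sp <- split(seq_len(nrow(edges)), key)
  res <- lapply(sp, function(idx) {
    sub <- edges[idx, , drop = FALSE]
    ity <- unique(sub$itype)
    data.frame(source = min(sub$source[1], sub$target[1]),
               target = max(sub$source[1], sub$target[1]),
               score = max(sub$score),
               itype = if (any(ity != "coreg")) ity[ity != "coreg"][1] else
                 "coreg",
               provenance = paste(sort(unique(unlist(
                 strsplit(sub$provenance, ";", fixed = TRUE)))),
                 collapse = ";"),
               stringsAsFactors = FALSE)
  })
  edges <- do.call(rbind, res)
  edges <- edges[order(edges$source, edges$target), , drop = FALSE]
  rownames(edges) <- NULL
  edges
}
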
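#' Enumerate single-gene and combined functional units
#'
#' Every measured gene yields one single-gene unit (its own z-scored
#' pattern). A gene with weighted neighbors additionally yields one
#' combined unit per provenance group — the neighbors that share one
#' originating regulator or direct interaction source — plus one combined
#' unit over all neighbors, mirroring the way a gene can act alone, with
#' one interacting partner set, or with all of its coregulatory partners.
#' Combined units carry the anchor's softmax weights renormalized over the
#' chosen partner subset (summing to 1); partner lists are truncated to the
#' `max_partners` highest-weight partners. Units with identical weighted
#' partner sets are deduplicated globally: such units have identical
#' expression patterns (the pattern depends only on the partners), and
#' keeping one copy per target of a popular regulator would over-weight
#' that single pattern in the module search.
#'
#' Reference interactions are not specific to the expression data at hand,
#' so neighbors whose correlation with the anchor is indistinguishable
#' from the permutation null are excluded from combined units: a partner
#' is kept only when the null percentile of its edge correlation is at
#' least `min_partner_sig` (default 0.95, i.e. significant at the 0.05
#' level). This suppresses false-positive units from decoy or
#' condition-irrelevant interactions while leaving data-consistent
#' partners untouched.
#'
#' @param net A [weight_edges()] result (`coreg_network`).
#' @param expr Expression matrix.
#' @param max_partners Maximum partners per combined unit (default 10).
#' @param min_partner_sig Minimum null percentile of the anchor-partner
#'   correlation for a neighbor to enter combined units (default 0.95; 0
#'   disables the filter).
#' @return Object of class `functional_units`: `units` (data frame
#'   `unit_id, anchor, kind, group, n_partners`), `partners` (list of named
#'   weight vectors), `A` (units x genes weight matrix), `patterns`
#'   (units x samples matrix `A %*% Z`), `genes`, `Z` (z-scored
#'   expression), `n` (sample count).
#' @export
enumerate_units <- function(net, expr, max_partners = 10L,
                            min_partner_sig = 0.95) {
  stopifnot(inherits(net, "coreg_network"))
  genes <- rownames(expr)
  Z <- zscore_rows(expr)
  e <- net$edges
  if (!is.null(e$pct) && min_partner_sig > 0) {
    dropped <- sum(e$pct < min_partner_sig)
    if (dropped > 0) {
      mn_log("unit enumeration: %d of %d directed edges below the %.2f significance floor",
             dropped, nrow(e), min_partner_sig)
    }
    e <- e[e$pct >= min_partner_sig, , drop = FALSE]
  }
  by_src <- split(seq_len(nrow(e)), e$source)

  ids <- character(0); anchors <- character(0); kinds <- character(0)
  groups <- character(0); plist <- list()
  seen_global <- character(0)

  for (g in genes) {
    ids <- c(ids, paste0(g, "::single"))
    anchors <- c(anchors, g)
    kinds <- c(kinds, "single")
    groups <- c(groups, "")
    plist[length(plist) + 1] <- list(NULL)

    idx <- by_src[[g]]
    if (is.null(idx)) next
    tgt <- e$target[idx]
    W <- e$W[idx]
    prov <- strsplit(e$provenance[idx], ";", fixed = TRUE)

    tags <- sort(unique(unlist(prov)))
    cand <- lapply(tags, function(tg) {
      which(vapply(prov, function(p) tg %in% p, logical(1)))
    })
    names(cand) <- tags
    cand$all <- seq_along(idx)

    for (tg in names(cand)) {
      sel <- cand[[tg]]
      ord <- order(-W[sel], tgt[sel])
      sel <- sel[ord][seq_len(min(length(sel), max_partners))]
      # a combined unit is identified by its weighted partner set: units
      # with identical partner sets have identical expression patterns and
      # would otherwise be counted several times over (e.g. one copy per
      # target of a shared regulator), over-weighting that pattern in the
      # module search
      w_sig <- W[sel] / sum(W[sel])
      sig <- paste(paste(sort(tgt[sel]), collapse = "\r"),
                   paste(sprintf("%.9f", w_sig[order(tgt[sel])]),
                         collapse = "\r"), sep = "\n")
      if (sig %in% seen_global) next
      seen_global <- c(seen_global, sig)
      w <- W[sel] / sum(W[sel])
      names(w) <- tgt[sel]
      ids <- c(ids, paste0(g, "::", tg))
      anchors <- c(anchors, g)
      kinds <- c(kinds, "combined")
      groups <- c(groups, tg)
      plist[[length(plist) + 1]] <- w
    }
  }

  A <- matrix(0, nrow = length(ids), ncol = length(genes),
              dimnames = list(ids, genes))
  for (i in seq_along(ids)) {
    if (kinds[i] == "single") {
      A[i, anchors[i]] <- 1
    } else {
      A[i, names(plist[[i]])] <- plist[[i]]
    }
  }
  units <- data.frame(unit_id = ids, anchor = anchors, kind = kinds,
                      group = groups,
                      n_partners = vapply(plist, length, integer(1)),
                      stringsAsFactors = FALSE)
  rownames(units) <- NULL
  structure(list(units = units, partners = plist, A = A,
                 patterns = A %*% Z, genes = genes, Z = Z, n = ncol(Z)),
            class = "functional_units")
}

#' @export
print.functional_units <- function(x, ...) {
  cat(sprintf(
    "<functional_units> %d units (%d single, %d combined) over %d genes, %d samples\n",
    nrow(x$units), sum(x$units$kind == "single"),
    sum(x$units$kind == "combined"), length(x$genes), x$n))
  invisible(x)
}

# extract one unit as a plain list (anchor, kind, partners = named weights)
fu_unit <- function(fu, i) {
  if (is.character(i)) i <- match(i, fu$units$unit_id)
  list(unit_id = fu$units$unit_id[i], anchor = fu$units$anchor[i],
       kind = fu$units$kind[i], partners = fu$partners[[i]])
}

#' Expression pattern of a functional unit
#'
#' A single-gene unit's pattern is the z-scored row of its anchor. A
#' combined unit's pattern is the weighted average
#' `sum_i w_i * zscore(partner_i)` with the weights renormalized to sum to
#' 1 over the unit's partners, so it lies componentwise in the convex hull
#' of the partner z-patterns.
#'
#' @param unit A list with `anchor`, `kind`, and (for combined units)
#'   `partners` = named weight vector, as stored by [enumerate_units()].
#' @param expr Expression matrix containing every referenced gene row.
#' @return Numeric pattern of length `ncol(expr)`.
#' @export
unit_pattern <- function(unit, expr) {
  if (identical(unit$kind, "single")) {
    if (!unit$anchor %in% rownames(expr)) {
      stop("anchor '", unit$anchor, "' absent from expression matrix")
    }
    return(unname(zscore(expr[unit$anchor, ])))
  }
  w <- unit$partners
  if (is.null(w) || length(w) == 0) stop("combined unit without partners")
  missing <- setdiff(names(w), rownames(expr))
  if (length(missing)) {
    stop("partner absent from expression matrix: ",
         paste(missing, collapse = ", "))
  }
  w <- w / sum(w)
  pat <- numeric(ncol(expr))
  for (p in names(w)) pat <- pat + w[[p]] * zscore(expr[p, ])
  unname(pat)
}
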
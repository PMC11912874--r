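#' Per-patient coregulation-similarity scores
#'
#' All rows are z-scored so every gene carries the same weight; the score
#' of patient `j` is the squared deviation of the target from each
#' coregulatory partner, summed over partners:
#' `S_j = sum_p (v_target,j - v_p,j)^2`. With exactly two partners this is
#' `(v1j - v2j)^2 + (v1j - v3j)^2`; the sum generalizes it to any partner
#' count. A high `S_j` means the target has escaped the shared expression
#' pattern of its partners in that patient.
#'
#' Coregulation can be negative as well as positive (repressed targets),
#' and the deviation statistic presumes a common orientation, so by
#' default each partner's z-row is flipped to the sign of its correlation
#' with the target before the deviations are taken — the same
#' absolute-orientation convention the module machinery applies through
#' `|r|`. The flip uses expression only, never survival, so the
#' downstream log-rank calibration is unaffected.
#'
#' @param target_row Raw expression of the target gene across patients.
#' @param partner_rows Matrix of raw partner expression (partners x
#'   patients), at least 2 rows.
#' @param align_signs Flip anti-correlated partners onto the target's
#'   orientation (default `TRUE`).
#' @return Non-negative numeric vector `S`, one score per patient.
#' @export
similarity_scores <- function(target_row, partner_rows,
                              align_signs = TRUE) {
  if (is.vector(partner_rows)) partner_rows <- rbind(partner_rows)
  if (nrow(partner_rows) < 2) stop("insufficient coregulatory partners")
  if (ncol(partner_rows) != length(target_row)) {
    stop("target and partners must cover the same patients")
  }
  zt <- zscore(target_row)
  zp <- zscore_rows(partner_rows)
  if (align_signs) {
    flip <- ifelse(as.vector(zp %*% zt) >= 0, 1, -1)
    zp <- zp * flip
  }
  d <- sweep(zp, 2, zt)
  S <- colSums(d^2)
  names(S) <- names(target_row) %||% colnames(partner_rows)
  S
}

#' Rank-split log-rank test
#'
#' Ranks patients by a score, compares the top-ranked fraction against the
#' bottom-ranked fraction with the standard log-rank test (chi-square,
#' 1 df), and reports which group has the worse survival (the lower
#' Kaplan-Meier curve, read off observed minus expected events). Cohorts
#' that cannot be split — a constant score, a group below `min_group`
#' patients, or a group without any event — are flagged untestable instead
#' of raising.
#'
#' @param S Numeric score per patient; names, when present, are matched
#'   against `survival$sample_id`.
#' @param survival Data frame `sample_id, time, event` ([read_survival()]).
#' @param split_fraction Fraction of patients in each of the two compared
#'   groups (default 0.5: median split).
#' @param min_group Minimum patients per group (default 10).
#' @return List `p, statistic, direction ("top"/"bottom" = worse group),
#'   n_top, n_bottom, untestable, reason`.
#' @export
logrank_rank_test <- function(S, survival, split_fraction = 0.5,
                              min_group = 10L) {
  if (!is.null(names(S))) {
    common <- intersect(names(S), survival$sample_id)
    survival <- survival[match(common, survival$sample_id), , drop = FALSE]
    S <- S[common]
  } else if (length(S) != nrow(survival)) {
    stop("unnamed score vector must match survival rows")
  }
  n <- length(S)
  untestable <- function(reason) {
    list(p = NA_real_, statistic = NA_real_, direction = NA_character_,
         n_top = NA_integer_, n_bottom = NA_integer_, untestable = TRUE,
         reason = reason)
  }
  n_g <- floor(n * split_fraction)
  if (n_g < 1) return(untestable("cohort too small to split"))
  if (diff(range(S)) < 1e-15) return(untestable("degenerate ranking: constant scores"))
  if (n_g < min_group) return(untestable("group below min_group"))

  ord <- order(-S, survival$sample_id)
  grp <- rep(NA_character_, n)
  grp[ord[seq_len(n_g)]] <- "top"
  grp[ord[seq.int(n - n_g + 1L, n)]] <- "bottom"
  keep <- !is.na(grp)
  df <- data.frame(time = survival$time[keep], event = survival$event[keep],
                   grp = factor(grp[keep], levels = c("top", "bottom")))
  ev <- tapply(df$event, df$grp, sum)
  if (any(ev == 0)) return(untestable("no events in one group"))

  sd <- survival::survdiff(survival::Surv(time, event) ~ grp, data = df)
  p <- stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE)
  # group with observed > expected events sits on the lower KM curve
  worse <- if ((sd$obs[1] - sd$exp[1]) >= 0) "top" else "bottom"
  list(p = unname(p), statistic = unname(sd$chisq), direction = worse,
       n_top = n_g, n_bottom = n_g, untestable = FALSE, reason = NA_character_)
}

#' Conventional expression-based survival baseline
#'
#' The same rank-split log-rank machinery as [logrank_rank_test()], but
#' ranking patients by the raw expression of one gene instead of the
#' network similarity score. Used to ask which network-detected relations
#' would evade a conventional single-gene survival analysis.
#'
#' @param gene_row Named expression vector of one gene across patients.
#' @inheritParams logrank_rank_test
#' @return As [logrank_rank_test()].
#' @export
expression_survival_baseline <- function(gene_row, survival,
                                         split_fraction = 0.5,
                                         min_group = 10L) {
  logrank_rank_test(gene_row, survival, split_fraction = split_fraction,
                    min_group = min_group)
}

#' Network-based survival scan over regulator-target relations
#'
#' For every regulator `t` recorded in the consensus provenance and every
#' target `g1` with at least two co-targets of `t` in the same consensus
#' module, the scan computes the per-patient similarity scores of `g1`
#' against those co-targets ([similarity_scores()]), runs the rank-split
#' log-rank test, and adjusts across all tested relations by
#' Benjamini-Hochberg. A significant relation means the breakdown of
#' `t -> g1` regulation stratifies patient survival even when neither
#' gene's raw expression does.
#'
#' @param consensus A [build_consensus()] result whose edges carry
#'   regulator `provenance` annotations.
#' @param expr Expression matrix (patients in columns).
#' @param survival Survival table ([read_survival()]).
#' @param fdr FDR threshold flagging hits (default 0.05).
#' @param split_fraction,min_group Passed to [logrank_rank_test()].
#' @param max_partners Cap on co-targets per relation, keeping the ones
#'   most correlated with the target (default 10).
#' @return Data frame of class `relation_scan`: one row per tested
#'   relation (`regulator, target, n_partners, partners, p, direction,
#'   adjusted_p, hit`), ordered by `adjusted_p`; untestable relations keep
#'   `NA` p-values.
#' @export
scan_network <- function(consensus, expr, survival, fdr = 0.05,
                         split_fraction = 0.5, min_group = 10L,
                         max_partners = 10L) {
  edges <- if (inherits(consensus, "consensus_network")) consensus$edges
    else as_edge_df(consensus)
  if (!"gene_a" %in% names(edges)) {
    edges$gene_a <- edges$source
    edges$gene_b <- edges$target
  }
  if (is.null(edges$provenance)) {
    stop("consensus network carries no regulator provenance; ",
         "rebuild with build_consensus(..., networks = )")
  }
  common <- intersect(colnames(expr), survival$sample_id)
  if (length(common) < 4) stop("too few patients shared by expr and survival")
  expr <- expr[, common, drop = FALSE]
  survival <- survival[match(common, survival$sample_id), , drop = FALSE]

  prov <- strsplit(ifelse(is.na(edges$provenance), "", edges$provenance),
                   ";", fixed = TRUE)
  tags <- sort(unique(unlist(prov)))
  regulators <- tags[!startsWith(tags, "direct:") & tags != ""]

  rows <- list()
  for (R in regulators) {
    sel <- vapply(prov, function(p) R %in% p, logical(1))
    sub <- edges[sel, , drop = FALSE]
    genes <- sort(unique(c(sub$gene_a, sub$gene_b)))
    genes <- genes[genes %in% rownames(expr)]
    for (g1 in genes) {
      partners <- sort(unique(c(sub$gene_b[sub$gene_a == g1],
                                sub$gene_a[sub$gene_b == g1])))
      partners <- partners[partners %in% rownames(expr)]
      if (length(partners) < 2) next
      if (length(partners) > max_partners) {
        r <- vapply(partners, function(p) {
          abs(stats::cor(expr[g1, ], expr[p, ]))
        }, numeric(1))
        partners <- partners[order(-r, partners)][seq_len(max_partners)]
        partners <- sort(partners)
      }
      S <- similarity_scores(expr[g1, ], expr[partners, , drop = FALSE])
      lt <- logrank_rank_test(S, survival,
                              split_fraction = split_fraction,
                              min_group = min_group)
      rows[[length(rows) + 1]] <- data.frame(
        regulator = R, target = g1, n_partners = length(partners),
        partners = paste(partners, collapse = ";"),
        p = lt$p, direction = lt$direction %||% NA_character_,
        untestable = lt$untestable, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    mn_log("survival scan: no relation with >= 2 co-targets", level = "WARN")
    out <- data.frame(regulator = character(0), target = character(0),
                      n_partners = integer(0), partners = character(0),
                      p = numeric(0), direction = character(0),
                      untestable = logical(0), adjusted_p = numeric(0),
                      hit = logical(0))
    class(out) <- c("relation_scan", class(out))
    attr(out, "fdr") <- fdr
    return(out)
  }
  out <- do.call(rbind, rows)
  out$adjusted_p <- NA_real_
  testable <- !out$untestable
  out$adjusted_p[testable] <- stats::p.adjust(out$p[testable], method = "BH")
  out$hit <- !is.na(out$adjusted_p) & out$adjusted_p < fdr
  out <- out[order(out$adjusted_p, out$regulator, out$target), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("relation_scan", class(out))
  attr(out, "fdr") <- fdr
  out
}

#' Compare network-based hits with the expression-only baseline
#'
#' For every tested relation, runs the conventional expression-based
#' survival analysis on the target (and on the regulator when it is
#' measured) and reports which network-detected relations would evade the
#' expression-only screen.
#'
#' @param scan A [scan_network()] result.
#' @param expr,survival As in [scan_network()].
#' @param fdr FDR threshold applied to the baseline p-values (BH across
#'   the scanned targets).
#' @param split_fraction Passed to [expression_survival_baseline()].
#' @return `scan` with extra columns `baseline_p, baseline_adjusted_p,
#'   baseline_hit, network_only`.
#' @export
baseline_comparison <- function(scan, expr, survival, fdr = 0.05,
                                split_fraction = 0.5) {
  common <- intersect(colnames(expr), survival$sample_id)
  expr <- expr[, common, drop = FALSE]
  survival <- survival[match(common, survival$sample_id), , drop = FALSE]
  bp <- vapply(scan$target, function(g) {
    if (!g %in% rownames(expr)) return(NA_real_)
    expression_survival_baseline(expr[g, ], survival,
                                 split_fraction = split_fraction)$p
  }, numeric(1))
  scan$baseline_p <- unname(bp)
  scan$baseline_adjusted_p <- stats::p.adjust(scan$baseline_p, method = "BH")
  scan$baseline_hit <- !is.na(scan$baseline_adjusted_p) &
    scan$baseline_adjusted_p < fdr
  scan$network_only <- scan$hit & !scan$baseline_hit
  scan
}
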
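#' Weight coregulatory edges by softmax of prior x correlation probability
#'
#' For a gene `G0` with neighbors `G1..Gk`, the directed weight of the
#' edge towards `Gi` is
#' `W_{0,i} = exp(S_{0,i} * P_{0,i}) / sum_j exp(S_{0,j} * P_{0,j})`,
#' where `S` is the prior confidence score in \[0, 1\] and `P` the
#' correlation probability of [correlation_probability()]. Weights out of
#' every node therefore sum to 1. Each edge also carries the Pearson
#' correlation `r` of its endpoints and its sign; probabilities always use
#' `|r|`, so anti-correlated partners are retained with `sign = -1`.
#'
#' `strict = TRUE` switches the denominator to
#' `sum_j exp(S_{0,i} * P_{0,j})` (the neighbor's own prior replaced by a
#' fixed `S_{0,i}` in every term), an asymmetric normalization variant
#' kept for comparison; the default pairs each neighbor's own prior with
#' its own probability, the only form in which the denominator terms are
#' neighbor-consistent.
#'
#' @param edges Undirected edge data frame from [rewire_regulators()]
#'   (columns `source`, `target`, `score`, plus optional `itype`,
#'   `provenance`).
#' @param expr Expression matrix; every edge endpoint must be a row.
#' @param null Optional [corr_null()]; built from `B`, `seed` when `NULL`.
#' @param B,seed Permutation-null parameters.
#' @param strict Use the literal alternative denominator (see above).
#' @return Object of class `coreg_network`: `nodes`, directed `edges`
#'   data frame (`source, target, S, P, W, r, sign, itype, provenance`),
#'   sample count `n`, and the `null` used.
#' @export
weight_edges <- function(edges, expr, null = NULL, B = 1000L, seed = 1L,
                         strict = FALSE) {
  edges <- as_edge_df(edges)
  if (nrow(edges) == 0) stop("no edges to weight")
  if (is.null(edges$score)) edges$score <- 1
  nodes <- sort(union(edges$source, edges$target))
  missing <- setdiff(nodes, rownames(expr))
  if (length(missing)) {
    stop("edge endpoints absent from expression matrix: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  null <- null %||% corr_null(ncol(expr), B = B, seed = seed)
  Z <- zscore_rows(expr[nodes, , drop = FALSE])
  n <- ncol(Z)

  r <- rowSums(Z[edges$source, , drop = FALSE] *
                 Z[edges$target, , drop = FALSE]) / n
  pct <- percentile_from_r(abs(r), null)
  P <- prob_from_r(abs(r), null)

  dir_df <- data.frame(
    source = c(edges$source, edges$target),
    target = c(edges$target, edges$source),
    S = rep(edges$score, 2), P = rep(P, 2), pct = rep(pct, 2),
    r = rep(r, 2),
    itype = rep(edges$itype %||% "interaction", 2),
    provenance = rep(edges$provenance %||% "direct", 2),
    stringsAsFactors = FALSE)
  dir_df$sign <- ifelse(dir_df$r >= 0, 1L, -1L)

  dir_df <- dir_df[order(dir_df$source, dir_df$target), , drop = FALSE]
  dir_df$W <- NA_real_
  for (idx in split(seq_len(nrow(dir_df)), dir_df$source)) {
    S <- dir_df$S[idx]
    P <- dir_df$P[idx]
    if (strict) {
      # denominator sum_j exp(S_i * P_j): one normalizer per neighbor i
      dir_df$W[idx] <- vapply(seq_along(idx), function(i) {
        exp(S[i] * P[i]) / sum(exp(S[i] * P))
      }, numeric(1))
    } else {
      w <- exp(S * P)
      dir_df$W[idx] <- w / sum(w)
    }
  }
  rownames(dir_df) <- NULL
  structure(list(nodes = nodes,
                 edges = dir_df[, c("source", "target", "S", "P", "pct",
                                    "W", "r", "sign", "itype",
                                    "provenance")],
                 n = n, null = null, strict = strict),
            class = "coreg_network")
}

#' @export
print.coreg_network <- function(x, ...) {
  cat(sprintf(
    "<coreg_network> %d nodes, %d directed weighted edges (n = %d samples)%s\n",
    length(x$nodes), nrow(x$edges), x$n,
    if (isTRUE(x$strict)) " [strict normalization]" else ""))
  invisible(x)
}
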
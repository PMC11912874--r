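# deterministic fixture builders used across the test files

# k mean-zero, population-unit-variance, mutually orthogonal patterns of
# length n (orthogonalized by QR after centering, so their pairwise Pearson
# correlations are exactly 0)
orthonormal_patterns <- function(n, k, seed = 42) {
  set.seed(seed)
  X <- matrix(rnorm(n * k), n, k)
  X <- sweep(X, 2, colMeans(X))
  Q <- qr.Q(qr(X))
  apply(Q, 2, function(v) v / sqrt(mean((v - mean(v))^2)))
}

# pattern with exact Pearson correlation r to f (f, g orthonormal pop-z)
pattern_with_r <- function(f, g, r) r * f + sqrt(1 - r^2) * g

# small expression matrix from a named list of numeric rows
expr_from_rows <- function(rows, samples = NULL) {
  m <- do.call(rbind, rows)
  rownames(m) <- names(rows)
  colnames(m) <- samples %||% sprintf("S%02d", seq_len(ncol(m)))
  expression_matrix(m)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_tsv_lines <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(lines, path)
  path
}

# functional_units object built directly from a list of patterns: each
# entry either a gene name (single unit) or list(anchor=, partners=named
# weights); expr supplies the rows
fu_from_spec <- function(expr, specs) {
  Z <- t(apply(unclass(expr), 1, function(v) (v - mean(v)) / sqrt(mean((v - mean(v))^2))))
  genes <- rownames(expr)
  n <- ncol(expr)
  ids <- character(0); anchors <- character(0); kinds <- character(0)
  plist <- list()
  A <- matrix(0, 0, length(genes), dimnames = list(NULL, genes))
  for (sp in specs) {
    if (is.character(sp)) {
      ids <- c(ids, paste0(sp, "::single"))
      anchors <- c(anchors, sp); kinds <- c(kinds, "single")
      plist[length(plist) + 1] <- list(NULL)
      row <- numeric(length(genes)); names(row) <- genes; row[sp] <- 1
      A <- rbind(A, row)
    } else {
      w <- sp$partners / sum(sp$partners)
      ids <- c(ids, paste0(sp$anchor, "::", paste(names(w), collapse = "+")))
      anchors <- c(anchors, sp$anchor); kinds <- c(kinds, "combined")
      plist[[length(plist) + 1]] <- w
      row <- numeric(length(genes)); names(row) <- genes; row[names(w)] <- w
      A <- rbind(A, row)
    }
  }
  rownames(A) <- ids
  structure(list(units = data.frame(unit_id = ids, anchor = anchors,
                                    kind = kinds, group = "",
                                    n_partners = lengths(plist),
                                    stringsAsFactors = FALSE),
                 partners = plist, A = A, patterns = A %*% Z,
                 genes = genes, Z = Z, n = n),
            class = "functional_units")
}

# exhaustive CP maximum over all assignments of units to at most k modules
brute_force_best_cp <- function(fu, k, null) {
  n_units <- nrow(fu$units)
  grid <- do.call(expand.grid, rep(list(seq_len(k)), n_units))
  best <- -Inf
  for (i in seq_len(nrow(grid))) {
    v <- state_value(fu, as.integer(grid[i, ]), null)$value
    if (v > best) best <- v
  }
  best
}
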
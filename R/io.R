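#' Read a genes x samples expression matrix
#'
#' Expects TSV or CSV (chosen from the file extension, `.csv` = comma) with
#' gene identifiers in the first column and sample identifiers in the
#' header. Rows with more than 50% missing values are dropped; remaining
#' missing values are handled by `na_policy`: `"row_mean"` (default)
#' imputes the mean of the observed entries of the row, `"drop"` removes
#' any row with a missing value, `"zero"` sets them to 0. Constant rows are
#' dropped with a warning because downstream z-scoring requires variance.
#'
#' @param path File path.
#' @param na_policy One of `"row_mean"`, `"drop"`, `"zero"`.
#' @param sep Field separator; default inferred from the extension.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path, na_policy = c("row_mean", "drop", "zero"),
                            sep = NULL) {
  na_policy <- match.arg(na_policy)
  if (is.null(sep)) {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "",
                          comment.char = "", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 3) stop("expression matrix needs >= 2 samples")
  genes <- as.character(df[[1]])
  if (anyDuplicated(genes)) {
    stop("duplicate gene id: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- genes

  frac_na <- rowMeans(is.na(m))
  if (any(frac_na > 0.5)) {
    mn_log("dropping %d gene rows with >50%% missing values",
           sum(frac_na > 0.5))
    m <- m[frac_na <= 0.5, , drop = FALSE]
  }
  if (anyNA(m)) {
    if (na_policy == "drop") {
      m <- m[!apply(is.na(m), 1, any), , drop = FALSE]
    } else if (na_policy == "zero") {
      m[is.na(m)] <- 0
    } else {
      idx <- which(apply(is.na(m), 1, any))
      for (i in idx) {
        v <- m[i, ]
        m[i, is.na(v)] <- mean(v, na.rm = TRUE)
      }
    }
  }
  constant <- apply(m, 1, function(v) popsd(v) < 1e-12)
  if (any(constant)) {
    warning(sum(constant), " constant gene row(s) dropped")
    m <- m[!constant, , drop = FALSE]
  }
  expression_matrix(m)
}

#' Write an expression matrix as TSV
#'
#' @param expr Expression matrix (genes x samples).
#' @param path Output path.
#' @param digits Significant digits used for formatting (byte-stable).
#' @export
write_expression <- function(expr, path, digits = 8) {
  lines <- c(paste(c("gene", colnames(expr)), collapse = "\t"),
             vapply(seq_len(nrow(expr)), function(i) {
               paste(c(rownames(expr)[i],
                       sprintf(paste0("%.", digits, "g"), expr[i, ])),
                     collapse = "\t")
             }, character(1)))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Construct a typed interaction set
#'
#' Applies the container invariants: self-loops are dropped with a warning,
#' duplicate (source, target) rows are collapsed keeping the maximum score,
#' and scores (when `normalize = TRUE` and any are outside \[0, 1\]) are
#' min-max normalized. Directed defaults to `TRUE` for regulatory types
#' (`tf_target`, `mirna_target`, `ligand_receptor`, `ligand_tf`) and
#' `FALSE` for `ppi`.
#'
#' @param edges Data frame with columns `source`, `target`, optional
#'   `score` (missing scores are set to 1).
#' @param itype Interaction type tag.
#' @param name Set name; defaults to `itype`.
#' @param directed Logical; default by `itype` as above.
#' @param normalize Min-max normalize scores to \[0, 1\] when needed.
#' @return Object of class `interaction_set`.
#' @export
interaction_set <- function(edges, itype = c("ppi", "tf_target",
                                             "mirna_target",
                                             "ligand_receptor", "ligand_tf",
                                             "custom"),
                            name = NULL, directed = NULL, normalize = TRUE) {
  itype <- match.arg(itype)
  stopifnot(is.data.frame(edges), all(c("source", "target") %in% names(edges)))
  directed <- directed %||% (itype != "ppi")
  edges$source <- as.character(edges$source)
  edges$target <- as.character(edges$target)
  if (is.null(edges$score)) edges$score <- 1
  edges$score <- as.numeric(edges$score)

  loop <- edges$source == edges$target
  if (any(loop)) {
    warning(sum(loop), " self-loop row(s) dropped")
    edges <- edges[!loop, , drop = FALSE]
  }
  if (nrow(edges) == 0) stop("interaction set '", name %||% itype, "' is empty")

  if (normalize && any(edges$score < 0 | edges$score > 1)) {
    rng <- range(edges$score)
    edges$score <- if (diff(rng) < 1e-12) 1 else
      (edges$score - rng[1]) / diff(rng)
  }

  key <- if (directed) paste(edges$source, edges$target, sep = "\r") else
    pair_key(edges$source, edges$target)
  if (anyDuplicated(key)) {
    ord <- order(key, -edges$score)
    edges <- edges[ord, , drop = FALSE]
    edges <- edges[!duplicated(key[ord]), , drop = FALSE]
  }
  edges <- edges[order(edges$source, edges$target),
                 c("source", "target", "score"), drop = FALSE]
  rownames(edges) <- NULL
  structure(list(name = name %||% itype, itype = itype,
                 directed = directed, edges = edges),
            class = "interaction_set")
}

#' @export
print.interaction_set <- function(x, ...) {
  cat(sprintf("<interaction_set> '%s' (%s, %s): %d edges, %d nodes\n",
              x$name, x$itype, if (x$directed) "directed" else "undirected",
              nrow(x$edges),
              length(union(x$edges$source, x$edges$target))))
  invisible(x)
}

#' Read an interaction edge list
#'
#' Reads a headerless 2-4 column TSV: `source`, `target`, optional numeric
#' `score`, optional `database` tag. When the score column is absent every
#' score is set to 1; provided scores are min-max normalized to \[0, 1\].
#' Self-loop rows are dropped with a warning; malformed rows raise an error
#' naming the offending line. With a database column,
#' `min_db_support > 1` keeps only edges reported by at least that many
#' distinct databases.
#'
#' @param path File path (lines starting with `#` are skipped).
#' @param itype Interaction type tag, see [interaction_set()].
#' @param name Set name; defaults to the file base name.
#' @param min_db_support Minimum number of distinct supporting databases
#'   (only meaningful when a 4th column is present).
#' @param directed Override the directedness default of `itype`.
#' @return An [interaction_set()].
#' @export
read_interactions <- function(path, itype = "ppi", name = NULL,
                              min_db_support = 1L, directed = NULL) {
  raw <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", raw)
  lineno <- which(keep)
  parts <- strsplit(raw[keep], "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (length(parts) == 0) stop("no interaction rows in ", path)
  bad <- which(nf < 2 | nf > 4)
  if (length(bad)) {
    stop("malformed interaction row at line ", lineno[bad[1]], " of ", path,
         " (expected 2-4 tab-separated fields, found ", nf[bad[1]], ")")
  }
  src <- vapply(parts, `[[`, character(1), 1)
  tgt <- vapply(parts, `[[`, character(1), 2)
  has_score <- all(nf >= 3)
  score <- rep(1, length(parts))
  if (any(nf >= 3)) {
    if (!has_score) {
      stop("malformed interaction row at line ",
           lineno[which(nf < 3)[1]], " of ", path,
           " (score column present only on some rows)")
    }
    sc <- vapply(parts, `[[`, character(1), 3)
    score <- suppressWarnings(as.numeric(sc))
    if (anyNA(score)) {
      stop("malformed interaction row at line ",
           lineno[which(is.na(score))[1]], " of ", path,
           " (non-numeric score)")
    }
  }
  db <- if (all(nf == 4)) vapply(parts, `[[`, character(1), 4) else NULL

  edges <- data.frame(source = src, target = tgt, score = score,
                      stringsAsFactors = FALSE)
  if (!is.null(db) && min_db_support > 1) {
    key <- paste(src, tgt, sep = "\r")
    support <- tapply(db, key, function(d) length(unique(d)))
    ok <- support[key] >= min_db_support
    mn_log("min_db_support=%d: keeping %d of %d rows", min_db_support,
           sum(ok), length(ok))
    edges <- edges[ok, , drop = FALSE]
    if (nrow(edges) == 0) stop("no interaction survives min_db_support")
  }
  interaction_set(edges, itype = itype,
                  name = name %||% sub("\\.[^.]*$", "", basename(path)),
                  directed = directed, normalize = has_score)
}

#' Write an interaction set as a TSV edge list
#'
#' @param set An [interaction_set()].
#' @param path Output path.
#' @export
write_interactions <- function(set, path) {
  e <- set$edges
  lines <- sprintf("%s\t%s\t%.8g", e$source, e$target, e$score)
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a survival table
#'
#' TSV with header columns `sample`, `time`, `event` (1 = event observed,
#' 0 = censored). Times must be non-negative.
#'
#' @param path File path.
#' @return Data frame with columns `sample_id`, `time`, `event`.
#' @export
read_survival <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  need <- c("sample", "time", "event")
  if (!all(need %in% names(df))) {
    stop("survival table needs columns: ", paste(need, collapse = ", "))
  }
  out <- data.frame(sample_id = as.character(df$sample),
                    time = as.numeric(df$time),
                    event = as.integer(df$event),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(out$sample_id)) stop("duplicate sample id in survival table")
  if (any(out$time < 0)) stop("negative survival time")
  if (!all(out$event %in% c(0L, 1L))) stop("event must be 0 or 1")
  out
}

#' Write a survival table
#' @param survival Data frame with `sample_id`, `time`, `event`.
#' @param path Output path.
#' @export
write_survival <- function(survival, path) {
  lines <- c("sample\ttime\tevent",
             sprintf("%s\t%.8g\t%d", survival$sample_id, survival$time,
                     survival$event))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

# coerce a module_set / list of gene vectors to a named list of gene vectors
module_gene_sets <- function(modules) {
  if (inherits(modules, "module_set")) {
    out <- lapply(modules$modules, `[[`, "genes")
    names(out) <- vapply(modules$modules, `[[`, character(1), "module_id")
    return(out)
  }
  if (is.character(modules)) modules <- list(modules)
  if (is.null(names(modules))) {
    names(modules) <- sprintf("M%d", seq_along(modules))
  }
  lapply(modules, as.character)
}

#' Write gene modules to GMT and/or long TSV
#'
#' GMT holds one module per line (`name`, description = module size, then
#' member genes); a gene shared by several modules appears on every one of
#' their lines, so overlap is preserved. The long TSV has columns
#' `module_id`, `gene`, `unit_kind`, `correlation_score` (kind and score
#' are available when `modules` is a [finalize_assignment()] result,
#' otherwise written as `member` / `NA`). Output is byte-stable for a fixed
#' module order.
#'
#' @param modules A `module_set` or (named) list of gene id vectors.
#' @param path Output path.
#' @param format `"gmt"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_modules <- function(modules, path, format = c("gmt", "tsv")) {
  format <- match.arg(format)
  sets <- module_gene_sets(modules)
  if (length(sets) == 0) {
    warning("empty module list; writing empty file")
    writeLines(character(0), path, useBytes = TRUE)
    return(invisible(path))
  }
  if (format == "gmt") {
    lines <- vapply(names(sets), function(id) {
      paste(c(id, length(sets[[id]]), sets[[id]]), collapse = "\t")
    }, character(1))
    writeLines(lines, path, useBytes = TRUE)
    return(invisible(path))
  }
  rows <- character(0)
  is_ms <- inherits(modules, "module_set")
  for (id in names(sets)) {
    genes <- sets[[id]]
    kind <- rep("member", length(genes))
    score <- rep(NA_real_, length(genes))
    if (is_ms) {
      mod <- modules$modules[[id]]
      kind <- ifelse(genes %in% mod$partner_genes, "anchor;partner",
                     "anchor")
      score <- unname(mod$gene_scores[genes])
    }
    rows <- c(rows, sprintf("%s\t%s\t%s\t%s", id, genes, kind,
                            ifelse(is.na(score), "NA",
                                   sprintf("%.6f", score))))
  }
  writeLines(c("module_id\tgene\tunit_kind\tcorrelation_score", rows), path,
             useBytes = TRUE)
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' @param path File path.
#' @return Named list of gene id vectors (descriptions are dropped).
#' @export
read_gmt <- function(path) {
  parts <- strsplit(readLines(path), "\t", fixed = TRUE)
  parts <- parts[lengths(parts) >= 3]
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, character(1), 1)
  sets
}

# normalize heterogeneous edge inputs to a data frame with source/target
as_edge_df <- function(edges) {
  if (inherits(edges, "coreg_network")) edges <- edges$edges
  if (inherits(edges, "module_network")) edges <- edges$edges
  if (inherits(edges, "consensus_network")) edges <- edges$edges
  if (inherits(edges, "interaction_set")) edges <- edges$edges
  stopifnot(is.data.frame(edges))
  nm <- names(edges)
  if (!"source" %in% nm && "gene_a" %in% nm) {
    edges$source <- edges$gene_a
    edges$target <- edges$gene_b
  }
  if (!all(c("source", "target") %in% names(edges))) {
    stop("edge table needs source/target (or gene_a/gene_b) columns")
  }
  edges
}

#' Write a network edge list as SIF or GraphML
#'
#' SIF rows are `source<TAB>type<TAB>target`. GraphML (via igraph)
#' preserves all extra edge columns (weight, sign, provenance, ...) as
#' edge attributes, so a written network can be read back with
#' [read_network()] without loss.
#'
#' @param edges Data frame with `source`, `target` and optional attribute
#'   columns (`itype` used as the SIF relation; networks produced by this
#'   package can be passed directly).
#' @param path Output path.
#' @param format `"sif"` or `"graphml"`.
#' @param directed Write GraphML as a directed graph.
#' @return `path`, invisibly.
#' @export
write_network <- function(edges, path, format = c("sif", "graphml"),
                          directed = TRUE) {
  if (!is.character(format) ||
      !all(format %in% c("sif", "graphml"))) {
    stop("unknown network format '", paste(format, collapse = ","),
         "'; supported formats: sif, graphml")
  }
  format <- match.arg(format)
  edges <- as_edge_df(edges)
  if (format == "sif") {
    itype <- if (is.null(edges$itype)) rep("interacts", nrow(edges)) else
      edges$itype
    writeLines(sprintf("%s\t%s\t%s", edges$source, itype, edges$target),
               path, useBytes = TRUE)
    return(invisible(path))
  }
  keep <- c("source", "target",
            setdiff(names(edges), c("source", "target")))
  g <- igraph::graph_from_data_frame(edges[, keep, drop = FALSE],
                                     directed = directed)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Read a GraphML network back into an edge data frame
#'
#' @param path GraphML file written by [write_network()].
#' @return Data frame with `source`, `target` and any stored attributes.
#' @export
read_network <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  df <- igraph::as_data_frame(g, what = "edges")
  names(df)[1:2] <- c("source", "target")
  df
}

#' Read a YAML configuration file
#'
#' A flat YAML mapping mirroring the command-line flags; see the `modnet`
#' CLI script in `inst/cli/`.
#'
#' @param path YAML file.
#' @return Named list.
#' @export
read_config <- function(path) yaml::read_yaml(path)
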
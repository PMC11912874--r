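`%||%` <- function(a, b) if (is.null(a)) b else a

# population standard deviation (divisor n, not n-1)
popsd <- function(x) sqrt(mean((x - mean(x))^2))

#' Z-score normalize an expression pattern
#'
#' Centers a vector to mean 0 and scales it to population standard
#' deviation 1. Every expression pattern entering unit, module, or survival
#' computations passes through this transform so that each gene carries the
#' same weight regardless of its raw expression scale.
#'
#' @param x Numeric vector of length >= 2; must not be constant.
#' @return Numeric vector with mean 0 and population SD 1.
#' @export
#' @examples
#' zscore(c(1, 2, 3))
zscore <- function(x) {
  if (!is.numeric(x) || length(x) < 2) {
    stop("zscore() needs a numeric vector of length >= 2")
  }
  s <- popsd(x)
  if (s < 1e-12) stop("constant gene: zero variance")
  (x - mean(x)) / s
}

# row-wise population z-score; rejects constant rows
zscore_rows <- function(m) {
  if (!is.matrix(m)) m <- rbind(m)
  mu <- rowMeans(m)
  xc <- m - mu
  s <- sqrt(rowMeans(xc^2))
  bad <- s < 1e-12
  if (any(bad)) {
    stop("constant gene: zero variance in ",
         paste(rownames(m)[bad] %||% which(bad), collapse = ", "))
  }
  xc / s
}

# timestamped, level-controlled logging; INFO silenced unless
# options(modnet.quiet = FALSE)
mn_log <- function(fmt, ..., level = "INFO") {
  if (identical(level, "INFO") && isTRUE(getOption("modnet.quiet", TRUE))) {
    return(invisible(NULL))
  }
  message(sprintf("[%s %s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  level, sprintf(fmt, ...)))
  invisible(NULL)
}

# canonical key for an unordered gene pair
pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")

#' Construct a validated expression matrix
#'
#' Wraps a genes x samples numeric matrix after checking the container
#' invariants: unique gene and sample identifiers, at least two samples, and
#' all values finite. Gene identifiers are opaque case-sensitive strings; no
#' symbol or alias mapping is applied.
#'
#' @param values Numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids).
#' @return The matrix with class `expr_matrix` prepended.
#' @export
expression_matrix <- function(values) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("expression values must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("expression matrix needs gene rownames and sample colnames")
  }
  if (anyDuplicated(rownames(values))) {
    stop("duplicate gene id: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  }
  if (anyDuplicated(colnames(values))) stop("duplicate sample id")
  if (ncol(values) < 2) stop("expression matrix needs >= 2 samples")
  if (!all(is.finite(values))) stop("non-finite values in expression matrix")
  if (!inherits(values, "expr_matrix")) {
    class(values) <- c("expr_matrix", class(values))
  }
  values
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d samples\n", nrow(x), ncol(x)))
  cat("genes:  ", paste(utils::head(rownames(x), 5), collapse = ", "),
      if (nrow(x) > 5) ", ..." else "", "\n", sep = "")
  cat("samples:", paste(utils::head(colnames(x), 5), collapse = ", "),
      if (ncol(x) > 5) ", ..." else "", "\n", sep = "")
  invisible(x)
}
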
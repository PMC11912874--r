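# deterministic gene/sample naming shared by the generators
synth_gene_names <- function(n_modules, gpm, n_overlap, n_noise) {
  mods <- unlist(lapply(seq_len(n_modules), function(m) {
    sprintf("M%dG%03d", m, seq_len(gpm[m]))
  }))
  ov <- if (n_modules >= 2 && any(n_overlap > 0)) {
    unlist(lapply(seq_len(n_modules - 1L), function(m) {
      if (n_overlap[m] == 0) return(character(0))
      sprintf("OV%d.%dG%02d", m, m + 1L, seq_len(n_overlap[m]))
    }))
  } else character(0)
  noise <- if (n_noise > 0) sprintf("NOISE%03d", seq_len(n_noise)) else
    character(0)
  list(modules = mods, overlap = ov, noise = noise)
}

#' Generate an expression cohort with planted coregulated modules
#'
#' Latent-factor Gaussian model: each module is driven by one standard
#' normal factor; a member gene is
#' `sign * (within_r * factor + sqrt(1 - within_r^2) * noise_sd * eps)`,
#' so with `noise_sd = 1` its correlation with the factor is `within_r`.
#' A fraction `frac_negative` of members is anti-correlated (sign -1).
#' Overlap genes load on the sum of two consecutive module factors
#' (scaled by `1/sqrt(2)`) and belong to both modules in the ground
#' truth. Independent noise genes are appended. The generator is a pure
#' function of its parameters and seed.
#'
#' @param n_modules Number of planted modules.
#' @param genes_per_module Genes per module (scalar or length
#'   `n_modules`).
#' @param n_samples Number of samples.
#' @param within_r Target member-factor correlation, in (0, 1).
#' @param noise_sd Relative scale of the member-specific noise
#'   (1 = calibrated so member-factor correlation equals `within_r`).
#' @param frac_negative Fraction of members anti-correlated with their
#'   factor.
#' @param overlap_frac Fraction of a module's size planted as shared
#'   genes with the next module.
#' @param n_noise_genes Unstructured noise genes appended.
#' @param seed Integer seed.
#' @return `list(expr, truth)` where `truth` (class `planted_truth`)
#'   records module gene sets, per-gene module labels, overlap and
#'   negative genes, the latent factors, and the full parameter record.
#' @export
generate_module_cohort <- function(n_modules = 4L, genes_per_module = 25L,
                                   n_samples = 100L, within_r = 0.8,
                                   noise_sd = 1, frac_negative = 0.2,
                                   overlap_frac = 0.1, n_noise_genes = 20L,
                                   seed = 1L) {
  if (within_r <= 0 || within_r >= 1) stop("within_r must lie in (0, 1)")
  gpm <- rep_len(as.integer(genes_per_module), n_modules)
  n_ov <- if (n_modules >= 2) {
    pmin(round(overlap_frac * gpm[-n_modules]), Inf)
  } else integer(0)
  if (any(n_ov > gpm[-n_modules])) {
    stop("infeasible parameters: overlap exceeds module size")
  }
  params <- list(n_modules = n_modules, genes_per_module = gpm,
                 n_samples = as.integer(n_samples), within_r = within_r,
                 noise_sd = noise_sd, frac_negative = frac_negative,
                 overlap_frac = overlap_frac,
                 n_noise_genes = as.integer(n_noise_genes),
                 seed = as.integer(seed))
  nm <- synth_gene_names(n_modules, gpm, n_ov, n_noise_genes)
  samples <- sprintf("S%03d", seq_len(n_samples))

  set.seed(as.integer(seed))
  FM <- matrix(stats::rnorm(n_modules * n_samples), nrow = n_modules)
  a <- within_r
  b <- sqrt(1 - within_r^2) * noise_sd

  module_genes <- stats::setNames(vector("list", n_modules),
                                  sprintf("M%d", seq_len(n_modules)))
  gene_modules <- list()
  negative <- character(0)
  rows <- list()

  gi <- 0L
  for (m in seq_len(n_modules)) {
    n_neg <- round(frac_negative * gpm[m])
    neg_idx <- if (n_neg > 0) sample(seq_len(gpm[m]), n_neg) else integer(0)
    for (i in seq_len(gpm[m])) {
      gi <- gi + 1L
      g <- nm$modules[gi]
      sgn <- if (i %in% neg_idx) -1 else 1
      rows[[g]] <- sgn * (a * FM[m, ] + b * stats::rnorm(n_samples))
      module_genes[[m]] <- c(module_genes[[m]], g)
      gene_modules[[g]] <- sprintf("M%d", m)
      if (sgn < 0) negative <- c(negative, g)
    }
  }
  oi <- 0L
  if (n_modules >= 2) {
    for (m in seq_len(n_modules - 1L)) {
      if (n_ov[m] == 0) next
      f2 <- (FM[m, ] + FM[m + 1L, ]) / sqrt(2)
      for (i in seq_len(n_ov[m])) {
        oi <- oi + 1L
        g <- nm$overlap[oi]
        rows[[g]] <- a * f2 + b * stats::rnorm(n_samples)
        module_genes[[m]] <- c(module_genes[[m]], g)
        module_genes[[m + 1L]] <- c(module_genes[[m + 1L]], g)
        gene_modules[[g]] <- sprintf("M%d", c(m, m + 1L))
      }
    }
  }
  for (g in nm$noise) rows[[g]] <- stats::rnorm(n_samples)

  expr <- do.call(rbind, rows)
  colnames(expr) <- samples
  expr <- expression_matrix(expr)

  truth <- structure(list(module_genes = module_genes,
                          gene_modules = gene_modules,
                          overlap_genes = nm$overlap,
                          negative_genes = sort(negative),
                          noise_genes = nm$noise,
                          factors = FM, params = params),
                     class = "planted_truth")
  list(expr = expr, truth = truth)
}

#' Generate reference interaction sets consistent with a planted truth
#'
#' Emits a TF-style regulator set (per module, `n_regulators` regulators
#' each targeting a random `target_frac` of the module's genes) and a PPI
#' set among co-module genes, plus `decoy_frac` random cross-module decoy
#' edges in each. With probability `regulator_expressed_frac` a regulator
#' is one of the module's measured member genes (so it also appears in the
#' expression matrix); otherwise it gets a fresh identifier absent from
#' the matrix and reachable only through a functional layer.
#'
#' @param truth A [generate_module_cohort()] truth.
#' @param decoy_frac Decoy edges as a fraction of true edges.
#' @param regulator_expressed_frac Probability that a regulator is a
#'   measured member gene.
#' @param n_regulators Regulators per module.
#' @param target_frac Fraction of module genes each regulator targets.
#' @param ppi_degree Within-module PPI partners drawn per gene.
#' @param seed Integer seed.
#' @return `list(sets = list(tf, ppi), truth)` with
#'   `truth$regulator_map`, `truth$expressed_regulators`, and
#'   `truth$decoy_edges` filled in.
#' @export
generate_interactions <- function(truth, decoy_frac = 0.1,
                                  regulator_expressed_frac = 0,
                                  n_regulators = 2L, target_frac = 0.8,
                                  ppi_degree = 2L, seed = 1L) {
  stopifnot(inherits(truth, "planted_truth"))
  set.seed(as.integer(seed))
  mods <- truth$module_genes
  all_genes <- unlist(mods, use.names = FALSE)
  pool <- c(all_genes, truth$noise_genes)

  reg_map <- list()
  expressed <- character(0)
  tf_src <- character(0); tf_tgt <- character(0)
  for (m in seq_along(mods)) {
    members <- mods[[m]]
    for (k in seq_len(n_regulators)) {
      if (stats::runif(1) < regulator_expressed_frac) {
        avail <- setdiff(members, names(reg_map))
        reg <- if (length(avail)) sample(avail, 1) else
          sprintf("TF_M%d_%d", m, k)
      } else {
        reg <- sprintf("TF_M%d_%d", m, k)
      }
      cand <- setdiff(members, reg)
      n_t <- max(2L, round(target_frac * length(cand)))
      targets <- sort(sample(cand, min(n_t, length(cand))))
      reg_map[[reg]] <- targets
      if (reg %in% members) expressed <- c(expressed, reg)
      tf_src <- c(tf_src, rep(reg, length(targets)))
      tf_tgt <- c(tf_tgt, targets)
    }
  }
  n_true <- length(tf_src)
  n_decoy <- round(decoy_frac * n_true)
  decoys <- data.frame(source = character(0), target = character(0))
  if (n_decoy > 0) {
    regs <- sample(names(reg_map), n_decoy, replace = TRUE)
    d_tgt <- vapply(regs, function(R) {
      own <- unique(unlist(lapply(truth$gene_modules[reg_map[[R]]], c)))
      outside <- pool[!vapply(truth$gene_modules[pool], function(gm) {
        any(gm %in% own)
      }, logical(1)) | pool %in% truth$noise_genes]
      outside <- setdiff(outside, c(R, reg_map[[R]]))
      sample(outside, 1)
    }, character(1))
    decoys <- data.frame(source = regs, target = unname(d_tgt),
                         stringsAsFactors = FALSE)
    tf_src <- c(tf_src, decoys$source)
    tf_tgt <- c(tf_tgt, d_tgt)
  }
  tf <- interaction_set(data.frame(source = tf_src, target = tf_tgt,
                                   score = 1, stringsAsFactors = FALSE),
                        itype = "tf_target", name = "tf_synth",
                        normalize = FALSE)

  ppi_a <- character(0); ppi_b <- character(0)
  for (m in seq_along(mods)) {
    members <- mods[[m]]
    for (g in members) {
      others <- setdiff(members, g)
      k <- min(ppi_degree, length(others))
      if (k == 0) next
      pp <- sample(others, k)
      ppi_a <- c(ppi_a, rep(g, k)); ppi_b <- c(ppi_b, pp)
    }
  }
  n_pdecoy <- round(decoy_frac * length(ppi_a))
  if (n_pdecoy > 0) {
    pa <- sample(pool, n_pdecoy, replace = TRUE)
    pb <- vapply(pa, function(g) sample(setdiff(pool, g), 1), character(1))
    ppi_a <- c(ppi_a, pa); ppi_b <- c(ppi_b, unname(pb))
  }
  ppi <- interaction_set(data.frame(source = ppi_a, target = ppi_b,
                                    score = 1, stringsAsFactors = FALSE),
                         itype = "ppi", name = "ppi_synth",
                         normalize = FALSE)

  truth$regulator_map <- reg_map[order(names(reg_map))]
  truth$expressed_regulators <- sort(expressed)
  truth$decoy_edges <- decoys
  truth$params$decoy_frac <- decoy_frac
  truth$params$regulator_expressed_frac <- regulator_expressed_frac
  truth$params$interaction_seed <- as.integer(seed)
  list(sets = list(tf = tf, ppi = ppi), truth = truth)
}

# expected censored fraction when events are Exp(rate) mixed over patients
# and censoring is Uniform(0, a)
censor_fraction <- function(a, rates) {
  mean((1 - exp(-rates * a)) / (rates * a))
}

#' Generate a survival cohort with one broken regulator-target relation
#'
#' Regenerates the planted-module expression structure at `n_patients`
#' patients, then severs the control of one regulator over one target in a
#' `broken_frac` subset of patients: the target's expression there is
#' resampled independently of the module factor (same marginal
#' distribution), which raises its coregulation-similarity score `S`; a
#' non-zero `break_shift` additionally lowers the severed target's level
#' by that many row standard deviations, emulating outright loss of an
#' activating input. Event times are exponential, with the affected
#' patients' hazard
#' multiplied by `hazard_ratio`; censoring times are uniform on
#' `(0, c_max)` with `c_max` calibrated so the expected censored fraction
#' equals `censor_rate`. `hazard_ratio = 1` yields a null cohort in which
#' the broken relation carries no survival signal.
#'
#' @param truth A [generate_interactions()] truth (must carry
#'   `regulator_map`).
#' @param hazard_ratio Hazard multiplier (>= 1) for affected patients.
#' @param broken_frac Fraction of patients with the severed relation.
#' @param censor_rate Expected fraction of censored patients.
#' @param n_patients Cohort size.
#' @param baseline_hazard Baseline exponential event rate.
#' @param break_shift Downward shift (in row SDs) of the severed target in
#'   affected patients (default 0: pure decorrelation).
#' @param seed Integer seed.
#' @return `list(expr, survival, truth)`; `truth$broken_relation` is
#'   `c(regulator, target)` and `truth$affected_samples` the patient ids
#'   with the severed relation.
#' @export
generate_survival_cohort <- function(truth, hazard_ratio = 3,
                                     broken_frac = 0.5, censor_rate = 0.3,
                                     n_patients = 200L,
                                     baseline_hazard = 0.1,
                                     break_shift = 0, seed = 1L) {
  stopifnot(inherits(truth, "planted_truth"))
  if (is.null(truth$regulator_map)) {
    stop("truth lacks regulator_map; run generate_interactions() first")
  }
  if (hazard_ratio < 1) stop("hazard_ratio must be >= 1")
  p <- truth$params
  cohort <- generate_module_cohort(
    n_modules = p$n_modules, genes_per_module = p$genes_per_module,
    n_samples = n_patients, within_r = p$within_r, noise_sd = p$noise_sd,
    frac_negative = p$frac_negative, overlap_frac = p$overlap_frac,
    n_noise_genes = p$n_noise_genes, seed = as.integer(seed) + 77003L)
  expr <- cohort$expr

  # deterministic relation choice: largest regulator, alphabetical ties
  sizes <- vapply(truth$regulator_map, length, integer(1))
  reg <- names(sort(sizes, decreasing = TRUE))[1]
  targets <- sort(truth$regulator_map[[reg]])
  g1 <- targets[1]

  set.seed(as.integer(seed))
  patients <- colnames(expr)
  affected <- sort(sample(patients, round(broken_frac * n_patients)))
  if (length(affected)) {
    s1 <- stats::sd(expr[g1, ])
    expr[g1, affected] <- stats::rnorm(length(affected),
                                       mean = mean(expr[g1, ]) -
                                         break_shift * s1,
                                       sd = s1)
  }
  rates <- ifelse(patients %in% affected,
                  baseline_hazard * hazard_ratio, baseline_hazard)
  t_event <- stats::rexp(n_patients, rate = rates)
  if (censor_rate > 0) {
    c_max <- stats::uniroot(function(a) censor_fraction(a, rates) - censor_rate,
                            lower = 1e-8, upper = 1e8, tol = 1e-10)$root
    t_cens <- stats::runif(n_patients, 0, c_max)
  } else {
    t_cens <- rep(Inf, n_patients)
  }
  surv <- data.frame(sample_id = patients,
                     time = pmin(t_event, t_cens),
                     event = as.integer(t_event <= t_cens),
                     stringsAsFactors = FALSE)

  truth2 <- cohort$truth
  truth2$regulator_map <- truth$regulator_map
  truth2$expressed_regulators <- truth$expressed_regulators
  truth2$broken_relation <- c(regulator = reg, target = g1)
  truth2$affected_samples <- affected
  truth2$params$hazard_ratio <- hazard_ratio
  truth2$params$broken_frac <- broken_frac
  truth2$params$censor_rate <- censor_rate
  truth2$params$baseline_hazard <- baseline_hazard
  truth2$params$break_shift <- break_shift
  truth2$params$survival_seed <- as.integer(seed)
  list(expr = expr, survival = surv, truth = truth2)
}

#' @export
print.planted_truth <- function(x, ...) {
  cat(sprintf("<planted_truth> %d modules (%s genes), %d overlap, %d noise\n",
              x$params$n_modules,
              paste(x$params$genes_per_module, collapse = "/"),
              length(x$overlap_genes), length(x$noise_genes)))
  if (!is.null(x$regulator_map)) {
    cat(sprintf("  %d regulators (%d measured)\n",
                length(x$regulator_map), length(x$expressed_regulators)))
  }
  if (!is.null(x$broken_relation)) {
    cat(sprintf("  broken relation: %s -> %s (%d affected patients)\n",
                x$broken_relation[["regulator"]],
                x$broken_relation[["target"]], length(x$affected_samples)))
  }
  invisible(x)
}

#' Serialize a planted truth record to JSON
#'
#' @param truth A `planted_truth`.
#' @param path Output path.
#' @export
write_truth <- function(truth, path) {
  x <- unclass(truth)
  x$factors <- NULL   # large and reproducible from params + seed
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}
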
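test_that("similarity scores implement the summed squared z-deviation", {
  set.seed(41)
  n <- 30
  target <- rnorm(n, mean = 5, sd = 2)
  partners <- rbind(p1 = rnorm(n), p2 = 3 * target + rnorm(n, sd = 0.5),
                    p3 = rnorm(n, 10, 4))
  colnames(partners) <- names(target) <- sprintf("s%02d", 1:n)
  S <- similarity_scores(target, partners, align_signs = FALSE)

  # independent oracle: z-score by hand and sum the squared deviations
  zs <- function(v) (v - mean(v)) / sqrt(mean((v - mean(v))^2))
  zt <- zs(target)
  S_hand <- zs(partners[1, ]) * 0
  for (p in rownames(partners)) S_hand <- S_hand + (zt - zs(partners[p, ]))^2
  expect_equal(unname(S), unname(S_hand), tolerance = 1e-12)
  expect_true(all(S >= 0))

  # identical rows give zero everywhere
  same <- rbind(a = target, b = target)
  expect_equal(unname(similarity_scores(target, same)), rep(0, n),
               tolerance = 1e-12)

  # partner order does not matter; shifts are absorbed by z-scoring
  expect_equal(similarity_scores(target, partners[c(3, 1, 2), ]),
               similarity_scores(target, partners))
  shifted <- partners; shifted[1, ] <- shifted[1, ] + 100
  expect_equal(similarity_scores(target, shifted),
               similarity_scores(target, partners), tolerance = 1e-9)

  expect_error(similarity_scores(target, partners[1, , drop = FALSE]),
               "insufficient")
})

test_that("sign alignment makes anti-correlated partners equivalent to flipped ones", {
  set.seed(42)
  n <- 40
  target <- rnorm(n)
  p_pos <- 0.9 * target + 0.3 * rnorm(n)
  p2 <- rnorm(n)
  S_ref <- similarity_scores(target, rbind(a = p_pos, b = p2))
  S_neg <- similarity_scores(target, rbind(a = -p_pos, b = p2))
  expect_equal(S_ref, S_neg, tolerance = 1e-12)
})

test_that("the rank-split log-rank test agrees with the textbook computation", {
  set.seed(43)
  n <- 30
  S <- runif(n)
  surv <- data.frame(sample_id = sprintf("s%02d", 1:n),
                     time = round(rexp(n, 0.2), 3),
                     event = rbinom(n, 1, 0.8))
  names(S) <- surv$sample_id
  res <- logrank_rank_test(S, surv, min_group = 5)

  # textbook observed-minus-expected log-rank on the same split
  ord <- order(-S, surv$sample_id)
  grp <- rep(NA, n); grp[ord[1:15]] <- 1; grp[ord[16:30]] <- 0
  tt <- surv$time; ev <- surv$event
  O <- 0; E <- 0; V <- 0
  for (t in sort(unique(tt[ev == 1]))) {
    at_risk <- tt >= t
    n1 <- sum(at_risk & grp == 1); n0 <- sum(at_risk & grp == 0)
    d <- sum(tt == t & ev == 1 & !is.na(grp))
    d1 <- sum(tt == t & ev == 1 & grp == 1)
    nn <- n1 + n0
    if (nn < 2 || d == 0) next
    O <- O + d1
    E <- E + d * n1 / nn
    V <- V + d * (n1 / nn) * (n0 / nn) * (nn - d) / (nn - 1)
  }
  chisq_hand <- (O - E)^2 / V
  expect_equal(res$statistic, chisq_hand, tolerance = 1e-6)
  expect_equal(res$p, pchisq(chisq_hand, 1, lower.tail = FALSE),
               tolerance = 1e-6)
})

test_that("degenerate cohorts are flagged untestable, not errors", {
  surv <- data.frame(sample_id = sprintf("s%d", 1:30),
                     time = rexp(30, 0.1), event = rep(1L, 30))
  S_const <- setNames(rep(2, 30), surv$sample_id)
  res <- logrank_rank_test(S_const, surv, min_group = 5)
  expect_true(res$untestable)
  expect_match(res$reason, "degenerate")

  # no events in one group
  surv2 <- surv
  S <- setNames(seq_len(30), surv$sample_id)
  surv2$event[16:30] <- 0L   # bottom-ranked group all censored
  res2 <- logrank_rank_test(S, surv2, min_group = 5)
  expect_true(res2$untestable)

  res3 <- logrank_rank_test(S, surv, min_group = 20)
  expect_true(res3$untestable)
})

test_that("the split test is calibrated under the null and sees real effects", {
  set.seed(44)
  n <- 60
  rej <- replicate(200, {
    surv <- data.frame(sample_id = sprintf("s%02d", 1:n),
                       time = rexp(n, 0.1),
                       event = rbinom(n, 1, 0.8))
    S <- setNames(rnorm(n), surv$sample_id)
    logrank_rank_test(S, surv)$p < 0.05
  })
  # nominal 5% within Monte-Carlo tolerance
  expect_gt(mean(rej), 0.01)
  expect_lt(mean(rej), 0.05 + 3 * sqrt(0.05 * 0.95 / 200))

  # perfect separation: expression a monotone function of survival time
  surv <- data.frame(sample_id = sprintf("s%02d", 1:n),
                     time = sort(rexp(n, 0.1)), event = rep(1L, n))
  gene <- setNames(-seq_len(n), surv$sample_id)  # high expr = short life
  res <- expression_survival_baseline(gene, surv)
  expect_lt(res$p, 1e-8)
  expect_equal(res$direction, "top")
})

test_that("scan_network tests provenance relations and respects preconditions", {
  base <- generate_module_cohort(n_modules = 2, genes_per_module = 6,
                                 overlap_frac = 0, n_noise_genes = 2,
                                 seed = 45)
  gi <- generate_interactions(base$truth, decoy_frac = 0, n_regulators = 1,
                              target_frac = 1, seed = 45)
  sc <- generate_survival_cohort(gi$truth, hazard_ratio = 1,
                                 n_patients = 80, seed = 45)
  rew <- rewire_regulators(build_multilayer(sc$expr, gi$sets), sc$expr)
  cons <- build_consensus(list(sc$truth$module_genes),
                          networks = list(rew))
  scan <- scan_network(cons, sc$expr, sc$survival)
  # every tested relation has >= 2 co-targets of its regulator
  expect_true(all(scan$n_partners >= 2))
  expect_true(all(grepl("^TF_", scan$regulator)))
  expect_s3_class(scan, "relation_scan")
  # BH adjustment keeps order: adjusted >= raw
  ok <- !scan$untestable
  expect_true(all(scan$adjusted_p[ok] >= scan$p[ok] - 1e-15))

  # a regulator with a single co-target is never tested: restrict the
  # consensus to one edge of one regulator
  cons1 <- cons
  keep <- grepl("TF_M1_1", cons1$edges$provenance)
  cons1$edges <- cons1$edges[keep, ][1, , drop = FALSE]
  scan1 <- scan_network(cons1, sc$expr, sc$survival)
  expect_equal(nrow(scan1), 0L)

  # consensus without provenance is rejected
  cons2 <- cons; cons2$edges$provenance <- NULL
  expect_error(scan_network(cons2, sc$expr, sc$survival), "provenance")
})

test_that("baseline comparison flags network-only relations", {
  base <- generate_module_cohort(n_modules = 2, genes_per_module = 5,
                                 overlap_frac = 0, n_noise_genes = 0,
                                 seed = 46)
  gi <- generate_interactions(base$truth, decoy_frac = 0, n_regulators = 1,
                              target_frac = 1, seed = 46)
  sc <- generate_survival_cohort(gi$truth, hazard_ratio = 2,
                                 n_patients = 80, seed = 46)
  rew <- rewire_regulators(build_multilayer(sc$expr, gi$sets), sc$expr)
  cons <- build_consensus(list(sc$truth$module_genes), networks = list(rew))
  scan <- scan_network(cons, sc$expr, sc$survival)
  cmp <- baseline_comparison(scan, sc$expr, sc$survival)
  expect_true(all(c("baseline_p", "baseline_adjusted_p", "network_only")
                  %in% names(cmp)))
  expect_equal(cmp$network_only, cmp$hit & !cmp$baseline_hit)
})
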
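# engineered micro-cohorts: single-gene units on exactly-known correlations

test_that("unit-module probability follows the weighted combination rule", {
  f <- orthonormal_patterns(30, 3, seed = 21)
  expr <- expr_from_rows(list(p1 = pattern_with_r(f[, 1], f[, 2], 0.7),
                              p2 = pattern_with_r(f[, 1], f[, 3], 0.3),
                              g = f[, 2]))
  fu <- fu_from_spec(expr, list("p1", "p2",
                                list(anchor = "g",
                                     partners = c(p1 = 0.5, p2 = 0.5))))
  null <- corr_null(30, B = 300, seed = 21)
  feature <- f[, 1]
  p1 <- correlation_probability(expr["p1", ], feature, null = null)
  p2 <- correlation_probability(expr["p2", ], feature, null = null)
  pu <- unit_module_probability(fu, "g::p1+p2", feature, null)
  expect_equal(pu, 0.5 * p1 + 0.5 * p2, tolerance = 1e-9)
  # singleton weight: probability equals the partner's own probability
  fu2 <- fu_from_spec(expr, list(list(anchor = "g",
                                      partners = c(p1 = 1))))
  expect_equal(unit_module_probability(fu2, 1, feature, null), p1,
               tolerance = 1e-9)
  # a unit whose pattern equals the feature scores probability 1
  fu3 <- fu_from_spec(expr, list("g"))
  expect_equal(unit_module_probability(fu3, 1, f[, 2], null), 1)
  expect_error(unit_module_probability(fu3, 1, rep(0, 30), null),
               "degenerate")
})

test_that("correlation scores are |r|-weighted sums; strict mode keeps the sign", {
  f <- orthonormal_patterns(24, 3, seed = 22)
  x1 <- pattern_with_r(f[, 1], f[, 2], 0.9)
  x2 <- -pattern_with_r(f[, 1], f[, 3], 0.5)  # negatively correlated
  expr <- expr_from_rows(list(p1 = x1, p2 = x2, g = f[, 2]))
  fu <- fu_from_spec(expr, list(list(anchor = "g",
                                     partners = c(p1 = 0.6, p2 = 0.4))))
  feature <- f[, 1]
  # independent oracle: plain Pearson correlations
  r1 <- cor(x1, feature); r2 <- cor(x2, feature)
  expect_equal(correlation_score(fu, 1, feature),
               0.6 * abs(r1) + 0.4 * abs(r2), tolerance = 1e-9)
  expect_equal(correlation_score(fu, 1, feature),
               0.6 * 0.9 + 0.4 * 0.5, tolerance = 1e-6)
  # asymmetric variant: |.| on the first term only
  expect_equal(correlation_score(fu, 1, feature, strict = TRUE),
               0.6 * abs(r1) + 0.4 * r2, tolerance = 1e-9)
  expect_lt(correlation_score(fu, 1, feature, strict = TRUE),
            correlation_score(fu, 1, feature))
})

test_that("split_module separates units at the threshold, ties to the high side", {
  f <- orthonormal_patterns(40, 5, seed = 23)
  rs <- c(0.9, 0.5, 0.3, 0.1)
  rows <- lapply(seq_along(rs), function(i) {
    pattern_with_r(f[, 1], f[, i + 1], rs[i])
  })
  names(rows) <- sprintf("g%d", seq_along(rs))
  expr <- expr_from_rows(rows)
  fu <- fu_from_spec(expr, as.list(names(rows)))
  module <- list(unit_ids = 1:4, feature = f[, 1])
  sp <- split_module(fu, module, threshold = 0.4)
  expect_equal(sp$high, 1:2)
  expect_equal(sp$low, 3:4)
  # all scores above the threshold: infeasible
  expect_null(split_module(fu, module, threshold = 0.05))
  # a unit exactly at the threshold joins the high submodule
  thr <- sp$scores[2]
  sp2 <- split_module(fu, module, threshold = thr)
  expect_true(2 %in% sp2$high)
})

test_that("the low-level controller is greedy, monotone, and deterministic", {
  f <- orthonormal_patterns(30, 2, seed = 24)
  rows <- list(a1 = pattern_with_r(f[, 1], f[, 2], 0.95),
               a2 = pattern_with_r(f[, 1], f[, 2], 0.9),
               b1 = pattern_with_r(f[, 2], f[, 1], 0.95),
               b2 = pattern_with_r(f[, 2], f[, 1], 0.9))
  expr <- expr_from_rows(rows)
  fu <- fu_from_spec(expr, as.list(names(rows)))
  null <- corr_null(30, B = 300, seed = 24)

  # one module: a single pass, V = sum of probabilities against it
  res1 <- low_level_assign(fu, rep(1L, 4), null)
  expect_equal(res1$K, 1L)
  expect_equal(res1$value,
               sum(modnet:::prob_units_mat(fu, res1$features, null)))

  # misplaced unit b1 migrates to its block; result equals the exhaustive
  # optimum over all 2^4 assignments
  res2 <- low_level_assign(fu, c(1L, 1L, 1L, 2L), null)
  expect_equal(res2$assignment[1], res2$assignment[2])
  expect_equal(res2$assignment[3], res2$assignment[4])
  expect_true(res2$assignment[1] != res2$assignment[3])
  best <- brute_force_best_cp(fu, 2, null)
  expect_equal(res2$value, best, tolerance = 1e-9)

  # determinism and the best-value contract
  res2b <- low_level_assign(fu, c(1L, 1L, 1L, 2L), null)
  expect_identical(res2$trace, res2b$trace)
  expect_equal(res2$value, max(res2$trace$CP))
})

test_that("high-level search finds planted structure and respects the discount", {
  # two tight orthogonal blocks: the discount penalty (gamma scales with
  # the total value) rejects any further fragmentation of a clean block
  f <- orthonormal_patterns(40, 3, seed = 25)
  set.seed(250)
  rows <- c(lapply(1:6, function(i) {
    0.99 * f[, 1] + sqrt(1 - 0.99^2) * rnorm(40)
  }), lapply(1:6, function(i) {
    0.99 * f[, 2] + sqrt(1 - 0.99^2) * rnorm(40)
  }))
  names(rows) <- c(sprintf("a%d", 1:6), sprintf("b%d", 1:6))
  expr <- expr_from_rows(rows)
  fu <- fu_from_spec(expr, as.list(names(rows)))
  null <- corr_null(40, B = 300, seed = 25)

  st <- high_level_search(fu, null = null)
  expect_equal(st$K, 2L)
  groups <- split(fu$units$anchor, st$assignment)
  expect_setequal(vapply(groups, function(g) paste(sort(substr(g, 1, 1)),
                                                   collapse = ""),
                         character(1)),
                  c("aaaaaa", "bbbbbb"))
  # the greedy search result is within the exhaustive 2-module optimum
  best <- brute_force_best_cp(fu, 2, null)
  expect_lte(st$value, best + 1e-9)

  # homogeneous block: no split improves, one module remains
  fu_a <- fu_from_spec(expr[1:6, ], as.list(sprintf("a%d", 1:6)))
  st_a <- high_level_search(fu_a, null = null)
  expect_equal(st_a$K, 1L)

  # gamma = 0: the discounted reward is always negative, no split accepted
  st0 <- high_level_search(fu, gamma = 0, null = null)
  expect_equal(st0$K, 1L)

  # determinism and the module-count bound
  st_b <- high_level_search(fu, null = null)
  expect_identical(st$trace, st_b$trace)
  expect_lte(st$K, nrow(fu$units))
})

test_that("finalize_assignment produces overlapping gene-level modules", {
  f <- orthonormal_patterns(30, 2, seed = 26)
  # gene g: its own pattern follows factor 1, its combined unit follows
  # factor 2 -> the gene must appear in both modules
  rows <- list(a1 = pattern_with_r(f[, 1], f[, 2], 0.99),
               a2 = pattern_with_r(f[, 1], f[, 2], 0.985),
               b1 = pattern_with_r(f[, 2], f[, 1], 0.99),
               b2 = pattern_with_r(f[, 2], f[, 1], 0.985),
               g  = pattern_with_r(f[, 1], f[, 2], 0.98))
  expr <- expr_from_rows(rows)
  fu <- fu_from_spec(expr, c(as.list(names(rows)),
                             list(list(anchor = "g",
                                       partners = c(b1 = 0.5, b2 = 0.5)))))
  null <- corr_null(30, B = 300, seed = 26)
  st <- high_level_search(fu, null = null)
  mods <- finalize_assignment(st, fu)
  expect_equal(length(mods$modules), 2L)
  in_mod <- vapply(mods$modules, function(m) "g" %in% m$genes, logical(1))
  expect_equal(sum(in_mod), 2L)

  # single-module state: every gene lands in that module
  fu1 <- fu_from_spec(expr[1:2, ], list("a1", "a2"))
  st1 <- high_level_search(fu1, null = null)
  mods1 <- finalize_assignment(st1, fu1)
  expect_equal(length(mods1$modules), 1L)
  expect_setequal(mods1$modules[[1]]$genes, c("a1", "a2"))
})

test_that("state_value recomputes features and CP from an assignment", {
  f <- orthonormal_patterns(20, 2, seed = 27)
  expr <- expr_from_rows(list(a = f[, 1], b = f[, 2]))
  fu <- fu_from_spec(expr, list("a", "b"))
  null <- corr_null(20, B = 200, seed = 27)
  sv <- state_value(fu, c(1L, 2L), null)
  expect_equal(dim(sv$features), c(2L, 20L))
  expect_equal(sv$value, 2, tolerance = 1e-9)  # each unit matches its feature
})
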
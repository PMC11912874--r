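test_that("module networks keep known edges and fall back to coexpression", {
  f <- orthonormal_patterns(20, 3, seed = 31)
  expr <- expr_from_rows(list(
    A = f[, 1], B = pattern_with_r(f[, 1], f[, 2], 0.9),
    C = pattern_with_r(f[, 1], f[, 3], 0.85),
    D = pattern_with_r(f[, 1], f[, 2], 0.7)))
  ppi <- interaction_set(data.frame(source = c("A", "B"),
                                    target = c("B", "C"), score = 1),
                         itype = "ppi", normalize = FALSE)
  mln <- build_multilayer(expr, ppi)

  # A-B and B-C known; D isolated -> coexpression fallback (|r| >= 0.6)
  net <- assemble_module_network(c("A", "B", "C", "D"), mln, expr,
                                 coexpr_threshold = 0.6)
  known <- net$edges[net$edges$itype == "ppi", ]
  expect_setequal(paste(known$source, known$target), c("A B", "B C"))
  co <- net$edges[net$edges$itype == "coexpression", ]
  expect_true(all(co$source == "D" | co$target == "D"))
  expect_true(all(co$weight >= 0.6))
  # every member has degree >= 1
  deg <- table(c(net$edges$source, net$edges$target))
  expect_true(all(c("A", "B", "C", "D") %in% names(deg)))
})

test_that("two-gene modules with no known edge use the best-partner rule", {
  set.seed(32)
  expr <- expr_from_rows(list(A = rnorm(15), B = rnorm(15), C = rnorm(15)))
  ppi <- interaction_set(data.frame(source = "A", target = "B", score = 1),
                         itype = "ppi", normalize = FALSE)
  mln <- build_multilayer(expr, ppi)
  # module {A, C} has no known internal edge; correlation is weak but the
  # single best partner is still linked
  net <- assemble_module_network(c("A", "C"), mln, expr,
                                 coexpr_threshold = 0.99)
  expect_equal(nrow(net$edges), 1L)
  expect_equal(net$edges$itype, "coexpression")

  expect_warning(one <- assemble_module_network("A", mln, expr),
                 "single-gene")
  expect_equal(nrow(one$edges), 0L)
})

test_that("consensus keeps only pairs co-moduled in every condition", {
  conds <- list(
    stage1 = list(M1 = c("a", "b", "c"), M2 = c("d", "e")),
    stage2 = list(M1 = c("a", "b"), M2 = c("c", "d", "e")),
    stage3 = list(M1 = c("a", "b", "c", "d", "e")),
    stage4 = list(M1 = c("a", "b", "e"), M2 = c("c", "d")))
  cons <- build_consensus(conds)
  keys <- paste(cons$edges$gene_a, cons$edges$gene_b)
  expect_true("a b" %in% keys)        # together in 4/4
  expect_false("c d" %in% keys)       # together in 3/4 only
  expect_false("a c" %in% keys)       # together in 2/4 only

  # independent set-algebra oracle: intersection of per-condition co-module
  # pair sets
  pair_set <- function(ms) {
    unique(unlist(lapply(ms, function(g) {
      if (length(g) < 2) return(character(0))
      pr <- combn(sort(g), 2)
      paste(pr[1, ], pr[2, ])
    })))
  }
  oracle <- Reduce(intersect, lapply(conds, pair_set))
  expect_setequal(keys, oracle)

  # relaxation flag: pairs co-moduled in >= 3 of 4 conditions return
  cons3 <- build_consensus(conds, min_conditions = 3)
  keys3 <- paste(cons3$edges$gene_a, cons3$edges$gene_b)
  expect_true(all(c("a b", "c d", "d e") %in% keys3))
  expect_false("a c" %in% keys3)

  # degenerate single condition: the co-module graph itself
  c1 <- build_consensus(conds[1])
  expect_setequal(paste(c1$edges$gene_a, c1$edges$gene_b),
                  pair_set(conds[[1]]))

  expect_warning(build_consensus(list(list(M1 = c("a", "b")),
                                      list(M1 = c("x", "y")))),
                 "no gene pair")
})

test_that("consensus edges inherit regulator provenance from networks", {
  conds <- list(list(M1 = c("a", "b", "c")))
  nw <- data.frame(source = c("a", "a"), target = c("b", "c"),
                   provenance = c("R1;direct:ppi", "R1"))
  cons <- build_consensus(conds, networks = list(nw))
  e <- cons$edges
  ab <- e$provenance[e$gene_a == "a" & e$gene_b == "b"]
  expect_equal(ab, "R1;direct:ppi")
  expect_true(is.na(e$provenance[e$gene_a == "b" & e$gene_b == "c"]))
})

test_that("crosstalk assembly keeps only fully supported sender-bridge-receiver paths", {
  sender <- data.frame(source = c("TF1", "TF2", "TF3"),
                       target = c("L1", "L2", "L2"))
  bridge <- interaction_set(data.frame(source = c("L1", "L2", "L9"),
                                       target = c("RT1", "RT2", "RT3"),
                                       score = 1),
                            itype = "ligand_tf", normalize = FALSE)
  receiver <- data.frame(source = c("RT1", "RT1", "RT9"),
                         target = c("t1", "t2", "t3"))
  ct <- assemble_crosstalk(sender, receiver, bridge)
  # L9 has no sender TF; RT2 has no downstream target: both pruned
  expect_equal(ct$bridge_edges$source, "L1")
  expect_equal(ct$sender_edges$source, "TF1")
  expect_setequal(ct$receiver_edges$target, c("t1", "t2"))
  # no dangling bridge endpoint (tier audit)
  expect_true(all(ct$bridge_edges$source %in% ct$sender_edges$target))
  expect_true(all(ct$bridge_edges$target %in% ct$receiver_edges$source))

  # path-count oracle: DFS over the three tiers
  n_paths <- 0
  for (i in seq_len(nrow(ct$sender_edges))) {
    lig <- ct$sender_edges$target[i]
    for (rt in ct$bridge_edges$target[ct$bridge_edges$source == lig]) {
      n_paths <- n_paths +
        sum(ct$receiver_edges$source == rt)
    }
  }
  expect_equal(n_paths, 2L)  # TF1 -> L1 -> RT1 -> {t1, t2}

  expect_warning(assemble_crosstalk(sender[0, ], receiver, bridge),
                 "no bridge edge")
})

test_that("hypergeometric enrichment matches an explicit combinatorial tail", {
  bg <- sprintf("g%04d", 1:1000)
  set10 <- bg[1:10]
  mods <- list(hit = bg[1:10], miss = bg[101:110])
  res <- enrich_modules(mods, list(s = set10), background = bg)

  tail_p <- function(k0, K, N, n) {
    sum(vapply(k0:min(K, n), function(k) {
      choose(K, k) * choose(N - K, n - k) / choose(N, n)
    }, numeric(1)))
  }
  hit <- res[res$module == "hit", ]
  expect_equal(hit$p, tail_p(10, 10, 1000, 10), tolerance = 1e-12)
  miss <- res[res$module == "miss", ]
  expect_equal(miss$p, 1, tolerance = 1e-12)   # zero overlap -> tail is 1

  # module equal to the background: p = 1 for every set
  res2 <- enrich_modules(list(all = bg), list(s = set10), background = bg)
  expect_equal(res2$p, 1, tolerance = 1e-12)

  # BH adjustment is monotone and bounded by 1
  expect_true(all(res$adjusted_p >= res$p - 1e-15))
  expect_true(all(res$adjusted_p <= 1))
})
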
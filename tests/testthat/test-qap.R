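test_that("self-comparison gives r_obs = 1 and hand-enumerable exact p at g = 3", {
  A <- matrix(c(1, 0.1, 0.5, 0.1, 1, 0.9, 0.5, 0.9, 1), 3, 3,
              dimnames = list(letters[1:3], letters[1:3]))
  res <- qap_exhaustive(A, A)
  expect_equal(res$r_obs, 1)
  # all off-diagonal values distinct: only the identity relabeling
  # reproduces the alignment, so p = 1/3! (verified against the direct
  # per-permutation oracle)
  perms <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                 c(3, 1, 2), c(3, 2, 1))
  r_all <- apply(perms, 1, function(p) qap_r_for_perm(A, A, p))
  expect_equal(res$p, mean(r_all >= 1 - 1e-12))
  expect_equal(res$p, 1 / 6)
  expect_equal(res$mode, "exhaustive")
})

test_that("zero off-diagonal variance yields an undefined association", {
  A <- matrix(0.4, 4, 4); diag(A) <- 1
  B <- random_symmetric_matrix(4)
  res <- qap_exhaustive(B, A)
  expect_false(res$defined)
  expect_true(is.na(res$p))
})

test_that("QAP is invariant under a common relabeling of both matrices", {
  withr::with_seed(31, {
    A <- random_symmetric_matrix(5)
    B <- random_symmetric_matrix(5)
    perm <- sample(5)
    Ap <- A[perm, perm]; Bp <- B[perm, perm]
    r1 <- qap_exhaustive(A, B); r2 <- qap_exhaustive(Ap, Bp)
    expect_equal(r1$r_obs, r2$r_obs, tolerance = 1e-12)
    expect_equal(r1$p, r2$p)
  })
})

test_that("monte-carlo p approaches the exhaustive p and never returns 0", {
  withr::with_seed(37, {
    for (i in 1:5) {
      A <- random_symmetric_matrix(5)
      B <- random_symmetric_matrix(5)
      pe <- qap_exhaustive(A, B)$p
      pm <- qap_correlation(A, B, n_perm = 5000, seed = 1000 + i,
                            mode = "monte_carlo")$p
      expect_lt(abs(pm - pe),
                max(3 * sqrt(pe * (1 - pe) / 5000), 2 / 5001))
      expect_gte(pm, 1 / 5001)
    }
    # maximally dissimilar pair: add-one estimator still bounded away from 0
    A <- random_symmetric_matrix(5)
    B <- A; B[upper.tri(B)] <- -A[upper.tri(A)]
    B[lower.tri(B)] <- t(B)[lower.tri(B)]
    pm <- qap_correlation(A, B, n_perm = 200, seed = 2, mode = "monte_carlo")
    expect_gte(pm$p, 1 / 201)
  })
})

test_that("exhaustive mode is auto-selected when g! <= n_perm and is deterministic", {
  A <- random_symmetric_matrix(5); B <- random_symmetric_matrix(5)
  r <- qap_correlation(A, B, n_perm = 5000)
  expect_equal(r$mode, "exhaustive")
  expect_equal(r$p, qap_correlation(A, B, n_perm = 5000)$p)
  big1 <- random_symmetric_matrix(9); big2 <- random_symmetric_matrix(9)
  expect_error(qap_correlation(big1, big2, mode = "exhaustive"), "g > 8")
})

test_that("coexpression matrices have the declared structure", {
  s <- quick_study(seed = 41, effects = default_effects())
  tab <- s$expression_true
  m <- coexpression_matrix(tab, "winner", "Dm")
  expect_s3_class(m, "coexpr_matrix")
  expect_equal(diag(m$r), rep(1, 6), ignore_attr = TRUE)
  expect_equal(m$r, t(m$r))
  expect_true(all(abs(m$r[upper.tri(m$r)]) <= 1))
  expect_true(all(m$n[upper.tri(m$n)] == 12))
  up <- upper.tri(m$p)
  expect_true(all(m$p_adj[up] >= m$p[up] - 1e-12))
  # duplicating a gene as two variables gives r = 1 on that pair
  dup <- tab[tab$gene == "bdnf" & tab$treatment == "winner" &
               tab$nucleus == "Dm", ]
  dup$gene <- "bdnf2"
  m2 <- coexpression_matrix(rbind(tab, dup), "winner", "Dm",
                            genes = c("bdnf", "bdnf2"))
  expect_equal(m2$r["bdnf", "bdnf2"], 1)
})

test_that("genes with too few observations are marked missing", {
  s <- quick_study(seed = 43)
  tab <- s$expression_true
  tab <- tab[!(tab$gene == "wnt3" & tab$treatment == "loser" &
                 tab$nucleus == "Vv" &
                 tab$fish_id %in% unique(tab$fish_id)[1:43]), ]
  expect_message(m <- coexpression_matrix(tab, "loser", "Vv"), "wnt3")
  expect_true("wnt3" %in% m$dropped_genes)
  expect_true(all(is.na(m$r["wnt3", setdiff(m$genes, "wnt3")])))
})

test_that("partition letters follow the similarity-graph components", {
  C <- coexpr_archetype(1, paste0("g", 1:6))
  # three identical matrices: complete graph, single class
  ms <- list(u1 = C, u2 = C, u3 = C)
  p <- partition_states(ms, axis = "treatments", n_perm = 5000)
  expect_true(all(p$labels == "A"))
  # similarity threshold below the attainable minimum p: empty graph,
  # one class per unit
  p2 <- partition_states(ms, axis = "nuclei", alpha = 1 / 1000,
                         n_perm = 5000)
  expect_equal(sort(unname(p2$labels)), c("a", "b", "c"))
  expect_equal(nrow(p2$edges), 3)
})

test_that("undefined associations exclude their units from the partition", {
  C <- coexpr_archetype(2, paste0("g", 1:5))
  flat <- matrix(0.2, 5, 5); diag(flat) <- 1
  dimnames(flat) <- dimnames(C)
  p <- partition_states(list(a = C, b = C, c = flat), n_perm = 1000,
                        seed = 1)
  expect_true("c" %in% p$excluded)
  expect_false("c" %in% names(p$labels))
})

test_that("significance marks follow the adjusted-p thresholds", {
  expect_equal(significance_marks(c(0.0004, 0.004, 0.04, 0.08, 0.4, NA)),
               c("***", "**", "*", ".", "", ""))
})
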
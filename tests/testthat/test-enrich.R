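test_that("hypergeometric p matches hand-derived and boundary cases", {
  # empty sum in the printed formula
  expect_equal(hypergeom_p(10, 4, 5, 0), 1)
  # C(5,3)C(5,1) + C(5,4)C(5,0) over C(10,4) = 55/210
  expect_equal(hypergeom_p(10, 4, 5, 3), 55 / 210, tolerance = 1e-14)
  # every gene annotated to the term
  expect_equal(hypergeom_p(100, 10, 100, 10), 1)
  # bounds violations
  expect_error(hypergeom_p(10, 4, 11, 1), class = "pscnet_domain_error")
  expect_error(hypergeom_p(10, 4, 5, 5), class = "pscnet_domain_error")
  expect_error(hypergeom_p(10, 4, 5, -1), class = "pscnet_domain_error")
})

test_that("hypergeometric p is non-increasing in m and agrees with phyper", {
  set.seed(11)
  for (rep in 1:50) {
    N <- sample(5:5000, 1)
    n <- sample(0:N, 1)
    M <- sample(1:N, 1)
    hi <- min(n, M)
    p <- hypergeom_p(N, n, M, 0:hi)
    expect_true(all(diff(p) <= 1e-12))
    # dual route: stats::phyper upper tail
    ref <- stats::phyper(0:hi - 1, M, N - M, n, lower.tail = FALSE)
    expect_equal(p, ref, tolerance = 1e-10)
  }
})

test_that("Cohen's kappa matches the 2x2 hand computation and edge rules", {
  universe <- sprintf("g%03d", 1:100)
  # disjoint 10 vs 10 in 100: table (0,10,10,80), kappa = -1/9
  expect_equal(kappa_score(universe[1:10], universe[11:20], universe),
               -1 / 9, tolerance = 1e-12)
  # identical non-trivial sets
  expect_equal(kappa_score(universe[1:10], universe[1:10], universe), 1)
  # degenerate: both terms equal the whole universe
  expect_equal(kappa_score(universe, universe, universe), 1)
  # degenerate: universe vs empty set
  expect_equal(kappa_score(universe, character(0), universe), 0)
  expect_error(kappa_score("a", "a", character(0)),
               class = "pscnet_domain_error")
})

test_that("kappa is symmetric and invariant under universe relabeling", {
  set.seed(3)
  universe <- sprintf("g%03d", 1:80)
  for (rep in 1:20) {
    a <- sample(universe, sample(1:40, 1))
    b <- sample(universe, sample(1:40, 1))
    k1 <- kappa_score(a, b, universe)
    expect_equal(k1, kappa_score(b, a, universe), tolerance = 1e-12)
    relabel <- setNames(sample(universe), universe)
    expect_equal(kappa_score(unname(relabel[a]), unname(relabel[b]),
                             unname(relabel)),
                 k1, tolerance = 1e-12)
  }
})

test_that("enrichment handles empty lists and is self-consistent", {
  sets <- list(T1 = sprintf("g%d", 1:10), T2 = sprintf("g%d", 5:20))
  universe <- sprintf("g%d", 1:40)
  e0 <- enrich_terms(character(0), sets, universe = universe)
  expect_true(all(e0$m == 0))
  expect_true(all(e0$p_value == 1))
  expect_false(any(e0$significant))

  # a term identical to the DE list with N = 2n
  de <- sprintf("g%d", 1:20)
  sets2 <- list(SAME = de)
  e1 <- enrich_terms(de, sets2, universe = sprintf("g%d", 1:40))
  expect_equal(e1$p_value, hypergeom_p(40, 20, 20, 20), tolerance = 1e-14)

  # genes outside the universe are dropped with a warning
  expect_warning(enrich_terms(c(de, "nope"), sets2,
                              universe = sprintf("g%d", 1:40)),
                 "dropped")
  expect_error(enrich_terms(de, sets2, universe = character(0)),
               class = "pscnet_domain_error")
})

test_that("enrichment ranking is invariant to input term order", {
  set.seed(8)
  universe <- sprintf("g%03d", 1:200)
  sets <- lapply(1:12, function(i) sample(universe, 25))
  names(sets) <- sprintf("T%02d", 1:12)
  de <- sample(universe, 30)
  e1 <- enrich_terms(de, sets, universe = universe)
  e2 <- enrich_terms(de, sets[sample(12)], universe = universe)
  expect_equal(as.data.frame(e1), as.data.frame(e2))
})

test_that("planted enriched terms rank above background terms", {
  hits <- 0
  runs <- 50
  for (s in seq_len(runs)) {
    cfg <- sim_config(n_genes = 300, n_de = 40, n_hubs = 0, n_cis_pairs = 0,
                      n_terms = 20, term_size = 20, n_enriched_terms = 3,
                      enrich_odds = 8, seed = 1000 + s)
    b <- simulate_counts(cfg)
    e <- enrich_terms(b$truth$de_genes$gene_id, b$gene_sets,
                      universe = b$annotation$gene_id)
    planted_ranks <- which(e$term_id %in% b$truth$enriched_terms)
    if (max(planted_ranks) == length(b$truth$enriched_terms)) hits <- hits + 1
  }
  expect_gte(hits / runs, 0.95)
})

test_that("term clustering merges redundant terms and isolates dissimilar ones", {
  universe <- sprintf("g%03d", 1:100)
  sets <- list(A1 = universe[1:20], A2 = universe[1:20], B = universe[41:60])
  de <- universe[c(1:15, 41:50)]
  e <- enrich_terms(de, sets, universe = universe)
  cl <- cluster_terms(e, sets, universe = universe, threshold = 0.3)
  expect_equal(dplyr::n_distinct(cl$cluster[!is.na(cl$cluster)]), 2)
  expect_equal(cl$cluster[cl$term_id == "A1"], cl$cluster[cl$term_id == "A2"])
  expect_false(cl$cluster[cl$term_id == "B"] %in%
                 cl$cluster[cl$term_id == "A1"])
  expect_equal(sum(cl$representative), 2)

  # all pairwise kappas below threshold -> singletons
  sets2 <- list(X = universe[1:10], Y = universe[11:20], Z = universe[21:30])
  de2 <- universe[c(1:8, 11:18, 21:28)]
  e2 <- enrich_terms(de2, sets2, universe = universe)
  cl2 <- cluster_terms(e2, sets2, universe = universe, threshold = 0.3)
  expect_equal(dplyr::n_distinct(cl2$cluster[!is.na(cl2$cluster)]),
               sum(!is.na(cl2$cluster)))
})

test_that("two planted term families are recovered as two clusters", {
  set.seed(4)
  universe <- sprintf("g%03d", 1:200)
  core_a <- universe[1:25]
  core_b <- universe[101:125]
  # within-family Jaccard >= 0.8 (24 of 25 shared), zero overlap between
  sets <- list(A1 = core_a, A2 = c(core_a[1:24], universe[30]),
               B1 = core_b, B2 = c(core_b[1:24], universe[130]))
  de <- c(core_a[1:20], core_b[1:20])
  e <- enrich_terms(de, sets, universe = universe)
  cl <- cluster_terms(e, sets, universe = universe, threshold = 0.3)
  lab <- setNames(cl$cluster, cl$term_id)
  expect_equal(lab[["A1"]], lab[["A2"]])
  expect_equal(lab[["B1"]], lab[["B2"]])
  expect_false(lab[["A1"]] == lab[["B1"]])
})
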
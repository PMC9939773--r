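test_that("median-of-ratios size factors match hand computations", {
  # identical samples -> unit factors
  m <- matrix(c(10, 20, 10, 20), ncol = 2,
              dimnames = list(NULL, c("a", "b")))
  counts <- dplyr::bind_cols(tibble::tibble(gene_id = c("G1", "G2")),
                             tibble::as_tibble(m))
  expect_equal(unname(size_factors(counts)), c(1, 1))

  # sample b = 2x sample a, genes (10, 20): factors (1/sqrt(2), sqrt(2))
  m <- matrix(c(10, 20, 20, 40), ncol = 2,
              dimnames = list(NULL, c("a", "b")))
  counts <- dplyr::bind_cols(tibble::tibble(gene_id = c("G1", "G2")),
                             tibble::as_tibble(m))
  expect_equal(unname(size_factors(counts)), c(1 / sqrt(2), sqrt(2)),
               tolerance = 1e-12)

  # an all-zero sample is degenerate
  m <- matrix(c(10, 20, 0, 0), ncol = 2, dimnames = list(NULL, c("a", "b")))
  counts <- dplyr::bind_cols(tibble::tibble(gene_id = c("G1", "G2")),
                             tibble::as_tibble(m))
  expect_error(size_factors(counts), class = "pscnet_degenerate_input")
})

test_that("size factors are stable under sample relabeling", {
  set.seed(1)
  m <- matrix(rpois(60, 50), nrow = 10)
  colnames(m) <- sprintf("s%d", 1:6)
  counts <- dplyr::bind_cols(tibble::tibble(gene_id = sprintf("G%d", 1:10)),
                             tibble::as_tibble(m))
  sf <- size_factors(counts)
  perm <- c(4, 2, 6, 1, 3, 5)
  counts_p <- counts[, c(1, 1 + perm)]
  expect_equal(size_factors(counts_p), sf[perm])
})

test_that("zero-variance genes are ns with p = 1", {
  # many flat genes pin the size factors at 1 so the flat gene stays constant
  m <- rbind(matrix(50, nrow = 9, ncol = 6),
             c(10, 12, 11, 200, 210, 190))   # strong DE gene
  de <- test_de(toy_counts(m), toy_samples, min_expr = 0)
  flat <- de[de$gene_id == "G01", ]
  expect_equal(flat$p_value, 1)
  expect_equal(flat$direction, "ns")
  expect_equal(de$direction[de$gene_id == "G10"], "up")
})

test_that("relabeling groups flips fold changes and swaps directions", {
  set.seed(7)
  m <- matrix(rnbinom(240, mu = 100, size = 20), nrow = 40)
  m[1:5, 4:6] <- m[1:5, 4:6] * 8
  counts <- toy_counts(m, sprintf("G%02d", 1:40))
  de1 <- test_de(counts, toy_samples, min_expr = 0)
  swapped <- toy_samples
  swapped$group <- ifelse(swapped$group == "control", "case", "control")
  de2 <- test_de(counts, swapped, min_expr = 0)
  expect_equal(de2$log2fc, -de1$log2fc, tolerance = 1e-12)
  expect_equal(de2$p_value, de1$p_value, tolerance = 1e-12)
  expect_equal(de2$direction[de1$direction == "up"],
               rep("down", sum(de1$direction == "up")))
  expect_equal(de2$direction[de1$direction == "down"],
               rep("up", sum(de1$direction == "down")))
})

test_that("direction labels follow the (fdr, log2fc) rule exactly", {
  b <- simulate_counts(sim_config(n_genes = 400, n_de = 60, seed = 13,
                                  n_cis_pairs = 0))
  de <- test_de(b$counts, b$samples, alpha = 0.05, fc_min = 2)
  expected <- ifelse(de$fdr < 0.05 & de$log2fc >= 1, "up",
                     ifelse(de$fdr < 0.05 & de$log2fc <= -1, "down", "ns"))
  expect_identical(de$direction, expected)
})

test_that("insufficient replication and missing groups are errors", {
  m <- matrix(rpois(12, 30), nrow = 2)
  colnames(m) <- sprintf("s%d", 1:6)
  counts <- dplyr::bind_cols(tibble::tibble(gene_id = c("G1", "G2")),
                             tibble::as_tibble(m))
  samples <- tibble::tibble(sample_id = sprintf("s%d", 1:6),
                            group = c("control", rep("case", 5)))
  expect_error(test_de(counts, samples),
               class = "pscnet_insufficient_replication")
  expect_error(test_de(counts, samples[-1, ]), "without group")
})

test_that("partition_de yields four disjoint lists with matching counts", {
  # empty input
  empty <- test_de(toy_counts(matrix(50, 2, 6)), toy_samples, min_expr = 0)
  ann0 <- tibble::tibble(gene_id = c("G01", "G02"),
                         biotype = c("lncRNA", "mRNA"))
  p0 <- partition_de(empty, ann0)
  expect_equal(p0$n, rep(0L, 4))

  # one up lncRNA + one down mRNA -> counts (1, 0, 0, 1)
  m <- rbind(c(10, 11, 10, 300, 310, 290),
             c(300, 310, 290, 10, 11, 10),
             c(50, 52, 48, 49, 51, 50))
  ann <- tibble::tibble(gene_id = c("G01", "G02", "G03"),
                        biotype = c("lncRNA", "mRNA", "mRNA"))
  de <- test_de(toy_counts(m), toy_samples, annotation = ann, min_expr = 0)
  p <- partition_de(de)
  expect_equal(p$n[p$biotype == "lncRNA" & p$direction == "up"], 1L)
  expect_equal(p$n[p$biotype == "lncRNA" & p$direction == "down"], 0L)
  expect_equal(p$n[p$biotype == "mRNA" & p$direction == "up"], 0L)
  expect_equal(p$n[p$biotype == "mRNA" & p$direction == "down"], 1L)
  expect_equal(sum(p$n) + attr(p, "n_ns"), nrow(de))

  # unannotated gene is an error naming the gene
  expect_error(partition_de(de, ann[-1, ]), "G01",
               class = "pscnet_annotation_mismatch")
})

test_that("a planted 30-up/70-down lncRNA split is recovered within 10% per cell", {
  cfg <- sim_config(n_genes = 500, frac_lncRNA = 0.4, n_de = 250,
                    de_frac_up = 0.3, de_log2fc = 3, nb_dispersion = 0.01,
                    n_hubs = 0, n_cis_pairs = 0, seed = 77)
  b <- simulate_counts(cfg)
  # planted lncRNA split: 100 DE lncRNAs, 30% up
  truth <- dplyr::left_join(b$truth$de_genes,
                            b$annotation[, c("gene_id", "biotype")],
                            by = "gene_id")
  n_up_true <- sum(truth$biotype == "lncRNA" & truth$log2fc > 0)
  n_down_true <- sum(truth$biotype == "lncRNA" & truth$log2fc < 0)
  de <- test_de(b$counts, b$samples, b$annotation)
  p <- partition_de(de)
  n_up <- p$n[p$biotype == "lncRNA" & p$direction == "up"]
  n_down <- p$n[p$biotype == "lncRNA" & p$direction == "down"]
  expect_lte(abs(n_up - n_up_true), ceiling(0.1 * n_up_true))
  expect_lte(abs(n_down - n_down_true), ceiling(0.1 * n_down_true))
})
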
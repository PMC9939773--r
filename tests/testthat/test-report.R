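sim_and_write <- function(dir, seed = 101, ...) {
  cfg <- sim_config(n_genes = 400, n_de = 60, n_cis_pairs = 4, seed = seed,
                    ...)
  b <- simulate_counts(cfg)
  g <- simulate_interaction_graph(cfg)
  paths <- write_sim_bundle(b, dir, graph = g)
  list(bundle = b, graph = g, paths = paths)
}

test_that("the 2^-ddCt calculator matches direct arithmetic", {
  make <- function(target_case) tibble::tibble(
    sample_id = sprintf("s%d", 1:6),
    group = rep(c("control", "case"), each = 3),
    target_ct = c(20, 20, 20, rep(target_case, 3)),
    reference_ct = rep(15, 6))
  expect_equal(ddct(make(20))$fold_change, 1)
  expect_equal(ddct(make(21))$fold_change, 0.5)
  r <- ddct(make(23))  # control dCt mean 5, case 8 -> ddCt 3
  expect_equal(r$ddct, 3)
  expect_equal(r$fold_change, 0.125)
  expect_equal(r$direction, "down")
  expect_equal(glance(r)$fold_change, 0.125)

  bad <- make(20); bad$target_ct[1] <- NA
  expect_error(ddct(bad), "finite")
  expect_error(ddct(dplyr::rename(make(20), ct = target_ct)), "columns")
})

test_that("top_k_by_p caps at availability and breaks ties by gene id", {
  b <- simulate_counts(sim_config(n_genes = 50, frac_lncRNA = 0.2, n_de = 10,
                                  n_hubs = 1, hub_module_size = 3,
                                  n_cis_pairs = 1, n_terms = 5, seed = 55))
  de <- test_de(b$counts, b$samples, b$annotation)
  norm <- normalize_counts(b$counts)
  top <- top_k_by_p(de, norm, k = 100)
  expect_equal(nrow(top), nrow(de))  # k beyond availability
  expect_true(all(diff(top$p_value) >= 0))
  ties <- split(top$gene_id, top$p_value)
  expect_true(all(vapply(ties, function(g) !is.unsorted(g), logical(1))))
  lnc_only <- top_k_by_p(de, norm, k = 5, biotype = "lncRNA")
  expect_lte(nrow(lnc_only), 5)
})

test_that("planted DE genes are over-represented among the top-k by p", {
  b <- simulate_counts(sim_config(n_genes = 1000, n_de = 100, seed = 61,
                                  n_cis_pairs = 0))
  de <- test_de(b$counts, b$samples, b$annotation)
  norm <- normalize_counts(b$counts)
  top <- top_k_by_p(de, norm, k = 100)
  m <- sum(top$gene_id %in% b$truth$de_genes$gene_id)
  p <- hypergeom_p(nrow(de), nrow(top), nrow(b$truth$de_genes), m)
  expect_lt(p, 0.01)
})

test_that("the pipeline runs end-to-end and reconciles its manifest", {
  dir <- withr::local_tempdir()
  s <- sim_and_write(file.path(dir, "in"))
  cfg <- pipeline_config(
    counts = s$paths[["counts"]], samples = s$paths[["samples"]],
    annotation_bed = s$paths[["annotation_bed"]],
    biotype = s$paths[["biotype"]], gmt = s$paths[["gmt"]],
    sif = s$paths[["sif"]], out_dir = file.path(dir, "out"))
  res <- run_pipeline(cfg)
  expected <- c("de_results.tsv", "de_summary.tsv", "enrichment.tsv",
                "network_edges.tsv", "network_edges.sif",
                "network_nodes.tsv", "top_hubs.tsv", "modules.tsv",
                "cis_pairs.tsv", "heatmap_top_lncRNA.tsv",
                "heatmap_top_mRNA.tsv", "volcano.tsv", "run_manifest.txt")
  for (f in expected) {
    path <- file.path(dir, "out", f)
    expect_true(file.exists(path), label = f)
    expect_gt(file.size(path), 0)
  }
  man <- readLines(file.path(dir, "out", "run_manifest.txt"))
  get <- function(key) as.numeric(sub(".*: ", "", grep(key, man, value = TRUE)))
  expect_equal(get("genes_tested"), get("genes_input") - get("genes_prefiltered"))
  expect_equal(sum(res$de$direction != "ns"),
               get("de_lncRNA_up") + get("de_lncRNA_down") +
                 get("de_mRNA_up") + get("de_mRNA_down"))
  # detected MCODE modules should include the planted clique
  expect_true(any(vapply(res$modules$members,
                         function(m) setequal(m, s$graph$clique),
                         logical(1))))
})

test_that("degenerate thresholds call every tested gene", {
  dir <- withr::local_tempdir()
  s <- sim_and_write(file.path(dir, "in"), seed = 71)
  cfg <- pipeline_config(
    counts = s$paths[["counts"]], samples = s$paths[["samples"]],
    annotation_bed = s$paths[["annotation_bed"]],
    biotype = s$paths[["biotype"]], gmt = s$paths[["gmt"]],
    out_dir = file.path(dir, "out"), alpha = 1, fc_min = 1)
  res <- run_pipeline(cfg)
  expect_true(all(res$de$direction %in% c("up", "down")))
})

test_that("tables round-trip losslessly through their own readers", {
  dir <- withr::local_tempdir()
  s <- sim_and_write(dir)
  b <- s$bundle
  counts2 <- read_counts(s$paths[["counts"]])
  expect_equal(as.data.frame(counts2), as.data.frame(b$counts))
  samples2 <- read_samples(s$paths[["samples"]])
  expect_equal(as.data.frame(samples2), as.data.frame(b$samples))
  ann2 <- read_annotation(s$paths[["annotation_bed"]], s$paths[["biotype"]])
  expect_equal(as.data.frame(ann2[order(ann2$gene_id), ]),
               as.data.frame(b$annotation[order(b$annotation$gene_id), ]))
  gmt2 <- read_gmt(s$paths[["gmt"]])
  expect_equal(unname(gmt2), b$gene_sets$genes)
  expect_equal(names(gmt2), b$gene_sets$term_id)
  sif2 <- read_sif(s$paths[["sif"]])
  expect_equal(as.data.frame(sif2), as.data.frame(s$graph$edges))
})
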
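#' Pipeline configuration
#'
#' Collects input paths and stage thresholds for [run_pipeline()]. Inputs
#' follow the on-disk layout of [write_sim_bundle()]: counts TSV, samples
#' TSV, 6-column BED plus biotype TSV, GMT gene sets, and optionally a SIF
#' interaction network for dense-module detection (when absent, modules are
#' detected on the co-expression network itself).
#'
#' @param counts,samples,annotation_bed,biotype,gmt Input file paths.
#' @param sif Optional SIF interaction edge list path.
#' @param out_dir Output directory (created if needed).
#' @param alpha,fc_min,min_expr,pseudocount DE screen thresholds, see
#'   [test_de()].
#' @param r_min,p_max Co-expression thresholds, see [build_network()].
#' @param kappa Kappa threshold for term clustering (default 0.3).
#' @param top_terms Significant terms clustered (default 20).
#' @param window Cis window in bp (default 100000).
#' @param vwp MCODE vertex weight percentage (default 0.2).
#' @param n_hubs Hubs reported (default 10).
#' @param top_k Genes per biotype in the heat-map table (default 100).
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(counts, samples, annotation_bed, biotype, gmt,
                            sif = NULL, out_dir,
                            alpha = 0.05, fc_min = 2, min_expr = 1,
                            pseudocount = 1, r_min = 0.9, p_max = 0.01,
                            kappa = 0.3, top_terms = 20, window = 100000,
                            vwp = 0.2, n_hubs = 10, top_k = 100) {
  cfg <- list(counts = counts, samples = samples,
              annotation_bed = annotation_bed, biotype = biotype, gmt = gmt,
              sif = sif, out_dir = out_dir,
              alpha = alpha, fc_min = fc_min, min_expr = min_expr,
              pseudocount = pseudocount, r_min = r_min, p_max = p_max,
              kappa = kappa, top_terms = top_terms, window = window,
              vwp = vwp, n_hubs = n_hubs, top_k = top_k)
  for (f in c("counts", "samples", "annotation_bed", "biotype", "gmt"))
    if (!file.exists(cfg[[f]])) config_error(f, "file does not exist")
  if (!is.null(sif) && !file.exists(sif)) config_error("sif", "file does not exist")
  if (alpha <= 0 || alpha > 1) config_error("alpha", "must lie in (0, 1]")
  if (fc_min < 1) config_error("fc_min", "must be >= 1")
  if (r_min < 0 || r_min > 1) config_error("r_min", "must lie in [0, 1]")
  if (p_max <= 0 || p_max > 1) config_error("p_max", "must lie in (0, 1]")
  if (window < 0) config_error("window", "must be >= 0")
  if (vwp < 0 || vwp >= 1) config_error("vwp", "must lie in [0, 1)")
  structure(cfg, class = "pipeline_config")
}

#' Run the full downstream analysis pipeline
#'
#' Executes the stages in dependency order — DE screen, biotype/direction
#' partition, gene-set enrichment with kappa clustering, lncRNA-mRNA
#' co-expression network and hub ranking, dense-module detection (on the SIF
#' network when provided, else on the co-expression network), cis-target
#' prediction, and plotting-ready tables (volcano, top-k-by-p heat-map
#' input) — writing each result as TSV into `out_dir` together with a
#' `run_manifest.txt` recording thresholds and in/out counts of every
#' filtering step. All stages are deterministic, so a rerun with the same
#' config is byte-identical.
#'
#' @param config A [pipeline_config()] object.
#' @return Invisibly, a named list with all stage results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  counts <- read_counts(config$counts)
  samples <- read_samples(config$samples)
  annotation <- read_annotation(config$annotation_bed, config$biotype)
  gene_sets <- read_gmt(config$gmt)

  de <- test_de(counts, samples, annotation,
                alpha = config$alpha, fc_min = config$fc_min,
                min_expr = config$min_expr, pseudocount = config$pseudocount)
  de_sum <- partition_de(de)
  enr <- suppressWarnings(
    enrich_terms(c(de_genes_of(de_sum, "lncRNA"), de_genes_of(de_sum, "mRNA")),
                 gene_sets, universe = annotation$gene_id,
                 alpha = 0.05))
  enr_clustered <- if (any(enr$significant)) {
    cluster_terms(enr, gene_sets, universe = annotation$gene_id,
                  threshold = config$kappa, top_k = config$top_terms)
  } else enr

  net <- build_network(counts, de_sum, r_min = config$r_min,
                       p_max = config$p_max,
                       pseudocount = config$pseudocount)
  hubs <- top_hubs(net, de, k = config$n_hubs)

  module_edges <- if (!is.null(config$sif)) {
    filter_edges(read_sif(config$sif), min_score = NULL)
  } else {
    net$edges %>% select(node_a = "lncRNA", node_b = "mRNA")
  }
  mods <- if (nrow(module_edges) > 0) {
    annotate_modules(mcode_find(module_edges, vwp = config$vwp),
                     gene_sets, universe = annotation$gene_id)
  } else {
    structure(tibble(module = integer(0), seed = character(0),
                     size = integer(0), density = numeric(0),
                     score = numeric(0), members = list(),
                     top_terms = list()),
              class = c("mcode_result", "tbl_df", "tbl", "data.frame"))
  }

  cis <- predict_cis(de_sum, annotation, counts, window = config$window,
                     pseudocount = config$pseudocount)

  norm <- normalize_counts(counts)
  heatmap_lnc <- top_k_by_p(de, norm, k = config$top_k, biotype = "lncRNA")
  heatmap_mrna <- top_k_by_p(de, norm, k = config$top_k, biotype = "mRNA")
  volcano <- de %>% as_tibble() %>%
    mutate(neg_log10_p = -log10(pmax(.data$p_value, .Machine$double.xmin))) %>%
    select("gene_id", "log2fc", "neg_log10_p", "direction")

  out <- config$out_dir
  write_tsv_file <- function(x, name) {
    readr::write_tsv(as_tibble(x), file.path(out, name))
  }
  write_tsv_file(de, "de_results.tsv")
  write_tsv_file(select(as_tibble(de_sum), -"genes"), "de_summary.tsv")
  write_tsv_file(flatten_list_col(enr_clustered), "enrichment.tsv")
  write_tsv_file(net$edges, "network_edges.tsv")
  write_sif(net$edges %>%
              select(node_a = "lncRNA", node_b = "mRNA") %>%
              mutate(relation = "coexp"),
            file.path(out, "network_edges.sif"))
  write_tsv_file(net$nodes, "network_nodes.tsv")
  write_tsv_file(hubs, "top_hubs.tsv")
  write_tsv_file(flatten_list_col(mods), "modules.tsv")
  write_tsv_file(cis, "cis_pairs.tsv")
  write_tsv_file(heatmap_lnc, "heatmap_top_lncRNA.tsv")
  write_tsv_file(heatmap_mrna, "heatmap_top_mRNA.tsv")
  write_tsv_file(volcano, "volcano.tsv")

  manifest <- c(
    sprintf("alpha: %g", config$alpha),
    sprintf("fc_min: %g", config$fc_min),
    sprintf("min_expr: %g", config$min_expr),
    sprintf("r_min: %g", config$r_min),
    sprintf("p_max: %g", config$p_max),
    sprintf("kappa: %g", config$kappa),
    sprintf("window: %g", config$window),
    sprintf("vwp: %g", config$vwp),
    sprintf("genes_input: %d", attr(de, "n_input")),
    sprintf("genes_prefiltered: %d", attr(de, "n_prefiltered")),
    sprintf("genes_tested: %d", nrow(de)),
    sprintf("de_lncRNA_up: %d", de_sum$n[de_sum$biotype == "lncRNA" & de_sum$direction == "up"]),
    sprintf("de_lncRNA_down: %d", de_sum$n[de_sum$biotype == "lncRNA" & de_sum$direction == "down"]),
    sprintf("de_mRNA_up: %d", de_sum$n[de_sum$biotype == "mRNA" & de_sum$direction == "up"]),
    sprintf("de_mRNA_down: %d", de_sum$n[de_sum$biotype == "mRNA" & de_sum$direction == "down"]),
    sprintf("terms_tested: %d", nrow(enr)),
    sprintf("terms_significant: %d", sum(enr$significant)),
    sprintf("network_nodes: %d", nrow(net$nodes)),
    sprintf("network_edges: %d", nrow(net$edges)),
    sprintf("pairs_tested: %d", net$n_tested),
    sprintf("pairs_undefined: %d", net$n_undefined),
    sprintf("modules_found: %d", nrow(mods)),
    sprintf("cis_pairs: %d", nrow(cis)))
  writeLines(manifest, file.path(out, "run_manifest.txt"))

  invisible(list(de = de, de_summary = de_sum, enrichment = enr_clustered,
                 network = net, hubs = hubs, modules = mods, cis = cis,
                 heatmap_lncRNA = heatmap_lnc, heatmap_mRNA = heatmap_mrna,
                 volcano = volcano, manifest = manifest))
}

# collapse list-columns to comma-separated strings for TSV output
flatten_list_col <- function(x) {
  x <- as_tibble(x)
  for (col in names(x)) {
    if (is.list(x[[col]])) {
      x[[col]] <- map_chr(x[[col]], function(v) {
        if (is.data.frame(v)) {
          paste(sprintf("%s(%.3g)", v[[1]], v[[2]]), collapse = ",")
        } else paste(v, collapse = ",")
      })
    }
  }
  x
}

#' Top genes by p-value for heat-map input
#'
#' Selects the `k` genes with the smallest DE p-values (optionally within one
#' biotype), ties broken by gene id, and returns their normalized expression
#' rows in that order.
#'
#' @param de A `de_result` from [test_de()].
#' @param normalized Normalized count tibble from [normalize_counts()].
#' @param k Number of genes (default 100); capped at the available genes.
#' @param biotype Optional `"lncRNA"` or `"mRNA"` restriction (requires a
#'   `biotype` column in `de`).
#' @return Tibble: `gene_id`, `p_value`, then the sample columns.
#' @export
top_k_by_p <- function(de, normalized, k = 100, biotype = NULL) {
  res <- as_tibble(de)
  if (!is.null(biotype)) {
    if (!"biotype" %in% names(res))
      abort("`de` has no biotype column; rerun test_de() with annotation")
    res <- filter(res, .data$biotype == !!biotype)
  }
  res %>%
    arrange(.data$p_value, .data$gene_id) %>%
    slice_head(n = k) %>%
    select("gene_id", "p_value") %>%
    left_join(normalized, by = "gene_id")
}

#' Relative quantification by the 2^-ddCt method
#'
#' Computes per-sample `dCt = target Ct - reference Ct`, the group contrast
#' `ddCt = mean(case dCt) - mean(control dCt)` (group-mean calibration, the
#' natural choice for an unpaired two-group design), and the fold change
#' `2^-ddCt`. A fold change below 1 is labelled downregulated.
#'
#' @param data Tibble with columns `sample_id`, `group` (`control`/`case`),
#'   `target_ct`, `reference_ct`; Ct values must be finite and every sample
#'   must carry both measurements.
#' @param gene Optional gene label carried into the result.
#' @return Object of class `ddct_result`: list with `delta_ct` (per-sample
#'   tibble), `ddct`, `fold_change`, `direction`, `gene`.
#' @export
ddct <- function(data, gene = NA_character_) {
  need <- c("sample_id", "group", "target_ct", "reference_ct")
  if (!all(need %in% names(data)))
    abort(sprintf("`data` must have columns: %s", paste(need, collapse = ", ")))
  if (anyDuplicated(data$sample_id))
    abort("duplicate sample ids in `data`")
  if (any(!is.finite(data$target_ct)) || any(!is.finite(data$reference_ct)))
    abort("Ct values must be finite")
  if (!all(data$group %in% c("control", "case")) ||
      !all(c("control", "case") %in% data$group))
    abort("`group` must contain both 'control' and 'case'")
  delta <- data %>%
    mutate(delta_ct = .data$target_ct - .data$reference_ct) %>%
    select("sample_id", "group", "delta_ct")
  dd <- mean(delta$delta_ct[delta$group == "case"]) -
    mean(delta$delta_ct[delta$group == "control"])
  fold <- 2^(-dd)
  structure(list(delta_ct = delta, ddct = dd, fold_change = fold,
                 direction = if (fold < 1) "down" else if (fold > 1) "up"
                             else "unchanged",
                 gene = gene),
            class = "ddct_result")
}

#' @export
print.ddct_result <- function(x, ...) {
  cat(sprintf("<ddct_result>%s ddCt = %.4g, fold change 2^-ddCt = %.4g (%s)\n",
              if (is.na(x$gene)) "" else paste0(" ", x$gene),
              x$ddct, x$fold_change, x$direction))
  invisible(x)
}
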
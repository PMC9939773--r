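#' Read and write pipeline input files
#'
#' Readers and writers for the plain-text formats the pipeline consumes:
#' counts TSV (`gene_id` + one column per sample), samples TSV (`sample_id`,
#' `group`), 6-column BED (0-based half-open) paired with a biotype TSV, GMT
#' gene sets, and SIF interaction edges. All readers return tibbles matching
#' the in-memory contracts of the analysis functions.
#'
#' @param path File path.
#' @return `read_counts()`/`read_samples()`: tibbles mirroring the files.
#' @name pscnet_io
NULL

#' @rdname pscnet_io
#' @export
read_counts <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' @rdname pscnet_io
#' @export
read_samples <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = readr::cols(sample_id = "c", group = "c"))
}

#' @rdname pscnet_io
#' @param bed_path 6-column BED file (chrom, start, end, gene_id, score,
#'   strand), no header.
#' @param biotype_path TSV with header `gene_id`, `biotype` and optionally
#'   `novelty`.
#' @return `read_annotation()`: annotation tibble (`gene_id`, `biotype`,
#'   `chrom`, `start`, `end`, `strand`, `novelty`).
#' @export
read_annotation <- function(bed_path, biotype_path) {
  bed <- readr::read_tsv(bed_path,
                         col_names = c("chrom", "start", "end", "gene_id",
                                       "score", "strand"),
                         col_types = "ciicdc", progress = FALSE)
  bio <- readr::read_tsv(biotype_path, show_col_types = FALSE,
                         progress = FALSE)
  out <- left_join(bed, bio, by = "gene_id")
  if (!"novelty" %in% names(out)) out$novelty <- "known"
  if (anyNA(out$biotype))
    abort("annotation: biotype missing for some genes",
          class = "pscnet_annotation_mismatch")
  select(out, "gene_id", "biotype", "chrom", "start", "end", "strand",
         "novelty")
}

#' @rdname pscnet_io
#' @param annotation Annotation tibble as returned by [read_annotation()].
#' @export
write_annotation <- function(annotation, bed_path, biotype_path) {
  bed <- annotation %>%
    mutate(score = 0) %>%
    select("chrom", "start", "end", "gene_id", "score", "strand")
  readr::write_tsv(bed, bed_path, col_names = FALSE)
  readr::write_tsv(select(annotation, "gene_id", "biotype", "novelty"),
                   biotype_path)
  invisible(annotation)
}

#' @rdname pscnet_io
#' @return `read_gmt()`: named list mapping term id to member gene ids
#'   (coercible by the enrichment functions).
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' @rdname pscnet_io
#' @param sets Gene-set collection (tibble with `term_id`, `description`,
#'   `genes` list-column, or a named list).
#' @export
write_gmt <- function(sets, path) {
  sets <- as_gene_sets(sets)
  lines <- purrr::pmap_chr(sets, function(term_id, description, genes) {
    paste(c(term_id, description, genes), collapse = "\t")
  })
  writeLines(lines, path)
  invisible(sets)
}

#' @rdname pscnet_io
#' @return `read_sif()`: tibble `node_a`, `node_b` (relation dropped).
#' @export
read_sif <- function(path) {
  x <- readr::read_tsv(path, col_names = c("node_a", "relation", "node_b"),
                       col_types = "ccc", progress = FALSE)
  select(x, "node_a", "node_b")
}

#' @rdname pscnet_io
#' @param edges Tibble with `node_a`, `node_b` and optionally `relation`.
#' @export
write_sif <- function(edges, path) {
  relation <- if ("relation" %in% names(edges)) edges$relation else "pp"
  readr::write_tsv(tibble(node_a = edges$node_a, relation = relation,
                          node_b = edges$node_b),
                   path, col_names = FALSE)
  invisible(edges)
}

#' Export a co-expression network as GraphML
#'
#' Writes the network with node attributes (`type`, `degree`) and edge
#' attributes (`r`, `p_value`) in GraphML for import into Cytoscape.
#'
#' @param network A `coex_network` from [build_network()].
#' @param path Output file.
#' @export
write_graphml <- function(network, path) {
  stopifnot(inherits(network, "coex_network"))
  g <- igraph::graph_from_data_frame(
    network$edges %>% select("lncRNA", "mRNA", "r", "p_value"),
    directed = FALSE,
    vertices = network$nodes %>% select("node", "type", "degree"))
  igraph::write_graph(g, path, format = "graphml")
  invisible(network)
}

#' Write a simulated bundle to disk
#'
#' Emits the generator output in the pipeline's input formats: `counts.tsv`,
#' `samples.tsv`, `annotation.bed` + `biotype.tsv`, `gene_sets.gmt`,
#' `manifest.json` (ground truth), and, when an interaction graph is
#' supplied, `graph.sif`.
#'
#' @param bundle A `sim_bundle` from [simulate_counts()].
#' @param dir Output directory (created if needed).
#' @param graph Optional `sim_graph` from [simulate_interaction_graph()].
#' @return Invisibly, a named vector of the written paths.
#' @export
write_sim_bundle <- function(bundle, dir, graph = NULL) {
  stopifnot(inherits(bundle, "sim_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(counts = file.path(dir, "counts.tsv"),
             samples = file.path(dir, "samples.tsv"),
             annotation_bed = file.path(dir, "annotation.bed"),
             biotype = file.path(dir, "biotype.tsv"),
             gmt = file.path(dir, "gene_sets.gmt"),
             manifest = file.path(dir, "manifest.json"))
  readr::write_tsv(bundle$counts, paths["counts"])
  readr::write_tsv(bundle$samples, paths["samples"])
  write_annotation(bundle$annotation, paths["annotation_bed"],
                   paths["biotype"])
  write_gmt(bundle$gene_sets, paths["gmt"])
  truth <- bundle$truth
  jsonlite::write_json(
    list(de_genes = truth$de_genes,
         hub_assignments = truth$hub_assignments,
         cis_truth = truth$cis_truth,
         enriched_terms = truth$enriched_terms),
    paths["manifest"], auto_unbox = TRUE, digits = NA)
  if (!is.null(graph)) {
    paths <- c(paths, sif = file.path(dir, "graph.sif"))
    write_sif(graph$edges, paths["sif"])
  }
  invisible(paths)
}
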
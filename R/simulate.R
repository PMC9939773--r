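#' Simulation configuration
#'
#' Builds and validates the configuration for the synthetic two-group RNA-seq
#' generator. The defaults emulate a small case/control profiling study: five
#' control and five case libraries, a mixed lncRNA/mRNA gene catalogue,
#' negative-binomial counts, a planted differentially expressed (DE) fraction
#' at |log2 fold change| = 2, three correlation-hub lncRNAs with dedicated
#' mRNA modules, genomically proximal lncRNA-mRNA pairs, and gene sets with a
#' planted over-representation of DE genes.
#'
#' @param n_genes Total number of genes.
#' @param frac_lncRNA Fraction of genes annotated as lncRNA, in (0, 1).
#' @param n_control,n_case Samples per group.
#' @param n_de Number of planted mean-shift DE genes (split across biotypes in
#'   proportion to `frac_lncRNA`; hub genes are planted in addition).
#' @param de_log2fc Magnitude of the planted effect, log2 units. Case-group
#'   means are multiplied by `2^(+/- de_log2fc)`.
#' @param de_frac_up Fraction of planted DE genes that are upregulated.
#' @param nb_mean_log2_range Interval for the baseline log2 mean expression;
#'   per-gene means are drawn uniformly on this range.
#' @param nb_dispersion Negative-binomial dispersion phi >= 0, with the
#'   RNA-seq convention `variance = mu + phi * mu^2` (phi = 0 gives Poisson).
#' @param n_hubs Number of planted hub lncRNAs.
#' @param hub_module_size mRNAs per hub; recycled to length `n_hubs`.
#' @param hub_factor_sd Standard deviation of the shared latent factor on the
#'   log2 scale.
#' @param hub_noise_sd Residual log2-scale noise of hub-correlated genes; at 0
#'   every hub member is an exact affine function of the latent factor.
#' @param hub_de If `TRUE`, the latent factor carries the group shift so hub
#'   genes are themselves DE at `de_log2fc` (signed by each member's loading).
#' @param n_cis_pairs Number of planted genomically proximal DE lncRNA-mRNA
#'   pairs, each on its own chromosome.
#' @param cis_gap_bp Genomic gap(s) in bp for the planted pairs; recycled to
#'   `n_cis_pairs`. Default spreads gaps over 0-90 kb.
#' @param n_terms,term_size Number and size of synthetic gene sets.
#' @param n_enriched_terms Terms whose members are sampled preferentially from
#'   planted DE genes.
#' @param enrich_odds Sampling odds ratio favouring DE genes in enriched terms.
#' @param clique_size,n_background,background_density Parameters of
#'   [simulate_interaction_graph()]: planted clique size, background node
#'   count, and Erdos-Renyi edge probability.
#' @param seed RNG seed; seeded runs are bit-reproducible.
#'
#' @return A validated list of class `sim_config`.
#' @seealso [simulate_counts()], [simulate_interaction_graph()]
#' @export
sim_config <- function(n_genes = 2000, frac_lncRNA = 0.2,
                       n_control = 5, n_case = 5,
                       n_de = 200, de_log2fc = 2, de_frac_up = 0.5,
                       nb_mean_log2_range = c(3, 10), nb_dispersion = 0.05,
                       n_hubs = 3, hub_module_size = c(30, 20, 10),
                       hub_factor_sd = 0.5, hub_noise_sd = 0.25, hub_de = TRUE,
                       n_cis_pairs = 8, cis_gap_bp = NULL,
                       n_terms = 50, term_size = 40, n_enriched_terms = 5,
                       enrich_odds = 8,
                       clique_size = 6, n_background = 100,
                       background_density = 0.05,
                       seed = 1L) {
  pos_int <- function(x, field, zero_ok = FALSE) {
    if (length(x) != 1 || !is.finite(x) || x != round(x) ||
        x < if (zero_ok) 0 else 1) {
      config_error(field, if (zero_ok) "must be a non-negative integer"
                   else "must be a positive integer")
    }
    as.integer(x)
  }
  cfg <- list(
    n_genes = pos_int(n_genes, "n_genes"),
    frac_lncRNA = frac_lncRNA,
    n_control = pos_int(n_control, "n_control"),
    n_case = pos_int(n_case, "n_case"),
    n_de = pos_int(n_de, "n_de", zero_ok = TRUE),
    de_log2fc = de_log2fc, de_frac_up = de_frac_up,
    nb_mean_log2_range = nb_mean_log2_range,
    nb_dispersion = nb_dispersion,
    n_hubs = pos_int(n_hubs, "n_hubs", zero_ok = TRUE),
    hub_module_size = hub_module_size,
    hub_factor_sd = hub_factor_sd, hub_noise_sd = hub_noise_sd,
    hub_de = isTRUE(hub_de),
    n_cis_pairs = pos_int(n_cis_pairs, "n_cis_pairs", zero_ok = TRUE),
    cis_gap_bp = cis_gap_bp,
    n_terms = pos_int(n_terms, "n_terms", zero_ok = TRUE),
    term_size = pos_int(term_size, "term_size"),
    n_enriched_terms = pos_int(n_enriched_terms, "n_enriched_terms",
                               zero_ok = TRUE),
    enrich_odds = enrich_odds,
    clique_size = pos_int(clique_size, "clique_size", zero_ok = TRUE),
    n_background = pos_int(n_background, "n_background", zero_ok = TRUE),
    background_density = background_density,
    seed = pos_int(seed, "seed", zero_ok = TRUE)
  )
  if (!is.numeric(frac_lncRNA) || frac_lncRNA <= 0 || frac_lncRNA >= 1)
    config_error("frac_lncRNA", "must lie strictly in (0, 1)")
  if (cfg$n_de > cfg$n_genes)
    config_error("n_de", "cannot exceed n_genes")
  if (length(nb_mean_log2_range) != 2 || diff(nb_mean_log2_range) < 0)
    config_error("nb_mean_log2_range", "must be an increasing interval")
  if (nb_dispersion < 0)
    config_error("nb_dispersion", "must be >= 0")
  if (hub_noise_sd < 0)
    config_error("hub_noise_sd", "must be >= 0")
  if (hub_factor_sd <= 0)
    config_error("hub_factor_sd", "must be > 0")
  if (de_frac_up < 0 || de_frac_up > 1)
    config_error("de_frac_up", "must lie in [0, 1]")
  if (enrich_odds <= 0)
    config_error("enrich_odds", "must be > 0")
  if (background_density < 0 || background_density > 1)
    config_error("background_density", "must be a probability")

  n_lnc <- round(cfg$n_genes * frac_lncRNA)
  n_mrna <- cfg$n_genes - n_lnc
  if (n_lnc < cfg$n_hubs)
    config_error("n_hubs", "exceeds the number of lncRNA genes")
  cfg$hub_module_size <-
    if (cfg$n_hubs > 0) {
      hms <- as.integer(rep_len(hub_module_size, cfg$n_hubs))
      if (any(hms < 1)) config_error("hub_module_size", "must be >= 1")
      hms
    } else integer(0)
  n_de_lnc <- round(cfg$n_de * frac_lncRNA)
  n_de_mrna <- cfg$n_de - n_de_lnc
  if (n_de_lnc + cfg$n_hubs > n_lnc)
    config_error("n_de", "leaves too few lncRNAs after hub plants")
  if (n_de_mrna + sum(cfg$hub_module_size) > n_mrna)
    config_error("n_de", "leaves too few mRNAs after hub plants")
  cfg$cis_gap_bp <-
    if (cfg$n_cis_pairs > 0) {
      gaps <- if (is.null(cis_gap_bp))
        round(seq(0, 90000, length.out = cfg$n_cis_pairs))
      else rep_len(cis_gap_bp, cfg$n_cis_pairs)
      if (any(gaps < 0)) config_error("cis_gap_bp", "must be >= 0")
      as.integer(gaps)
    } else integer(0)
  if (cfg$n_cis_pairs > min(n_de_lnc, n_de_mrna))
    config_error("n_cis_pairs",
                 "exceeds the planted DE genes available per biotype")
  if (cfg$n_enriched_terms > cfg$n_terms)
    config_error("n_enriched_terms", "cannot exceed n_terms")
  if (cfg$n_terms > 0 && cfg$term_size > cfg$n_genes)
    config_error("term_size", "cannot exceed n_genes")
  cfg$n_lnc <- as.integer(n_lnc)
  cfg$n_mrna <- as.integer(n_mrna)
  cfg$n_de_lnc <- as.integer(n_de_lnc)
  cfg$n_de_mrna <- as.integer(n_de_mrna)
  structure(cfg, class = "sim_config")
}

#' Simulate a two-group expression study with planted structure
#'
#' Draws a gene-level count matrix for a control/case design with known
#' (manifest-recorded) plants: mean-shift DE genes, hub lncRNAs whose member
#' mRNAs share a latent log-scale factor, genomically proximal cis pairs on
#' dedicated chromosomes, and gene sets over-representing DE genes.
#'
#' Counts for ordinary genes are negative binomial with mean `mu` and
#' variance `mu + phi * mu^2`; planted DE genes have the case-group mean
#' multiplied by `2^(+/- de_log2fc)`. Hub genes are built on the log2 scale as
#' `baseline + loading * factor + noise`, exponentiated and rounded, which
#' makes their pairwise Pearson correlation tunable via `hub_noise_sd` (1 in
#' the noiseless limit). Coordinates use a synthetic genome: each planted cis
#' pair sits alone on its own chromosome at the configured gap, and all other
#' genes are spaced > 100 kb apart.
#'
#' @param config A [sim_config()] object.
#' @return An object of class `sim_bundle`: a list with `counts` (tibble,
#'   `gene_id` + one column per sample), `samples` (`sample_id`, `group`),
#'   `annotation` (`gene_id`, `biotype`, `chrom`, `start`, `end`, `strand`,
#'   `novelty`; 0-based half-open), `gene_sets` (tibble `term_id`,
#'   `description`, `genes` list-column), and `truth`, the ground-truth
#'   manifest (`de_genes`, `hub_assignments`, `cis_truth`, `enriched_terms`).
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n_samples <- config$n_control + config$n_case
  sample_ids <- c(sprintf("ctrl_%d", seq_len(config$n_control)),
                  sprintf("case_%d", seq_len(config$n_case)))
  groups <- rep(c("control", "case"), c(config$n_control, config$n_case))
  is_case <- groups == "case"

  gene_ids <- c(sprintf("LNC%05d", seq_len(config$n_lnc)),
                sprintf("MRNA%05d", seq_len(config$n_mrna)))
  biotype <- rep(c("lncRNA", "mRNA"), c(config$n_lnc, config$n_mrna))
  lnc_ids <- gene_ids[biotype == "lncRNA"]
  mrna_ids <- gene_ids[biotype == "mRNA"]
  novelty <- ifelse(biotype == "lncRNA",
                    ifelse(runif(config$n_genes) < 0.6, "novel", "known"),
                    "known")

  log2_mu <- runif(config$n_genes, config$nb_mean_log2_range[1],
                   config$nb_mean_log2_range[2])
  mu <- 2^log2_mu
  names(mu) <- gene_ids

  # hub plants: lncRNA anchors + disjoint mRNA member modules
  hub_lnc <- if (config$n_hubs > 0) sample(lnc_ids, config$n_hubs)
             else character(0)
  hub_members <- list()
  if (config$n_hubs > 0) {
    pool <- sample(mrna_ids, sum(config$hub_module_size))
    hub_members <- split(pool, rep(seq_len(config$n_hubs),
                                   config$hub_module_size))
    names(hub_members) <- hub_lnc
  }
  hub_gene_ids <- c(hub_lnc, unlist(hub_members, use.names = FALSE))

  # mean-shift DE plants, disjoint from hub genes, split by biotype
  de_lnc <- sample(setdiff(lnc_ids, hub_lnc), config$n_de_lnc)
  de_mrna <- sample(setdiff(mrna_ids, hub_gene_ids), config$n_de_mrna)
  de_ids <- c(de_lnc, de_mrna)
  de_sign <- ifelse(runif(config$n_de) < config$de_frac_up, 1, -1)
  de_lfc <- setNames(de_sign * config$de_log2fc, de_ids)

  # baseline NB counts; DE case means scaled by 2^(signed lfc)
  mu_mat <- matrix(mu, nrow = config$n_genes, ncol = n_samples)
  if (config$n_de > 0)
    mu_mat[match(de_ids, gene_ids), is_case] <-
      mu_mat[match(de_ids, gene_ids), is_case] * 2^de_lfc
  counts <- matrix(
    if (config$nb_dispersion > 0)
      rnbinom(length(mu_mat), size = 1 / config$nb_dispersion, mu = mu_mat)
    else rpois(length(mu_mat), lambda = mu_mat),
    nrow = config$n_genes, dimnames = list(gene_ids, sample_ids))

  # hub genes: shared latent factor on the log2 scale, +/-1 loadings
  hub_truth_lfc <- numeric(0)
  offset <- if (config$hub_de) config$de_log2fc else 0
  for (h in seq_along(hub_lnc)) {
    z <- rnorm(n_samples, 0, config$hub_factor_sd) +
      ifelse(is_case, offset / 2, -offset / 2)
    genes_h <- c(hub_lnc[h], hub_members[[h]])
    loading <- c(1, sample(c(1, -1), length(hub_members[[h]]), replace = TRUE))
    vals <- outer(log2(mu[genes_h]), rep(1, n_samples)) +
      outer(loading, z) +
      matrix(rnorm(length(genes_h) * n_samples, 0, config$hub_noise_sd),
             nrow = length(genes_h))
    counts[genes_h, ] <- pmax(round(2^vals), 0)
    if (offset != 0)
      hub_truth_lfc <- c(hub_truth_lfc, setNames(loading * offset, genes_h))
  }

  # coordinates: cis pairs on dedicated chromosomes, others spaced 250 kb
  cis_lnc <- if (config$n_cis_pairs > 0) sample(de_lnc, config$n_cis_pairs)
             else character(0)
  cis_mrna <- if (config$n_cis_pairs > 0) sample(de_mrna, config$n_cis_pairs)
              else character(0)
  gene_len <- 1000L
  chrom <- setNames(rep(NA_character_, config$n_genes), gene_ids)
  start <- setNames(rep(NA_integer_, config$n_genes), gene_ids)
  for (i in seq_len(config$n_cis_pairs)) {
    cc <- sprintf("chr_cis%d", i)
    chrom[cis_lnc[i]] <- cc; start[cis_lnc[i]] <- 0L
    chrom[cis_mrna[i]] <- cc
    start[cis_mrna[i]] <- gene_len + config$cis_gap_bp[i]
  }
  rest <- gene_ids[is.na(chrom)]
  per_chrom <- 40L
  chrom[rest] <- sprintf("chr%d", ((seq_along(rest) - 1) %/% per_chrom) + 1)
  start[rest] <- as.integer(((seq_along(rest) - 1) %% per_chrom) * 250000L)
  start_vec <- unname(start[gene_ids])
  annotation <- tibble(
    gene_id = gene_ids, biotype = biotype,
    chrom = unname(chrom[gene_ids]),
    start = start_vec,
    end = start_vec + gene_len,
    strand = sample(c("+", "-"), config$n_genes, replace = TRUE),
    novelty = novelty)

  truth_de <- c(de_lfc, hub_truth_lfc)
  gene_sets <- simulate_gene_sets(config, gene_ids, names(truth_de))

  truth <- list(
    de_genes = tibble(gene_id = names(truth_de), log2fc = unname(truth_de)),
    hub_assignments = hub_members,
    cis_truth = tibble(lncRNA = cis_lnc, mRNA = cis_mrna,
                       chrom = sprintf("chr_cis%s", seq_len(config$n_cis_pairs)),
                       gap = config$cis_gap_bp),
    enriched_terms = attr(gene_sets, "enriched_terms"))

  structure(list(
    counts = bind_cols(tibble(gene_id = gene_ids),
                       as_tibble(counts, .name_repair = "minimal")),
    samples = tibble(sample_id = sample_ids, group = groups),
    annotation = annotation,
    gene_sets = gene_sets,
    truth = truth,
    config = config), class = "sim_bundle")
}

# gene sets with planted over-representation of DE genes (weighted sampling
# without replacement at odds `enrich_odds`)
simulate_gene_sets <- function(config, gene_ids, de_ids) {
  if (config$n_terms == 0) {
    gs <- tibble(term_id = character(0), description = character(0),
                 genes = list())
    attr(gs, "enriched_terms") <- character(0)
    return(gs)
  }
  w <- ifelse(gene_ids %in% de_ids, config$enrich_odds, 1)
  term_ids <- sprintf("TERM%03d", seq_len(config$n_terms))
  genes <- lapply(seq_len(config$n_terms), function(j) {
    if (j <= config$n_enriched_terms)
      sort(sample(gene_ids, config$term_size, prob = w))
    else
      sort(sample(gene_ids, config$term_size))
  })
  gs <- tibble(term_id = term_ids,
               description = sprintf("synthetic gene set %d",
                                     seq_len(config$n_terms)),
               genes = genes)
  attr(gs, "enriched_terms") <- term_ids[seq_len(config$n_enriched_terms)]
  gs
}

#' Simulate an interaction network with a planted clique
#'
#' Generates an undirected simple graph: an Erdos-Renyi background at
#' `background_density` over `n_background + clique_size` nodes, with a clique
#' of `clique_size` nodes superimposed. Serves as a stand-in protein
#' interaction network for dense-module detection, with the clique membership
#' recorded so recovery can be verified.
#'
#' @param config A [sim_config()] object (`clique_size`, `n_background`,
#'   `background_density`, `seed`).
#' @return A list of class `sim_graph`: `edges` (tibble `node_a`, `node_b`,
#'   canonically ordered), `nodes`, and `clique` (the planted members).
#' @export
simulate_interaction_graph <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n_nodes <- config$n_background + config$clique_size
  if (config$clique_size > n_nodes || n_nodes < 1)
    config_error("clique_size", "exceeds the total node count")
  set.seed(config$seed)
  nodes <- sprintf("N%04d", seq_len(n_nodes))
  clique <- sort(sample(nodes, config$clique_size))
  pairs <- if (n_nodes >= 2) t(utils::combn(nodes, 2)) else
    matrix(character(0), ncol = 2)
  keep <- runif(nrow(pairs)) < config$background_density
  in_clique <- pairs[, 1] %in% clique & pairs[, 2] %in% clique
  keep <- keep | in_clique
  edges <- tibble(node_a = pairs[keep, 1], node_b = pairs[keep, 2]) %>%
    arrange(.data$node_a, .data$node_b)
  structure(list(edges = edges, nodes = nodes, clique = clique),
            class = "sim_graph")
}

#' @export
print.sim_bundle <- function(x, ...) {
  cat(sprintf(
    "<sim_bundle> %d genes (%d lncRNA / %d mRNA) x %d samples\n",
    nrow(x$annotation), sum(x$annotation$biotype == "lncRNA"),
    sum(x$annotation$biotype == "mRNA"), nrow(x$samples)))
  cat(sprintf("  planted: %d DE genes, %d hubs, %d cis pairs, %d/%d enriched terms\n",
              nrow(x$truth$de_genes), length(x$truth$hub_assignments),
              nrow(x$truth$cis_truth), length(x$truth$enriched_terms),
              nrow(x$gene_sets)))
  invisible(x)
}
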
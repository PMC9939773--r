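#' Upper-tail hypergeometric enrichment p-value
#'
#' Probability of observing at least `m` list genes in a term,
#' `P(X >= m) = 1 - sum_{i=0}^{m-1} C(M,i) C(N-M, n-i) / C(N,n)`,
#' where `N` is the number of annotated genes in the universe, `n` the number
#' of list genes in the universe, `M` the genes annotated to the term and `m`
#' the list genes in the term. Computed as a direct upper-tail sum of
#' log-space binomial coefficients, which is numerically stable for large
#' universes.
#'
#' @param N,n,M Scalars satisfying `0 <= M <= N`, `0 <= n <= N`.
#' @param m Overlap count(s); vectorized. Must satisfy `0 <= m <= min(n, M)`.
#' @return Numeric vector of p-values in `[0, 1]`, same length as `m`.
#' @export
hypergeom_p <- function(N, n, M, m) {
  if (length(N) != 1 || length(n) != 1 || length(M) != 1)
    abort("N, n and M must be scalars")
  vals <- c(N, n, M, m)
  if (any(!is.finite(vals)) || any(vals != round(vals)))
    abort("all arguments must be non-negative integers")
  if (M > N || n > N || M < 0 || n < 0 || N < 0)
    abort("bounds violated: need 0 <= M <= N and 0 <= n <= N",
          class = "pscnet_domain_error")
  if (any(m < 0) || any(m > min(n, M)))
    abort("bounds violated: need 0 <= m <= min(n, M)",
          class = "pscnet_domain_error")
  lo <- max(0, n + M - N)
  hi <- min(n, M)
  i <- lo:hi
  terms <- exp(lchoose(M, i) + lchoose(N - M, n - i) - lchoose(N, n))
  # tail[j] = P(X >= i[j]); support below lo has probability 0
  tail <- rev(cumsum(rev(terms)))
  out <- ifelse(m <= lo, 1, tail[pmax(m, lo) - lo + 1])
  pmin(pmax(out, 0), 1)
}

# normalize a gene-set collection to a tibble(term_id, description, genes)
as_gene_sets <- function(sets) {
  if (is.data.frame(sets)) {
    stopifnot(all(c("term_id", "genes") %in% names(sets)))
    out <- as_tibble(sets)
    if (!"description" %in% names(out)) out$description <- out$term_id
  } else if (is.list(sets)) {
    out <- tibble(term_id = names(sets), description = names(sets),
                  genes = unname(lapply(sets, as.character)))
  } else {
    abort("`sets` must be a tibble with term_id/genes or a named list")
  }
  if (anyDuplicated(out$term_id)) abort("duplicate term ids in gene sets")
  if (any(purrr::map_int(out$genes, length) == 0))
    abort("empty gene set in collection")
  out[c("term_id", "description", "genes")]
}

#' Hypergeometric over-representation analysis
#'
#' Tests every term of a gene-set collection for over-representation of a
#' gene list against a finite universe, using [hypergeom_p()]. Results are
#' ranked by `-log10(p)` descending with ties broken by `term_id`;
#' significance is flagged at raw `p < alpha` (a BH-adjusted column is also
#' provided for transparency but does not drive the flag).
#'
#' @param de_genes Character vector of list genes (e.g. DEGs). Genes outside
#'   the universe are dropped with a warning.
#' @param sets Gene-set collection: tibble (`term_id`, `description`,
#'   `genes` list-column) or a named list of gene id vectors (e.g. from
#'   [read_gmt()]).
#' @param universe Annotated universe of gene ids; defaults to the union of
#'   all term members. Term members outside the universe are ignored.
#' @param alpha Raw-p significance threshold (default 0.05).
#' @return Tibble of class `enrich_result`: `term_id`, `description`, `N`,
#'   `n`, `M`, `m`, `p_value`, `neg_log10_p`, `fdr`, `significant`.
#'   Attribute `n_dropped` counts list genes outside the universe.
#' @export
enrich_terms <- function(de_genes, sets, universe = NULL, alpha = 0.05) {
  sets <- as_gene_sets(sets)
  if (is.null(universe))
    universe <- unique(unlist(sets$genes, use.names = FALSE))
  universe <- unique(as.character(universe))
  if (length(universe) == 0)
    abort("empty universe", class = "pscnet_domain_error")
  de_genes <- unique(as.character(de_genes))
  n_dropped <- sum(!de_genes %in% universe)
  if (n_dropped > 0)
    warn(sprintf("%d list gene(s) outside the universe were dropped",
                 n_dropped))
  de_in <- intersect(de_genes, universe)
  N_univ <- length(universe); n_hit <- length(de_in)
  out <- sets %>%
    mutate(members = map(.data$genes, ~ intersect(.x, universe)),
           N = N_univ, n = n_hit,
           M = map_int(.data$members, length),
           m = map_int(.data$members, ~ length(intersect(.x, de_in)))) %>%
    filter(.data$M > 0) %>%
    mutate(p_value = purrr::map2_dbl(.data$M, .data$m,
                                     function(M_t, m_t)
                                       hypergeom_p(N_univ, n_hit, M_t, m_t)),
           neg_log10_p = -log10(.data$p_value),
           fdr = p.adjust(.data$p_value, method = "BH"),
           significant = .data$p_value < alpha) %>%
    select("term_id", "description", "N", "n", "M", "m",
           "p_value", "neg_log10_p", "fdr", "significant") %>%
    arrange(desc(.data$neg_log10_p), .data$term_id)
  structure(out, class = c("enrich_result", class(out)),
            n_dropped = n_dropped, alpha = alpha,
            universe_size = N_univ)
}

#' Cohen's kappa between two gene sets over a universe
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` of the two sets'
#' binary membership vectors over the universe. In the degenerate case
#' `p_e = 1` (both marginals trivial) kappa is defined as 1 when the sets are
#' equal and 0 otherwise, preserving continuity with the concordant and
#' discordant limits.
#'
#' @param term_a,term_b Character vectors of gene ids (subsets of `universe`).
#' @param universe Non-empty character vector of gene ids.
#' @return Kappa in `[-1, 1]`.
#' @export
kappa_score <- function(term_a, term_b, universe) {
  universe <- unique(as.character(universe))
  N <- length(universe)
  if (N == 0) abort("empty universe", class = "pscnet_domain_error")
  a <- unique(as.character(term_a)); b <- unique(as.character(term_b))
  if (!all(a %in% universe) || !all(b %in% universe))
    abort("terms must be subsets of the universe", class = "pscnet_domain_error")
  both <- length(intersect(a, b))
  na <- length(a); nb <- length(b)
  p_o <- (both + (N - na - nb + both)) / N
  p_e <- (na * nb + (N - na) * (N - nb)) / N^2
  if (p_e >= 1) return(if (setequal(a, b)) 1 else 0)
  (p_o - p_e) / (1 - p_e)
}

#' Cluster enriched terms by kappa similarity
#'
#' Average-linkage hierarchical clustering of significant terms on the
#' distance `1 - kappa`, cut at the coarsest partition in which every
#' multi-member cluster has mean pairwise kappa above the threshold. Each
#' cluster is labelled by a representative: its lowest-p term (ties by
#' `term_id`).
#'
#' @param enrichment An `enrich_result` from [enrich_terms()]; at least one
#'   significant term is required.
#' @param sets The gene-set collection used for the enrichment.
#' @param universe Universe over which kappa is computed; defaults to the
#'   union of all term members.
#' @param threshold Kappa threshold for merging (default 0.3).
#' @param top_k If set, clustering is restricted to the `top_k` significant
#'   terms by p-value (ties by `term_id`).
#' @return The enrichment tibble with added `cluster` (integer; `NA` for
#'   unclustered terms) and `representative` (logical) columns; the
#'   `hclust` tree is attached as attribute `tree`.
#' @export
cluster_terms <- function(enrichment, sets, universe = NULL,
                          threshold = 0.3, top_k = NULL) {
  stopifnot(inherits(enrichment, "enrich_result"))
  sets <- as_gene_sets(sets)
  if (is.null(universe))
    universe <- unique(unlist(sets$genes, use.names = FALSE))
  sig <- enrichment %>%
    as_tibble() %>%
    filter(.data$significant) %>%
    arrange(.data$p_value, .data$term_id)
  if (nrow(sig) == 0)
    abort("no significant terms to cluster", class = "pscnet_domain_error")
  if (!is.null(top_k)) sig <- slice_head(sig, n = top_k)
  ids <- sig$term_id
  members <- setNames(sets$genes, sets$term_id)[ids]
  k <- length(ids)
  K <- matrix(1, k, k, dimnames = list(ids, ids))
  if (k > 1) {
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        K[i, j] <- K[j, i] <- kappa_score(members[[i]], members[[j]], universe)
      }
    }
  }
  tree <- if (k > 1) hclust(as.dist(1 - K), method = "average") else NULL
  labels <- cluster_cut(tree, K, threshold)
  names(labels) <- ids

  out <- enrichment %>%
    as_tibble() %>%
    mutate(cluster = unname(labels[.data$term_id]))
  rep_ids <- out %>%
    filter(!is.na(.data$cluster)) %>%
    arrange(.data$p_value, .data$term_id) %>%
    group_by(.data$cluster) %>%
    slice_head(n = 1) %>%
    pull(.data$term_id)
  out <- mutate(out, representative = .data$term_id %in% rep_ids)
  structure(out, class = class(enrichment),
            n_dropped = attr(enrichment, "n_dropped"),
            alpha = attr(enrichment, "alpha"),
            universe_size = attr(enrichment, "universe_size"),
            tree = tree, kappa = K, threshold = threshold)
}

# coarsest cut (fewest clusters) in which every cluster's mean pairwise
# kappa exceeds the threshold; singletons pass trivially
cluster_cut <- function(tree, K, threshold) {
  k <- nrow(K)
  if (k == 1) return(setNames(1L, rownames(K)))
  for (ncl in seq_len(k)) {
    labels <- cutree(tree, k = ncl)
    ok <- all(vapply(split(names(labels), labels), function(ids) {
      if (length(ids) < 2) return(TRUE)
      sub <- K[ids, ids]
      mean(sub[lower.tri(sub)]) > threshold
    }, logical(1)))
    if (ok) return(labels)
  }
  setNames(seq_len(k), rownames(K))
}
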
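# edges tibble (node_a, node_b [, score]) -> simple undirected igraph
as_interaction_graph <- function(edges, nodes = NULL) {
  if (inherits(edges, "igraph")) {
    return(igraph::simplify(igraph::as_undirected(edges, mode = "collapse")))
  }
  stopifnot(all(c("node_a", "node_b") %in% names(edges)))
  g <- igraph::graph_from_data_frame(
    edges[c("node_a", "node_b")], directed = FALSE,
    vertices = if (is.null(nodes)) NULL else sort(unique(nodes)))
  igraph::simplify(g)
}

graph_density <- function(g) {
  n <- igraph::vcount(g)
  if (n < 2) return(0)
  igraph::ecount(g) / choose(n, 2)
}

#' Filter interaction edges by confidence score
#'
#' Keeps edges with score strictly greater than `min_score` (so a score
#' exactly at the cutoff is dropped), the convention used for
#' confidence-scored protein interaction networks.
#'
#' @param edges Tibble with `node_a`, `node_b` and, when filtering, `score`
#'   in `[0, 1]`.
#' @param min_score Strict lower bound (default 0.7); `NULL` disables
#'   filtering, in which case unscored edges pass.
#' @return The filtered edge tibble.
#' @export
filter_edges <- function(edges, min_score = 0.7) {
  stopifnot(all(c("node_a", "node_b") %in% names(edges)))
  if (is.null(min_score)) return(edges)
  if (!"score" %in% names(edges) || anyNA(edges$score))
    config_error("min_score", "requested but edges carry no complete scores")
  filter(edges, .data$score > min_score)
}

#' MCODE vertex weights
#'
#' Weight of a vertex v is `k * density(H)` where `H` is the highest k-core
#' of the subgraph induced by v's neighbours (v excluded) and `k` its core
#' number. Vertices whose neighbourhood has no edges (isolated nodes, leaves,
#' star centres) get weight 0.
#'
#' @param edges Edge tibble (`node_a`, `node_b`) or an igraph object;
#'   treated as a simple undirected graph.
#' @return Tibble with `node` and `weight`, sorted by node id.
#' @export
mcode_weight <- function(edges) {
  g <- as_interaction_graph(edges)
  vs <- igraph::V(g)$name
  w <- vapply(vs, function(v) {
    nb <- igraph::neighbors(g, v)$name
    if (length(nb) < 2) return(0)
    sub <- igraph::induced_subgraph(g, nb)
    if (igraph::ecount(sub) == 0) return(0)
    core <- igraph::coreness(sub)
    kmax <- max(core)
    h <- igraph::induced_subgraph(sub, names(core)[core == kmax])
    kmax * graph_density(h)
  }, numeric(1))
  tibble(node = vs, weight = unname(w)) %>% arrange(.data$node)
}

#' Detect densely connected modules (MCODE-style)
#'
#' Seeded greedy expansion: every vertex of positive weight seeds a candidate
#' module in which neighbours with weight at least `(1 - vwp) * seed weight`
#' are admitted breadth-first. Each candidate is post-processed — optional
#' fluff (neighbours whose closed-neighbourhood density exceeds
#' `fluff_density`), optional haircut to the seed's component of the 2-core,
#' and a density trim that extends the haircut by peeling below-average-degree
#' members while this strictly raises the module density without
#' disconnecting it. Candidates smaller than `min_size` are discarded, the
#' rest are scored `density x size`, and modules are selected greedily in
#' score order (ties by lexicographically smallest member) subject to node
#' disjointness, so each vertex belongs to at most one module. Vertices of
#' weight 0 never seed: an edgeless neighbourhood cannot anchor a dense
#' region, and a zero admission threshold would flood sparse components.
#'
#' @param edges Edge tibble (`node_a`, `node_b`) or igraph object.
#' @param vwp Vertex weight percentage in `[0, 1)` (default 0.2).
#' @param haircut Remove singly-connected members via the 2-core
#'   (default TRUE).
#' @param fluff Add dense-neighbourhood boundary vertices (default FALSE).
#' @param fluff_density Closed-neighbourhood density threshold for fluff
#'   (default 0.2).
#' @param trim Apply the density-increasing peel after the haircut
#'   (default TRUE).
#' @param min_size Minimum module size (default 3).
#' @return Tibble of class `mcode_result`: `module`, `seed`, `size`,
#'   `density`, `score`, `members` (sorted list-column), ranked by score.
#' @export
mcode_find <- function(edges, vwp = 0.2, haircut = TRUE, fluff = FALSE,
                       fluff_density = 0.2, trim = TRUE, min_size = 3) {
  if (length(vwp) != 1 || !is.finite(vwp) || vwp < 0 || vwp >= 1)
    abort("`vwp` must lie in [0, 1)", class = "pscnet_domain_error")
  g <- as_interaction_graph(edges)
  wt <- mcode_weight(g)
  w <- setNames(wt$weight, wt$node)
  seeds <- wt %>% arrange(desc(.data$weight), .data$node) %>% pull(.data$node)
  adj <- igraph::adjacent_vertices(g, igraph::V(g))
  adj <- lapply(adj, function(v) v$name)
  names(adj) <- igraph::V(g)$name

  expand_seed <- function(seed) {
    thr <- (1 - vwp) * w[seed]
    members <- seed
    queue <- seed
    seen <- structure(TRUE, names = seed)
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      for (u in adj[[v]]) {
        if (is.na(seen[u]) && w[u] >= thr) {
          seen[u] <- TRUE
          members <- c(members, u)
          queue <- c(queue, u)
        }
      }
    }
    members
  }

  raw <- lapply(seeds[w[seeds] > 0], expand_seed)
  raw <- unique(lapply(raw, sort))

  finalize <- function(members) {
    if (fluff) {
      boundary <- setdiff(unique(unlist(adj[members], use.names = FALSE)),
                          members)
      add <- boundary[vapply(boundary, function(u) {
        nb <- union(adj[[u]], u)
        graph_density(igraph::induced_subgraph(g, nb)) > fluff_density
      }, logical(1))]
      members <- c(members, add)
    }
    if (haircut && length(members) > 1) {
      sub <- igraph::induced_subgraph(g, members)
      core <- igraph::coreness(sub)
      keep <- names(core)[core >= 2]
      if (length(keep) == 0) return(character(0))
      sub2 <- igraph::induced_subgraph(sub, keep)
      comp <- igraph::components(sub2)
      memb <- setNames(comp$membership, igraph::V(sub2)$name)
      # keep the largest component, ties by smallest member id
      sizes <- comp$csize
      cand <- which(sizes == max(sizes))
      firsts <- vapply(cand, function(ci) min(names(memb)[memb == ci]),
                       character(1))
      members <- names(memb)[memb == cand[order(firsts)][1]]
    }
    if (trim) members <- density_trim(g, members, min_size)
    sort(members)
  }

  cands <- unique(Filter(function(m) length(m) >= min_size,
                         lapply(raw, finalize)))
  mods <- list()
  if (length(cands) > 0) {
    dens <- vapply(cands, function(m)
      graph_density(igraph::induced_subgraph(g, m)), numeric(1))
    score <- dens * lengths(cands)
    firsts <- vapply(cands, `[`, character(1), 1)
    used <- character(0)
    for (i in order(-score, firsts)) {
      if (any(cands[[i]] %in% used)) next
      used <- c(used, cands[[i]])
      mods[[length(mods) + 1]] <- tibble(
        seed = cands[[i]][which.max(w[cands[[i]]])],
        size = length(cands[[i]]), density = dens[i], score = score[i],
        members = list(cands[[i]]))
    }
  }
  out <- if (length(mods) == 0) {
    tibble(seed = character(0), size = integer(0), density = numeric(0),
           score = numeric(0), members = list())
  } else bind_rows(mods)
  out <- out %>%
    mutate(module = row_number()) %>%
    select("module", "seed", "size", "density", "score", "members")
  structure(out, class = c("mcode_result", class(out)),
            params = list(vwp = vwp, haircut = haircut, fluff = fluff,
                          trim = trim, min_size = min_size))
}

# peel below-average-degree members while this strictly increases density
# and keeps the module connected; never shrinks below min_size
density_trim <- function(g, members, min_size) {
  while (length(members) > min_size) {
    sub <- igraph::induced_subgraph(g, members)
    e <- igraph::ecount(sub)
    dens <- graph_density(sub)
    deg <- igraph::degree(sub)
    # removing v improves density iff deg(v) < 2e/n (below average)
    low <- names(deg)[deg < 2 * e / length(members)]
    low <- low[order(deg[low], low)]
    improved <- FALSE
    for (v in low) {
      cand <- setdiff(members, v)
      sub2 <- igraph::induced_subgraph(g, cand)
      if (igraph::components(sub2)$no == 1 &&
          graph_density(sub2) > dens + 1e-12) {
        members <- cand
        improved <- TRUE
        break
      }
    }
    if (!improved) break
  }
  members
}

#' Annotate detected modules by gene-set enrichment
#'
#' Runs [enrich_terms()] on each module's members and retains at most the
#' three lowest-p terms per module. Modules with no member in the universe
#' are annotated with an empty term list.
#'
#' @param mods An `mcode_result` from [mcode_find()].
#' @param sets Gene-set collection (tibble or named list).
#' @param universe Enrichment universe; defaults to the union of term members.
#' @param n_top Number of terms retained per module (default 3).
#' @return `mods` with an added `top_terms` list-column of tibbles
#'   (`term_id`, `p_value`).
#' @export
annotate_modules <- function(mods, sets, universe = NULL, n_top = 3) {
  stopifnot(inherits(mods, "mcode_result"))
  sets <- as_gene_sets(sets)
  if (is.null(universe))
    universe <- unique(unlist(sets$genes, use.names = FALSE))
  ann <- map(mods$members, function(genes) {
    if (length(intersect(genes, universe)) == 0)
      return(tibble(term_id = character(0), p_value = numeric(0)))
    res <- suppressWarnings(enrich_terms(genes, sets, universe = universe))
    res %>% as_tibble() %>%
      arrange(.data$p_value, .data$term_id) %>%
      slice_head(n = n_top) %>%
      select("term_id", "p_value")
  })
  out <- mutate(as_tibble(mods), top_terms = ann)
  structure(out, class = class(mods), params = attr(mods, "params"))
}
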
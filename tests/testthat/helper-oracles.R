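# Independent oracles used across the suite. These deliberately use different
# routes than the package implementation.

# printed-formula oracle: 1 - sum_{i=0}^{m-1} C(M,i) C(N-M,n-i) / C(N,n),
# direct (non-log) binomial coefficients
hyper_oracle <- function(N, n, M, m) {
  if (m == 0) return(1)
  i <- 0:(m - 1)
  p <- 1 - sum(choose(M, i) * choose(N - M, n - i)) / choose(N, n)
  min(max(p, 0), 1)
}

# brute-force Benjamini-Hochberg: sort, p * n / rank, cumulative min from the
# largest rank, cap at 1, restore order
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# exhaustive densest connected subgraph of a given cardinality
densest_connected_density <- function(edges, size) {
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  g <- igraph::simplify(g)
  nodes <- igraph::V(g)$name
  best <- 0
  for (comb in utils::combn(nodes, size, simplify = FALSE)) {
    sub <- igraph::induced_subgraph(g, comb)
    if (igraph::components(sub)$no == 1) {
      best <- max(best, igraph::ecount(sub) / choose(size, 2))
    }
  }
  best
}

# direct covariance/variance Pearson formula
pearson_oracle <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

# tiny deterministic count bundle built by hand (2 groups x 3 samples)
toy_counts <- function(mat, gene_ids = sprintf("G%02d", seq_len(nrow(mat)))) {
  colnames(mat) <- c(sprintf("ctrl_%d", 1:3), sprintf("case_%d", 1:3))
  dplyr::bind_cols(tibble::tibble(gene_id = gene_ids),
                   tibble::as_tibble(mat, .name_repair = "minimal"))
}

toy_samples <- tibble::tibble(
  sample_id = c(sprintf("ctrl_%d", 1:3), sprintf("case_%d", 1:3)),
  group = rep(c("control", "case"), each = 3))

# complete-graph edge list on the given node names
k_edges <- function(nodes) {
  pairs <- t(utils::combn(nodes, 2))
  tibble::tibble(node_a = pairs[, 1], node_b = pairs[, 2])
}
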
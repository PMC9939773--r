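#' Pearson correlation with t-test p-value
#'
#' Standard Pearson r with the two-sided p-value from
#' `t = r * sqrt(n - 2) / sqrt(1 - r^2)` on `n - 2` degrees of freedom;
#' `|r| = 1` gives p = 0. A zero-variance vector yields `r = NA`, the signal
#' by which callers exclude (and count) undefined correlations.
#'
#' @param x,y Numeric vectors of equal length >= 3 with finite values.
#' @return A one-row tibble with columns `r` and `p_value`.
#' @export
pearson_with_p <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    abort("x and y must have equal length >= 3")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    abort("x and y must be finite")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(tibble(r = NA_real_, p_value = NA_real_))
  r <- cor(x, y)
  tibble(r = r, p_value = r_pvalue(r, length(x)))
}

# two-sided p for H0: rho = 0 via the t transform; |r| = 1 -> 0
r_pvalue <- function(r, n) {
  p <- rep(0, length(r))
  ok <- is.finite(r) & abs(r) < 1
  t <- r[ok] * sqrt(n - 2) / sqrt(1 - r[ok]^2)
  p[ok] <- 2 * pt(-abs(t), df = n - 2)
  p[!is.finite(r)] <- NA_real_
  p
}

#' Build the DE lncRNA-mRNA co-expression network
#'
#' Computes Pearson correlation (with t-test p) for every DE-lncRNA x DE-mRNA
#' pair across all samples and keeps pairs with `|r| > r_min` and
#' `p < p_max` as edges. By default expression is median-of-ratios
#' normalized and log2(x + pseudocount) transformed before correlating;
#' lncRNA-lncRNA and mRNA-mRNA pairs are never tested. Nodes with no passing
#' edge are excluded from the network.
#'
#' @param counts Tibble with `gene_id` plus one column per sample.
#' @param de A `de_summary` from [partition_de()], or `NULL` if `lncRNAs` and
#'   `mRNAs` are given directly.
#' @param lncRNAs,mRNAs Optional explicit DE gene id vectors overriding `de`.
#' @param r_min Absolute correlation threshold, exclusive (default 0.9).
#' @param p_max Correlation p-value threshold, exclusive (default 0.01).
#' @param scale `"log2"` (default) correlates `log2(normalized + pseudocount)`;
#'   `"normalized"` correlates the normalized values directly.
#' @param normalize Apply median-of-ratios normalization first (default TRUE).
#' @param pseudocount Pseudo-count for the log2 scale (default 1).
#' @return Object of class `coex_network`: list with `edges` (tibble
#'   `lncRNA`, `mRNA`, `r`, `p_value`), `nodes` (tibble `node`, `type`,
#'   `degree`, ranked by degree then id), `n_samples`, `n_tested`,
#'   `n_undefined` (zero-variance pairs excluded), and `params`.
#' @export
build_network <- function(counts, de = NULL, lncRNAs = NULL, mRNAs = NULL,
                          r_min = 0.9, p_max = 0.01,
                          scale = c("log2", "normalized"),
                          normalize = TRUE, pseudocount = 1) {
  scale <- match.arg(scale)
  if (is.null(lncRNAs) || is.null(mRNAs)) {
    if (is.null(de)) abort("supply `de` or both `lncRNAs` and `mRNAs`")
    lncRNAs <- de_genes_of(de, "lncRNA")
    mRNAs <- de_genes_of(de, "mRNA")
  }
  lncRNAs <- sort(unique(lncRNAs)); mRNAs <- sort(unique(mRNAs))
  m <- counts_to_matrix(counts)
  missing <- setdiff(c(lncRNAs, mRNAs), rownames(m))
  if (length(missing) > 0)
    abort(sprintf("DE gene(s) absent from the count matrix: %s",
                  paste(head(missing, 5), collapse = ", ")))
  if (normalize) m <- sweep(m, 2, size_factors(counts)[colnames(m)], "/")
  if (scale == "log2") m <- log2(m + pseudocount)

  empty_edges <- tibble(lncRNA = character(0), mRNA = character(0),
                        r = numeric(0), p_value = numeric(0))
  n_samp <- ncol(m)
  if (length(lncRNAs) == 0 || length(mRNAs) == 0) {
    return(new_coex_network(empty_edges, n_samp, 0L, 0L,
                            list(r_min = r_min, p_max = p_max, scale = scale)))
  }
  suppressWarnings(
    R <- cor(t(m[lncRNAs, , drop = FALSE]), t(m[mRNAs, , drop = FALSE])))
  P <- matrix(r_pvalue(as.vector(R), n_samp), nrow = nrow(R),
              dimnames = dimnames(R))
  n_undefined <- sum(is.na(R))
  pass <- !is.na(R) & abs(R) > r_min & P < p_max
  idx <- which(pass, arr.ind = TRUE)
  edges <- tibble(lncRNA = rownames(R)[idx[, 1]],
                  mRNA = colnames(R)[idx[, 2]],
                  r = R[idx], p_value = P[idx]) %>%
    arrange(.data$lncRNA, .data$mRNA)
  new_coex_network(edges, n_samp, length(R), n_undefined,
                   list(r_min = r_min, p_max = p_max, scale = scale))
}

new_coex_network <- function(edges, n_samples, n_tested, n_undefined, params) {
  nodes <- bind_rows(
    edges %>% count(node = .data$lncRNA, name = "degree") %>%
      mutate(type = "lncRNA"),
    edges %>% count(node = .data$mRNA, name = "degree") %>%
      mutate(type = "mRNA")) %>%
    arrange(desc(.data$degree), .data$node) %>%
    select("node", "type", "degree")
  structure(list(edges = edges, nodes = nodes,
                 n_samples = n_samples, n_tested = n_tested,
                 n_undefined = n_undefined, params = params),
            class = "coex_network")
}

#' Top hub lncRNAs by connectivity degree
#'
#' Ranks network lncRNAs by degree (descending, ties broken by gene id) and
#' returns the first `k` with their regulation direction from the DE screen,
#' mirroring a "top hub" table (Number, Gene, Degree, Regulation).
#'
#' @param network A `coex_network` from [build_network()].
#' @param de Optional `de_result` (or any tibble with `gene_id`, `direction`)
#'   used to attach the regulation direction.
#' @param k Number of hubs to return (> 0); capped at the available lncRNAs.
#' @return Tibble with `rank`, `gene_id`, `degree` and (if `de` given)
#'   `regulation`.
#' @export
top_hubs <- function(network, de = NULL, k = 10) {
  stopifnot(inherits(network, "coex_network"))
  if (length(k) != 1 || !is.finite(k) || k <= 0)
    abort("`k` must be a positive integer", class = "pscnet_domain_error")
  out <- network$nodes %>%
    filter(.data$type == "lncRNA") %>%
    arrange(desc(.data$degree), .data$node) %>%
    slice_head(n = k) %>%
    mutate(rank = row_number()) %>%
    select("rank", gene_id = "node", "degree")
  if (!is.null(de)) {
    out <- left_join(out,
                     select(as_tibble(de), "gene_id", regulation = "direction"),
                     by = "gene_id")
  }
  out
}

#' @export
print.coex_network <- function(x, ...) {
  cat(sprintf("<coex_network> %d nodes, %d edges (|r| > %g, p < %g, %s scale)\n",
              nrow(x$nodes), nrow(x$edges),
              x$params$r_min, x$params$p_max, x$params$scale))
  cat(sprintf("  %d pairs tested across %d samples; %d undefined correlations excluded\n",
              x$n_tested, x$n_samples, x$n_undefined))
  invisible(x)
}
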
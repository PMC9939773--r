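# counts tibble (gene_id + sample columns) -> named numeric matrix
counts_to_matrix <- function(counts) {
  if (!"gene_id" %in% names(counts))
    abort("`counts` must have a `gene_id` column followed by sample columns")
  if (anyDuplicated(counts$gene_id))
    abort("duplicate gene ids in `counts`")
  m <- as.matrix(counts[setdiff(names(counts), "gene_id")])
  if (anyDuplicated(colnames(m))) abort("duplicate sample ids in `counts`")
  storage.mode(m) <- "double"
  if (any(!is.finite(m)) || any(m < 0)) abort("counts must be finite and >= 0")
  rownames(m) <- counts$gene_id
  m
}

matrix_to_counts <- function(m) {
  bind_cols(tibble(gene_id = rownames(m)),
            as_tibble(m, .name_repair = "minimal"))
}

#' Median-of-ratios size factors
#'
#' Per-sample size factors computed against the geometric-mean reference gene:
#' for each sample the factor is the median ratio of its counts to the
#' reference, taken over genes with nonzero counts in every sample. A matrix
#' of identical columns yields all factors equal to 1.
#'
#' @param counts Tibble with `gene_id` plus one column per sample.
#' @return Named numeric vector of size factors, one per sample.
#' @export
size_factors <- function(counts) {
  m <- counts_to_matrix(counts)
  zero_samples <- colnames(m)[colSums(m) == 0]
  if (length(zero_samples) > 0)
    abort(sprintf("sample(s) with all-zero counts: %s",
                  paste(zero_samples, collapse = ", ")),
          class = "pscnet_degenerate_input")
  log_ref <- rowMeans(log(m))
  keep <- is.finite(log_ref)
  if (!any(keep))
    abort("no gene has nonzero counts in every sample; size factors undefined",
          class = "pscnet_degenerate_input")
  apply(m[keep, , drop = FALSE], 2,
        function(col) exp(median(log(col) - log_ref[keep])))
}

#' Normalize a count matrix by median-of-ratios size factors
#'
#' @inheritParams size_factors
#' @return Tibble of the same shape with each sample column divided by its
#'   size factor; the factors are attached as attribute `size_factors`.
#' @export
normalize_counts <- function(counts) {
  m <- counts_to_matrix(counts)
  sf <- size_factors(counts)
  out <- matrix_to_counts(sweep(m, 2, sf[colnames(m)], "/"))
  attr(out, "size_factors") <- sf
  out
}

#' Screen differentially expressed genes
#'
#' Normalizes counts (median-of-ratios), applies a minimum-expression
#' prefilter, tests each gene with a two-sided Welch t-test on
#' `log2(normalized + pseudocount)`, corrects with Benjamini-Hochberg over the
#' tested genes only, and labels direction: `up` iff `fdr < alpha` and
#' `log2fc >= log2(fc_min)`, `down` for the mirrored condition, else `ns`.
#' The fold change is `log2((mean_case + pseudocount) /
#' (mean_control + pseudocount))` on normalized group means. Genes with zero
#' variance and equal means in both groups receive p = 1 so they enter the
#' BH denominator deterministically.
#'
#' @param counts Tibble with `gene_id` plus one column per sample.
#' @param samples Tibble with `sample_id` and `group` (values `control`,
#'   `case`); every sample column must be covered.
#' @param annotation Optional annotation tibble (`gene_id`, `biotype`, ...);
#'   if supplied, a `biotype` column is joined onto the result.
#' @param alpha FDR threshold (default 0.05).
#' @param fc_min Minimum absolute fold change on the linear scale (default 2).
#' @param min_expr Prefilter: genes kept only if mean normalized count is
#'   >= `min_expr` in at least one group (default 1). Filtered genes are
#'   excluded from testing and from the BH denominator.
#' @param pseudocount Pseudo-count added before the log2 transform (default 1).
#' @return Tibble of class `de_result`: `gene_id`, (`biotype`,)
#'   `base_mean_control`, `base_mean_case`, `log2fc`, `p_value`, `fdr`,
#'   `direction`. Attributes: `size_factors`, `n_input`, `n_prefiltered`,
#'   `params`.
#' @export
test_de <- function(counts, samples, annotation = NULL,
                    alpha = 0.05, fc_min = 2, min_expr = 1, pseudocount = 1) {
  m <- counts_to_matrix(counts)
  if (!all(c("sample_id", "group") %in% names(samples)))
    abort("`samples` must have columns `sample_id` and `group`")
  missing_grp <- setdiff(colnames(m), samples$sample_id)
  if (length(missing_grp) > 0)
    abort(sprintf("samples without group assignment: %s",
                  paste(missing_grp, collapse = ", ")))
  grp <- setNames(samples$group, samples$sample_id)[colnames(m)]
  if (!all(grp %in% c("control", "case")))
    abort("`group` must be 'control' or 'case'")
  n1 <- sum(grp == "control"); n2 <- sum(grp == "case")
  if (n1 < 2 || n2 < 2)
    abort("each group needs >= 2 samples", class = "pscnet_insufficient_replication")

  sf <- size_factors(counts)
  norm <- sweep(m, 2, sf[colnames(m)], "/")
  mean_ctrl <- rowMeans(norm[, grp == "control", drop = FALSE])
  mean_case <- rowMeans(norm[, grp == "case", drop = FALSE])
  keep <- mean_ctrl >= min_expr | mean_case >= min_expr
  n_input <- nrow(m)

  norm <- norm[keep, , drop = FALSE]
  mean_ctrl <- mean_ctrl[keep]; mean_case <- mean_case[keep]
  L <- log2(norm + pseudocount)
  x1 <- L[, grp == "control", drop = FALSE]
  x2 <- L[, grp == "case", drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  d <- m2 - m1
  p <- rep(1, length(d))
  ok <- se2 > 0
  df <- se2[ok]^2 / ((v1[ok] / n1)^2 / (n1 - 1) + (v2[ok] / n2)^2 / (n2 - 1))
  p[ok] <- 2 * pt(-abs(d[ok] / sqrt(se2[ok])), df)
  p[!ok & d != 0] <- 0  # constant but different groups
  fdr <- p.adjust(p, method = "BH")
  log2fc <- log2((mean_case + pseudocount) / (mean_ctrl + pseudocount))
  direction <- de_direction(log2fc, fdr, alpha, fc_min)

  out <- tibble(gene_id = rownames(norm),
                base_mean_control = unname(mean_ctrl),
                base_mean_case = unname(mean_case),
                log2fc = unname(log2fc),
                p_value = unname(p), fdr = unname(fdr),
                direction = unname(direction))
  if (!is.null(annotation)) {
    out <- out %>%
      left_join(select(annotation, "gene_id", "biotype"), by = "gene_id") %>%
      select("gene_id", "biotype", dplyr::everything())
  }
  structure(out,
            class = c("de_result", class(out)),
            size_factors = sf,
            n_input = n_input,
            n_prefiltered = n_input - nrow(out),
            params = list(alpha = alpha, fc_min = fc_min,
                          min_expr = min_expr, pseudocount = pseudocount))
}

# direction labels are a pure function of (log2fc, fdr, alpha, fc_min)
de_direction <- function(log2fc, fdr, alpha, fc_min) {
  ifelse(fdr < alpha & log2fc >= log2(fc_min), "up",
         ifelse(fdr < alpha & log2fc <= -log2(fc_min), "down", "ns"))
}

#' Partition DE results by biotype and direction
#'
#' Splits significant genes into the four disjoint lists lncRNA-up,
#' lncRNA-down, mRNA-up, mRNA-down with their counts.
#'
#' @param results A `de_result` tibble from [test_de()].
#' @param annotation Optional annotation with `gene_id`, `biotype`; required
#'   if `results` carries no `biotype` column. An unannotated gene is an
#'   error naming the gene.
#' @return Tibble of class `de_summary` with one row per biotype x direction
#'   (up/down): `biotype`, `direction`, `n`, `genes` (list-column, sorted).
#' @export
partition_de <- function(results, annotation = NULL) {
  res <- as_tibble(results)
  if (!is.null(annotation)) {
    res$biotype <- NULL
    res <- left_join(res, select(annotation, "gene_id", "biotype"),
                     by = "gene_id")
  } else if (!"biotype" %in% names(res)) {
    abort("`results` has no biotype column; supply `annotation`")
  }
  bad <- res$gene_id[is.na(res$biotype)]
  if (length(bad) > 0)
    abort(sprintf("gene(s) missing biotype annotation: %s",
                  paste(head(bad, 5), collapse = ", ")),
          class = "pscnet_annotation_mismatch")
  grid <- tidyr::expand_grid(biotype = c("lncRNA", "mRNA"),
                             direction = c("up", "down"))
  out <- grid %>%
    mutate(genes = purrr::map2(.data$biotype, .data$direction, function(b, d) {
      sort(res$gene_id[res$biotype == b & res$direction == d])
    }),
    n = purrr::map_int(.data$genes, length)) %>%
    select("biotype", "direction", "n", "genes")
  structure(out, class = c("de_summary", class(out)),
            n_ns = sum(res$direction == "ns"))
}

# helper: pull the DE gene ids of one biotype out of a de_summary
de_genes_of <- function(de_summary, biotype) {
  stopifnot(inherits(de_summary, "de_summary"))
  sort(unlist(de_summary$genes[de_summary$biotype == biotype],
              use.names = FALSE))
}
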
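#' Gap between two genomic intervals
#'
#' Minimum separation in bp between two 0-based half-open intervals on the
#' same chromosome: 0 when they overlap or abut, otherwise the distance
#' between the facing ends. If chromosomes are supplied and differ, the pair
#' is non-comparable and `NA` is returned (callers skip such pairs).
#'
#' @param start_a,end_a,start_b,end_b Interval coordinates (vectorized),
#'   0-based half-open with `start < end`.
#' @param chrom_a,chrom_b Optional chromosome names.
#' @return Integer-valued numeric vector of gaps (`NA` across chromosomes).
#' @export
interval_gap <- function(start_a, end_a, start_b, end_b,
                         chrom_a = NULL, chrom_b = NULL) {
  if (any(start_a >= end_a) || any(start_b >= end_b))
    abort("intervals must satisfy start < end", class = "pscnet_domain_error")
  gap <- pmax(0, pmax(start_a, start_b) - pmin(end_a, end_b))
  if (!is.null(chrom_a) && !is.null(chrom_b))
    gap[chrom_a != chrom_b] <- NA_real_
  gap
}

#' Predict cis-regulated lncRNA targets by genomic window
#'
#' Pairs every DE lncRNA with every DE mRNA on the same chromosome whose
#' interval gap is at most `window` bp (inclusive; the symmetric,
#' strand-agnostic reading of "within 100 kbp upstream and downstream"), and
#' attaches the expression Pearson correlation. The correlation is reported
#' for all window-passing pairs regardless of any co-expression network
#' threshold, since proximal pairs of interest can carry sub-threshold r.
#' Pairs are ranked by |r| descending, ties by (lncRNA, mRNA) ids.
#'
#' @param de A `de_summary` from [partition_de()], or `NULL` with explicit
#'   `lncRNAs`/`mRNAs`.
#' @param annotation Annotation tibble with `gene_id`, `chrom`, `start`,
#'   `end` (0-based half-open). DE genes without coordinates are skipped and
#'   counted in attribute `n_missing_coords`.
#' @param counts Count tibble used to compute correlations, on the same
#'   scale conventions as [build_network()].
#' @param window Maximum gap in bp (default 100000); must be >= 0.
#' @param lncRNAs,mRNAs Optional explicit DE id vectors overriding `de`.
#' @inheritParams build_network
#' @return Tibble of class `cis_result`: `lncRNA`, `mRNA`, `chrom`, `gap`,
#'   `r`, `p_value`.
#' @export
predict_cis <- function(de, annotation, counts, window = 100000,
                        lncRNAs = NULL, mRNAs = NULL,
                        scale = c("log2", "normalized"),
                        normalize = TRUE, pseudocount = 1) {
  scale <- match.arg(scale)
  if (length(window) != 1 || !is.finite(window) || window < 0)
    abort("`window` must be >= 0", class = "pscnet_domain_error")
  if (is.null(lncRNAs) || is.null(mRNAs)) {
    if (is.null(de)) abort("supply `de` or both `lncRNAs` and `mRNAs`")
    lncRNAs <- de_genes_of(de, "lncRNA")
    mRNAs <- de_genes_of(de, "mRNA")
  }
  ann <- annotation %>%
    filter(!is.na(.data$chrom), !is.na(.data$start), !is.na(.data$end)) %>%
    select("gene_id", "chrom", "start", "end")
  n_missing <- sum(!c(lncRNAs, mRNAs) %in% ann$gene_id)

  pairs <- inner_join(
    ann %>% filter(.data$gene_id %in% lncRNAs) %>%
      rename(lncRNA = "gene_id", start_a = "start", end_a = "end"),
    ann %>% filter(.data$gene_id %in% mRNAs) %>%
      rename(mRNA = "gene_id", start_b = "start", end_b = "end"),
    by = "chrom", relationship = "many-to-many")
  if (nrow(pairs) > 0) {
    pairs <- pairs %>%
      mutate(gap = interval_gap(.data$start_a, .data$end_a,
                                .data$start_b, .data$end_b)) %>%
      filter(.data$gap <= window)
  } else {
    pairs <- mutate(pairs, gap = numeric(0))
  }

  if (nrow(pairs) > 0) {
    m <- counts_to_matrix(counts)
    if (normalize) m <- sweep(m, 2, size_factors(counts)[colnames(m)], "/")
    if (scale == "log2") m <- log2(m + pseudocount)
    rp <- purrr::map2(pairs$lncRNA, pairs$mRNA, function(a, b) {
      suppressWarnings(pearson_with_p(m[a, ], m[b, ]))
    })
    pairs$r <- map_dbl(rp, "r")
    pairs$p_value <- map_dbl(rp, "p_value")
  } else {
    pairs$r <- numeric(0); pairs$p_value <- numeric(0)
  }
  out <- pairs %>%
    select("lncRNA", "mRNA", "chrom", "gap", "r", "p_value") %>%
    arrange(desc(abs(.data$r)), .data$lncRNA, .data$mRNA)
  structure(out, class = c("cis_result", class(out)),
            n_missing_coords = n_missing, window = window)
}
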
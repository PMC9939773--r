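#' Tidy and summarise pscnet result objects
#'
#' broom-style accessors: `tidy()` returns the per-unit table of a result
#' (per gene, per term, per edge, per module, per sample), `glance()` a
#' one-row summary.
#'
#' @param x A pscnet result object.
#' @param ... Unused.
#' @return A tibble.
#' @name pscnet_tidiers
NULL

#' @rdname pscnet_tidiers
#' @export
tidy.de_result <- function(x, ...) as_tibble(x)

#' @rdname pscnet_tidiers
#' @export
glance.de_result <- function(x, ...) {
  p <- attr(x, "params")
  tibble(n_input = attr(x, "n_input"),
         n_prefiltered = attr(x, "n_prefiltered"),
         n_tested = nrow(x),
         n_up = sum(x$direction == "up"),
         n_down = sum(x$direction == "down"),
         alpha = p$alpha, fc_min = p$fc_min)
}

#' @rdname pscnet_tidiers
#' @export
tidy.de_summary <- function(x, ...) select(as_tibble(x), -"genes")

#' @rdname pscnet_tidiers
#' @export
tidy.enrich_result <- function(x, ...) as_tibble(x)

#' @rdname pscnet_tidiers
#' @export
glance.enrich_result <- function(x, ...) {
  tibble(n_terms = nrow(x),
         n_significant = sum(x$significant),
         n_clusters = if ("cluster" %in% names(x))
           dplyr::n_distinct(x$cluster, na.rm = TRUE) else NA_integer_,
         universe_size = attr(x, "universe_size"),
         n_dropped = attr(x, "n_dropped"))
}

#' @rdname pscnet_tidiers
#' @export
tidy.coex_network <- function(x, ...) x$edges

#' @rdname pscnet_tidiers
#' @export
glance.coex_network <- function(x, ...) {
  tibble(n_nodes = nrow(x$nodes),
         n_edges = nrow(x$edges),
         n_lncRNA = sum(x$nodes$type == "lncRNA"),
         n_mRNA = sum(x$nodes$type == "mRNA"),
         n_tested = x$n_tested,
         n_undefined = x$n_undefined,
         r_min = x$params$r_min,
         p_max = x$params$p_max)
}

#' @rdname pscnet_tidiers
#' @export
tidy.mcode_result <- function(x, ...) as_tibble(x)

#' @rdname pscnet_tidiers
#' @export
glance.mcode_result <- function(x, ...) {
  tibble(n_modules = nrow(x),
         n_genes = length(unique(unlist(x$members))),
         top_score = if (nrow(x)) max(x$score) else NA_real_)
}

#' @rdname pscnet_tidiers
#' @export
tidy.cis_result <- function(x, ...) as_tibble(x)

#' @rdname pscnet_tidiers
#' @export
tidy.ddct_result <- function(x, ...) x$delta_ct

#' @rdname pscnet_tidiers
#' @export
glance.ddct_result <- function(x, ...) {
  tibble(gene = x$gene, ddct = x$ddct, fold_change = x$fold_change,
         direction = x$direction)
}
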
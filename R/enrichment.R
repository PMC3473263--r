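# Regulation-enrichment analysis: is a gene group over-represented for
# targets of particular regulators?

#' Regulation-enrichment analysis of a gene group
#'
#' Tests, for every candidate regulator gene, whether the group contains
#' more of that regulator's targets than expected by chance relative to a
#' gene universe. Candidates are all genes with at least one regulatee in
#' the universe under the chosen mode/depth. For a candidate with K
#' targets in the universe (size N), of which k fall in the group (size
#' n), the raw p-value is the hypergeometric upper tail
#' `P(X >= k) = sum_{i=k}^{min(K,n)} C(K,i) C(N-K,n-i) / C(N,n)`,
#' i.e. a one-sided Fisher exact test in the enrichment direction.
#' P-values are corrected across all candidates tested.
#'
#' @param group A [gene_group()]; must be a subset of the universe.
#' @param network A `gene_network`.
#' @param mode `"direct"` (direct targets only) or `"indirect"` (direct
#'   plus indirect targets within `depth`).
#' @param depth Reachability bound for indirect mode.
#' @param universe Character vector of genes (default: all network
#'   nodes).
#' @param alpha Significance threshold applied to adjusted p-values.
#' @param correction `"BH"`, `"bonferroni"` or `"none"`.
#' @return A `reg_enrichment` tibble, one row per candidate regulator:
#'   `regulator`, `k`, `K`, `n`, `N`, `p_raw`, `p_adj`, `significant`,
#'   sorted by `p_adj` then regulator id. The number of candidates tested
#'   is in `attr(, "n_tests")`.
#' @export
regulation_enrichment <- function(group, network,
                                  mode = c("direct", "indirect"),
                                  depth = Inf, universe = NULL,
                                  alpha = 0.05,
                                  correction = c("BH", "bonferroni",
                                                 "none")) {
  stopifnot(inherits(group, "gene_group"), inherits(network, "gene_network"))
  mode <- match.arg(mode)
  correction <- match.arg(correction)
  if (is.null(universe)) universe <- network$nodes
  universe <- unique(as.character(universe))
  outside <- setdiff(group$members, universe)
  if (length(outside)) {
    stop("group is not contained in the universe: ",
         paste(utils::head(outside, 5), collapse = ", "), call. = FALSE)
  }
  adj <- adjacency_list(network, "out")
  d <- if (mode == "direct") 1 else depth
  targets_of <- function(g) intersect(reach_set(adj, g, d), universe)

  n <- length(group$members)
  N <- length(universe)
  rows <- purrr::map(sort(network$nodes), function(r) {
    tg <- targets_of(r)
    K <- length(tg)
    if (K == 0) return(NULL)
    k <- length(intersect(tg, group$members))
    tibble::tibble(regulator = r, k = k, K = K, n = n, N = N,
                   p_raw = stats::phyper(k - 1, K, N - K, n,
                                         lower.tail = FALSE))
  })
  res <- dplyr::bind_rows(rows)
  if (nrow(res) == 0) {
    res <- tibble::tibble(regulator = character(0), k = integer(0),
                          K = integer(0), n = integer(0), N = integer(0),
                          p_raw = numeric(0), p_adj = numeric(0),
                          significant = logical(0))
  } else {
    res$p_adj <- stats::p.adjust(res$p_raw, method = correction)
    res$significant <- res$p_adj < alpha
    res <- dplyr::arrange(res, .data$p_adj, .data$regulator)
  }
  attr(res, "n_tests") <- nrow(res)
  attr(res, "options") <- list(mode = mode, depth = depth, alpha = alpha,
                               correction = correction)
  class(res) <- c("reg_enrichment", class(res))
  res
}
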
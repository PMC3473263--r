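# broom-style tidiers for the package's result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an influence ranking
#'
#' @param x A `reg_influence` object.
#' @param ... Unused.
#' @return A tibble with `gene`, `score`, `direct_targets`, `rank`.
#' @exportS3Method generics::tidy
tidy.reg_influence <- function(x, ...) {
  genes <- x$ranking
  tibble::tibble(
    gene = genes,
    score = unname(x$score[genes]),
    direct_targets = unname(x$direct_targets[genes]),
    rank = seq_along(genes))
}

#' @rdname tidy.reg_influence
#' @exportS3Method generics::glance
glance.reg_influence <- function(x, ...) {
  tibble::tibble(
    n_genes = length(x$score),
    iterations = x$iterations_used,
    converged = x$converged,
    normalization = x$options$normalization,
    damping = x$options$damping)
}

#' Tidy a gene network
#'
#' @param x A `gene_network`.
#' @param ... Unused.
#' @return The edge tibble (`from`, `to`, `mode`, `provenance`).
#' @exportS3Method generics::tidy
tidy.gene_network <- function(x, ...) x$edges

#' @rdname tidy.gene_network
#' @exportS3Method generics::glance
glance.gene_network <- function(x, ...) {
  tibble::tibble(
    n_nodes = length(x$nodes),
    n_edges = nrow(x$edges),
    n_regulators = sum(network_out_degree(x) > 0),
    include = paste(x$include, collapse = "+"))
}

#' Tidy a parity classification
#'
#' @param x A `parity_classification`.
#' @param ... Unused.
#' @return A tibble with `entity` and `class` (activator / inhibitor /
#'   unknown).
#' @exportS3Method generics::tidy
tidy.parity_classification <- function(x, ...) {
  tibble::tibble(
    entity = c(x$activators, x$inhibitors, x$unknown),
    class = rep(c("activator", "inhibitor", "unknown"),
                c(length(x$activators), length(x$inhibitors),
                  length(x$unknown))))
}

#' @rdname tidy.parity_classification
#' @exportS3Method generics::glance
glance.parity_classification <- function(x, ...) {
  tibble::tibble(
    target = x$target,
    n_activators = length(x$activators),
    n_inhibitors = length(x$inhibitors),
    n_unknown = length(x$unknown),
    depth = x$depth)
}

#' Tidy a gene group
#'
#' @param x A `gene_group`.
#' @param ... Unused.
#' @return A tibble with a `gene` column.
#' @exportS3Method generics::tidy
tidy.gene_group <- function(x, ...) {
  tibble::tibble(gene = x$members)
}
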
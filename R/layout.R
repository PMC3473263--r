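# Coordinate layouts for the regulatory overview: elliptical and layered.

new_reg_layout <- function(coords, kind) {
  attr(coords, "kind") <- kind
  class(coords) <- c("reg_layout", class(coords))
  coords
}

#' Elliptical regulatory-overview layout
#'
#' Places sigma-factor genes (genes whose product is named as the sigma
#' factor of any promoter) on an innermost ellipse, all other regulator
#' genes (non-zero out-degree) on a second ellipse, and the remaining
#' genes on an outer ellipse, grouped contiguously by their regulator
#' cluster (see [cluster_genes_by_regulators()]). A gene that is both a
#' sigma factor and an ordinary regulator is drawn on the sigma ring only.
#' Ellipses share a 2:1 axis ratio with radii 1, 2 and 4; nodes are evenly
#' spaced by angle, ordered lexicographically within a ring (within a
#' cluster for the outer ring). The layout is deterministic and assigns
#' every node a distinct coordinate.
#'
#' @param network A non-empty `gene_network`.
#' @param model The [regulatory_model()] the network was built from (used
#'   to identify sigma-factor genes).
#' @return A `reg_layout` tibble with columns `gene`, `x`, `y`, `ring`.
#' @export
elliptical_layout <- function(network, model) {
  stopifnot(inherits(network, "gene_network"))
  if (length(network$nodes) == 0) stop("network has no nodes", call. = FALSE)
  sigma <- intersect(sigma_factor_genes(model), network$nodes)
  outd <- network_out_degree(network)
  ring1 <- sort(sigma)
  ring2 <- sort(setdiff(network$nodes[outd[network$nodes] > 0], ring1))
  rest <- setdiff(network$nodes, c(ring1, ring2))

  # outer ring: cluster-contiguous order
  clusters <- cluster_genes_by_regulators(network)
  ring3 <- character(0)
  for (g in clusters$genes) ring3 <- c(ring3, sort(intersect(g, rest)))
  ring3 <- c(ring3, sort(setdiff(rest, ring3)))

  radii <- c(1, 2, 4)
  rings <- list(ring1, ring2, ring3)
  rows <- list()
  for (r in 1:3) {
    genes <- rings[[r]]
    n <- length(genes)
    if (n == 0) next
    theta <- 2 * pi * (seq_len(n) - 1) / n
    rows[[r]] <- tibble::tibble(
      gene = genes,
      x = 2 * radii[r] * cos(theta),
      y = radii[r] * sin(theta),
      ring = r
    )
  }
  new_reg_layout(dplyr::bind_rows(rows), "elliptical")
}

#' Layered regulatory-overview layout
#'
#' Regulator genes (non-zero out-degree) occupy the upper layers and all
#' remaining genes the bottom layer (layer 0). A regulator's layer is one
#' plus the length of the longest path from it through regulator-only
#' nodes, computed on the regulator-induced subgraph with strongly
#' connected components collapsed (so mutually regulating genes share a
#' layer). Higher layer indices are drawn above. Within a layer, x
#' positions are evenly spaced and centred; the bottom layer is ordered
#' cluster-contiguously, other layers lexicographically.
#'
#' @inheritParams elliptical_layout
#' @return A `reg_layout` tibble with columns `gene`, `x`, `y`, `layer`.
#' @export
layered_layout <- function(network, model) {
  stopifnot(inherits(network, "gene_network"))
  if (length(network$nodes) == 0) stop("network has no nodes", call. = FALSE)
  outd <- network_out_degree(network)
  regulators <- sort(network$nodes[outd[network$nodes] > 0])
  bottom <- setdiff(network$nodes, regulators)

  layer <- stats::setNames(integer(length(network$nodes)), network$nodes)
  if (length(regulators) > 0) {
    e <- dplyr::filter(network$edges, .data$from %in% regulators,
                       .data$to %in% regulators)
    gr <- igraph::make_empty_graph(directed = TRUE) +
      igraph::vertices(regulators)
    if (nrow(e)) {
      gr <- igraph::add_edges(gr, rbind(match(e$from, regulators),
                                        match(e$to, regulators)))
    }
    comp <- igraph::components(gr, mode = "strong")
    memb <- comp$membership
    # condensation DAG over SCCs
    ncomp <- comp$no
    cedges <- unique(cbind(memb[match(e$from, regulators)],
                           memb[match(e$to, regulators)]))
    if (length(cedges)) cedges <- cedges[cedges[, 1] != cedges[, 2], ,
                                         drop = FALSE]
    succ <- split(cedges[, 2], cedges[, 1])
    cg <- igraph::make_empty_graph(directed = TRUE) +
      igraph::vertices(seq_len(ncomp))
    if (nrow(cedges)) cg <- igraph::add_edges(cg, t(cedges))
    order_rev <- rev(as.integer(igraph::topo_sort(cg, mode = "out")))
    clayer <- integer(ncomp)
    for (cmp in order_rev) {
      s <- succ[[as.character(cmp)]]
      clayer[cmp] <- 1L + if (length(s)) max(clayer[s]) else 0L
    }
    layer[regulators] <- clayer[memb]
  }

  # bottom layer: cluster-contiguous; upper layers: lexicographic
  clusters <- cluster_genes_by_regulators(network)
  bottom_order <- character(0)
  for (g in clusters$genes) bottom_order <- c(bottom_order,
                                              sort(intersect(g, bottom)))
  bottom_order <- c(bottom_order, sort(setdiff(bottom, bottom_order)))

  rows <- list()
  for (lv in sort(unique(unname(layer)))) {
    genes <- if (lv == 0L) bottom_order else
      sort(names(layer)[layer == lv & names(layer) %in% regulators])
    n <- length(genes)
    if (n == 0) next
    rows[[length(rows) + 1L]] <- tibble::tibble(
      gene = genes,
      x = seq_len(n) - (n + 1) / 2,
      y = as.numeric(lv),
      layer = lv
    )
  }
  new_reg_layout(dplyr::bind_rows(rows), "layered")
}
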
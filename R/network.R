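# Gene-level signed regulatory network.

EDGE_MODES <- c("activation", "inhibition", "dual", "unknown")

mode_to_edge_label <- c("+" = "activation", "-" = "inhibition",
                        "dual" = "dual", "unknown" = "unknown")

# Label-merge lattice: unknown < activation/inhibition < dual.
merge_edge_modes <- function(modes) {
  modes <- unique(modes)
  if ("dual" %in% modes ||
      all(c("activation", "inhibition") %in% modes)) return("dual")
  if ("activation" %in% modes) return("activation")
  if ("inhibition" %in% modes) return("inhibition")
  "unknown"
}

new_gene_network <- function(nodes, edges, include) {
  structure(
    list(nodes = sort(unique(nodes)),
         edges = dplyr::arrange(edges, .data$from, .data$to),
         include = include),
    class = "gene_network")
}

#' Build the gene-level regulatory network of a model
#'
#' Creates a directed graph over the model's genes in which an edge from
#' gene A to gene B means A regulates B. For every regulation of an
#' included class, edges run from each gene encoding the regulator
#' ([regulator_genes()]) to each gene affected by the regulated entity
#' ([regulated_genes()]), labelled by the regulation's mode. Enzyme-level
#' (substrate) modulation never contributes edges. With `"sigma"`
#' included, each gene encoding a promoter's sigma factor gets an
#' activation edge to every gene of that promoter's TU, with provenance
#' tag `sigma:<promoter id>`. Parallel edges for one ordered gene pair are
#' merged: a conflicting activation/inhibition pair (or any dual) merges
#' to `dual`; `unknown` is dominated by any informative label; provenance
#' ids are unioned.
#'
#' @param model A valid [regulatory_model()].
#' @param include Subset of `c("transcriptional", "translational",
#'   "sigma")`: which influence classes contribute edges.
#' @return A `gene_network`: node set (all model genes), an edge tibble
#'   (`from`, `to`, `mode`, list-column `provenance`), and the include
#'   flags used.
#' @export
build_gene_network <- function(model,
                               include = c("transcriptional",
                                           "translational", "sigma")) {
  stopifnot(inherits(model, "regulatory_model"))
  include <- match.arg(include, c("transcriptional", "translational", "sigma"),
                       several.ok = TRUE)
  rg <- model$regulations
  from <- character(0); to <- character(0)
  mode <- character(0); prov <- character(0)

  classes <- character(0)
  if ("transcriptional" %in% include) classes <- c(classes,
                                                   TRANSCRIPTIONAL_CLASSES)
  if ("translational" %in% include) classes <- c(classes,
                                                 "regulation-of-translation")
  for (i in which(rg$reg_class %in% classes)) {
    sources <- entity_genes(model, rg$regulator_id[i])
    targets <- expand_regulated_entity(model, rg$regulated_entity_id[i])
    if (length(sources) == 0 || length(targets) == 0) next
    grid <- expand.grid(s = sources, t = targets, stringsAsFactors = FALSE)
    from <- c(from, grid$s); to <- c(to, grid$t)
    mode <- c(mode, rep(mode_to_edge_label[[rg$mode[i]]], nrow(grid)))
    prov <- c(prov, rep(rg$id[i], nrow(grid)))
  }

  if ("sigma" %in% include) {
    pr <- model$promoters
    for (i in which(!is.na(pr$sigma_factor_id))) {
      sources <- entity_genes(model, pr$sigma_factor_id[i])
      tu <- entity_record(model, "transcription_units", pr$tu_id[i])
      if (is.null(tu) || length(sources) == 0) next
      targets <- tu$gene_ids[[1]]
      grid <- expand.grid(s = sources, t = targets, stringsAsFactors = FALSE)
      from <- c(from, grid$s); to <- c(to, grid$t)
      mode <- c(mode, rep("activation", nrow(grid)))
      prov <- c(prov, rep(paste0("sigma:", pr$id[i]), nrow(grid)))
    }
  }

  raw <- tibble::tibble(from = from, to = to, mode = mode, prov = prov)
  edges <- raw |>
    dplyr::group_by(.data$from, .data$to) |>
    dplyr::summarise(
      mode = merge_edge_modes(.data$mode),
      provenance = list(sort(unique(.data$prov))),
      .groups = "drop")
  new_gene_network(model$genes$id, edges, include)
}

#' @export
print.gene_network <- function(x, ...) {
  cat("<gene_network: ", length(x$nodes), " genes, ", nrow(x$edges),
      " edges; include = ", paste(x$include, collapse = "+"), ">\n", sep = "")
  invisible(x)
}

# adjacency lists; direction "out" (targets) or "in" (regulators)
adjacency_list <- function(network, direction = c("out", "in")) {
  direction <- match.arg(direction)
  e <- network$edges
  adj <- stats::setNames(vector("list", length(network$nodes)), network$nodes)
  if (nrow(e)) {
    sp <- if (direction == "out") split(e$to, e$from) else split(e$from, e$to)
    adj[names(sp)] <- sp
  }
  adj
}

network_out_degree <- function(network) {
  d <- stats::setNames(integer(length(network$nodes)), network$nodes)
  if (nrow(network$edges)) {
    t <- table(network$edges$from)
    d[names(t)] <- as.integer(t)
  }
  d
}

#' Cluster non-regulator genes by their regulator sets
#'
#' Two genes fall in the same cluster iff the sets of genes that directly
#' regulate them (their in-neighbours) are identical. Genes that are
#' themselves regulators (non-zero out-degree) are excluded from
#' clustering; genes with no regulators form the "unregulated" cluster
#' (empty regulator set). Clusters are ordered by size (descending), ties
#' broken by the lexicographically smallest member.
#'
#' @param network A `gene_network`.
#' @return A tibble with one row per cluster: `cluster` (integer id),
#'   `regulators` (list-column, the shared regulator set), `genes`
#'   (list-column, sorted members) and `size`.
#' @export
cluster_genes_by_regulators <- function(network) {
  stopifnot(inherits(network, "gene_network"))
  outd <- network_out_degree(network)
  members <- network$nodes[outd[network$nodes] == 0L]
  inadj <- adjacency_list(network, "in")
  keys <- vapply(members, function(g) {
    paste(sort(unique(inadj[[g]])), collapse = "\x1f")
  }, character(1))
  groups <- split(members, keys)
  genes <- lapply(groups, function(g) sort(g))
  sizes <- lengths(genes)
  reps <- vapply(genes, `[`, character(1), 1)
  ord <- order(-sizes, reps)
  genes <- genes[ord]
  regulators <- lapply(names(groups)[ord], function(k) {
    if (k == "") character(0) else strsplit(k, "\x1f", fixed = TRUE)[[1]]
  })
  tibble::tibble(
    cluster = seq_along(genes),
    regulators = regulators,
    genes = unname(genes),
    size = unname(sizes[ord])
  )
}

#' Extract a regulatory subnetwork around seed genes
#'
#' Keeps the seed genes plus every gene reachable from them within `depth`
#' steps following edges toward regulatees (`"regulatees"`), toward
#' regulators (`"regulators"`), or both; all network edges among the
#' retained genes are kept with their labels and provenance.
#'
#' @param network A `gene_network`.
#' @param seed_genes Character vector of genes present in the network.
#' @param direction One of `"regulatees"`, `"regulators"`, `"both"`.
#' @param depth Positive number of steps, or `Inf` for the closure.
#' @return A `gene_network` restricted to the retained genes.
#' @export
subnetwork <- function(network, seed_genes,
                       direction = c("regulatees", "regulators", "both"),
                       depth = Inf) {
  stopifnot(inherits(network, "gene_network"), depth >= 1)
  direction <- match.arg(direction)
  missing <- setdiff(seed_genes, network$nodes)
  if (length(missing)) {
    stop("unknown seed gene(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  adjs <- list()
  if (direction %in% c("regulatees", "both"))
    adjs <- c(adjs, list(adjacency_list(network, "out")))
  if (direction %in% c("regulators", "both"))
    adjs <- c(adjs, list(adjacency_list(network, "in")))

  visited <- unique(seed_genes)
  frontier <- visited
  d <- 0
  while (length(frontier) > 0 && d < depth) {
    nxt <- unique(unlist(lapply(adjs, function(a)
      unlist(a[frontier], use.names = FALSE)), use.names = FALSE))
    frontier <- setdiff(nxt, visited)
    visited <- c(visited, frontier)
    d <- d + 1
  }
  keep <- sort(visited)
  e <- dplyr::filter(network$edges, .data$from %in% keep, .data$to %in% keep)
  new_gene_network(keep, e, network$include)
}
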
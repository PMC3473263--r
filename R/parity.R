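# Signed entity graph and parity propagation: net activators/inhibitors
# of a target, with effects multiplicative in sign along paths.

SIGN_SET <- list("+" = 1L, "-" = -1L, "+-" = c(1L, -1L))

sign_label <- function(v) {
  v <- sort(unique(as.integer(v)), decreasing = TRUE)
  if (identical(v, c(1L, -1L))) "+-" else if (identical(v, 1L)) "+" else "-"
}

# Entity -> parity node. A gene and its single-gene polypeptide/RNA
# product share one node (the gene id); complexes, modified forms,
# multi-gene products and compounds are their own nodes.
parity_node_of <- function(model, entity_id) {
  kind <- entity_kind(model, entity_id)
  if (is.na(kind)) return(NA_character_)
  if (kind %in% c("gene", "compound")) return(entity_id)
  if (kind != "product") return(NA_character_)
  p <- entity_record(model, "products", entity_id)
  if (p$kind %in% c("polypeptide", "rna") && length(p$gene_ids[[1]]) == 1) {
    p$gene_ids[[1]]
  } else {
    entity_id
  }
}

#' Build the signed entity graph of all regulatory influences
#'
#' Nodes are genes (unified with their single-gene polypeptide/RNA
#' product), complexes, modified forms and compounds. Edges carry a sign
#' (`+`, `-`, or `+-` for dual) and provenance, and are added from:
#' (a) every non-enzyme-level regulation, regulator entity to each
#' regulated gene, signed by mode (unknown-mode interactions carry no
#' information and are omitted; dual contributes both signs);
#' (b) enzyme-modulation regulations, regulator to the enzyme;
#' (c) every irreversible reaction: reactants and enzymes activate each
#' reaction product, while the enzyme and the other reactants inhibit
#' each reactant (they promote its consumption); reversible reactions
#' contribute nothing;
#' (d) complex formation (each component activates the complex) and
#' covalent modification (the unmodified form activates the modified
#' form).
#' Compounds participating in more than `hub_threshold` reactions are
#' excluded outright — such hub metabolites are unlikely to carry
#' regulatory signal and only clutter the graph.
#'
#' @param model A valid [regulatory_model()].
#' @param hub_threshold Maximum number of reactions a compound may
#'   participate in before it is pruned (default 10).
#' @param physiological_only Drop interactions explicitly flagged not
#'   physiologically relevant.
#' @param include Regulation classes contributing edges (default: all).
#' @return A `parity_graph`: sorted `nodes`, an edge tibble (`from`,
#'   `to`, `sign`, list-column `provenance`), and the options used.
#' @export
build_parity_graph <- function(model, hub_threshold = 10L,
                               physiological_only = FALSE,
                               include = REG_CLASSES) {
  stopifnot(inherits(model, "regulatory_model"), hub_threshold >= 1)
  include <- match.arg(include, REG_CLASSES, several.ok = TRUE)

  # hub metabolites: participation in > hub_threshold reactions
  part <- model$index$rxns_by_participant
  hubs <- names(part)[lengths(part) > hub_threshold &
                        names(part) %in% model$compounds$id]

  from <- character(0); to <- character(0)
  sgn <- character(0); prov <- character(0)
  add <- function(f, t, s, p) {
    if (length(f) == 0 || length(t) == 0) return(invisible())
    grid <- expand.grid(f = f, t = t, stringsAsFactors = FALSE)
    from <<- c(from, grid$f); to <<- c(to, grid$t)
    sgn <<- c(sgn, rep(s, nrow(grid))); prov <<- c(prov, rep(p, nrow(grid)))
    invisible()
  }
  mode_sign <- c("+" = "+", "-" = "-", "dual" = "+-")

  rg <- model$regulations
  keep <- rg$reg_class %in% include & rg$mode %in% names(mode_sign)
  if (physiological_only) {
    keep <- keep & !(!is.na(rg$physiologically_relevant) &
                       !rg$physiologically_relevant)
  }
  for (i in which(keep)) {
    src <- parity_node_of(model, rg$regulator_id[i])
    if (is.na(src)) next
    s <- mode_sign[[rg$mode[i]]]
    if (rg$reg_class[i] == "regulation-of-enzyme-activity") {
      tgt_id <- rg$regulated_entity_id[i]
      k <- entity_kind(model, tgt_id)
      enz <- if (identical(k, "product")) tgt_id
             else entity_record(model, "reactions", tgt_id)$enzyme_ids[[1]]
      tgts <- vapply(enz, function(e) parity_node_of(model, e), character(1))
      add(src, tgts[!is.na(tgts)], s, rg$id[i])
    } else {
      genes <- expand_regulated_entity(model, rg$regulated_entity_id[i])
      add(src, genes, s, rg$id[i])
    }
  }

  rx <- model$reactions
  for (i in which(!rx$reversible)) {
    nodes_of <- function(ids) {
      v <- vapply(ids, function(e) parity_node_of(model, e), character(1))
      unique(v[!is.na(v)])
    }
    reactants <- nodes_of(rx$reactant_ids[[i]])
    products <- nodes_of(rx$product_ids[[i]])
    enzymes <- nodes_of(rx$enzyme_ids[[i]])
    for (p in products) add(setdiff(c(reactants, enzymes), p), p, "+", rx$id[i])
    for (cc in reactants) {
      add(setdiff(c(enzymes, reactants), cc), cc, "-", rx$id[i])
    }
  }

  pd <- model$products
  for (i in seq_len(nrow(pd))) {
    self <- parity_node_of(model, pd$id[i])
    if (is.na(self)) next
    if (pd$kind[i] == "complex") {
      comps <- vapply(pd$component_ids[[i]], function(e)
        parity_node_of(model, e), character(1))
      add(unique(comps[!is.na(comps)]), self, "+",
          paste0("component-of:", pd$id[i]))
    } else if (pd$kind[i] == "modified-form" &&
               !is.na(pd$unmodified_form_id[i])) {
      base <- parity_node_of(model, pd$unmodified_form_id[i])
      if (!is.na(base)) add(base, self, "+",
                            paste0("component-of:", pd$id[i]))
    }
  }

  product_nodes <- unique(stats::na.omit(vapply(pd$id, function(e)
    parity_node_of(model, e), character(1))))
  nodes <- unique(c(model$genes$id, model$compounds$id, product_nodes))
  nodes <- setdiff(nodes, hubs)

  e <- tibble::tibble(from = from, to = to, sign = sgn, prov = prov)
  e <- dplyr::filter(e, !.data$from %in% hubs, !.data$to %in% hubs)
  edges <- e |>
    dplyr::group_by(.data$from, .data$to) |>
    dplyr::summarise(
      sign = sign_label(unlist(SIGN_SET[.data$sign], use.names = FALSE)),
      provenance = list(sort(unique(.data$prov))),
      .groups = "drop") |>
    dplyr::arrange(.data$from, .data$to)

  structure(
    list(nodes = sort(nodes), edges = edges,
         options = list(hub_threshold = hub_threshold,
                        physiological_only = physiological_only,
                        include = include),
         excluded_hubs = sort(hubs)),
    class = "parity_graph")
}

#' @export
print.parity_graph <- function(x, ...) {
  cat("<parity_graph: ", length(x$nodes), " entities, ", nrow(x$edges),
      " signed edges", sep = "")
  if (length(x$excluded_hubs))
    cat(", ", length(x$excluded_hubs), " hub compound(s) excluded", sep = "")
  cat(">\n")
  invisible(x)
}

parity_out_adj <- function(pgraph) {
  e <- pgraph$edges
  if (nrow(e) == 0) return(list())
  idx <- split(seq_len(nrow(e)), e$from)
  lapply(idx, function(i) list(to = e$to[i], sign = SIGN_SET[e$sign[i]]))
}

# nodes with a directed path to `target` of length <= depth (target incl.)
parity_scope <- function(pgraph, target, depth) {
  e <- pgraph$edges
  radj <- if (nrow(e)) split(e$from, e$to) else list()
  visited <- target
  frontier <- target
  d <- 0
  while (length(frontier) > 0 && d < depth) {
    nxt <- setdiff(unique(unlist(radj[frontier], use.names = FALSE)), visited)
    visited <- c(visited, nxt)
    frontier <- nxt
    d <- d + 1
  }
  visited
}

# Sign set (subset of {+1, -1}) over simple paths u -> ... -> target of
# length <= depth whose intermediate nodes are determined and not pruned.
path_sign_search <- function(u, target, adj, depth, determined, pruned) {
  found_plus <- FALSE
  found_minus <- FALSE
  visit <- function(node, signs, len, on_path) {
    out <- adj[[node]]
    if (is.null(out)) return(invisible())
    for (j in seq_along(out$to)) {
      v <- out$to[j]
      new_signs <- unique(as.vector(outer(signs, out$sign[[j]])))
      if (v == target) {
        if (1L %in% new_signs) found_plus <<- TRUE
        if (-1L %in% new_signs) found_minus <<- TRUE
        if (found_plus && found_minus) return(invisible())
      } else if (len + 1L < depth && !(v %in% on_path) &&
                 isTRUE(determined[[v]]) && !(v %in% pruned)) {
        visit(v, new_signs, len + 1L, c(on_path, v))
        if (found_plus && found_minus) return(invisible())
      }
    }
    invisible()
  }
  visit(u, 1L, 0L, u)
  out <- integer(0)
  if (found_plus) out <- c(out, 1L)
  if (found_minus) out <- c(out, -1L)
  out
}

#' Classify upstream entities as net activators or inhibitors of a target
#'
#' Propagates regulation parity through the signed entity graph: effects
#' are multiplicative in sign, so an inhibitor of an inhibitor is an
#' indirect activator. An entity's sign set is the set of path-sign
#' products over simple paths (no node revisited) to the target of length
#' at most `depth` whose intermediate nodes all have an unambiguous sign.
#' An entity reached by both a positive and a negative path has unknown
#' net effect; it is pruned — further regulatory effects through it are
#' ignored — and the remaining signs are recomputed from scratch, at most
#' once per node, until no new conflict appears.
#'
#' @param pgraph A [build_parity_graph()] result.
#' @param target A node of the graph (gene or entity id).
#' @param depth Maximum path length in edges (default 6).
#' @return A `parity_classification`: `target`, sorted entity vectors
#'   `activators`, `inhibitors`, `unknown`, the per-entity `sign_sets`,
#'   `depth` and the number of prune/recompute rounds. Entities with no
#'   admissible path are absent from all three lists.
#' @export
classify_influences <- function(pgraph, target, depth = 6L) {
  stopifnot(inherits(pgraph, "parity_graph"), depth >= 1)
  if (!target %in% pgraph$nodes) {
    stop("target '", target, "' is not a node of the parity graph",
         call. = FALSE)
  }
  scope <- parity_scope(pgraph, target, depth)
  candidates <- sort(setdiff(scope, target))
  adj <- parity_out_adj(pgraph)

  pruned <- character(0)
  sigma <- list()
  rounds <- 0L
  repeat {
    rounds <- rounds + 1L
    if (rounds > length(candidates) + 1L) {
      stop("parity fixpoint failed to terminate", call. = FALSE)  # nocov
    }
    sigma <- list()
    determined <- stats::setNames(as.list(rep(FALSE, length(candidates))),
                                  candidates)
    conflict <- NULL
    repeat {
      changed <- FALSE
      for (u in setdiff(candidates, pruned)) {
        s <- path_sign_search(u, target, adj, depth, determined, pruned)
        if (length(s) == 2) { conflict <- u; break }
        if (length(s) == 1 && !identical(sigma[[u]], s)) {
          sigma[[u]] <- s
          determined[[u]] <- TRUE
          changed <- TRUE
        }
      }
      if (!is.null(conflict) || !changed) break
    }
    if (is.null(conflict)) break
    pruned <- c(pruned, conflict)
  }

  signs <- vapply(names(sigma), function(u) sign_label(sigma[[u]]),
                  character(1))
  sign_sets <- as.list(signs)
  for (u in pruned) sign_sets[[u]] <- "+-"
  structure(
    list(target = target,
         activators = sort(names(signs)[signs == "+"]),
         inhibitors = sort(names(signs)[signs == "-"]),
         unknown = sort(pruned),
         sign_sets = sign_sets,
         depth = depth,
         rounds = rounds),
    class = "parity_classification")
}

#' @export
print.parity_classification <- function(x, ...) {
  cat("<parity_classification of '", x$target, "' (depth ", x$depth, ")>\n",
      "  activators: ", length(x$activators),
      "  inhibitors: ", length(x$inhibitors),
      "  unknown: ", length(x$unknown), "\n", sep = "")
  invisible(x)
}

#' Paths through which a regulator influences a target
#'
#' Enumerates the simple paths from `regulator` to `target` of length at
#' most `depth` whose intermediate nodes all have an unambiguous net sign
#' (per [classify_influences()]); paths through unknown or unclassified
#' entities are excluded. Each path is annotated with its per-edge signs
#' and the overall sign product.
#'
#' @inheritParams classify_influences
#' @param regulator Source node.
#' @return A tibble sorted by path length then lexicographically:
#'   `length`, `sign` (product; `+-` if a dual edge is traversed),
#'   list-columns `nodes` and `edge_signs`, and a display string `path`.
#'   Zero rows if the target is unreachable.
#' @export
influence_paths <- function(pgraph, regulator, target, depth = 6L) {
  stopifnot(inherits(pgraph, "parity_graph"))
  for (nd in c(regulator, target)) {
    if (!nd %in% pgraph$nodes) {
      stop("node '", nd, "' is not in the parity graph", call. = FALSE)
    }
  }
  cls <- classify_influences(pgraph, target, depth)
  determined <- names(cls$sign_sets)[vapply(cls$sign_sets, function(s)
    s %in% c("+", "-"), logical(1))]
  adj <- parity_out_adj(pgraph)

  paths <- list()
  visit <- function(node, nodes, signs, len) {
    out <- adj[[node]]
    if (is.null(out)) return(invisible())
    for (j in seq_along(out$to)) {
      v <- out$to[j]
      es <- sign_label(out$sign[[j]])
      if (v == target) {
        paths[[length(paths) + 1L]] <<- list(nodes = c(nodes, v),
                                             signs = c(signs, es))
      } else if (len + 1L < depth && !(v %in% nodes) && v %in% determined) {
        visit(v, c(nodes, v), c(signs, es), len + 1L)
      }
    }
    invisible()
  }
  visit(regulator, regulator, character(0), 0L)

  if (length(paths) == 0) {
    return(tibble::tibble(length = integer(0), sign = character(0),
                          nodes = list(), edge_signs = list(),
                          path = character(0)))
  }
  rows <- purrr::map(paths, function(p) {
    prod <- Reduce(function(a, b) unique(as.vector(outer(a, b))),
                   SIGN_SET[p$signs], accumulate = FALSE)
    tibble::tibble(length = length(p$signs), sign = sign_label(prod),
                   nodes = list(p$nodes), edge_signs = list(p$signs),
                   path = paste(p$nodes, collapse = " -> "))
  })
  dplyr::arrange(dplyr::bind_rows(rows), .data$length, .data$path)
}
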
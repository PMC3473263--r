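# Gene-group algebra: regulators/regulatees, operon expansion, set
# operations and transformations to products and modulators.

#' Create a gene group
#'
#' A named set of gene ids carrying an append-only history of the
#' operations that produced it. Members are stored sorted and
#' duplicate-free.
#'
#' @param members Character vector of gene ids.
#' @param name Display name.
#' @param history Internal; prior operation descriptors.
#' @return A `gene_group` object.
#' @export
gene_group <- function(members, name = "group", history = character(0)) {
  structure(
    list(name = name, members = sort(unique(as.character(members))),
         history = history),
    class = "gene_group")
}

#' @export
print.gene_group <- function(x, ...) {
  cat("<gene_group '", x$name, "': ", length(x$members), " genes>\n", sep = "")
  if (length(x$members)) cat("  ", paste(utils::head(x$members, 12),
                                         collapse = ", "),
                             if (length(x$members) > 12) ", ..." else "",
                             "\n", sep = "")
  invisible(x)
}

group_derive <- function(members, parent, op) {
  gene_group(members, name = paste0(parent$name, ":", op),
             history = c(parent$history, op))
}

warn_absent <- function(group, known, what) {
  absent <- setdiff(group$members, known)
  if (length(absent)) {
    warning(length(absent), " group gene(s) absent from the ", what,
            " and ignored: ", paste(utils::head(absent, 5), collapse = ", "),
            call. = FALSE)
  }
  intersect(group$members, known)
}

# reachability of `start` along `adj`, up to `depth` steps, excluding the
# zero-step layer (a start node is returned only if re-reached).
reach_set <- function(adj, start, depth) {
  visited <- character(0)
  frontier <- start
  d <- 0
  out <- character(0)
  while (length(frontier) > 0 && d < depth) {
    nxt <- unique(unlist(adj[frontier], use.names = FALSE))
    out <- union(out, nxt)
    frontier <- setdiff(nxt, visited)
    visited <- union(visited, frontier)
    d <- d + 1
  }
  out
}

#' Regulators of a gene group
#'
#' Direct mode returns the union of in-neighbours of the members in the
#' network; indirect mode returns every gene from which a member can be
#' reached within `depth` steps (direct regulators included). A member
#' that regulates another member is part of the result.
#'
#' @param group A [gene_group()].
#' @param network A `gene_network`.
#' @param mode `"direct"` or `"indirect"` (direct + indirect).
#' @param depth Step bound for indirect mode (`Inf` = unbounded).
#' @return A `gene_group` of regulator genes.
#' @export
regulators_of <- function(group, network, mode = c("direct", "indirect"),
                          depth = Inf) {
  stopifnot(inherits(group, "gene_group"), inherits(network, "gene_network"))
  mode <- match.arg(mode)
  members <- warn_absent(group, network$nodes, "network")
  adj <- adjacency_list(network, "in")
  d <- if (mode == "direct") 1 else depth
  group_derive(reach_set(adj, members, d), group,
               paste0("regulators_of[", mode, ",depth=", d, "]"))
}

#' Regulatees of a gene group
#'
#' Mirror image of [regulators_of()]: forward reachability toward
#' regulated genes.
#'
#' @inheritParams regulators_of
#' @return A `gene_group` of regulated genes.
#' @export
regulatees_of <- function(group, network, mode = c("direct", "indirect"),
                          depth = Inf) {
  stopifnot(inherits(group, "gene_group"), inherits(network, "gene_network"))
  mode <- match.arg(mode)
  members <- warn_absent(group, network$nodes, "network")
  adj <- adjacency_list(network, "out")
  d <- if (mode == "direct") 1 else depth
  group_derive(reach_set(adj, members, d), group,
               paste0("regulatees_of[", mode, ",depth=", d, "]"))
}

#' Expand a gene group to whole operons
#'
#' Adds, for every member, all genes of every transcription unit that
#' contains the member. Genes in no TU are kept unchanged.
#'
#' @param group A [gene_group()].
#' @param model A [regulatory_model()].
#' @return A `gene_group`.
#' @export
expand_to_operons <- function(group, model) {
  stopifnot(inherits(group, "gene_group"), inherits(model, "regulatory_model"))
  g2t <- model$index$tus_by_gene
  extra <- unlist(lapply(group$members, function(g) {
    tus <- g2t[[g]]
    unlist(lapply(tus, function(tid) {
      entity_record(model, "transcription_units", tid)$gene_ids[[1]]
    }), use.names = FALSE)
  }), use.names = FALSE)
  group_derive(union(group$members, extra), group, "expand_to_operons")
}

#' Combine two gene groups
#'
#' Standard set algebra on group members; the history records both
#' operand names and the operation.
#'
#' @param a,b [gene_group()] objects over the same model.
#' @param op `"union"`, `"intersection"` or `"difference"` (a minus b).
#' @return A `gene_group`.
#' @export
combine_groups <- function(a, b, op = c("union", "intersection",
                                        "difference")) {
  stopifnot(inherits(a, "gene_group"), inherits(b, "gene_group"))
  op <- match.arg(op)
  members <- switch(op,
    union = union(a$members, b$members),
    intersection = intersect(a$members, b$members),
    difference = setdiff(a$members, b$members))
  gene_group(members, name = paste0(a$name, "_", op, "_", b$name),
             history = c(a$history, paste0(op, "(", a$name, ", ", b$name, ")")))
}

#' Transform a gene group to the products it encodes
#'
#' Returns the polypeptide/RNA products encoded by the member genes; with
#' `include_complexes = TRUE`, also every complex or modified form whose
#' component/unmodified-form closure contains such a product.
#'
#' @param group A [gene_group()].
#' @param model A [regulatory_model()].
#' @param include_complexes Include complexes and modified forms built
#'   from the direct products.
#' @return Sorted character vector of product ids.
#' @export
genes_to_products <- function(group, model, include_complexes = FALSE) {
  stopifnot(inherits(group, "gene_group"), inherits(model, "regulatory_model"))
  pd <- model$products
  direct <- pd$id[pd$kind %in% c("polypeptide", "rna") &
                    vapply(pd$gene_ids, function(g)
                      any(g %in% group$members), logical(1))]
  if (!include_complexes) return(sort(direct))
  out <- direct
  repeat {
    grow <- pd$id[!pd$id %in% out &
                    (vapply(pd$component_ids, function(cc)
                      any(cc %in% out), logical(1)) |
                       (!is.na(pd$unmodified_form_id) &
                          pd$unmodified_form_id %in% out))]
    if (length(grow) == 0) break
    out <- c(out, grow)
  }
  sort(out)
}

# enzyme-activity regulations targeting a product or a reaction
enzyme_regs_for <- function(model, physiological_only = FALSE) {
  rg <- model$regulations
  sel <- rg$reg_class %in% "regulation-of-enzyme-activity"
  if (physiological_only) {
    sel <- sel & !is.na(rg$physiologically_relevant) &
      rg$physiologically_relevant
  }
  rg[sel, ]
}

#' Substrate-level modulators of a set of products
#'
#' For the given products, collects the substrate-level activators and
#' inhibitors from enzyme-modulation regulations whose regulated entity is
#' the product itself or a reaction it catalyses (dual-mode interactions
#' count on both sides), and the ligands from the products' `ligand_ids`.
#'
#' @param products Character vector of product ids.
#' @param model A [regulatory_model()].
#' @param physiological_only If `TRUE`, only interactions flagged
#'   physiologically relevant are used.
#' @return Named list of sorted entity-id vectors: `activators`,
#'   `inhibitors`, `ligands`.
#' @export
modulators_of <- function(products, model, physiological_only = FALSE) {
  stopifnot(inherits(model, "regulatory_model"))
  rg <- enzyme_regs_for(model, physiological_only)
  rx <- model$reactions
  catalysed <- rx$id[vapply(rx$enzyme_ids, function(e)
    any(e %in% products), logical(1))]
  targets <- c(products, catalysed)
  hits <- rg[rg$regulated_entity_id %in% targets, ]
  act <- hits$regulator_id[hits$mode %in% c("+", "dual")]
  inh <- hits$regulator_id[hits$mode %in% c("-", "dual")]
  pd <- model$products
  lig <- unlist(pd$ligand_ids[pd$id %in% products], use.names = FALSE)
  list(activators = sort(unique(act)),
       inhibitors = sort(unique(inh)),
       ligands = sort(unique(lig)))
}

# does the component closure of product `pid` contain any of `compounds`?
closure_contains_compound <- function(model, pid, compounds,
                                      seen = character(0)) {
  if (pid %in% seen) return(FALSE)
  p <- entity_record(model, "products", pid)
  if (is.null(p)) return(FALSE)
  seen <- c(seen, pid)
  comps <- c(p$component_ids[[1]], p$unmodified_form_id)
  comps <- comps[!is.na(comps)]
  for (cid in comps) {
    if (cid %in% compounds) return(TRUE)
    if (identical(entity_kind(model, cid), "product") &&
        closure_contains_compound(model, cid, compounds, seen)) return(TRUE)
  }
  FALSE
}

#' Entities regulated or bound by a set of compounds
#'
#' For a group of metabolites: which enzymes do they activate or inhibit
#' (targets of enzyme-modulation regulations with a member compound as
#' regulator; reaction targets resolve to the reaction's enzymes), and
#' which proteins bind them (products listing a member among their
#' `ligand_ids`, plus regulator complexes whose component closure contains
#' a member compound).
#'
#' @param compounds Character vector of compound ids.
#' @param model A [regulatory_model()].
#' @return Named list of sorted entity-id vectors: `enzymes_activated`,
#'   `enzymes_inhibited`, `proteins_bound`.
#' @export
entities_regulated_by_compounds <- function(compounds, model) {
  stopifnot(inherits(model, "regulatory_model"))
  rg <- enzyme_regs_for(model)
  hits <- rg[rg$regulator_id %in% compounds, ]
  resolve_enzymes <- function(ids) {
    out <- character(0)
    for (tgt in ids) {
      k <- entity_kind(model, tgt)
      if (identical(k, "product")) out <- c(out, tgt)
      else if (identical(k, "reaction")) {
        out <- c(out, entity_record(model, "reactions", tgt)$enzyme_ids[[1]])
      }
    }
    out
  }
  act <- resolve_enzymes(hits$regulated_entity_id[hits$mode %in% c("+", "dual")])
  inh <- resolve_enzymes(hits$regulated_entity_id[hits$mode %in% c("-", "dual")])

  pd <- model$products
  bound <- pd$id[vapply(pd$ligand_ids, function(l)
    any(l %in% compounds), logical(1))]
  all_regulators <- unique(model$regulations$regulator_id)
  complex_regs <- all_regulators[all_regulators %in% pd$id]
  bound <- c(bound, complex_regs[vapply(complex_regs, function(pid)
    closure_contains_compound(model, pid, compounds), logical(1))])

  list(enzymes_activated = sort(unique(act)),
       enzymes_inhibited = sort(unique(inh)),
       proteins_bound = sort(unique(bound)))
}

#' Read a gene-list file into a gene group
#'
#' One gene id per line; blank lines and `#` comments are ignored.
#'
#' @param path Path to the gene-list file.
#' @param name Group name (defaults to the file name).
#' @return A `gene_group`.
#' @export
read_gene_group <- function(path, name = basename(path)) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  gene_group(lines[nzchar(lines)], name = name)
}
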
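# Referential and structural validation. Violations are data, not errors.

# Compatibility of regulation class with the kind of its regulated entity.
REG_CLASS_TARGETS <- list(
  "transcription-factor-binding" = "promoter",
  "allosteric-regulation-of-rnap" = "promoter",
  "transcriptional-attenuation" = "terminator",
  "regulation-of-translation" = c("tu", "gene"),
  "regulation-of-enzyme-activity" = c("reaction", "product")
)

#' Validate a regulatory model
#'
#' Checks every structural invariant of the data model: id uniqueness
#' (within each table and across the whole model, so entity references are
#' unambiguous), referential integrity of every id-valued field, per-type
#' rules (TU gene lists non-empty and duplicate-free, promoter/TU
#' back-links, terminator `site_index` within its TU, product-kind rules
#' and acyclic complex composition, non-empty reaction sides), regulation
#' mode/class vocabulary, and compatibility of each regulation class with
#' the kind of entity it regulates (e.g. attenuation must target a
#' terminator). The reserved protein-degradation regulation class is
#' reported as unsupported.
#'
#' @param model A [regulatory_model()].
#' @return A tibble with columns `entity_id`, `rule`, `detail`, one row per
#'   violation; zero rows iff the model is valid.
#' @export
validate_model <- function(model) {
  stopifnot(inherits(model, "regulatory_model"))
  errs <- list()
  bad <- function(entity_id, rule, detail) {
    errs[[length(errs) + 1L]] <<- tibble::tibble(
      entity_id = entity_id, rule = rule, detail = detail)
  }
  kind_of <- function(id) entity_kind(model, id)

  # -- id uniqueness, per table and globally
  all_ids <- character(0)
  for (tbl in MODEL_TABLES) {
    ids <- model[[tbl]]$id
    dup <- unique(ids[duplicated(ids)])
    for (d in dup) bad(d, "duplicate-id", paste0("id duplicated in ", tbl))
    all_ids <- c(all_ids, unique(ids))
  }
  gdup <- unique(all_ids[duplicated(all_ids)])
  for (d in gdup) bad(d, "duplicate-id", "id used by more than one entity kind")

  check_ref <- function(owner, ref, expect_kind, field) {
    if (is.na(ref)) return(invisible())
    k <- kind_of(ref)
    if (is.na(k)) {
      bad(owner, "unresolved-reference",
          paste0(field, " '", ref, "' does not resolve"))
    } else if (!k %in% expect_kind) {
      bad(owner, "wrong-reference-kind",
          paste0(field, " '", ref, "' is a ", k, ", expected ",
                 paste(expect_kind, collapse = "/")))
    }
    invisible()
  }
  check_refs <- function(owner, refs, expect_kind, field) {
    for (r in refs) check_ref(owner, r, expect_kind, field)
  }

  # -- genes
  g <- model$genes
  for (i in seq_len(nrow(g))) {
    check_ref(g$id[i], g$product_id[i], "product", "product_id")
  }

  # -- transcription units
  tus <- model$transcription_units
  for (i in seq_len(nrow(tus))) {
    id <- tus$id[i]
    gids <- tus$gene_ids[[i]]
    if (length(gids) == 0) bad(id, "empty-gene-list", "TU has no genes")
    if (anyDuplicated(gids)) bad(id, "duplicate-genes-in-tu",
                                 "TU gene list contains duplicates")
    check_refs(id, gids, "gene", "gene_ids")
    check_ref(id, tus$promoter_id[i], "promoter", "promoter_id")
    check_refs(id, tus$terminator_ids[[i]], "terminator", "terminator_ids")
  }

  # -- promoters (tu resolves; TU points back)
  pr <- model$promoters
  for (i in seq_len(nrow(pr))) {
    id <- pr$id[i]
    check_ref(id, pr$tu_id[i], "tu", "tu_id")
    tu <- entity_record(model, "transcription_units", pr$tu_id[i])
    if (!is.null(tu) && (is.na(tu$promoter_id) || tu$promoter_id != id)) {
      bad(id, "promoter-tu-backlink",
          paste0("TU '", pr$tu_id[i], "' does not name this promoter"))
    }
    check_ref(id, pr$sigma_factor_id[i], "product", "sigma_factor_id")
  }

  # -- terminators (tu resolves; 0 <= site_index < #genes)
  tm <- model$terminators
  for (i in seq_len(nrow(tm))) {
    id <- tm$id[i]
    check_ref(id, tm$tu_id[i], "tu", "tu_id")
    tu <- entity_record(model, "transcription_units", tm$tu_id[i])
    si <- tm$site_index[i]
    if (is.na(si)) {
      bad(id, "missing-site-index", "terminator lacks site_index")
    } else if (!is.null(tu)) {
      ng <- length(tu$gene_ids[[1]])
      if (si < 0 || si >= ng) {
        bad(id, "site-index-range",
            sprintf("site_index %d outside [0, %d)", si, ng))
      }
    }
  }

  # -- products
  pd <- model$products
  for (i in seq_len(nrow(pd))) {
    id <- pd$id[i]
    kind <- pd$kind[i]
    gids <- pd$gene_ids[[i]]
    comps <- pd$component_ids[[i]]
    if (is.na(kind) || !kind %in% PRODUCT_KINDS) {
      bad(id, "unknown-product-kind", paste0("kind '", kind, "'"))
      next
    }
    check_refs(id, gids, "gene", "gene_ids")
    check_refs(id, comps, c("product", "compound"), "component_ids")
    check_ref(id, pd$unmodified_form_id[i], "product", "unmodified_form_id")
    check_refs(id, pd$ligand_ids[[i]], "compound", "ligand_ids")
    if (kind %in% c("polypeptide", "rna")) {
      if (length(gids) == 0) bad(id, "product-needs-gene",
                                 paste0(kind, " lists no encoding gene"))
      if (length(comps) > 0) bad(id, "product-no-components",
                                 paste0(kind, " may not have components"))
    } else if (kind == "complex") {
      if (length(comps) == 0) bad(id, "complex-needs-components",
                                  "complex lists no components")
    } else if (kind == "modified-form") {
      if (is.na(pd$unmodified_form_id[i])) {
        bad(id, "modified-form-needs-base",
            "modified form lacks unmodified_form_id")
      }
    }
  }
  # component/modified-form graph must be acyclic
  for (cyc in product_graph_cycles(model)) {
    bad(cyc, "cyclic-product-graph",
        "product participates in a component/modified-form cycle")
  }

  # -- compounds: nothing beyond id uniqueness

  # -- reactions
  rx <- model$reactions
  for (i in seq_len(nrow(rx))) {
    id <- rx$id[i]
    if (length(rx$reactant_ids[[i]]) == 0)
      bad(id, "empty-reactants", "reaction has no reactants")
    if (length(rx$product_ids[[i]]) == 0)
      bad(id, "empty-products", "reaction has no products")
    check_refs(id, rx$reactant_ids[[i]], c("product", "compound"), "reactant_ids")
    check_refs(id, rx$product_ids[[i]], c("product", "compound"), "product_ids")
    check_refs(id, rx$enzyme_ids[[i]], "product", "enzyme_ids")
    if (is.na(rx$reversible[i]))
      bad(id, "missing-reversible", "reaction lacks reversible flag")
  }

  # -- regulations
  rg <- model$regulations
  for (i in seq_len(nrow(rg))) {
    id <- rg$id[i]
    cls <- rg$reg_class[i]
    if (identical(cls, REG_CLASS_RESERVED)) {
      bad(id, "unsupported-class",
          "regulation of protein degradation is reserved but unsupported")
      next
    }
    if (is.na(cls) || !cls %in% REG_CLASSES) {
      bad(id, "unknown-class", paste0("reg_class '", cls, "'"))
      next
    }
    if (is.na(rg$mode[i]) || !rg$mode[i] %in% MODES) {
      bad(id, "unknown-mode", paste0("mode '", rg$mode[i], "'"))
    }
    check_ref(id, rg$regulator_id[i], c("product", "compound"), "regulator_id")
    tgt <- rg$regulated_entity_id[i]
    if (is.na(tgt)) {
      bad(id, "unresolved-reference", "regulated_entity_id is missing")
    } else {
      k <- kind_of(tgt)
      if (is.na(k)) {
        bad(id, "unresolved-reference",
            paste0("regulated_entity_id '", tgt, "' does not resolve"))
      } else if (!k %in% REG_CLASS_TARGETS[[cls]]) {
        bad(id, "class-entity-incompatible",
            paste0(cls, " may not regulate a ", k))
      }
    }
  }

  if (length(errs) == 0) {
    tibble::tibble(entity_id = character(0), rule = character(0),
                   detail = character(0))
  } else {
    dplyr::bind_rows(errs)
  }
}

# ids of products on a cycle of component_ids/unmodified_form_id links
product_graph_cycles <- function(model) {
  pd <- model$products
  if (nrow(pd) == 0) return(character(0))
  edges <- list()
  for (i in seq_len(nrow(pd))) {
    to <- c(pd$component_ids[[i]], pd$unmodified_form_id[i])
    to <- to[!is.na(to)]
    to <- to[to %in% pd$id]  # compound components cannot cycle
    if (length(to)) edges[[length(edges) + 1L]] <-
        cbind(rep(pd$id[i], length(to)), to)
  }
  if (length(edges) == 0) return(character(0))
  em <- do.call(rbind, edges)
  gr <- igraph::graph_from_edgelist(em, directed = TRUE)
  comp <- igraph::components(gr, mode = "strong")
  cyc_comps <- which(comp$csize > 1)
  out <- names(comp$membership)[comp$membership %in% cyc_comps]
  # self-loops are cycles too
  loops <- em[em[, 1] == em[, 2], 1]
  sort(unique(c(out, loops)))
}
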
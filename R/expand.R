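# Expansion semantics: from a regulation record to the genes it touches.

#' Genes affected by a regulatory interaction
#'
#' Expands the regulated entity of one regulation to gene level. Regulation
#' of a promoter affects every gene of the promoter's transcription unit
#' (in TU order, promoter-proximal first); regulation of a terminator
#' (attenuation) affects only the genes downstream of the terminator, i.e.
#' those with 1-based position greater than the terminator's `site_index`;
#' regulation of a TU affects all of its genes; regulation of a single gene
#' affects that gene; regulation of a reaction or of a product (enzyme
#' modulation) expands to no genes.
#'
#' @param model A [regulatory_model()].
#' @param regulation_id Id of a regulation in `model`.
#' @return Character vector of gene ids (possibly empty), in TU order where
#'   a TU is involved.
#' @seealso [regulator_genes()]
#' @export
regulated_genes <- function(model, regulation_id) {
  reg <- entity_record(model, "regulations", regulation_id)
  if (is.null(reg)) {
    stop("unknown regulation id '", regulation_id, "'", call. = FALSE)
  }
  expand_regulated_entity(model, reg$regulated_entity_id)
}

expand_regulated_entity <- function(model, target_id) {
  kind <- entity_kind(model, target_id)
  if (is.na(kind)) {
    stop("regulated entity '", target_id, "' does not resolve", call. = FALSE)
  }
  switch(kind,
    gene = target_id,
    tu = {
      tu <- entity_record(model, "transcription_units", target_id)
      tu$gene_ids[[1]]
    },
    promoter = {
      p <- entity_record(model, "promoters", target_id)
      tu <- entity_record(model, "transcription_units", p$tu_id)
      if (is.null(tu)) stop("promoter '", target_id, "' has unresolved TU",
                            call. = FALSE)
      tu$gene_ids[[1]]
    },
    terminator = {
      t <- entity_record(model, "terminators", target_id)
      tu <- entity_record(model, "transcription_units", t$tu_id)
      if (is.null(tu)) stop("terminator '", target_id, "' has unresolved TU",
                            call. = FALSE)
      gids <- tu$gene_ids[[1]]
      if (t$site_index >= length(gids)) character(0)
      else gids[seq_along(gids) > t$site_index]
    },
    reaction = character(0),
    product = character(0),
    stop("entity '", target_id, "' (", kind,
         ") cannot be a regulated entity", call. = FALSE)
  )
}

#' Genes encoding the regulator of a regulatory interaction
#'
#' Recursively resolves the regulator entity to the genes that encode it:
#' a polypeptide or RNA product contributes its encoding genes; a modified
#' form contributes the genes of its unmodified form; a complex contributes
#' the union over its product components (small-molecule components
#' contribute nothing); a free compound (e.g. a riboswitch ligand)
#' contributes no genes. The result is sorted and duplicate-free.
#'
#' @inheritParams regulated_genes
#' @return Sorted character vector of gene ids (possibly empty).
#' @export
regulator_genes <- function(model, regulation_id) {
  reg <- entity_record(model, "regulations", regulation_id)
  if (is.null(reg)) {
    stop("unknown regulation id '", regulation_id, "'", call. = FALSE)
  }
  entity_genes(model, reg$regulator_id)
}

# Recursive gene resolution for any entity id (product/compound/gene).
entity_genes <- function(model, entity_id, seen = character(0)) {
  if (is.na(entity_id)) return(character(0))
  if (entity_id %in% seen) {
    stop("cyclic product composition at '", entity_id, "'", call. = FALSE)
  }
  kind <- entity_kind(model, entity_id)
  if (is.na(kind)) {
    stop("regulator entity '", entity_id, "' does not resolve", call. = FALSE)
  }
  if (kind == "gene") return(entity_id)
  if (kind == "compound") return(character(0))
  if (kind != "product") {
    stop("entity '", entity_id, "' (", kind, ") cannot act as a regulator",
         call. = FALSE)
  }
  p <- entity_record(model, "products", entity_id)
  seen <- c(seen, entity_id)
  out <- switch(p$kind,
    polypeptide = p$gene_ids[[1]],
    rna = p$gene_ids[[1]],
    "modified-form" = entity_genes(model, p$unmodified_form_id, seen),
    complex = {
      comps <- p$component_ids[[1]]
      unlist(lapply(comps, function(cid) {
        if (identical(entity_kind(model, cid), "product")) {
          entity_genes(model, cid, seen)
        } else character(0)
      }), use.names = FALSE)
    },
    character(0)
  )
  sort(unique(out))
}

# Classify a regulator entity as protein / rna / small-molecule.
# Modified forms classify via their base form; complexes via components
# (any polypeptide -> protein; else any rna -> rna; else protein).
entity_class3 <- function(model, entity_id, seen = character(0)) {
  kind <- entity_kind(model, entity_id)
  if (is.na(kind)) return(NA_character_)
  if (kind == "compound") return("small-molecule")
  if (kind == "gene") return("protein")
  if (kind != "product") return(NA_character_)
  if (entity_id %in% seen) return(NA_character_)
  p <- entity_record(model, "products", entity_id)
  seen <- c(seen, entity_id)
  switch(p$kind,
    polypeptide = "protein",
    rna = "rna",
    "modified-form" = entity_class3(model, p$unmodified_form_id, seen),
    complex = {
      cls <- vapply(p$component_ids[[1]], function(cid)
        entity_class3(model, cid, seen), character(1))
      if (any(cls == "protein", na.rm = TRUE)) "protein"
      else if (any(cls == "rna", na.rm = TRUE)) "rna"
      else "protein"
    },
    NA_character_
  )
}

# Genes whose product serves as the sigma factor of at least one promoter.
sigma_factor_genes <- function(model) {
  sf <- model$promoters$sigma_factor_id
  sf <- unique(sf[!is.na(sf)])
  out <- unlist(lapply(sf, function(id) entity_genes(model, id)),
                use.names = FALSE)
  sort(unique(out))
}
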
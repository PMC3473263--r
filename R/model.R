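# Regulatory model container: eight entity tables plus lookup indices.

REG_CLASSES <- c(
  "transcription-factor-binding",
  "allosteric-regulation-of-rnap",
  "transcriptional-attenuation",
  "regulation-of-translation",
  "regulation-of-enzyme-activity"
)

# Reserved but unsupported: validate_model() flags it rather than erroring.
REG_CLASS_RESERVED <- "regulation-of-protein-degradation"

TRANSCRIPTIONAL_CLASSES <- c(
  "transcription-factor-binding",
  "allosteric-regulation-of-rnap",
  "transcriptional-attenuation"
)

MODES <- c("+", "-", "dual", "unknown")

PRODUCT_KINDS <- c("polypeptide", "rna", "complex", "modified-form")

# column-name -> type tag ("chr", "int", "lgl", "list") per table
model_table_spec <- function() {
  list(
    genes = c(id = "chr", name = "chr", product_id = "chr"),
    transcription_units = c(id = "chr", gene_ids = "list", promoter_id = "chr",
                            terminator_ids = "list"),
    promoters = c(id = "chr", tu_id = "chr", sigma_factor_id = "chr"),
    terminators = c(id = "chr", tu_id = "chr", site_index = "int"),
    products = c(id = "chr", kind = "chr", gene_ids = "list",
                 component_ids = "list", unmodified_form_id = "chr",
                 ligand_ids = "list"),
    compounds = c(id = "chr", name = "chr"),
    reactions = c(id = "chr", reactant_ids = "list", product_ids = "list",
                  enzyme_ids = "list", reversible = "lgl"),
    regulations = c(id = "chr", reg_class = "chr", sub_class = "chr",
                    mechanism = "chr", regulator_id = "chr",
                    regulated_entity_id = "chr", mode = "chr",
                    physiologically_relevant = "lgl",
                    binding_site_position = "int",
                    binding_site_description = "chr")
  )
}

empty_col <- function(type, n = 0L) {
  switch(type,
    chr  = rep(NA_character_, n),
    int  = rep(NA_integer_, n),
    lgl  = rep(NA, n),
    list = rep(list(character(0)), n),
    stop("unknown column type: ", type)
  )
}

normalise_table <- function(df, spec, table_name) {
  if (is.null(df)) df <- tibble::tibble()
  df <- tibble::as_tibble(df)
  n <- nrow(df)
  out <- tibble::tibble(.rows = n)
  for (col in names(spec)) {
    type <- spec[[col]]
    if (col %in% names(df)) {
      v <- df[[col]]
      v <- switch(type,
        chr = as.character(v),
        int = as.integer(v),
        lgl = as.logical(v),
        list = {
          if (!is.list(v)) v <- as.list(v)
          v <- unname(v)
          lapply(v, function(x) {
            if (is.null(x) || length(x) == 0) character(0) else as.character(x)
          })
        }
      )
    } else {
      v <- empty_col(type, n)
    }
    out[[col]] <- v
  }
  if (n > 0 && anyNA(out$id)) {
    stop("table '", table_name, "' contains a missing id", call. = FALSE)
  }
  # canonical row order: sorted by id (ties keep input order)
  out[order(out$id), , drop = FALSE]
}

#' Assemble a regulatory model from entity tables
#'
#' A `regulatory_model` holds eight tibbles describing a bacterial
#' regulation dataset: genes, transcription units (TUs), promoters,
#' terminators, gene products (polypeptides, RNAs, complexes, modified
#' forms), small-molecule compounds, metabolic reactions, and the
#' regulatory interactions (`regulations`) linking them. Missing optional
#' columns are filled with `NA` / empty lists; multi-valued columns
#' (`gene_ids`, `component_ids`, ...) are list-columns of character
#' vectors. Lookup indices are built eagerly so downstream operations can
#' resolve ids in constant time.
#'
#' The constructor does not check referential integrity; run
#' [validate_model()] for that. Regulation `mode` uses the vocabulary
#' `"+"` (activation), `"-"` (inhibition), `"dual"`, `"unknown"`.
#'
#' @param genes,transcription_units,promoters,terminators,products,compounds,reactions,regulations
#'   Data frames (or `NULL` for empty) with the columns documented in the
#'   package vignette; only `id` is mandatory per table.
#' @param id Optional model identifier used in exports.
#' @return An object of class `regulatory_model`.
#' @export
regulatory_model <- function(genes = NULL, transcription_units = NULL,
                             promoters = NULL, terminators = NULL,
                             products = NULL, compounds = NULL,
                             reactions = NULL, regulations = NULL,
                             id = "model") {
  spec <- model_table_spec()
  m <- list(
    id = as.character(id),
    genes = normalise_table(genes, spec$genes, "genes"),
    transcription_units = normalise_table(transcription_units,
                                          spec$transcription_units,
                                          "transcription_units"),
    promoters = normalise_table(promoters, spec$promoters, "promoters"),
    terminators = normalise_table(terminators, spec$terminators, "terminators"),
    products = normalise_table(products, spec$products, "products"),
    compounds = normalise_table(compounds, spec$compounds, "compounds"),
    reactions = normalise_table(reactions, spec$reactions, "reactions"),
    regulations = normalise_table(regulations, spec$regulations, "regulations")
  )
  class(m) <- "regulatory_model"
  rebuild_indices(m)
}

MODEL_TABLES <- c("genes", "transcription_units", "promoters", "terminators",
                  "products", "compounds", "reactions", "regulations")

ENTITY_KIND <- c(genes = "gene", transcription_units = "tu",
                 promoters = "promoter", terminators = "terminator",
                 products = "product", compounds = "compound",
                 reactions = "reaction", regulations = "regulation")

rebuild_indices <- function(model) {
  idx <- new.env(parent = emptyenv())
  kind <- character(0)
  for (tbl in MODEL_TABLES) {
    ids <- model[[tbl]]$id
    rows <- seq_along(ids)
    names(rows) <- ids
    assign(paste0("row_", tbl), rows, envir = idx)
    if (length(ids)) {
      k <- rep(ENTITY_KIND[[tbl]], length(ids))
      names(k) <- ids
      kind <- c(kind, k)
    }
  }
  assign("kind", kind, envir = idx)

  # gene -> TU ids (a gene may sit in several TUs)
  tus <- model$transcription_units
  g2t <- list()
  if (nrow(tus)) {
    pairs <- tibble::tibble(
      tu = rep(tus$id, lengths(tus$gene_ids)),
      gene = unlist(tus$gene_ids, use.names = FALSE)
    )
    g2t <- split(pairs$tu, pairs$gene)
  }
  assign("tus_by_gene", g2t, envir = idx)

  # regulator entity -> regulation ids
  regs <- model$regulations
  r2r <- if (nrow(regs)) split(regs$id, regs$regulator_id) else list()
  assign("regs_by_regulator", r2r, envir = idx)

  # compound -> reaction ids in which it participates (reactant or product)
  rxns <- model$reactions
  c2r <- list()
  if (nrow(rxns)) {
    part <- lapply(seq_len(nrow(rxns)), function(i) {
      unique(c(rxns$reactant_ids[[i]], rxns$product_ids[[i]]))
    })
    pairs <- tibble::tibble(
      rxn = rep(rxns$id, lengths(part)),
      ent = unlist(part, use.names = FALSE)
    )
    c2r <- split(pairs$rxn, pairs$ent)
  }
  assign("rxns_by_participant", c2r, envir = idx)

  model$index <- idx
  model
}

entity_kind <- function(model, id) {
  unname(model$index$kind[id])
}

entity_row <- function(model, table, id) {
  r <- get(paste0("row_", table), envir = model$index)[id]
  unname(r)
}

# Fetch a one-row tibble for an id known to live in `table`; NULL if absent.
entity_record <- function(model, table, id) {
  r <- entity_row(model, table, id)
  if (is.na(r)) return(NULL)
  model[[table]][r, ]
}

#' @export
print.regulatory_model <- function(x, ...) {
  cat("<regulatory_model '", x$id, "'>\n", sep = "")
  for (tbl in MODEL_TABLES) {
    cat(sprintf("  %-20s %d\n", tbl, nrow(x[[tbl]])))
  }
  invisible(x)
}

#' @export
format.regulatory_model <- function(x, ...) {
  paste0("<regulatory_model '", x$id, "': ", nrow(x$genes), " genes, ",
         nrow(x$regulations), " regulations>")
}
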
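# Content statistics over a model, one row per reporting category.

STAT_CATEGORIES <- c(
  "transcriptional_regulation",
  "transcription_factor_binding",
  "allosteric_regulation_of_rnap",
  "attenuation",
  "translational_regulation",
  "translational_protein_mediated",
  "translational_rna_mediated",
  "translational_compound_mediated",
  "enzyme_modulation",
  "enzyme_modulation_physiological",
  "genes_with_regulator",
  "percent_of_genome",
  "regulators",
  "regulators_protein",
  "regulators_rna",
  "regulators_small_molecule",
  "enzymes_modulated",
  "enzymes_modulated_physiological",
  "enzyme_modulators",
  "enzyme_modulators_physiological"
)

#' Summarise regulation content of a model
#'
#' Computes the standard per-organism content statistics: regulation
#' counts per class (transcription-factor binding, allosteric regulation
#' of RNA polymerase, attenuation; translational regulation split by
#' protein-, RNA- and small-molecule-mediated mechanisms; enzyme
#' modulation with its physiologically-relevant subset), the number and
#' genome percentage of genes with at least one transcriptional or
#' translational regulator (computed through the gene-level expansion of
#' every such regulation, see [regulated_genes()]), distinct
#' transcriptional/translational regulator entities split into proteins,
#' RNAs and small molecules, and the numbers of enzymes subject to
#' substrate-level modulation and of distinct enzyme modulators, each with
#' a physiologically-relevant subset.
#'
#' @param model A valid [regulatory_model()].
#' @param physiological_only If `TRUE`, enzyme-modulation tallies count
#'   only interactions flagged physiologically relevant.
#' @return A tibble with columns `category` and `value`
#'   (`percent_of_genome` is a percentage; all other rows are counts).
#' @export
model_stats <- function(model, physiological_only = FALSE) {
  stopifnot(inherits(model, "regulatory_model"))
  rg <- model$regulations
  val <- stats::setNames(numeric(length(STAT_CATEGORIES)), STAT_CATEGORIES)

  n_class <- function(cls) sum(rg$reg_class %in% cls)
  val["transcription_factor_binding"] <- n_class("transcription-factor-binding")
  val["allosteric_regulation_of_rnap"] <- n_class("allosteric-regulation-of-rnap")
  val["attenuation"] <- n_class("transcriptional-attenuation")
  val["transcriptional_regulation"] <- n_class(TRANSCRIPTIONAL_CLASSES)
  val["translational_regulation"] <- n_class("regulation-of-translation")

  is_trans <- rg$reg_class %in% "regulation-of-translation"
  val["translational_protein_mediated"] <-
    sum(is_trans & rg$sub_class %in% "protein-mediated")
  val["translational_rna_mediated"] <-
    sum(is_trans & rg$sub_class %in% "rna-mediated")
  val["translational_compound_mediated"] <-
    sum(is_trans & rg$sub_class %in% "compound-mediated")

  is_enz <- rg$reg_class %in% "regulation-of-enzyme-activity"
  is_phys <- is_enz & !is.na(rg$physiologically_relevant) &
    rg$physiologically_relevant
  enz_sel <- if (physiological_only) is_phys else is_enz
  val["enzyme_modulation"] <- sum(enz_sel)
  val["enzyme_modulation_physiological"] <- sum(is_phys)

  # gene coverage through expansion of expression-level regulations
  is_expr <- rg$reg_class %in% c(TRANSCRIPTIONAL_CLASSES,
                                 "regulation-of-translation")
  covered <- character(0)
  for (id in rg$id[is_expr]) {
    covered <- c(covered, regulated_genes(model, id))
  }
  covered <- unique(covered)
  val["genes_with_regulator"] <- length(covered)
  n_genes <- nrow(model$genes)
  val["percent_of_genome"] <-
    if (n_genes > 0) 100 * length(covered) / n_genes else 0

  # distinct expression-level regulator entities, typed
  regulators <- unique(rg$regulator_id[is_expr])
  cls3 <- vapply(regulators, function(id) entity_class3(model, id),
                 character(1))
  val["regulators"] <- length(regulators)
  val["regulators_protein"] <- sum(cls3 %in% "protein")
  val["regulators_rna"] <- sum(cls3 %in% "rna")
  val["regulators_small_molecule"] <- sum(cls3 %in% "small-molecule")

  # enzymes subject to modulation; regulated entity may be the enzyme
  # product itself or a reaction it catalyses
  modulated_enzymes <- function(sel) {
    out <- character(0)
    for (i in which(sel)) {
      tgt <- rg$regulated_entity_id[i]
      k <- entity_kind(model, tgt)
      if (identical(k, "product")) {
        out <- c(out, tgt)
      } else if (identical(k, "reaction")) {
        rx <- entity_record(model, "reactions", tgt)
        out <- c(out, rx$enzyme_ids[[1]])
      }
    }
    unique(out)
  }
  val["enzymes_modulated"] <- length(modulated_enzymes(enz_sel))
  val["enzymes_modulated_physiological"] <- length(modulated_enzymes(is_phys))
  val["enzyme_modulators"] <- length(unique(rg$regulator_id[enz_sel]))
  val["enzyme_modulators_physiological"] <-
    length(unique(rg$regulator_id[is_phys]))

  out <- tibble::tibble(category = STAT_CATEGORIES, value = unname(val))
  attr(out, "n_genes") <- n_genes
  attr(out, "physiological_only") <- physiological_only
  out
}
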
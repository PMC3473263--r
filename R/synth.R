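# Seeded generator of synthetic regulatory models with a ground-truth
# ledger, so every analysis is testable without external data.

#' Parameters for the synthetic-model generator
#'
#' Defaults describe a small bacterium-like model: operon sizes follow a
#' geometric distribution (mean 1.7 genes), about 5% of genes encode
#' transcription factors and 0.5% sigma factors, each TF regulates a
#' Poisson number of promoters (mean 5), activation and inhibition are
#' equally common (45% each) with a little dual (3%) and unknown-mode
#' regulation, attenuation and translational regulation are added as
#' fractions (5% / 8%) of the transcription-factor interaction count, and
#' a small metabolic layer (compounds, irreversible/reversible reactions,
#' enzyme modulations with an 80% physiologically-relevant rate) plus one
#' deliberately hub-like compound exercise the reaction-derived analyses.
#'
#' @param n_genes Number of genes.
#' @param n_tfs,n_sigma Numbers of transcription-factor and sigma-factor
#'   genes (`n_tfs + n_sigma <= n_genes`).
#' @param n_srna Number of small-RNA regulator genes.
#' @param operon_size_mean Mean of the geometric operon-size distribution
#'   (minimum size 1).
#' @param targets_per_tf_mean Mean promoters targeted per TF (Poisson,
#'   minimum 1).
#' @param p_activation,p_inhibition,p_dual Regulation mode probabilities
#'   (remainder: unknown mode).
#' @param f_attenuation,f_translational Attenuation / translational
#'   interaction counts as fractions of the TF interaction count.
#' @param n_compounds,n_reactions,f_reversible,n_enzyme_modulations,f_physiological
#'   Metabolic layer sizes and rates.
#' @param hub_compound_count,hub_degree Number of hub compounds and the
#'   exact number of reactions each is wired into (requires
#'   `n_reactions >= hub_degree`).
#' @return A `synth_params` list, validated.
#' @export
synth_params <- function(n_genes = 200L,
                         n_tfs = max(1L, round(0.05 * n_genes)),
                         n_sigma = max(1L, round(0.005 * n_genes)),
                         n_srna = max(1L, round(0.01 * n_genes)),
                         operon_size_mean = 1.7,
                         targets_per_tf_mean = 5,
                         p_activation = 0.45, p_inhibition = 0.45,
                         p_dual = 0.03,
                         f_attenuation = 0.05, f_translational = 0.08,
                         n_compounds = max(4L, round(0.15 * n_genes)),
                         n_reactions = max(2L, round(0.12 * n_genes)),
                         f_reversible = 0.3,
                         n_enzyme_modulations = max(1L,
                                                    round(0.08 * n_genes)),
                         f_physiological = 0.8,
                         hub_compound_count = 1L, hub_degree = 12L) {
  p <- list(n_genes = as.integer(n_genes), n_tfs = as.integer(n_tfs),
            n_sigma = as.integer(n_sigma), n_srna = as.integer(n_srna),
            operon_size_mean = operon_size_mean,
            targets_per_tf_mean = targets_per_tf_mean,
            p_activation = p_activation, p_inhibition = p_inhibition,
            p_dual = p_dual, f_attenuation = f_attenuation,
            f_translational = f_translational,
            n_compounds = as.integer(n_compounds),
            n_reactions = as.integer(n_reactions),
            f_reversible = f_reversible,
            n_enzyme_modulations = as.integer(n_enzyme_modulations),
            f_physiological = f_physiological,
            hub_compound_count = as.integer(hub_compound_count),
            hub_degree = as.integer(hub_degree))
  fr <- c(p$p_activation, p$p_inhibition, p$p_dual, p$f_attenuation,
          p$f_translational, p$f_reversible, p$f_physiological)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]",
                                 call. = FALSE)
  if (p$p_activation + p$p_inhibition + p$p_dual > 1) {
    stop("mode probabilities must sum to at most 1", call. = FALSE)
  }
  if (p$n_genes < 1) stop("n_genes must be positive", call. = FALSE)
  if (p$n_tfs + p$n_sigma + p$n_srna > p$n_genes) {
    stop("n_tfs + n_sigma + n_srna exceeds n_genes", call. = FALSE)
  }
  if (p$operon_size_mean < 1 || p$operon_size_mean > p$n_genes) {
    stop("operon_size_mean must lie in [1, n_genes]", call. = FALSE)
  }
  if (p$hub_compound_count > 0 && p$hub_degree > p$n_reactions) {
    stop("hub_degree exceeds n_reactions; hub compounds cannot be wired",
         call. = FALSE)
  }
  if (p$n_reactions > 0 && p$n_compounds < 4) {
    stop("need at least 4 compounds to wire reactions", call. = FALSE)
  }
  structure(p, class = "synth_params")
}

# deterministic per-phase RNG substream derived from the master seed, so
# adding a generation phase never perturbs earlier ones
substream_seed <- function(master, name) {
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 31 + ch) %% 2147483647
  ((master %% 2147483647) * 69069 + h) %% 2147483647
}

with_substream <- function(master, name, expr) {
  set.seed(substream_seed(master, name), kind = "Mersenne-Twister",
           sample.kind = "Rejection")
  expr
}

pad_id <- function(prefix, i, n) {
  sprintf("%s%0*d", prefix, max(4L, nchar(as.character(n))), i)
}

sample_mode <- function(n, p) {
  sample(MODES, n, replace = TRUE,
         prob = c(p$p_activation, p$p_inhibition, p$p_dual,
                  1 - p$p_activation - p$p_inhibition - p$p_dual))
}

#' Generate a synthetic regulatory model
#'
#' Builds a complete, internally consistent model from a single seed:
#' genes are partitioned into transcription units by the operon-size
#' distribution, every TU gets a promoter with a uniformly assigned sigma
#' factor, transcription factors (some as ligand-bound modified forms or
#' TF-ligand complexes) draw Poisson numbers of target promoters,
#' attenuation interactions create terminators at random internal
#' positions, translational interactions (protein-, small-RNA- and
#' riboswitch-mediated) target TUs or genes, and a metabolic layer wires
#' enzymes and compounds into reactions with substrate-level modulation.
#' All randomness derives from `seed` through named per-phase substreams,
#' so the output is byte-reproducible and stable under generator
#' extensions. Alongside the model, a ground-truth ledger records every
#' quantity the analyses later recompute (per-class counts, per-regulator
#' target-gene lists, per-gene regulator lists, the content-statistics
#' vector, hub compound ids), derived directly from the construction
#' bookkeeping rather than from the model-query functions.
#'
#' @param params A [synth_params()] object.
#' @param seed Master integer seed.
#' @return A list with elements `model` (a [regulatory_model()] that
#'   passes [validate_model()] by construction) and `ledger`.
#' @export
generate_model <- function(params = synth_params(), seed = 1L) {
  stopifnot(inherits(params, "synth_params"))
  p <- params
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }

  genes <- pad_id("g", seq_len(p$n_genes), p$n_genes)

  # --- operon structure
  tu_sizes <- with_substream(seed, "operons", {
    sizes <- integer(0)
    while (sum(sizes) < p$n_genes) {
      draw <- stats::rgeom(64, prob = 1 / p$operon_size_mean) + 1L
      sizes <- c(sizes, draw)
    }
    keep <- which(cumsum(sizes) >= p$n_genes)[1]
    sizes <- sizes[seq_len(keep)]
    sizes[keep] <- sizes[keep] - (sum(sizes) - p$n_genes)
    sizes[sizes > 0]
  })
  n_tus <- length(tu_sizes)
  tu_ids <- pad_id("tu", seq_len(n_tus), n_tus)
  pm_ids <- pad_id("pm", seq_len(n_tus), n_tus)
  tu_genes <- split(genes, rep(seq_len(n_tus), tu_sizes))
  names(tu_genes) <- tu_ids

  # --- roles
  roles <- with_substream(seed, "roles", {
    shuffled <- sample(genes)
    list(sigma = sort(shuffled[seq_len(p$n_sigma)]),
         tf = sort(shuffled[p$n_sigma + seq_len(p$n_tfs)]),
         srna = sort(shuffled[p$n_sigma + p$n_tfs + seq_len(p$n_srna)]))
  })
  product_id <- stats::setNames(paste0("p-", genes), genes)
  product_kind <- stats::setNames(rep("polypeptide", p$n_genes), genes)
  product_kind[roles$srna] <- "rna"

  # --- compounds (metabolites + regulator ligands + hubs)
  cmp_ids <- if (p$n_compounds > 0)
    pad_id("c", seq_len(p$n_compounds), p$n_compounds) else character(0)
  hub_ids <- if (p$hub_compound_count > 0)
    pad_id("hub", seq_len(p$hub_compound_count), p$hub_compound_count)
    else character(0)
  ligand_pool <- new.env(parent = emptyenv())
  ligand_pool$ids <- character(0)
  new_ligand <- function() {
    id <- sprintf("lg%04d", length(ligand_pool$ids) + 1L)
    ligand_pool$ids <- c(ligand_pool$ids, id)
    id
  }

  # --- sigma assignment
  sigma_for_pm <- with_substream(seed, "sigma", {
    sample(roles$sigma, n_tus, replace = TRUE)
  })

  # extra product records (complexes, modified forms) built as we go
  extra_products <- list()
  ledger_reg_class <- character(0)   # regulator entity id -> 3-way class
  reg_entity_genes <- list()         # regulator entity id -> encoding genes

  # --- TF regulator entities
  tf_entities <- with_substream(seed, "tf_entities", {
    stats::setNames(lapply(roles$tf, function(tf) {
      base <- product_id[[tf]]
      u <- stats::runif(1)
      if (u < 0.25) {
        lig <- new_ligand()
        id <- paste0("mf-", base)
        extra_products[[id]] <<- list(id = id, kind = "modified-form",
                                      unmodified_form_id = base,
                                      ligand_ids = lig)
        id
      } else if (u < 0.5) {
        lig <- new_ligand()
        id <- paste0("cx-", base)
        extra_products[[id]] <<- list(id = id, kind = "complex",
                                      component_ids = c(base, lig))
        id
      } else base
    }), roles$tf)
  })
  for (tf in roles$tf) {
    ent <- tf_entities[[tf]]
    ledger_reg_class[ent] <- "protein"
    reg_entity_genes[[ent]] <- tf
  }

  # --- regulation bookkeeping
  regs <- list()
  terms <- list()
  tu_terminators <- stats::setNames(vector("list", n_tus), tu_ids)
  ledger_targets <- list()     # regulation id -> target genes (from TU lists)
  ledger_reg_genes <- list()   # regulation id -> regulator genes
  reg_counter <- new.env(parent = emptyenv()); reg_counter$i <- 0L
  new_reg_id <- function() {
    reg_counter$i <- reg_counter$i + 1L
    sprintf("reg%05d", reg_counter$i)
  }
  add_reg <- function(reg_class, regulator, target, mode, targets_genes,
                      regulator_genes, sub_class = NA_character_,
                      mechanism = NA_character_, phys = NA,
                      bs_pos = NA_integer_, bs_desc = NA_character_) {
    id <- new_reg_id()
    regs[[id]] <<- tibble::tibble(
      id = id, reg_class = reg_class, sub_class = sub_class,
      mechanism = mechanism, regulator_id = regulator,
      regulated_entity_id = target, mode = mode,
      physiologically_relevant = phys, binding_site_position = bs_pos,
      binding_site_description = bs_desc)
    ledger_targets[[id]] <<- targets_genes
    ledger_reg_genes[[id]] <<- regulator_genes
    id
  }

  # --- transcription-factor regulations
  with_substream(seed, "tf_regs", {
    for (tf in roles$tf) {
      k <- max(1L, stats::rpois(1, p$targets_per_tf_mean))
      k <- min(k, n_tus)
      pms <- sample.int(n_tus, k)
      modes <- sample_mode(k, p)
      for (j in seq_len(k)) {
        cls <- if (stats::runif(1) < 0.02) "allosteric-regulation-of-rnap"
               else "transcription-factor-binding"
        bs_pos <- NA_integer_; bs_desc <- NA_character_
        if (cls == "transcription-factor-binding" && stats::runif(1) < 0.3) {
          bs_pos <- sample.int(500L, 1)
          bs_desc <- "upstream operator site"
        }
        add_reg(cls, tf_entities[[tf]], pm_ids[pms[j]], modes[j],
                targets_genes = tu_genes[[pms[j]]],
                regulator_genes = tf,
                bs_pos = bs_pos, bs_desc = bs_desc)
      }
    }
  })
  n_tf_regs <- reg_counter$i

  # --- attenuation
  with_substream(seed, "attenuation", {
    n_att <- round(p$f_attenuation * n_tf_regs)
    eligible <- which(tu_sizes >= 2)
    att_subs <- c("ribosome-mediated", "protein-mediated", "rna-mediated",
                  "small-molecule-mediated")
    if (length(eligible) > 0 && n_att > 0) {
      for (a in seq_len(n_att)) {
        tu_i <- eligible[sample.int(length(eligible), 1)]
        len <- tu_sizes[tu_i]
        si <- sample.int(len - 1L, 1)
        tid <- sprintf("tm%04d", length(terms) + 1L)
        terms[[tid]] <- tibble::tibble(id = tid, tu_id = tu_ids[tu_i],
                                        site_index = si)
        tu_terminators[[tu_i]] <- c(tu_terminators[[tu_i]], tid)
        sub <- sample(att_subs, 1)
        if (stats::runif(1) < 0.5) {
          regulator <- if (length(cmp_ids))
            sample(cmp_ids, 1) else new_ligand()
          rg_genes <- character(0)
          ledger_reg_class[regulator] <- "small-molecule"
        } else {
          g <- sample(setdiff(genes, roles$srna), 1)
          regulator <- product_id[[g]]
          rg_genes <- g
          ledger_reg_class[regulator] <- "protein"
        }
        reg_entity_genes[[regulator]] <- rg_genes
        downstream <- tu_genes[[tu_i]][(si + 1L):len]
        add_reg("transcriptional-attenuation", regulator, tid,
                sample_mode(1, p), targets_genes = downstream,
                regulator_genes = rg_genes, sub_class = sub)
      }
    }
  })

  # --- translational regulation
  with_substream(seed, "translational", {
    n_trans <- round(p$f_translational * n_tf_regs)
    mechs <- c("ribosome-blocking", "mrna-degradation", "both")
    for (a in seq_len(n_trans)) {
      u <- stats::runif(1)
      if (u < 0.45 && length(roles$srna) > 0) {
        g <- sample(roles$srna, 1)
        regulator <- product_id[[g]]
        sub <- "rna-mediated"; rg_genes <- g
        ledger_reg_class[regulator] <- "rna"
      } else if (u < 0.8) {
        g <- sample(setdiff(genes, roles$srna), 1)
        regulator <- product_id[[g]]
        sub <- "protein-mediated"; rg_genes <- g
        ledger_reg_class[regulator] <- "protein"
      } else {
        regulator <- new_ligand()  # riboswitch ligand
        sub <- "compound-mediated"; rg_genes <- character(0)
        ledger_reg_class[regulator] <- "small-molecule"
      }
      reg_entity_genes[[regulator]] <- rg_genes
      if (stats::runif(1) < 0.5) {
        tu_i <- sample.int(n_tus, 1)
        target <- tu_ids[tu_i]; tgt_genes <- tu_genes[[tu_i]]
      } else {
        target <- sample(genes, 1); tgt_genes <- target
      }
      add_reg("regulation-of-translation", regulator, target,
              sample_mode(1, p), targets_genes = tgt_genes,
              regulator_genes = rg_genes, sub_class = sub,
              mechanism = sample(mechs, 1))
    }
  })

  # --- reactions and hub wiring
  rxn_tbl <- NULL
  enzyme_pool <- character(0)
  if (p$n_reactions > 0) {
    rxn_tbl <- with_substream(seed, "reactions", {
      enz_genes <- sample(setdiff(genes, roles$srna),
                          min(max(2L, round(p$n_reactions / 2)),
                              p$n_genes - p$n_srna))
      enzyme_pool <- unname(product_id[enz_genes])
      rows <- lapply(seq_len(p$n_reactions), function(i) {
        picks <- sample(cmp_ids, 4)
        nr <- sample.int(2L, 1); np <- sample.int(2L, 1)
        tibble::tibble(
          id = sprintf("rx%04d", i),
          reactant_ids = list(sort(picks[seq_len(nr)])),
          product_ids = list(sort(picks[2L + seq_len(np)])),
          enzyme_ids = list(sample(enzyme_pool, 1)),
          reversible = stats::runif(1) < p$f_reversible)
      })
      tbl <- dplyr::bind_rows(rows)
      for (h in hub_ids) {
        into <- sample.int(p$n_reactions, p$hub_degree)
        for (i in into) {
          tbl$reactant_ids[[i]] <- sort(c(tbl$reactant_ids[[i]], h))
        }
      }
      tbl
    })
  }

  # --- enzyme modulation
  enz_mod <- list(enzymes = character(0), enzymes_phys = character(0),
                  modulators = character(0), modulators_phys = character(0),
                  n = 0L, n_phys = 0L)
  with_substream(seed, "enzyme_mods", {
    if (p$n_enzyme_modulations > 0) {
      for (a in seq_len(p$n_enzyme_modulations)) {
        regulator <- if (length(cmp_ids)) sample(cmp_ids, 1) else new_ligand()
        use_rxn <- !is.null(rxn_tbl) && stats::runif(1) < 0.3
        if (use_rxn) {
          i <- sample.int(nrow(rxn_tbl), 1)
          target <- rxn_tbl$id[i]
          enz <- rxn_tbl$enzyme_ids[[i]]
        } else {
          enz <- if (length(enzyme_pool)) sample(enzyme_pool, 1)
                 else unname(product_id[sample(setdiff(genes, roles$srna), 1)])
          target <- enz
        }
        phys <- stats::runif(1) < p$f_physiological
        add_reg("regulation-of-enzyme-activity", regulator, target,
                sample_mode(1, p), targets_genes = character(0),
                regulator_genes = character(0),
                mechanism = sample(c("allosteric", "competitive"), 1),
                phys = phys)
        enz_mod$n <- enz_mod$n + 1L
        enz_mod$enzymes <- union(enz_mod$enzymes, enz)
        enz_mod$modulators <- union(enz_mod$modulators, regulator)
        if (phys) {
          enz_mod$n_phys <- enz_mod$n_phys + 1L
          enz_mod$enzymes_phys <- union(enz_mod$enzymes_phys, enz)
          enz_mod$modulators_phys <- union(enz_mod$modulators_phys,
                                            regulator)
        }
      }
    }
  })

  # --- assemble tables
  reg_tbl <- if (length(regs)) dplyr::bind_rows(regs) else NULL
  term_tbl <- if (length(terms)) dplyr::bind_rows(terms) else NULL
  products_tbl <- tibble::tibble(
    id = unname(product_id),
    kind = unname(product_kind),
    gene_ids = as.list(genes),
    component_ids = rep(list(character(0)), p$n_genes),
    unmodified_form_id = NA_character_,
    ligand_ids = rep(list(character(0)), p$n_genes))
  if (length(extra_products)) {
    extra_tbl <- dplyr::bind_rows(lapply(extra_products, function(e) {
      tibble::tibble(
        id = e$id, kind = e$kind,
        gene_ids = list(character(0)),
        component_ids = list(if (is.null(e$component_ids)) character(0)
                             else e$component_ids),
        unmodified_form_id = if (is.null(e$unmodified_form_id)) NA_character_
                             else e$unmodified_form_id,
        ligand_ids = list(if (is.null(e$ligand_ids)) character(0)
                          else e$ligand_ids))
    }))
    products_tbl <- dplyr::bind_rows(products_tbl, extra_tbl)
  }
  all_cmp <- c(cmp_ids, hub_ids, ligand_pool$ids)
  compounds_tbl <- if (length(all_cmp))
    tibble::tibble(id = all_cmp, name = paste0("compound ", all_cmp))
    else NULL

  model <- regulatory_model(
    genes = tibble::tibble(id = genes, name = paste0("gene ", genes),
                           product_id = unname(product_id[genes])),
    transcription_units = tibble::tibble(
      id = tu_ids,
      gene_ids = unname(tu_genes),
      promoter_id = pm_ids,
      terminator_ids = lapply(tu_terminators, function(x)
        if (is.null(x)) character(0) else x)),
    promoters = tibble::tibble(id = pm_ids, tu_id = tu_ids,
                               sigma_factor_id =
                                 unname(product_id[sigma_for_pm])),
    terminators = term_tbl,
    products = products_tbl,
    compounds = compounds_tbl,
    reactions = rxn_tbl,
    regulations = reg_tbl,
    id = sprintf("synth-seed%d-n%d", seed, p$n_genes)
  )

  ledger <- build_ledger(model, p, seed, roles, ledger_targets,
                         ledger_reg_genes, ledger_reg_class, enz_mod,
                         hub_ids, reg_tbl)
  list(model = model, ledger = ledger)
}

# Ground truth assembled from construction bookkeeping only.
build_ledger <- function(model, p, seed, roles, ledger_targets,
                         ledger_reg_genes, ledger_reg_class, enz_mod,
                         hub_ids, reg_tbl) {
  cls <- if (is.null(reg_tbl)) character(0) else reg_tbl$reg_class
  sub <- if (is.null(reg_tbl)) character(0) else reg_tbl$sub_class
  ids <- if (is.null(reg_tbl)) character(0) else reg_tbl$id

  is_expr <- cls %in% c(TRANSCRIPTIONAL_CLASSES, "regulation-of-translation")
  covered <- unique(unlist(ledger_targets[ids[is_expr]], use.names = FALSE))

  expr_regulators <- unique(if (is.null(reg_tbl)) character(0)
                            else reg_tbl$regulator_id[is_expr])
  reg_cls <- ledger_reg_class[expr_regulators]

  # per-regulator-gene target lists over transcriptional regulations
  tf_targets <- list()
  gene_regulators <- list()
  for (i in which(is_expr)) {
    id <- ids[i]
    rgenes <- ledger_reg_genes[[id]]
    tgts <- ledger_targets[[id]]
    if (cls[i] %in% TRANSCRIPTIONAL_CLASSES) {
      for (g in rgenes) tf_targets[[g]] <- union(tf_targets[[g]], tgts)
    }
    for (t in tgts) gene_regulators[[t]] <- union(gene_regulators[[t]],
                                                  rgenes)
  }
  tf_targets <- lapply(tf_targets, sort)
  gene_regulators <- lapply(gene_regulators, sort)

  stats_vec <- stats::setNames(numeric(length(STAT_CATEGORIES)),
                               STAT_CATEGORIES)
  stats_vec["transcription_factor_binding"] <-
    sum(cls == "transcription-factor-binding")
  stats_vec["allosteric_regulation_of_rnap"] <-
    sum(cls == "allosteric-regulation-of-rnap")
  stats_vec["attenuation"] <- sum(cls == "transcriptional-attenuation")
  stats_vec["transcriptional_regulation"] <-
    sum(cls %in% TRANSCRIPTIONAL_CLASSES)
  stats_vec["translational_regulation"] <-
    sum(cls == "regulation-of-translation")
  stats_vec["translational_protein_mediated"] <-
    sum(cls == "regulation-of-translation" & sub %in% "protein-mediated")
  stats_vec["translational_rna_mediated"] <-
    sum(cls == "regulation-of-translation" & sub %in% "rna-mediated")
  stats_vec["translational_compound_mediated"] <-
    sum(cls == "regulation-of-translation" & sub %in% "compound-mediated")
  stats_vec["enzyme_modulation"] <- enz_mod$n
  stats_vec["enzyme_modulation_physiological"] <- enz_mod$n_phys
  stats_vec["genes_with_regulator"] <- length(covered)
  stats_vec["percent_of_genome"] <- 100 * length(covered) / p$n_genes
  stats_vec["regulators"] <- length(expr_regulators)
  stats_vec["regulators_protein"] <- sum(reg_cls == "protein")
  stats_vec["regulators_rna"] <- sum(reg_cls == "rna")
  stats_vec["regulators_small_molecule"] <- sum(reg_cls == "small-molecule")
  stats_vec["enzymes_modulated"] <- length(enz_mod$enzymes)
  stats_vec["enzymes_modulated_physiological"] <- length(enz_mod$enzymes_phys)
  stats_vec["enzyme_modulators"] <- length(enz_mod$modulators)
  stats_vec["enzyme_modulators_physiological"] <-
    length(enz_mod$modulators_phys)

  list(seed = seed, params = unclass(p),
       sigma_genes = roles$sigma, tf_genes = roles$tf,
       srna_genes = roles$srna,
       hub_compound_ids = hub_ids,
       regulation_targets = ledger_targets,
       regulator_gene_targets = tf_targets,
       gene_regulators = gene_regulators,
       stats = as.list(stats_vec))
}

#' Write a generator ledger as JSON
#'
#' @param ledger A ledger from [generate_model()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_ledger <- function(ledger, path) {
  json <- jsonlite::toJSON(ledger, auto_unbox = TRUE, pretty = 2, digits = NA)
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}
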
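test_that("a consistent model validates cleanly and indices resolve", {
  m <- toy_model()
  expect_s3_class(m, "regulatory_model")
  expect_identical(nrow(validate_model(m)), 0L)
  expect_identical(regulonkit:::entity_kind(m, "pm1"), "promoter")
  expect_identical(regulonkit:::entity_kind(m, "nope"), NA_character_)
})

test_that("validation reports broken references and incompatible classes", {
  m <- toy_model()
  # regulation pointing at a missing entity
  m$regulations$regulated_entity_id[1] <- "ghost"
  m <- regulonkit:::rebuild_indices(m)
  rep1 <- validate_model(m)
  expect_true(any(rep1$entity_id == "r1" &
                    rep1$rule == "unresolved-reference"))

  # attenuation pointing at a promoter
  m2 <- toy_model()
  m2$regulations$regulated_entity_id[3] <- "pm1"
  m2 <- regulonkit:::rebuild_indices(m2)
  rep2 <- validate_model(m2)
  expect_true(any(rep2$entity_id == "r3" &
                    rep2$rule == "class-entity-incompatible"))

  # duplicate gene id
  m3 <- toy_model()
  m3$genes$id[2] <- "g1"
  m3 <- regulonkit:::rebuild_indices(m3)
  expect_true(any(validate_model(m3)$rule == "duplicate-id"))

  # terminator site index out of range
  m4 <- toy_model()
  m4$terminators$site_index[1] <- 3L
  expect_true(any(validate_model(m4)$rule == "site-index-range"))

  # cyclic complex composition
  m5 <- toy_model()
  m5$products$component_ids[[which(m5$products$id == "cx1")]] <-
    c("cx2", "c1")
  m5$products$component_ids[[which(m5$products$id == "cx2")]] <-
    c("cx1", "p4")
  expect_true(any(validate_model(m5)$rule == "cyclic-product-graph"))

  # reserved degradation class is rejected as unsupported
  m6 <- toy_model()
  m6$regulations$reg_class[4] <- "regulation-of-protein-degradation"
  expect_true(any(validate_model(m6)$rule == "unsupported-class"))
})

test_that("regulated_genes follows promoter, terminator, TU and gene rules", {
  m <- toy_model()
  # promoter -> all genes of the TU, in order
  expect_identical(regulated_genes(m, "r1"), c("g1", "g2", "g3"))
  # terminator with site_index 1 in [g1,g2,g3] -> downstream only
  expect_identical(regulated_genes(m, "r3"), c("g2", "g3"))
  # TU target -> all TU genes; gene target -> that gene
  expect_identical(regulated_genes(m, "r4"), "g4")
  expect_identical(regulated_genes(m, "r7"), "g5")
  # enzyme-level regulation expands to no genes
  expect_identical(regulated_genes(m, "r5"), character(0))
  expect_identical(regulated_genes(m, "r6"), character(0))
  expect_error(regulated_genes(m, "rX"), "unknown regulation")
})

test_that("terminator expansion is monotone in site_index", {
  m <- toy_model()
  tu_genes <- c("g1", "g2", "g3")
  prev <- tu_genes
  for (si in 0:2) {
    m$terminators$site_index[1] <- si
    got <- regulated_genes(m, "r3")
    expect_identical(got, tu_genes[seq_along(tu_genes) > si])
    expect_true(all(got %in% prev))
    prev <- got
  }
})

test_that("regulator_genes resolves products recursively", {
  m <- toy_model()
  # TF-ligand complex resolves to the TF's gene; ligand contributes none
  expect_identical(regulator_genes(m, "r1"), "g8")
  # plain polypeptide and small RNA
  expect_identical(regulator_genes(m, "r2"), "g8")
  expect_identical(regulator_genes(m, "r4"), "g7")
  # free compounds (riboswitch ligand, attenuation metabolite) -> none
  expect_identical(regulator_genes(m, "r3"), character(0))
  expect_identical(regulator_genes(m, "r7"), character(0))
  # heterocomplex -> union of component genes, sorted
  m$regulations$regulator_id[2] <- "cx2"
  expect_identical(regulator_genes(m, "r2"), c("g1", "g4"))
  # invariant under component re-ordering
  m$products$component_ids[[which(m$products$id == "cx2")]] <- c("p4", "p1")
  expect_identical(regulator_genes(m, "r2"), c("g1", "g4"))
})

test_that("modified forms resolve through their base form", {
  m <- toy_model()
  m$products <- dplyr::bind_rows(
    m$products,
    tibble::tibble(id = "mf1", kind = "modified-form",
                   gene_ids = list(character(0)),
                   component_ids = list(character(0)),
                   unmodified_form_id = "p8", ligand_ids = list("c1")))
  m <- regulonkit:::rebuild_indices(m)
  m$regulations$regulator_id[1] <- "mf1"
  expect_identical(regulator_genes(m, "r1"), "g8")
  expect_identical(regulonkit:::entity_class3(m, "mf1"), "protein")
  expect_identical(regulonkit:::entity_class3(m, "p7"), "rna")
  expect_identical(regulonkit:::entity_class3(m, "c1"), "small-molecule")
})

test_that("model_stats mirrors the content-statistics categories", {
  m <- toy_model()
  st <- model_stats(m)
  v <- stats::setNames(st$value, st$category)
  expect_identical(v[["transcriptional_regulation"]], 3)
  expect_identical(v[["transcription_factor_binding"]], 2)
  expect_identical(v[["attenuation"]], 1)
  expect_identical(v[["translational_regulation"]], 2)
  expect_identical(v[["translational_rna_mediated"]], 1)
  expect_identical(v[["translational_compound_mediated"]], 1)
  expect_identical(v[["enzyme_modulation"]], 2)
  expect_identical(v[["enzyme_modulation_physiological"]], 1)
  # r1 covers g1-g3, r2/r4 cover g4, r3 covers g2-g3, r7 covers g5
  expect_identical(v[["genes_with_regulator"]], 5)
  expect_equal(v[["percent_of_genome"]], 100 * 5 / 9)
  expect_identical(v[["regulators"]], 5)
  expect_identical(v[["regulators_protein"]], 2)
  expect_identical(v[["regulators_rna"]], 1)
  expect_identical(v[["regulators_small_molecule"]], 2)
  # r5 targets p5 directly; r6 targets rx1 whose enzyme is p5
  expect_identical(v[["enzymes_modulated"]], 1)
  expect_identical(v[["enzyme_modulators"]], 2)
  expect_identical(v[["enzyme_modulators_physiological"]], 1)

  # the physiological filter restricts the main enzyme rows
  stp <- model_stats(m, physiological_only = TRUE)
  vp <- stats::setNames(stp$value, stp$category)
  expect_identical(vp[["enzyme_modulation"]], 1)
  expect_identical(vp[["enzyme_modulators"]], 1)
})

test_that("an empty model yields all-zero statistics", {
  st <- model_stats(regulatory_model())
  expect_true(all(st$value == 0))
})

test_that("expansion is total and TU-bounded on generated models", {
  gen <- generate_model(small_params(), seed = 11)
  m <- gen$model
  tu_sets <- lapply(m$transcription_units$gene_ids, identity)
  for (id in m$regulations$id) {
    got <- regulated_genes(m, id)   # must not error
    if (length(got) > 1) {
      expect_true(any(vapply(tu_sets, function(s) all(got %in% s),
                             logical(1))),
                  label = paste("targets of", id, "within one TU"))
    }
  }
})
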
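test_that("promoter regulation expands to edges on every TU gene", {
  m <- toy_model()
  net <- build_gene_network(m, include = "transcriptional")
  e <- net$edges
  # cx1 (TF g8) inhibits pm1 -> edges g8 -> g1,g2,g3
  for (tgt in c("g1", "g2", "g3")) {
    row <- e[e$from == "g8" & e$to == tgt, ]
    expect_identical(nrow(row), 1L)
    expect_identical(row$mode, "inhibition")
    expect_true("r1" %in% row$provenance[[1]])
  }
  # attenuation regulator is a compound: no gene-level edge
  expect_false(any(vapply(e$provenance, function(p) "r3" %in% p,
                          logical(1))))
  # translational class excluded here
  expect_false(any(e$from == "g7"))
})

test_that("conflicting labels merge to dual; unknown is dominated", {
  m <- toy_model()
  # add a second regulation: g8 activates pm1 via plain product
  m$regulations <- dplyr::bind_rows(
    m$regulations,
    tibble::tibble(id = "r8", reg_class = "transcription-factor-binding",
                   sub_class = NA, mechanism = NA, regulator_id = "p8",
                   regulated_entity_id = "pm1", mode = "+",
                   physiologically_relevant = NA,
                   binding_site_position = NA_integer_,
                   binding_site_description = NA))
  m <- regulonkit:::rebuild_indices(m)
  net <- build_gene_network(m, include = "transcriptional")
  row <- net$edges[net$edges$from == "g8" & net$edges$to == "g1", ]
  expect_identical(row$mode, "dual")
  expect_setequal(row$provenance[[1]], c("r1", "r8"))

  expect_identical(regulonkit:::merge_edge_modes(c("unknown", "activation")),
                   "activation")
  expect_identical(regulonkit:::merge_edge_modes("unknown"), "unknown")
  expect_identical(regulonkit:::merge_edge_modes(c("dual", "inhibition")),
                   "dual")
})

test_that("sigma-factor inclusion adds activation edges with provenance", {
  m <- toy_model()
  net <- build_gene_network(m, include = "sigma")
  e <- net$edges
  # sigma gene g9 -> all genes of tu1 and tu2
  expect_setequal(e$to[e$from == "g9"], c("g1", "g2", "g3", "g4"))
  expect_true(all(e$mode[e$from == "g9"] == "activation"))
  expect_true(all(grepl("^sigma:pm", unlist(e$provenance))))
  # excluded without the sigma flag
  net2 <- build_gene_network(m, include = "transcriptional")
  expect_false(any(net2$edges$from == "g9"))
})

test_that("network edges equal a ledger-derived brute-force edge set", {
  for (seed in c(3, 17)) {
    gen <- generate_model(small_params(), seed = seed)
    m <- gen$model
    led <- gen$ledger
    # expected edges re-derived from construction bookkeeping + promoters
    exp_edges <- character(0)
    rg <- m$regulations
    expr <- rg$id[rg$reg_class %in% c(regulonkit:::TRANSCRIPTIONAL_CLASSES,
                                      "regulation-of-translation")]
    for (id in expr) {
      srcs <- led$regulation_targets[[id]]   # targets from ledger
      rgen <- led$gene_regulators            # not needed here
      froms <- regulonkit:::entity_genes(m, rg$regulator_id[rg$id == id])
      for (f in froms) exp_edges <- c(exp_edges, paste(f, srcs))
    }
    pr <- m$promoters
    for (i in seq_len(nrow(pr))) {
      sg <- regulonkit:::entity_genes(m, pr$sigma_factor_id[i])
      tg <- m$transcription_units$gene_ids[[
        which(m$transcription_units$id == pr$tu_id[i])]]
      for (f in sg) exp_edges <- c(exp_edges, paste(f, tg))
    }
    net <- build_gene_network(m)
    expect_setequal(paste(net$edges$from, net$edges$to),
                    unique(exp_edges))
  }
})

test_that("network construction is invariant to regulation order", {
  m <- generate_model(small_params(), seed = 8)$model
  net1 <- build_gene_network(m)
  set.seed(1)
  m2 <- m
  m2$regulations <- m2$regulations[sample(nrow(m2$regulations)), ]
  m2 <- regulonkit:::rebuild_indices(m2)
  net2 <- build_gene_network(m2)
  expect_equal(net2$edges, net1$edges)
})

test_that("genes cluster by identical regulator sets", {
  net <- gnet(from = c("t", "t", "t", "u", "s"),
              to = c("g1", "g2", "g3", "g3", "t"),
              nodes = c("h1", "h2"))
  cl <- cluster_genes_by_regulators(net)
  find_cluster <- function(g) which(vapply(cl$genes, function(x)
    g %in% x, logical(1)))
  expect_identical(find_cluster("g1"), find_cluster("g2"))
  expect_false(find_cluster("g3") == find_cluster("g1"))
  # unregulated genes share the empty-set cluster
  expect_identical(find_cluster("h1"), find_cluster("h2"))
  expect_identical(cl$regulators[[find_cluster("h1")]], character(0))
  # regulators (t, u, s) are excluded from clustering
  expect_false(any(c("t", "u", "s") %in% unlist(cl$genes)))
  # ordered by size descending
  expect_true(all(diff(cl$size) <= 0))
})

test_that("elliptical layout partitions rings and is deterministic", {
  # 1 sigma gene, 2 TFs, 5 pure targets
  m <- regulatory_model(
    genes = tibble::tibble(id = c("sig", "tf1", "tf2", paste0("x", 1:5)),
                           name = NA, product_id = c("ps", "pt1", "pt2",
                                                     rep(NA, 5))),
    transcription_units = tibble::tibble(
      id = c("tuA", "tuB"), gene_ids = list(c("x1", "x2", "x3"),
                                            c("x4", "x5")),
      promoter_id = c("pmA", "pmB")),
    promoters = tibble::tibble(id = c("pmA", "pmB"),
                               tu_id = c("tuA", "tuB"),
                               sigma_factor_id = c("ps", "ps")),
    products = tibble::tibble(id = c("ps", "pt1", "pt2"),
                              kind = "polypeptide",
                              gene_ids = list("sig", "tf1", "tf2")),
    regulations = tibble::tibble(
      id = c("ra", "rb"),
      reg_class = "transcription-factor-binding",
      regulator_id = c("pt1", "pt2"),
      regulated_entity_id = c("pmA", "pmB"),
      mode = c("+", "-")))
  expect_identical(nrow(validate_model(m)), 0L)
  net <- build_gene_network(m)
  lay <- elliptical_layout(net, m)
  expect_identical(sum(lay$ring == 1), 1L)
  expect_identical(sum(lay$ring == 2), 2L)
  expect_identical(sum(lay$ring == 3), 5L)
  expect_identical(lay$gene[lay$ring == 1], "sig")
  # every node once, no shared coordinates
  expect_setequal(lay$gene, net$nodes)
  expect_false(anyDuplicated(paste(lay$x, lay$y)) > 0)
  # deterministic
  expect_equal(elliptical_layout(net, m), lay)
})

test_that("a gene that is both sigma factor and TF sits on ring 1 only", {
  m <- toy_model()
  # g9 is the sigma factor; also make it a TF via a new regulation
  m$regulations <- dplyr::bind_rows(
    m$regulations,
    tibble::tibble(id = "r9", reg_class = "transcription-factor-binding",
                   sub_class = NA, mechanism = NA, regulator_id = "p9",
                   regulated_entity_id = "pm3", mode = "+",
                   physiologically_relevant = NA,
                   binding_site_position = NA_integer_,
                   binding_site_description = NA))
  m <- regulonkit:::rebuild_indices(m)
  net <- build_gene_network(m)
  lay <- elliptical_layout(net, m)
  expect_identical(lay$ring[lay$gene == "g9"], 1L)
  expect_identical(sum(lay$gene == "g9"), 1L)
})

test_that("layered layout stacks regulators by longest path, SCCs merge", {
  net <- gnet(from = c("t1", "t2"), to = c("t2", "g"))
  lay <- layered_layout(net, toy_model())
  lv <- stats::setNames(lay$layer, lay$gene)
  expect_identical(lv[["t1"]], 2L)
  expect_identical(lv[["t2"]], 1L)
  expect_identical(lv[["g"]], 0L)
  expect_true(max(lay$y) == lay$y[lay$gene == "t1"])

  # mutual pair shares a layer
  net2 <- gnet(from = c("t1", "t2", "t1"), to = c("t2", "t1", "g"))
  lay2 <- layered_layout(net2, toy_model())
  lv2 <- stats::setNames(lay2$layer, lay2$gene)
  expect_identical(lv2[["t1"]], lv2[["t2"]])
  expect_identical(lv2[["g"]], 0L)

  # edgeless network: everything in the single bottom layer
  net3 <- regulonkit:::new_gene_network(c("a", "b"), net$edges[0, ],
                                        "transcriptional")
  lay3 <- layered_layout(net3, toy_model())
  expect_true(all(lay3$layer == 0L))
  expect_error(layered_layout(
    regulonkit:::new_gene_network(character(0), net$edges[0, ], "x"),
    toy_model()), "no nodes")
})

test_that("subnetwork respects direction and depth and terminates on cycles", {
  net <- gnet(from = c("a", "b", "c", "d"), to = c("b", "c", "a", "a"))
  # direct regulatees of a
  s1 <- subnetwork(net, "a", "regulatees", depth = 1)
  expect_setequal(s1$nodes, c("a", "b"))
  # unbounded on a cycle keeps the whole cycle and terminates
  s2 <- subnetwork(net, "a", "regulatees", depth = Inf)
  expect_setequal(s2$nodes, c("a", "b", "c"))
  # regulators of a
  s3 <- subnetwork(net, "a", "regulators", depth = 1)
  expect_setequal(s3$nodes, c("a", "c", "d"))
  # all seeds -> identity
  s4 <- subnetwork(net, net$nodes, "both", depth = Inf)
  expect_equal(s4$edges, net$edges)
  expect_error(subnetwork(net, "zz", "both"), "zz")
})

test_that("unbounded subnetwork equals matrix-power transitive closure", {
  for (seed in c(31, 32)) {
    net <- random_gene_network(seed, n = 12)
    nodes <- net$nodes
    A <- matrix(0, 12, 12, dimnames = list(nodes, nodes))
    for (i in seq_len(nrow(net$edges))) {
      A[net$edges$from[i], net$edges$to[i]] <- 1
    }
    reach <- diag(12); dimnames(reach) <- dimnames(A)
    P <- diag(12)
    for (k in seq_len(12)) { P <- P %*% A; reach <- reach + P }
    seed_gene <- nodes[1]
    expected <- nodes[reach[seed_gene, ] > 0]
    got <- subnetwork(net, seed_gene, "regulatees", depth = Inf)$nodes
    expect_setequal(got, expected)
  }
})
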
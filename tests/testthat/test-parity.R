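test_that("irreversible reactions emit the full activator/inhibitor edge set", {
  m <- regulatory_model(
    compounds = tibble::tibble(id = c("A", "B", "C"), name = NA),
    products = tibble::tibble(id = "E", kind = "polypeptide",
                              gene_ids = list("gE")),
    genes = tibble::tibble(id = "gE", name = NA, product_id = "E"),
    reactions = tibble::tibble(id = "r1", reactant_ids = list(c("A", "B")),
                               product_ids = list("C"),
                               enzyme_ids = list("E"),
                               reversible = FALSE))
  pg <- build_parity_graph(m)
  key <- paste(pg$edges$from, pg$edges$sign, pg$edges$to)
  expect_setequal(key, c("A + C", "B + C", "gE + C",
                         "gE - A", "gE - B", "B - A", "A - B"))
  # flipping to reversible removes every reaction edge
  m$reactions$reversible <- TRUE
  expect_identical(nrow(build_parity_graph(m)$edges), 0L)
})

test_that("complexes, modified forms and regulations wire the toy model", {
  m <- toy_model()
  pg <- build_parity_graph(m)
  e <- pg$edges
  edge <- function(f, t) e[e$from == f & e$to == t, ]
  # component edges into the TF-ligand complex, then inhibition out of it
  expect_identical(edge("c1", "cx1")$sign, "+")
  expect_identical(edge("g8", "cx1")$sign, "+")
  for (tgt in c("g1", "g2", "g3")) {
    expect_identical(edge("cx1", tgt)$sign, "-")
  }
  # single-gene products share their gene's node
  expect_false("p8" %in% pg$nodes)
  expect_true("cx1" %in% pg$nodes)
  # enzyme modulation points at the enzyme's gene node
  expect_identical(edge("c4", "g5")$sign, "-")
  # rx1 (irreversible) contributes, rx2 (reversible) does not
  expect_identical(edge("c2", "c4")$sign, "+")
  expect_identical(nrow(edge("c4", "c2")), 0L)
})

test_that("unknown-mode edges are omitted; dual contributes both signs", {
  m <- toy_model()
  m$regulations$mode[m$regulations$id == "r1"] <- "unknown"
  m$regulations$mode[m$regulations$id == "r2"] <- "dual"
  pg <- build_parity_graph(m)
  e <- pg$edges
  expect_identical(nrow(e[e$from == "cx1", ]), 0L)
  expect_identical(e$sign[e$from == "g8" & e$to == "g4"], "+-")
})

test_that("hub compounds are excluded and pruning is monotone", {
  gen <- generate_model(small_params(), seed = 21)
  m <- gen$model
  hub <- gen$ledger$hub_compound_ids
  expect_length(hub, 1)
  pg_strict <- build_parity_graph(m, hub_threshold = 3)
  pg_loose <- build_parity_graph(m, hub_threshold = 100)
  expect_false(hub %in% pg_strict$nodes)
  expect_true(hub %in% pg_loose$nodes)
  expect_true(hub %in% pg_strict$excluded_hubs)
  expect_false(any(pg_strict$edges$from == hub |
                     pg_strict$edges$to == hub))
  # raising the threshold never removes edges
  key_strict <- paste(pg_strict$edges$from, pg_strict$edges$to)
  key_loose <- paste(pg_loose$edges$from, pg_loose$edges$to)
  expect_true(all(key_strict %in% key_loose))
})

test_that("a double-negative chain makes an indirect activator", {
  # C -| A -| B: parity multiplies, so C activates B
  pg <- pgraph(from = c("C", "A"), to = c("A", "B"), sign = c("-", "-"))
  cls <- classify_influences(pg, "B")
  expect_identical(cls$activators, "C")
  expect_identical(cls$inhibitors, "A")
  expect_identical(cls$unknown, character(0))
})

test_that("conflicting parity marks a node unknown and prunes upstream", {
  # A reaches B positively (direct) and negatively (via m); D only
  # reaches B through A, so D stays unclassified
  pg <- pgraph(from = c("A", "A", "m", "D"),
               to = c("B", "m", "B", "A"),
               sign = c("+", "+", "-", "+"))
  cls <- classify_influences(pg, "B")
  expect_identical(cls$unknown, "A")
  expect_false("D" %in% c(cls$activators, cls$inhibitors, cls$unknown))
  expect_identical(cls$inhibitors, "m")
  expect_identical(cls$sign_sets[["A"]], "+-")
})

test_that("classification matches the exhaustive simple-path oracle", {
  for (seed in 301:340) {
    pg <- random_parity_graph(seed)
    set.seed(seed + 5000)
    target <- sample(pg$nodes, 1)
    cls <- classify_influences(pg, target, depth = 6)
    oracle <- oracle_parity_classify(pg, target, depth = 6)
    expect_same_classification(cls, oracle)
  }
})

test_that("negating the target's incoming edges swaps the classification", {
  # every admissible path crosses exactly one in-edge of the target, so
  # flipping those edge signs flips every path product
  for (seed in c(401, 402, 403, 404)) {
    pg <- random_parity_graph(seed)
    set.seed(seed)
    target <- sample(pg$nodes, 1)
    cls <- classify_influences(pg, target, depth = 6)
    flip <- pg
    into <- flip$edges$to == target
    flip$edges$sign[into] <-
      c("+" = "-", "-" = "+", "+-" = "+-")[flip$edges$sign[into]]
    cls2 <- classify_influences(flip, target, depth = 6)
    expect_identical(cls2$activators, cls$inhibitors)
    expect_identical(cls2$inhibitors, cls$activators)
    expect_identical(cls2$unknown, cls$unknown)
  }
})

test_that("deepening never flips a determined sign directly", {
  for (seed in c(501, 502, 503, 504)) {
    pg <- random_parity_graph(seed, max_n = 20)
    set.seed(seed)
    target <- sample(pg$nodes, 1)
    c1 <- classify_influences(pg, target, depth = 3)
    c2 <- classify_influences(pg, target, depth = 4)
    for (u in c1$activators) expect_false(u %in% c2$inhibitors)
    for (u in c1$inhibitors) expect_false(u %in% c2$activators)
  }
})

test_that("the fixpoint terminates on cyclic graphs within |V| rounds", {
  pg <- pgraph(from = c("a", "b", "c", "a", "x"),
               to = c("b", "c", "a", "t", "a"),
               sign = c("-", "-", "-", "+", "+"))
  cls <- classify_influences(pg, "t", depth = 6)
  expect_lte(cls$rounds, length(pg$nodes) + 1)
  # autoregulation does not feed a node's own sign back
  pg2 <- pgraph(from = c("a", "a"), to = c("a", "t"), sign = c("-", "+"))
  cls2 <- classify_influences(pg2, "t")
  expect_identical(cls2$activators, "a")
})

test_that("influence paths are admissible, signed and sorted", {
  pg <- pgraph(from = c("C", "A"), to = c("A", "B"), sign = c("-", "-"))
  paths <- influence_paths(pg, "C", "B")
  expect_identical(nrow(paths), 1L)
  expect_identical(paths$sign, "+")
  expect_identical(paths$nodes[[1]], c("C", "A", "B"))
  # unreachable pair -> zero rows
  expect_identical(nrow(influence_paths(pg, "B", "C")), 0L)
  # paths through an unknown node are excluded
  pgu <- pgraph(from = c("A", "A", "m", "D"),
                to = c("B", "m", "B", "A"),
                sign = c("+", "+", "-", "+"))
  expect_identical(nrow(influence_paths(pgu, "D", "B")), 0L)
  # multiple paths sort by length then lexicographically
  pg3 <- pgraph(from = c("s", "s", "u", "v"), to = c("u", "v", "t", "t"),
                sign = c("+", "-", "+", "+"))
  p3 <- influence_paths(pg3, "s", "t")
  expect_identical(p3$path, c("s -> u -> t", "s -> v -> t"))
  expect_identical(p3$sign, c("+", "-"))
})

test_that("classification respects the depth bound", {
  # chain of length 3 to the target: invisible at depth 2
  pg <- pgraph(from = c("w", "x", "y"), to = c("x", "y", "t"),
               sign = c("+", "+", "+"))
  c2 <- classify_influences(pg, "t", depth = 2)
  expect_false("w" %in% c(c2$activators, c2$inhibitors, c2$unknown))
  c3 <- classify_influences(pg, "t", depth = 3)
  expect_true("w" %in% c3$activators)
  expect_error(classify_influences(pg, "nope"), "not a node")
})

test_that("models with no reactions yield regulation/component edges only", {
  gen <- generate_model(synth_params(n_genes = 40, n_reactions = 0,
                                     n_enzyme_modulations = 0,
                                     hub_compound_count = 0), seed = 2)
  pg <- build_parity_graph(gen$model)
  expect_false(any(grepl("^rx", unlist(pg$edges$provenance))))
})
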
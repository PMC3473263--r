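# Hand-built fixtures and independent oracles shared across tests.

# A small but complete model: a 3-gene operon with attenuation, a
# sigma factor, a TF acting as a ligand-bound complex, a small RNA, a
# riboswitch, and a 2-reaction enzyme layer with modulation.
toy_model <- function() {
  regulatory_model(
    genes = tibble::tibble(
      id = paste0("g", 1:9),
      name = paste0("gene ", 1:9),
      product_id = paste0("p", 1:9)),
    transcription_units = tibble::tibble(
      id = c("tu1", "tu2", "tu3", "tu4"),
      gene_ids = list(c("g1", "g2", "g3"), "g4", c("g5", "g6"), "g7"),
      promoter_id = c("pm1", "pm2", "pm3", "pm4"),
      terminator_ids = list("tm1", character(0), character(0),
                            character(0))),
    promoters = tibble::tibble(
      id = c("pm1", "pm2", "pm3", "pm4"),
      tu_id = c("tu1", "tu2", "tu3", "tu4"),
      sigma_factor_id = c("p9", "p9", NA, NA)),
    terminators = tibble::tibble(id = "tm1", tu_id = "tu1",
                                 site_index = 1L),
    products = tibble::tibble(
      id = c(paste0("p", 1:9), "cx1", "cx2"),
      kind = c(rep("polypeptide", 6), "rna", "polypeptide", "polypeptide",
               "complex", "complex"),
      gene_ids = c(as.list(paste0("g", 1:9)), list(character(0)),
                   list(character(0))),
      component_ids = c(rep(list(character(0)), 9), list(c("p8", "c1")),
                        list(c("p1", "p4"))),
      unmodified_form_id = NA_character_,
      ligand_ids = c(rep(list(character(0)), 9), list("c1"),
                     list(character(0)))),
    compounds = tibble::tibble(id = paste0("c", 1:4),
                               name = paste0("compound ", 1:4)),
    reactions = tibble::tibble(
      id = c("rx1", "rx2"),
      reactant_ids = list(c("c2", "c3"), "c4"),
      product_ids = list("c4", "c2"),
      enzyme_ids = list("p5", "p6"),
      reversible = c(FALSE, TRUE)),
    regulations = tibble::tibble(
      id = paste0("r", 1:7),
      reg_class = c("transcription-factor-binding",
                    "transcription-factor-binding",
                    "transcriptional-attenuation",
                    "regulation-of-translation",
                    "regulation-of-enzyme-activity",
                    "regulation-of-enzyme-activity",
                    "regulation-of-translation"),
      sub_class = c(NA, NA, "ribosome-mediated", "rna-mediated", NA, NA,
                    "compound-mediated"),
      mechanism = c(NA, NA, NA, "ribosome-blocking", "allosteric",
                    "competitive", "ribosome-blocking"),
      regulator_id = c("cx1", "p8", "c3", "p7", "c4", "c2", "c1"),
      regulated_entity_id = c("pm1", "pm2", "tm1", "tu2", "p5", "rx1",
                              "g5"),
      mode = c("-", "+", "-", "-", "-", "+", "+"),
      physiologically_relevant = c(NA, NA, NA, NA, TRUE, FALSE, NA),
      binding_site_position = c(120L, NA, NA, NA, NA, NA, NA),
      binding_site_description = c("operator", NA, NA, NA, NA, NA, NA)),
    id = "toy")
}

# build a gene_network directly from an edge table
gnet <- function(from, to, mode = "activation", nodes = NULL,
                 include = c("transcriptional", "translational")) {
  stopifnot(length(from) == length(to))
  mode <- rep_len(mode, length(from))
  e <- tibble::tibble(from = from, to = to, mode = mode,
                      provenance = as.list(paste0("e", seq_along(from))))
  regulonkit:::new_gene_network(unique(c(from, to, nodes)), e, include)
}

random_gene_network <- function(seed, n = NULL, edge_factor = 2) {
  set.seed(seed)
  if (is.null(n)) n <- sample(20:50, 1)
  nodes <- sprintf("n%03d", seq_len(n))
  m <- round(edge_factor * n)
  from <- sample(nodes, m, replace = TRUE)
  to <- sample(nodes, m, replace = TRUE)
  keep <- !duplicated(paste(from, to))
  gnet(from[keep], to[keep],
       mode = sample(c("activation", "inhibition", "dual", "unknown"),
                     sum(keep), replace = TRUE),
       nodes = nodes)
}

# --- influence oracle: dense eigendecomposition of the explicit
# iteration matrix (independent of the power-method implementation)
oracle_influence <- function(network, damping = 0.001,
                             normalization = "regulator-count") {
  nodes <- network$nodes
  n <- length(nodes)
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  e <- network$edges
  for (i in seq_len(nrow(e))) A[e$from[i], e$to[i]] <- 1
  M <- A
  if (normalization == "regulator-count") {
    r <- colSums(A != 0)
    for (j in which(r > 0)) M[, j] <- A[, j] / r[j]
  }
  B <- (1 - damping) * (M + diag(n)) + damping * matrix(1 / n, n, n)
  ev <- eigen(B)
  dom <- which.max(Mod(ev$values))
  v <- Re(ev$vectors[, dom])
  if (sum(v) < 0) v <- -v
  v <- pmax(v, 0)
  stats::setNames(100 * v / max(v), nodes)
}

# --- parity fixtures and oracle
pgraph <- function(from, to, sign, nodes = NULL) {
  raw <- tibble::tibble(from = from, to = to, sign = sign)
  edges <- raw |>
    dplyr::group_by(from, to) |>
    dplyr::summarise(
      sign = regulonkit:::sign_label(
        unlist(regulonkit:::SIGN_SET[sign], use.names = FALSE)),
      provenance = list(paste0("e", dplyr::cur_group_id())),
      .groups = "drop") |>
    dplyr::arrange(from, to)
  structure(
    list(nodes = sort(unique(c(from, to, nodes))), edges = edges,
         options = list(hub_threshold = 10, physiological_only = FALSE,
                        include = regulonkit:::REG_CLASSES),
         excluded_hubs = character(0)),
    class = "parity_graph")
}

random_parity_graph <- function(seed, max_n = 30) {
  set.seed(seed)
  n <- sample(8:max_n, 1)
  nodes <- sprintf("v%02d", seq_len(n))
  m <- round(1.8 * n)
  from <- sample(nodes, m, replace = TRUE)
  to <- sample(nodes, m, replace = TRUE)
  if (seed %% 3 == 0) {   # every third graph is a DAG
    keep <- match(from, nodes) < match(to, nodes)
    from <- from[keep]; to <- to[keep]
  }
  sgn <- sample(c("+", "-", "+-"), length(from), replace = TRUE,
                prob = c(0.45, 0.45, 0.1))
  pgraph(from, to, sgn, nodes = nodes)
}

# Exhaustive simple-path oracle for parity classification: igraph
# enumerates the simple paths; determination is iterated to fixpoint
# with the same deterministic schedule (lexicographic sweeps, first
# conflicted node pruned, recompute from scratch).
oracle_parity_classify <- function(pg, target, depth = 6) {
  ig <- igraph::graph_from_data_frame(pg$edges[, c("from", "to")],
                                      directed = TRUE, vertices = pg$nodes)
  esign <- regulonkit:::SIGN_SET[pg$edges$sign]
  names(esign) <- paste(pg$edges$from, pg$edges$to, sep = "\r")
  path_signs <- function(vs) {
    acc <- 1L
    for (i in seq_len(length(vs) - 1)) {
      s <- esign[[paste(vs[i], vs[i + 1], sep = "\r")]]
      acc <- unique(as.integer(as.vector(outer(acc, s))))
    }
    acc
  }
  candidates <- sort(setdiff(pg$nodes, target))
  pruned <- character(0)
  repeat {
    sigma <- list()
    determined <- character(0)
    conflict <- NULL
    repeat {
      changed <- FALSE
      for (u in setdiff(candidates, pruned)) {
        sp <- suppressWarnings(igraph::all_simple_paths(
          ig, from = u, to = target, mode = "out", cutoff = depth))
        signs <- integer(0)
        for (pth in sp) {
          vs <- igraph::as_ids(pth)
          mids <- vs[-c(1, length(vs))]
          if (length(mids) == 0 ||
              (all(mids %in% determined) && !any(mids %in% pruned))) {
            signs <- unique(c(signs, path_signs(vs)))
          }
          if (length(signs) == 2) break
        }
        if (length(signs) == 2) { conflict <- u; break }
        if (length(signs) == 1 && !identical(sigma[[u]], signs)) {
          sigma[[u]] <- signs
          determined <- c(determined, u)
          changed <- TRUE
        }
      }
      if (!is.null(conflict) || !changed) break
    }
    if (is.null(conflict)) break
    pruned <- c(pruned, conflict)
  }
  sgn <- vapply(names(sigma), function(u) sigma[[u]], integer(1))
  list(activators = sort(names(sgn)[sgn == 1L]),
       inhibitors = sort(names(sgn)[sgn == -1L]),
       unknown = sort(pruned))
}

expect_same_classification <- function(cls, oracle) {
  expect_identical(cls$activators, oracle$activators)
  expect_identical(cls$inhibitors, oracle$inhibitors)
  expect_identical(cls$unknown, oracle$unknown)
}

# --- enrichment oracle: exhaustive subset enumeration
oracle_hyper_tail <- function(N, K, n, k) {
  combs <- utils::combn(N, n)
  hits <- colSums(combs <= K)
  mean(hits >= k)
}

small_params <- function(...) {
  synth_params(n_genes = 60, hub_degree = 4, ...)
}
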
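# Eigenvector influence ranking by the power method.

#' Rank genes by regulatory influence
#'
#' Scores every gene of a network by the dominant eigenvector of the
#' regulation adjacency matrix, a simplified PageRank. The adjacency
#' matrix has `A[i, j] = 1` iff gene i regulates gene j (edge labels are
#' ignored: activators and repressors count equally). Under
#' `normalization = "regulator-count"` each column j is divided by the
#' number of distinct regulators of j, so being the sole regulator of a
#' gene carries full weight while one of k co-regulators carries 1/k. The
#' score vector is iterated as `s <- (1 - damping) * (M + I) s + damping *
#' u` (u uniform), L1-normalising each step, until the L1 change drops
#' below `tolerance`; the identity shift suppresses period-two
#' oscillation on cyclic structures without changing eigenvectors. Final
#' scores are rescaled so the top gene scores exactly 100.
#'
#' @param network A non-empty `gene_network`.
#' @param normalization `"regulator-count"` (default) or `"none"`.
#' @param damping Damping weight in `[0, 1)`; default `0.001`.
#' @param tolerance Convergence threshold on the L1 step change.
#' @param max_iterations Iteration cap.
#' @return A `reg_influence` object: `score` (named, max 100),
#'   `direct_targets` (named out-degrees), `ranking` (gene ids, score
#'   descending, ties lexicographic), `iterations_used`, `converged`, and
#'   the options used. `tidy()` turns it into a tibble.
#' @export
influence_scores <- function(network,
                             normalization = c("regulator-count", "none"),
                             damping = 0.001, tolerance = 1e-12,
                             max_iterations = 100000L) {
  stopifnot(inherits(network, "gene_network"))
  normalization <- match.arg(normalization)
  stopifnot(damping >= 0, damping < 1, tolerance > 0, max_iterations >= 1)
  nodes <- network$nodes
  n <- length(nodes)
  if (n == 0) stop("network has no nodes", call. = FALSE)

  M <- influence_matrix(network, normalization)
  s <- rep(1 / n, n)
  u <- rep(1 / n, n)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iterations) {
    iter <- iter + 1L
    s_new <- (1 - damping) * (as.numeric(M %*% s) + s) + damping * u
    s_new <- s_new / sum(abs(s_new))
    delta <- sum(abs(s_new - s))
    s <- s_new
    if (delta < tolerance) { converged <- TRUE; break }
  }
  if (!converged && damping == 0) {
    stop("power iteration did not converge in ", max_iterations,
         " iterations at damping = 0; use a small positive damping ",
         "(e.g. 0.001)", call. = FALSE)
  }
  if (!converged) {
    warning("power iteration stopped before reaching tolerance", call. = FALSE)
  }

  score <- 100 * (s / max(s))
  names(score) <- nodes
  direct <- network_out_degree(network)
  ranking <- nodes[order(-score, nodes)]
  structure(
    list(score = score, direct_targets = direct, ranking = ranking,
         iterations_used = iter, converged = converged,
         options = list(normalization = normalization, damping = damping,
                        tolerance = tolerance,
                        max_iterations = max_iterations)),
    class = "reg_influence")
}

# Sparse iteration matrix: M[i, j] = A[i, j] (optionally / in-degree of j).
influence_matrix <- function(network, normalization) {
  nodes <- network$nodes
  n <- length(nodes)
  e <- network$edges
  if (nrow(e) == 0) {
    return(Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                dims = c(n, n)))
  }
  i <- match(e$from, nodes)
  j <- match(e$to, nodes)
  x <- rep(1, nrow(e))
  if (normalization == "regulator-count") {
    indeg <- table(j)
    x <- 1 / as.numeric(indeg[as.character(j)])
  }
  Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(n, n))
}

#' @export
print.reg_influence <- function(x, ...) {
  cat("<reg_influence: ", length(x$score), " genes, ",
      x$iterations_used, " iterations",
      if (!x$converged) " (not converged)", ">\n", sep = "")
  print(utils::head(tidy.reg_influence(x), 10))
  invisible(x)
}

#' Format the top of an influence ranking
#'
#' Returns the `top_n` highest-influence genes with display-formatted
#' scores: two significant figures below 10, integers at 10 and above
#' (so 100, 44, 8.2, 1.6). If a model is supplied, a product-role column
#' is derived from the gene's product.
#'
#' @param result A `reg_influence` object.
#' @param top_n Number of rows (all rows if larger than the gene count).
#' @param model Optional [regulatory_model()] for the product-role column.
#' @return A tibble with columns `rank`, `gene`, `product_role`, `score`,
#'   `score_printed`, `direct_targets`.
#' @export
rank_table <- function(result, top_n = 20L, model = NULL) {
  stopifnot(inherits(result, "reg_influence"))
  genes <- utils::head(result$ranking, top_n)
  role <- rep(NA_character_, length(genes))
  if (!is.null(model)) {
    role <- vapply(genes, function(g) {
      gr <- entity_record(model, "genes", g)
      if (is.null(gr) || is.na(gr$product_id)) return(NA_character_)
      p <- entity_record(model, "products", gr$product_id)
      if (is.null(p)) NA_character_ else paste0(p$kind, " ", p$id)
    }, character(1))
  }
  sc <- unname(result$score[genes])
  tibble::tibble(
    rank = seq_along(genes),
    gene = genes,
    product_role = role,
    score = sc,
    score_printed = format_influence_score(sc),
    direct_targets = unname(result$direct_targets[genes])
  )
}

format_influence_score <- function(x) {
  vapply(x, function(v) {
    if (v >= 10) sprintf("%d", round(v))
    else format(signif(v, 2))
  }, character(1))
}
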
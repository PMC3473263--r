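# XGMML export/import for Cytoscape.

XGMML_NS <- "http://www.cs.rpi.edu/XGMML"

#' Write a gene network as XGMML
#'
#' Produces a Cytoscape-importable XGMML 1.0 document: one directed
#' `<graph>`, one `<node>` per gene (numeric ids assigned in sorted
#' gene-id order; the gene id is the label, which Cytoscape keys on), and
#' one `<edge>` per regulatory edge carrying a string attribute `mode`
#' (activation/inhibition/dual/unknown) and a list attribute
#' `provenance` with the contributing regulation ids. If a layout is
#' supplied, each node gets `<graphics x= y=>` coordinates.
#'
#' @param network A non-empty `gene_network`.
#' @param path Output path.
#' @param layout Optional `reg_layout` covering exactly the network's
#'   nodes.
#' @param label Graph label (defaults to the include flags).
#' @return Invisibly, `path`.
#' @export
write_xgmml <- function(network, path, layout = NULL, label = NULL) {
  stopifnot(inherits(network, "gene_network"))
  if (length(network$nodes) == 0) {
    stop("cannot export an empty network", call. = FALSE)
  }
  if (is.null(label)) {
    label <- paste0("regulatory-network[",
                    paste(network$include, collapse = "+"), "]")
  }
  coords <- NULL
  if (!is.null(layout)) {
    extra <- setdiff(layout$gene, network$nodes)
    if (length(extra)) {
      stop("layout contains node(s) missing from the network: ",
           paste(utils::head(extra, 5), collapse = ", "), call. = FALSE)
    }
    missing <- setdiff(network$nodes, layout$gene)
    if (length(missing)) {
      stop("layout lacks coordinates for node(s): ",
           paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
    }
    coords <- layout[match(network$nodes, layout$gene), ]
  }

  doc <- xml2::xml_new_root("graph", label = label, directed = "1",
                            xmlns = XGMML_NS)
  xml2::xml_add_child(doc, "att", name = "include", type = "string",
                      value = paste(network$include, collapse = ","))
  node_id <- stats::setNames(seq_along(network$nodes), network$nodes)
  for (i in seq_along(network$nodes)) {
    g <- network$nodes[i]
    nd <- xml2::xml_add_child(doc, "node", id = as.character(i), label = g)
    if (!is.null(coords)) {
      xml2::xml_add_child(nd, "graphics", type = "ELLIPSE",
                          x = format(coords$x[i], digits = 10),
                          y = format(coords$y[i], digits = 10))
    }
  }
  e <- network$edges
  for (i in seq_len(nrow(e))) {
    ed <- xml2::xml_add_child(
      doc, "edge",
      label = paste0(e$from[i], " (", e$mode[i], ") ", e$to[i]),
      source = as.character(node_id[[e$from[i]]]),
      target = as.character(node_id[[e$to[i]]]))
    xml2::xml_add_child(ed, "att", name = "mode", type = "string",
                        value = e$mode[i])
    lst <- xml2::xml_add_child(ed, "att", name = "provenance", type = "list")
    for (pv in e$provenance[[i]]) {
      xml2::xml_add_child(lst, "att", name = "provenance", type = "string",
                          value = pv)
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read a gene network from an XGMML file
#'
#' Inverse of [write_xgmml()]: recovers nodes (by label), directed edges,
#' mode labels and provenance exactly. Refuses undirected graphs and
#' unknown mode strings.
#'
#' @param path Path to an XGMML file produced by [write_xgmml()] or an
#'   equivalent dialect.
#' @return A `gene_network`.
#' @export
read_xgmml <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  directed <- xml2::xml_attr(doc, "directed")
  if (is.na(directed) || directed != "1") {
    stop("XGMML graph is not directed", call. = FALSE)
  }
  nodes <- xml2::xml_find_all(doc, "./node")
  ids <- xml2::xml_attr(nodes, "id")
  labels <- xml2::xml_attr(nodes, "label")
  labels[is.na(labels)] <- ids[is.na(labels)]
  label_of <- stats::setNames(labels, ids)

  include <- xml2::xml_attr(
    xml2::xml_find_first(doc, "./att[@name='include']"), "value")
  include <- if (is.na(include)) character(0)
             else strsplit(include, ",", fixed = TRUE)[[1]]

  edges <- xml2::xml_find_all(doc, "./edge")
  rows <- purrr::map(edges, function(ed) {
    src <- xml2::xml_attr(ed, "source")
    tgt <- xml2::xml_attr(ed, "target")
    mode <- xml2::xml_attr(
      xml2::xml_find_first(ed, "./att[@name='mode']"), "value")
    if (is.na(mode)) mode <- "unknown"
    if (!mode %in% EDGE_MODES) {
      stop("unknown edge mode '", mode, "'", call. = FALSE)
    }
    prov <- xml2::xml_attr(
      xml2::xml_find_all(ed, "./att[@type='list']/att"), "value")
    tibble::tibble(from = label_of[[src]], to = label_of[[tgt]],
                   mode = mode,
                   provenance = list(sort(unique(prov))))
  })
  e <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(from = character(0), to = character(0),
                   mode = character(0), provenance = list())
  new_gene_network(labels, e, include)
}

#' Write a layout as TSV
#'
#' @param layout A `reg_layout`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_layout_tsv <- function(layout, path) {
  utils::write.table(as.data.frame(layout), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
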
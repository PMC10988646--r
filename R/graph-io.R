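# GEXF 1.2 and GraphML export/import for phenotype networks.
# Node attributes: kind (phenotype_hub/mirna/gene), sign (pos/neg/none),
# degree; edge attribute: weight (also the native GEXF/GraphML edge
# weight). Layout coordinates are embedded when present (viz:position in
# GEXF; x/y data keys in GraphML).

#' Export a network to GEXF or GraphML
#'
#' Writes a valid GEXF 1.2 or GraphML document with node attributes
#' \code{kind}, \code{sign} and \code{degree} and edge attribute
#' \code{weight}; 2-D coordinates are embedded when the network carries
#' them. Output is deterministic: nodes and edges are written in their
#' stored order with 6-significant-digit numbers.
#'
#' @param net a \code{phenotype_network}
#' @param path output path
#' @param format \code{"gexf"} or \code{"graphml"}
#' @return \code{path}, invisibly.
#' @export
write_graph_file <- function(net, path, format = c("gexf", "graphml")) {
  stopifnot(inherits(net, "phenotype_network"))
  if (!is.character(format) || !all(format %in% c("gexf", "graphml"))) {
    usage_error(sprintf("unsupported graph format '%s' (use gexf or graphml)",
                        format[1]))
  }
  format <- match.arg(format)
  if (format == "gexf") write_gexf(net, path) else write_graphml(net, path)
  invisible(path)
}

node_frame <- function(net) {
  n <- net$nodes
  if (!is.null(net$coordinates)) {
    idx <- match(n$id, net$coordinates$id)
    n$x <- net$coordinates$x[idx]
    n$y <- net$coordinates$y[idx]
  }
  n
}

write_gexf <- function(net, path) {
  doc <- xml2::xml_new_root(
    "gexf",
    xmlns = "http://www.gexf.net/1.2draft",
    "xmlns:viz" = "http://www.gexf.net/1.2draft/viz",
    version = "1.2")
  graph <- xml2::xml_add_child(doc, "graph", defaultedgetype = "undirected")
  attrs <- xml2::xml_add_child(graph, "attributes", class = "node")
  xml2::xml_add_child(attrs, "attribute", id = "kind", title = "kind",
                      type = "string")
  xml2::xml_add_child(attrs, "attribute", id = "sign", title = "sign",
                      type = "string")
  xml2::xml_add_child(attrs, "attribute", id = "degree", title = "degree",
                      type = "integer")
  nodes_el <- xml2::xml_add_child(graph, "nodes")
  nf <- node_frame(net)
  for (i in seq_len(nrow(nf))) {
    nd <- xml2::xml_add_child(nodes_el, "node", id = nf$id[i],
                              label = nf$id[i])
    av <- xml2::xml_add_child(nd, "attvalues")
    xml2::xml_add_child(av, "attvalue", `for` = "kind", value = nf$kind[i])
    xml2::xml_add_child(av, "attvalue", `for` = "sign", value = nf$sign[i])
    xml2::xml_add_child(av, "attvalue", `for` = "degree",
                        value = as.character(nf$degree[i]))
    if (!is.null(nf$x) && is.finite(nf$x[i])) {
      xml2::xml_add_child(nd, "viz:position", x = fmt_num(nf$x[i]),
                          y = fmt_num(nf$y[i]), z = "0")
    }
  }
  edges_el <- xml2::xml_add_child(graph, "edges")
  e <- net$edges
  for (i in seq_len(nrow(e))) {
    xml2::xml_add_child(edges_el, "edge", id = as.character(i - 1L),
                        source = e$mirna[i], target = e$hub[i],
                        weight = fmt_num(e$weight[i]))
  }
  xml2::write_xml(doc, path)
}

write_graphml <- function(net, path) {
  doc <- xml2::xml_new_root(
    "graphml", xmlns = "http://graphml.graphdrawing.org/xmlns")
  key <- function(id, dom, type) {
    xml2::xml_add_child(doc, "key", id = id, `for` = dom,
                        `attr.name` = id, `attr.type` = type)
  }
  key("kind", "node", "string"); key("sign", "node", "string")
  key("degree", "node", "int")
  key("x", "node", "double"); key("y", "node", "double")
  key("weight", "edge", "double")
  graph <- xml2::xml_add_child(doc, "graph", id = "G",
                               edgedefault = "undirected")
  nf <- node_frame(net)
  for (i in seq_len(nrow(nf))) {
    nd <- xml2::xml_add_child(graph, "node", id = nf$id[i])
    data_el <- function(k, v) {
      d <- xml2::xml_add_child(nd, "data", key = k)
      xml2::xml_set_text(d, v)
    }
    data_el("kind", nf$kind[i]); data_el("sign", nf$sign[i])
    data_el("degree", as.character(nf$degree[i]))
    if (!is.null(nf$x) && is.finite(nf$x[i])) {
      data_el("x", fmt_num(nf$x[i])); data_el("y", fmt_num(nf$y[i]))
    }
  }
  e <- net$edges
  for (i in seq_len(nrow(e))) {
    ed <- xml2::xml_add_child(graph, "edge", source = e$mirna[i],
                              target = e$hub[i])
    d <- xml2::xml_add_child(ed, "data", key = "weight")
    xml2::xml_set_text(d, fmt_num(e$weight[i]))
  }
  xml2::write_xml(doc, path)
}

#' Read a network written by \code{\link{write_graph_file}}
#'
#' Recovers node ids, kind/sign/degree attributes, edge endpoints and
#' weights (and coordinates when embedded) from a GEXF 1.2 or GraphML
#' document produced by this package.
#'
#' @param path path to the graph file
#' @param format \code{"gexf"} or \code{"graphml"}
#' @return List with \code{nodes} and \code{edges} data.frames (and
#'   \code{coordinates} when present).
#' @export
read_graph_file <- function(path, format = c("gexf", "graphml")) {
  format <- match.arg(format)
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  if (format == "gexf") {
    nodes <- xml2::xml_find_all(doc, ".//nodes/node")
    get_att <- function(nd, id) {
      xml2::xml_attr(xml2::xml_find_first(
        nd, sprintf(".//attvalue[@for='%s']", id)), "value")
    }
    ndf <- data.frame(
      id = xml2::xml_attr(nodes, "id"),
      kind = vapply(nodes, get_att, character(1), id = "kind"),
      sign = vapply(nodes, get_att, character(1), id = "sign"),
      degree = as.integer(vapply(nodes, get_att, character(1), id = "degree")),
      stringsAsFactors = FALSE)
    pos <- lapply(nodes, function(nd) {
      xml2::xml_find_first(nd, ".//*[local-name()='position']")
    })
    has_pos <- !vapply(pos, inherits, logical(1), "xml_missing")
    coords <- NULL
    if (any(has_pos)) {
      coords <- data.frame(
        id = ndf$id[has_pos],
        x = as.numeric(vapply(pos[has_pos], xml2::xml_attr, character(1), "x")),
        y = as.numeric(vapply(pos[has_pos], xml2::xml_attr, character(1), "y")),
        stringsAsFactors = FALSE)
    }
    edges <- xml2::xml_find_all(doc, ".//edges/edge")
    edf <- data.frame(
      mirna = xml2::xml_attr(edges, "source"),
      hub = xml2::xml_attr(edges, "target"),
      weight = as.numeric(xml2::xml_attr(edges, "weight")),
      stringsAsFactors = FALSE)
  } else {
    nodes <- xml2::xml_find_all(doc, ".//graph/node")
    get_key <- function(nd, k) {
      xml2::xml_text(xml2::xml_find_first(nd, sprintf(".//data[@key='%s']", k)))
    }
    ndf <- data.frame(
      id = xml2::xml_attr(nodes, "id"),
      kind = vapply(nodes, get_key, character(1), k = "kind"),
      sign = vapply(nodes, get_key, character(1), k = "sign"),
      degree = as.integer(vapply(nodes, get_key, character(1), k = "degree")),
      stringsAsFactors = FALSE)
    xs <- vapply(nodes, get_key, character(1), k = "x")
    coords <- NULL
    if (any(!is.na(xs))) {
      ys <- vapply(nodes, get_key, character(1), k = "y")
      keep <- !is.na(xs)
      coords <- data.frame(id = ndf$id[keep], x = as.numeric(xs[keep]),
                           y = as.numeric(ys[keep]), stringsAsFactors = FALSE)
    }
    edges <- xml2::xml_find_all(doc, ".//graph/edge")
    edf <- data.frame(
      mirna = xml2::xml_attr(edges, "source"),
      hub = xml2::xml_attr(edges, "target"),
      weight = as.numeric(vapply(edges, get_key, character(1), k = "weight")),
      stringsAsFactors = FALSE)
  }
  out <- list(nodes = ndf, edges = edf)
  if (!is.null(coords)) out$coordinates <- coords
  out
}
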
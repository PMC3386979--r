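# GraphML export/import: undirected graphs, a string node attribute "mode"
# (drug/target) and an integer edge attribute "weight".  Writing emits a
# fixed canonical layout so outputs are diffable and byte-stable; reading
# goes through xml2.

.xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub("\"", "&quot;", x, fixed = TRUE)
}

.graphml_lines <- function(node_ids, node_modes, from, to, weight) {
  c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
    '  <key id="d_mode" for="node" attr.name="mode" attr.type="string"/>',
    '  <key id="d_weight" for="edge" attr.name="weight" attr.type="int"/>',
    '  <graph id="G" edgedefault="undirected">',
    sprintf('    <node id="%s"><data key="d_mode">%s</data></node>',
            .xml_escape(node_ids), node_modes),
    if (length(from) > 0L) {
      sprintf(paste0('    <edge source="%s" target="%s">',
                     '<data key="d_weight">%d</data></edge>'),
              .xml_escape(from), .xml_escape(to), as.integer(weight))
    },
    '  </graph>',
    '</graphml>'
  )
}

#' Write a network in GraphML
#'
#' Undirected GraphML with a \code{mode} node attribute (\code{drug} or
#' \code{target}) and an integer \code{weight} edge attribute.  Accepts
#' either a two-mode \code{bipartite_network} (cross-edges carry the
#' interaction-frequency weight) or a one-mode \code{projected_network}
#' (edges carry shared-partner counts).  Output layout is canonical, so
#' write-read-write is byte-stable.
#'
#' @param x a \code{bipartite_network} or \code{projected_network}.
#' @param path file path.
#' @export
write_graphml <- function(x, path) {
  if (inherits(x, "bipartite_network")) {
    lines <- .graphml_lines(
      node_ids = c(x$drugs, x$targets),
      node_modes = c(rep("drug", length(x$drugs)),
                     rep("target", length(x$targets))),
      from = x$edges$drug, to = x$edges$target, weight = x$edges$weight
    )
  } else if (inherits(x, "projected_network")) {
    lines <- .graphml_lines(
      node_ids = x$nodes, node_modes = rep(x$mode, length(x$nodes)),
      from = x$edges$from, to = x$edges$to, weight = x$edges$weight
    )
  } else {
    stop("x must be a bipartite_network or projected_network", call. = FALSE)
  }
  writeLines(lines, path, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Read a network from GraphML
#'
#' Inverse of \code{\link{write_graphml}}.  A document whose nodes carry
#' both \code{drug} and \code{target} modes is returned as a
#' \code{bipartite_network}; a single-mode document as a
#' \code{projected_network}.
#'
#' @param path file path.
#' @return A \code{bipartite_network} or \code{projected_network}.
#' @export
read_graphml <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  graph <- xml2::xml_find_first(doc, ".//graph")
  if (inherits(graph, "xml_missing")) {
    stop(sprintf("%s: no <graph> element", path), call. = FALSE)
  }
  if (!identical(xml2::xml_attr(graph, "edgedefault"), "undirected")) {
    stop("directed networks unsupported (edgedefault is not undirected)",
         call. = FALSE)
  }
  nodes <- xml2::xml_find_all(graph, "./node")
  ids <- xml2::xml_attr(nodes, "id")
  modes <- xml2::xml_text(xml2::xml_find_first(nodes,
                                               "./data[@key='d_mode']"))
  if (anyNA(ids) || anyNA(modes) || !all(modes %in% c("drug", "target"))) {
    stop(sprintf("%s: every node needs an id and a drug/target mode", path),
         call. = FALSE)
  }
  edges <- xml2::xml_find_all(graph, "./edge")
  src <- xml2::xml_attr(edges, "source")
  tgt <- xml2::xml_attr(edges, "target")
  w <- xml2::xml_text(xml2::xml_find_first(edges,
                                           "./data[@key='d_weight']"))
  w <- suppressWarnings(as.integer(w))
  if (length(edges) > 0L && (anyNA(src) || anyNA(tgt) || anyNA(w))) {
    stop(sprintf("%s: every edge needs source, target and integer weight",
                 path), call. = FALSE)
  }
  if (all(c("drug", "target") %in% modes)) {
    drugs <- ids[modes == "drug"]
    targets <- ids[modes == "target"]
    src_is_drug <- src %in% drugs
    d <- ifelse(src_is_drug, src, tgt)
    t <- ifelse(src_is_drug, tgt, src)
    if (!all(d %in% drugs) || !all(t %in% targets)) {
      stop(sprintf("%s: two-mode edges must join a drug and a target", path),
           call. = FALSE)
    }
    if (length(d) == 0L) {
      return(structure(
        list(drugs = drugs, targets = targets,
             edges = data.frame(drug = character(), target = character(),
                                weight = integer(),
                                stringsAsFactors = FALSE)),
        class = "bipartite_network"
      ))
    }
    net <- build_bipartite(drug_target_pairs(d, t, w))
    # preserve the document's node order, including nodes without edges
    net$drugs <- drugs
    net$targets <- targets
    net
  } else {
    projected_network(mode = modes[1L], nodes = ids,
                      from = src, to = tgt, weight = w)
  }
}
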
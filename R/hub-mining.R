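#' Export one module as a weighted network
#'
#' Nodes are the module's members that keep at least one edge; edges are
#' member pairs whose topological overlap exceeds the threshold (or, with
#' `n_top_edges`, the strongest edges by weight, a density-controlled export
#' that is comparable across module sizes). Node connectivity is the sum of
#' retained incident edge weights.
#'
#' @param tom OTU x OTU TOM matrix (dimnames = OTU ids).
#' @param labels OTU -> module colour vector.
#' @param module module colour to export.
#' @param weight_threshold retain edges with TOM strictly above this value
#'   (in [0, 1]; 1 keeps nothing).
#' @param n_top_edges if non-NULL, retain this many strongest edges instead
#'   of thresholding (default export uses `3 * module size`).
#' @param genus optional named character vector OTU -> genus annotation.
#' @return object of class `weighted_network`: `nodes` (id, genus,
#'   connectivity) and `edges` (from, to, weight).
#' @export
export_module_network <- function(tom, labels, module, weight_threshold = 0,
                                  n_top_edges = NULL, genus = NULL) {
  if (!module %in% labels) stopf("unknown module '%s'", module)
  if (is.null(n_top_edges) &&
      (weight_threshold < 0 || weight_threshold > 1)) {
    stopf("`weight_threshold` must be in [0, 1]")
  }
  members <- names(labels)[labels == module]
  if (is.null(members)) members <- which(labels == module)
  sub <- tom[members, members, drop = FALSE]
  idx <- which(upper.tri(sub), arr.ind = TRUE)
  edges <- data.frame(from = members[idx[, 1]], to = members[idx[, 2]],
                      weight = sub[idx], stringsAsFactors = FALSE)
  edges <- if (!is.null(n_top_edges)) {
    edges <- edges[order(-edges$weight, edges$from, edges$to), , drop = FALSE]
    utils::head(edges[edges$weight > 0, , drop = FALSE], n_top_edges)
  } else {
    edges[edges$weight > weight_threshold, , drop = FALSE]
  }
  rownames(edges) <- NULL
  touched <- unique(c(edges$from, edges$to))
  ids <- members[members %in% touched]
  nodes <- data.frame(
    id = ids,
    genus = if (is.null(genus)) rep(NA_character_, length(ids)) else
      unname(genus[ids]),
    connectivity = vapply(ids, function(v) {
      sum(edges$weight[edges$from == v | edges$to == v])
    }, numeric(1)),
    stringsAsFactors = FALSE
  )
  structure(list(nodes = nodes, edges = edges), class = "weighted_network")
}

#' @export
print.weighted_network <- function(x, ...) {
  cat(sprintf("<weighted_network> %d nodes, %d edges\n",
              nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

as_igraph <- function(network) {
  igraph::graph_from_data_frame(network$edges, directed = FALSE,
                                vertices = network$nodes)
}

#' Maximal neighbourhood component centrality
#'
#' Size of the largest connected component of the subgraph induced by the
#' open neighbourhood of a node (the node itself excluded), computed on the
#' thresholded, unweighted graph. Isolated nodes score 0.
#'
#' @param network a `weighted_network`.
#' @param node node id, or `NULL` for all nodes.
#' @return integer MNC score(s), named when computed for all nodes.
#' @export
mnc <- function(network, node = NULL) {
  g <- as_igraph(network)
  score_one <- function(v) {
    nb <- igraph::neighbors(g, v)
    if (length(nb) == 0) return(0L)
    sub <- igraph::induced_subgraph(g, nb)
    max(igraph::components(sub)$csize)
  }
  if (!is.null(node)) {
    if (!node %in% network$nodes$id) stopf("node '%s' not in network", node)
    return(as.integer(score_one(node)))
  }
  stats::setNames(vapply(network$nodes$id, function(v) as.integer(score_one(v)),
                         integer(1)), network$nodes$id)
}

#' Top hub nodes by MNC
#'
#' Nodes ranked by (MNC descending, weighted connectivity descending, id
#' ascending); the first `k` are returned with their genus annotations. The
#' genus list preserves order of first appearance.
#'
#' @param network a `weighted_network`.
#' @param k number of hubs (default 10).
#' @return data.frame: rank, id, genus, mnc, connectivity.
#' @export
top_hubs <- function(network, k = 10) {
  assert_count(k, "k")
  if (nrow(network$edges) == 0) stopf("network has no edges")
  scores <- mnc(network)
  nd <- network$nodes
  ord <- order(-scores[nd$id], -nd$connectivity, nd$id)
  if (k > nrow(nd)) {
    warning(sprintf("k = %d exceeds node count %d; returning all", k, nrow(nd)))
    k <- nrow(nd)
  }
  sel <- ord[seq_len(k)]
  data.frame(rank = seq_len(k), id = nd$id[sel], genus = nd$genus[sel],
             mnc = as.integer(scores[nd$id[sel]]),
             connectivity = nd$connectivity[sel],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write a weighted network as edge-list / node TSVs (and SIF)
#'
#' @param network a `weighted_network`.
#' @param edge_path,node_path,sif_path output paths (`NULL` to skip).
#' @export
write_network <- function(network, edge_path = NULL, node_path = NULL,
                          sif_path = NULL) {
  if (!is.null(edge_path)) {
    e <- network$edges
    names(e) <- c("source", "target", "weight")
    utils::write.table(e, edge_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(node_path)) {
    n <- network$nodes
    n$mnc <- as.integer(mnc(network)[n$id])
    utils::write.table(n[, c("id", "genus", "mnc", "connectivity")],
                       node_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(sif_path)) {
    writeLines(sprintf("%s\tco\t%s", network$edges$from, network$edges$to),
               sif_path)
  }
  invisible(network)
}
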
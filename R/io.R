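# Graph and table exports for fitted networks.

#' Export a network's weighted edge list as CSV
#'
#' Columns \code{item_a}, \code{item_b}, \code{pcor}; only nonzero edges.
#'
#' @param network A \code{"symptom_network"}.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_edge_list <- function(network, path) {
  stopifnot(inherits(network, "symptom_network"))
  write.csv(summary(network)$edges, path, row.names = FALSE)
  invisible(path)
}

#' Export strength centrality as CSV
#'
#' @param network A \code{"symptom_network"}.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_centrality <- function(network, path) {
  write.csv(strength_centrality(network), path, row.names = FALSE)
  invisible(path)
}

network_igraph <- function(network, seed = 42L) {
  g <- igraph::graph_from_adjacency_matrix(abs(network$pcor),
                                           mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  if (igraph::ecount(g) > 0) {
    el <- igraph::as_edgelist(g, names = FALSE)
    igraph::E(g)$pcor <- network$pcor[el]
  }
  lay <- network_layout(network, seed = seed)
  igraph::V(g)$name <- network$items
  igraph::V(g)$x <- lay$x
  igraph::V(g)$y <- lay$y
  g
}

#' Export a network as GraphML
#'
#' Nodes carry the layout coordinates (unit square); edges carry both the
#' absolute weight and the signed partial correlation.
#'
#' @param network A \code{"symptom_network"}.
#' @param path Output path.
#' @param seed Layout seed.
#' @return The path, invisibly.
#' @export
write_graphml <- function(network, path, seed = 42L) {
  igraph::write_graph(network_igraph(network, seed), path,
                      format = "graphml")
  invisible(path)
}

#' Export a network as node-link JSON
#'
#' JSON object with \code{nodes} (id, label, x, y, strength) and
#' \code{links} (source/target as 1-based node indices, signed pcor weight).
#'
#' @param network A \code{"symptom_network"}.
#' @param path Output path.
#' @param seed Layout seed.
#' @return The path, invisibly.
#' @export
write_network_json <- function(network, path, seed = 42L) {
  lay <- network_layout(network, seed = seed)
  cent <- strength_centrality(network)
  pc <- network$pcor
  idx <- which(upper.tri(pc) & pc != 0, arr.ind = TRUE)
  links <- data.frame(source = idx[, 1], target = idx[, 2],
                      weight = pc[idx])
  payload <- list(
    nodes = data.frame(id = seq_along(network$items),
                       label = network$items,
                       x = lay$x, y = lay$y,
                       strength = cent$strength),
    links = links,
    method = network$method, n = network$n)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
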
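#' Effective graph of a Boolean network
#'
#' The interaction graph weighted by per-input *effectiveness*: edge `j -> i`
#' carries `e_ji`, the probability-like weight in `[0, 1]` that input `j`
#' actually matters for node `i`'s transition (the complement of the per-input
#' redundancy from [canalization()]). A fully redundant input — one the output
#' never depends on — has `e_ji = 0` and is dropped when `prune_zero = TRUE`,
#' so the effective graph is a subgraph of the interaction graph exposing the
#' pathways that truly drive the dynamics. Under the `"mean"` node-level
#' convention the in-weights of node `i` sum exactly to its effective
#' connectivity `k_e`.
#'
#' @param net A [boolean_network()].
#' @param prune_zero Drop edges with `e_ji = 0` (default); otherwise keep them
#'   with weight 0.
#' @return An object of class `effective_graph` wrapping an `igraph` whose
#'   edges carry a `weight` attribute.
#' @examples
#' eg <- effective_graph(boolean_network(list(
#'   lut_xor(name = "a", inputs = c("a", "b")),
#'   lut_xor(name = "b", inputs = c("a", "b")))))
#' @export
effective_graph <- function(net, prune_zero = TRUE) {
  stopifnot(inherits(net, "boolean_network"))
  edges <- NULL
  w <- numeric(0)
  for (nd in net$nodes) {
    if (nd$k == 0L) next
    e <- canalization(nd)$per_input$e
    keep <- if (prune_zero) e > 0 else rep(TRUE, nd$k)
    if (!any(keep)) next
    edges <- rbind(edges, cbind(nd$inputs[keep], nd$name))
    w <- c(w, e[keep])
  }
  g <- igraph::make_empty_graph(net$N, directed = TRUE)
  g <- igraph::set_vertex_attr(g, "name", value = net$names)
  if (!is.null(edges)) {
    g <- igraph::add_edges(g, t(edges))
    g <- igraph::set_edge_attr(g, "weight", value = w)
  }
  structure(list(graph = g, pruned = prune_zero), class = "effective_graph")
}

#' @export
print.effective_graph <- function(x, ...) {
  g <- x$graph
  cat(sprintf("Effective graph: %d nodes, %d edges%s\n",
              igraph::vcount(g), igraph::ecount(g),
              if (x$pruned) " (zero-effectiveness edges pruned)" else ""))
  if (igraph::ecount(g) > 0L) {
    el <- igraph::as_edgelist(g)
    df <- data.frame(from = el[, 1L], to = el[, 2L],
                     e = round(igraph::E(g)$weight, 4))
    print(utils::head(df[order(-df$e), ], 10L), row.names = FALSE)
  }
  invisible(x)
}
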
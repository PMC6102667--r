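#' Export a graph as DOT or GraphML text
#'
#' Serializes an [effective_graph()], [build_stg()]/[build_cstg()] transition
#' graph, or [canalizing_map()] for external rendering (e.g. Graphviz) or
#' downstream analysis. Output is deterministic — identical graphs export to
#' identical bytes — with vertices in declaration order and edges sorted.
#' Edge weights, edge kinds, t-unit thresholds and s-unit states are carried
#' as attributes.
#'
#' @param x The graph object.
#' @param format `"dot"` or `"graphml"`.
#' @param file Optional path; when given, the text is also written there.
#' @param ... Unused.
#' @return The serialized text as a single string, invisibly when `file` is
#'   given.
#' @export
export_graph <- function(x, format = c("dot", "graphml"), file = NULL, ...) {
  UseMethod("export_graph")
}

#' @export
export_graph.effective_graph <- function(x, format = c("dot", "graphml"),
                                         file = NULL, ...) {
  format <- match.arg(format)
  el <- igraph_edge_frame(x$graph, weight = TRUE)
  emit_graph(igraph::V(x$graph)$name, el, format, file,
             vattr = list(), eattr = c("weight"))
}

#' @export
export_graph.transition_graph <- function(x, format = c("dot", "graphml"),
                                          file = NULL, ...) {
  format <- match.arg(format)
  el <- igraph_edge_frame(x$graph, kind = TRUE)
  emit_graph(igraph::V(x$graph)$name, el, format, file,
             vattr = list(), eattr = c("kind"))
}

#' @export
export_graph.canalizing_map <- function(x, format = c("dot", "graphml"),
                                        file = NULL, ...) {
  format <- match.arg(format)
  u <- x$units
  el <- x$edges[order(x$edges$from, x$edges$to, x$edges$kind), , drop = FALSE]
  vattr <- list(kind = u$kind,
                state = ifelse(is.na(u$state), "", u$state),
                threshold = ifelse(is.na(u$threshold), "", u$threshold))
  emit_graph(u$id, el, format, file, vattr = vattr, eattr = "kind")
}

#' @export
export_graph.igraph <- function(x, format = c("dot", "graphml"),
                                file = NULL, ...) {
  format <- match.arg(format)
  nm <- igraph::V(x)$name
  if (is.null(nm)) nm <- as.character(seq_len(igraph::vcount(x)))
  has_w <- "weight" %in% igraph::edge_attr_names(x)
  el <- igraph_edge_frame(x, weight = has_w)
  emit_graph(nm, el, format, file,
             vattr = list(), eattr = if (has_w) "weight" else character(0))
}

igraph_edge_frame <- function(g, weight = FALSE, kind = FALSE) {
  el <- igraph::as_edgelist(g)
  df <- data.frame(from = el[, 1L], to = el[, 2L], stringsAsFactors = FALSE)
  if (weight) df$weight <- igraph::E(g)$weight
  if (kind) df$kind <- igraph::E(g)$kind
  ord <- order(df$from, df$to)
  df[ord, , drop = FALSE]
}

quote_dot <- function(x) paste0("\"", gsub("\"", "\\\\\"", x), "\"")

emit_graph <- function(vnames, edges, format, file, vattr, eattr) {
  txt <- if (format == "dot") emit_dot(vnames, edges, vattr, eattr)
         else emit_graphml(vnames, edges, vattr, eattr)
  if (!is.null(file)) {
    writeLines(txt, file, sep = "")
    return(invisible(txt))
  }
  txt
}

emit_dot <- function(vnames, edges, vattr, eattr) {
  lines <- "digraph G {"
  for (i in seq_along(vnames)) {
    attrs <- vapply(names(vattr), function(a)
      sprintf("%s=%s", a, quote_dot(vattr[[a]][i])), "")
    lines <- c(lines, sprintf("  %s%s;", quote_dot(vnames[i]),
                              if (length(attrs))
                                paste0(" [", paste(attrs, collapse = ", "), "]")
                              else ""))
  }
  for (i in seq_len(nrow(edges))) {
    attrs <- vapply(eattr, function(a)
      sprintf("%s=%s", a, quote_dot(format(edges[[a]][i], digits = 12))), "")
    lines <- c(lines, sprintf("  %s -> %s%s;",
                              quote_dot(edges$from[i]), quote_dot(edges$to[i]),
                              if (length(attrs))
                                paste0(" [", paste(attrs, collapse = ", "), "]")
                              else ""))
  }
  paste0(paste(c(lines, "}"), collapse = "\n"), "\n")
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

emit_graphml <- function(vnames, edges, vattr, eattr) {
  head <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    "<graphml xmlns=\"http://graphml.graphdrawing.org/xmlns\">")
  keys <- c(
    vapply(names(vattr), function(a) sprintf(
      "  <key id=\"v_%s\" for=\"node\" attr.name=\"%s\" attr.type=\"string\"/>",
      a, a), ""),
    vapply(eattr, function(a) sprintf(
      "  <key id=\"e_%s\" for=\"edge\" attr.name=\"%s\" attr.type=\"string\"/>",
      a, a), ""))
  body <- "  <graph id=\"G\" edgedefault=\"directed\">"
  for (i in seq_along(vnames)) {
    data <- vapply(names(vattr), function(a) sprintf(
      "      <data key=\"v_%s\">%s</data>", a,
      xml_escape(as.character(vattr[[a]][i]))), "")
    body <- c(body,
              sprintf("    <node id=\"%s\">", xml_escape(vnames[i])),
              data, "    </node>")
  }
  for (i in seq_len(nrow(edges))) {
    data <- vapply(eattr, function(a) sprintf(
      "      <data key=\"e_%s\">%s</data>", a,
      xml_escape(format(edges[[a]][i], digits = 12))), "")
    body <- c(body,
              sprintf("    <edge source=\"%s\" target=\"%s\">",
                      xml_escape(edges$from[i]), xml_escape(edges$to[i])),
              data, "    </edge>")
  }
  paste0(paste(c(head, keys, body, "  </graph>", "</graphml>"),
               collapse = "\n"), "\n")
}
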
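#' Boolean network
#'
#' A Boolean network is a directed graph of Boolean automata: each node carries
#' a [lookup_table()] whose inputs reference other nodes by name (the wiring
#' defines the interaction graph). Dynamics are synchronous: all automata
#' transition at the same time step.
#'
#' Network configurations (the joint state of all `N` automata) are encoded as
#' integers in `[0, 2^N)`, with the *first-declared node as the most
#' significant bit*.
#'
#' @param nodes A list of [lookup_table()] objects with unique names; every
#'   input name must resolve to a node.
#' @return An object of class `boolean_network` with fields `nodes` (named list
#'   of look-up tables), `names`, and `N`.
#' @examples
#' net <- boolean_network(list(lut_not(name = "x", inputs = "x")))
#' @export
boolean_network <- function(nodes) {
  stopifnot(is.list(nodes), length(nodes) > 0L,
            all(vapply(nodes, inherits, TRUE, "lookup_table")))
  nms <- vapply(nodes, `[[`, "", "name")
  if (anyDuplicated(nms)) {
    stop("duplicated node names: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "), call. = FALSE)
  }
  for (nd in nodes) {
    missing <- setdiff(nd$inputs, nms)
    if (length(missing)) {
      stop(sprintf("node '%s' references unknown input(s): %s",
                   nd$name, paste(missing, collapse = ", ")), call. = FALSE)
    }
  }
  names(nodes) <- nms
  structure(list(nodes = nodes, names = nms, N = length(nodes)),
            class = "boolean_network")
}

#' @export
print.boolean_network <- function(x, ...) {
  ks <- vapply(x$nodes, `[[`, 0L, "k")
  cat(sprintf("Boolean network: %d nodes, in-degrees %s\n", x$N,
              paste(range(ks), collapse = "-")))
  cat("  nodes:", paste(x$names, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.boolean_network <- function(object, ...) {
  ks <- vapply(object$nodes, `[[`, 0L, "k")
  data.frame(node = object$names, k = ks, row.names = NULL)
}

#' Interaction graph of a Boolean network
#'
#' The directed graph with an edge `j -> i` whenever node `j` is listed as an
#' input of node `i`, regardless of whether the input actually affects the
#' transition (compare [effective_graph()]).
#'
#' @param net A [boolean_network()].
#' @return An `igraph` directed graph whose vertices are the node names.
#' @export
interaction_graph <- function(net) {
  stopifnot(inherits(net, "boolean_network"))
  edges <- do.call(rbind, lapply(net$nodes, function(nd) {
    if (nd$k == 0L) return(NULL)
    cbind(nd$inputs, nd$name)
  }))
  g <- igraph::make_empty_graph(net$N, directed = TRUE)
  g <- igraph::set_vertex_attr(g, "name", value = net$names)
  if (!is.null(edges)) {
    g <- igraph::add_edges(g, t(edges))
  }
  g
}

#' Encode and decode network configurations
#'
#' Configurations map bijectively to integers in `[0, 2^N)`; the first-declared
#' node is the most significant bit.
#'
#' @param bits Integer vector over `{0,1}`, ordered by node declaration.
#' @param x Integer configuration encoding.
#' @param N Number of nodes.
#' @return `encode_config()` the integer encoding; `decode_config()` the bit
#'   vector.
#' @export
encode_config <- function(bits) bits_to_int(as.integer(bits))

#' @rdname encode_config
#' @export
decode_config <- function(x, N) int_to_bits(as.integer(x), N)

#' Synchronous update step
#'
#' Applies every node's look-up table to the current states of its inputs, all
#' at the same time step.
#'
#' @param net A [boolean_network()].
#' @param x A configuration: either an integer encoding or a bit vector of
#'   length `N` in declaration order.
#' @return The next configuration, in the same form as `x`.
#' @export
synchronous_step <- function(net, x) {
  stopifnot(inherits(net, "boolean_network"))
  bits <- if (length(x) == net$N && net$N > 1L) as.integer(x)
          else decode_config(x, net$N)
  stopifnot(length(bits) == net$N, all(bits %in% c(0L, 1L)))
  idx <- match(unlist(lapply(net$nodes, `[[`, "inputs")), net$names)
  nxt <- integer(net$N)
  off <- 0L
  for (i in seq_len(net$N)) {
    k <- net$nodes[[i]]$k
    states <- if (k > 0L) bits[idx[off + seq_len(k)]] else integer(0)
    nxt[i] <- net$nodes[[i]]$outputs[bits_to_int(states) + 1L]
    off <- off + k
  }
  if (length(x) == net$N) nxt else encode_config(nxt)
}

# successor of every configuration 0..2^N-1, vectorized; the synchronous map
successor_table <- function(net) {
  N <- net$N
  configs <- 0:(2L^N - 1L)
  succ <- integer(2L^N)
  for (i in seq_len(N)) {
    nd <- net$nodes[[i]]
    if (nd$k == 0L) {
      bit <- rep(nd$outputs, length(configs))
    } else {
      j <- match(nd$inputs, net$names)
      row <- integer(length(configs))
      for (p in seq_len(nd$k)) {
        row <- row + bitwAnd(bitwShiftR(configs, N - j[p]), 1L) *
          2L^(nd$k - p)
      }
      bit <- nd$outputs[row + 1L]
    }
    succ <- succ + bit * 2L^(N - i)
  }
  as.integer(succ)
}
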
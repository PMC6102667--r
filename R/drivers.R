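#' Driver set via structural controllability
#'
#' The structural-controllability heuristic estimates a minimal driver set
#' from the interaction graph alone: compute a maximum matching on the
#' bipartite out/in representation (an edge links the out-copy of `j` to the
#' in-copy of `i` whenever `j` inputs to `i`; self-inputs count); the nodes
#' whose in-copy is unmatched must be driven. If the matching is perfect, a
#' single control input suffices and the first-declared node is returned.
#'
#' @param net A [boolean_network()].
#' @return Character vector of driver node names (class preserved as a plain
#'   vector), deterministic for a given network.
#' @examples
#' sc_driver_set(load_example("motif_chain"))
#' @export
sc_driver_set <- function(net) {
  stopifnot(inherits(net, "boolean_network"))
  N <- net$N
  b <- igraph::make_empty_graph(2L * N, directed = FALSE)
  types <- rep(c(FALSE, TRUE), each = N)  # out-copies then in-copies
  edges <- NULL
  for (i in seq_len(N)) {
    js <- match(net$nodes[[i]]$inputs, net$names)
    if (length(js)) edges <- rbind(edges, cbind(js, N + i))
  }
  if (!is.null(edges)) b <- igraph::add_edges(b, t(edges))
  m <- igraph::max_bipartite_match(b, types = types)
  matched_in <- !is.na(m$matching[N + seq_len(N)])
  if (all(matched_in)) return(net$names[1L])
  net$names[!matched_in]
}

#' Driver set via minimum dominating set
#'
#' A dominating set of the interaction graph: every node is either in the set
#' or receives an edge from a member. Solved exactly by branch and bound for
#' networks up to `exact_limit` nodes (nodes with no incoming edge from
#' another node are forced into the set first); larger networks fall back to
#' the standard greedy cover, flagged via the `"exact"` attribute. Ties are
#' broken lexicographically on node declaration order, so the result is
#' deterministic.
#'
#' @param net A [boolean_network()].
#' @param exact_limit Largest `N` for which the exact search is attempted.
#' @return Character vector of node names with attribute `exact` (logical).
#' @export
mds_driver_set <- function(net, exact_limit = 25) {
  stopifnot(inherits(net, "boolean_network"))
  N <- net$N
  # dominates[[i]]: nodes dominated when i is picked (i itself + out-neighbors)
  out_nb <- lapply(seq_len(N), function(i) integer(0))
  in_nb <- lapply(seq_len(N), function(i) integer(0))
  for (i in seq_len(N)) {
    js <- match(net$nodes[[i]]$inputs, net$names)
    for (j in js) {
      out_nb[[j]] <- c(out_nb[[j]], i)
      in_nb[[i]] <- c(in_nb[[i]], j)
    }
  }
  dominates <- lapply(seq_len(N), function(i) unique(c(i, out_nb[[i]])))

  if (N > exact_limit) {
    sel <- greedy_dominating(dominates, N)
    res <- net$names[sort(sel)]
    attr(res, "exact") <- FALSE
    return(res)
  }

  # forced: nodes not dominated by any other node's pick
  forced <- which(vapply(seq_len(N), function(i)
    length(setdiff(in_nb[[i]], i)) == 0L, TRUE))
  best <- sort(unique(c(forced, greedy_dominating(dominates, N, forced))))

  covered0 <- rep(FALSE, N)
  for (i in forced) covered0[dominates[[i]]] <- TRUE

  search <- function(sel, covered) {
    if (all(covered)) {
      if (length(sel) < length(best) ||
          (length(sel) == length(best) &&
           lex_less(sort(sel), best))) best <<- sort(sel)
      return(invisible())
    }
    if (length(sel) + 1L > length(best)) return(invisible())
    u <- which(!covered)[1L]
    cands <- sort(unique(c(u, in_nb[[u]])))
    for (cand in cands) {
      cov2 <- covered
      cov2[dominates[[cand]]] <- TRUE
      search(c(sel, cand), cov2)
    }
  }
  search(forced, covered0)
  res <- net$names[best]
  attr(res, "exact") <- TRUE
  res
}

lex_less <- function(a, b) {
  for (i in seq_along(a)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  FALSE
}

greedy_dominating <- function(dominates, N, sel = integer(0)) {
  covered <- rep(FALSE, N)
  for (i in sel) covered[dominates[[i]]] <- TRUE
  while (!all(covered)) {
    gain <- vapply(seq_len(N), function(i) sum(!covered[dominates[[i]]]), 0L)
    pick <- which.max(gain)  # first index on ties: lexicographic
    sel <- c(sel, pick)
    covered[dominates[[pick]]] <- TRUE
  }
  sort(unique(sel))
}
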
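#' Brute-force oracles
#'
#' Deliberately naive reference implementations used to validate the
#' production algorithms in the test suite. They share no code with the
#' production paths and are exponential, hence capacity-capped: independence
#' beats speed.
#'
#' * `oracle_prime_implicants()` enumerates all `3^k` wildcard patterns, keeps
#'   those consistent with the requested output value that cover at least one
#'   row, and discards patterns that specialize another kept pattern.
#' * `oracle_permutation_closure()` checks a two-symbol schema by expanding
#'   every permutation of every group combination and testing each resulting
#'   pattern against the look-up table.
#' * `oracle_reachability()` computes per-vertex reachable sets by iterating a
#'   Boolean adjacency-matrix closure to fixpoint.
#' * `oracle_matching_size()` finds the maximum bipartite matching size of an
#'   interaction graph by exhaustive recursion over edge subsets.
#' * `oracle_dominating_set()` finds a minimum dominating set by enumerating
#'   all node subsets in increasing size and lexicographic order.
#'
#' @param lut A [lookup_table()].
#' @param value Output value (0/1).
#' @param ts A `ts_schema` from [two_symbol_schemata()].
#' @param g An `igraph` directed graph.
#' @param net A [boolean_network()].
#' @name oracles
NULL

#' @rdname oracles
#' @export
oracle_prime_implicants <- function(lut, value) {
  stopifnot(inherits(lut, "lookup_table"))
  k <- lut$k
  if (k > 6L) stop("oracle capped at k <= 6", call. = FALSE)
  value <- as.integer(value)
  if (k == 0L) {
    if (lut$outputs == value)
      return(schema_list(list(new_schema(character(0), value, lut$name))))
    return(schema_list(list()))
  }
  pats <- as.matrix(expand.grid(rep(list(c("0", "1", "#")), k),
                                stringsAsFactors = FALSE))[, k:1, drop = FALSE]
  ok <- apply(pats, 1L, function(p) {
    rows <- which(apply_pattern_match(p, k))
    length(rows) > 0L && all(lut$outputs[rows] == value)
  })
  pats <- pats[ok, , drop = FALSE]
  # maximality: drop p if some other consistent q generalizes it
  gen <- function(p, q) !identical(p, q) && all(q == p | q == "#")
  keep <- vapply(seq_len(nrow(pats)), function(i) {
    !any(vapply(seq_len(nrow(pats)), function(j)
      gen(pats[i, ], pats[j, ]), TRUE))
  }, TRUE)
  pats <- pats[keep, , drop = FALSE]
  schemas <- lapply(seq_len(nrow(pats)), function(i)
    new_schema(pats[i, ], value, lut$name))
  schema_list(schemas[order(vapply(schemas, schema_key, ""))])
}

# logical vector over rows 1..2^k: does the row match the pattern?
apply_pattern_match <- function(pattern, k) {
  vapply(seq_len(2L^k) - 1L, function(r) {
    bits <- int_to_bits(r, k)
    all(pattern == "#" | pattern == as.character(bits))
  }, TRUE)
}

#' @rdname oracles
#' @export
oracle_permutation_closure <- function(ts, lut) {
  stopifnot(inherits(ts, "ts_schema"), inherits(lut, "lookup_table"))
  k <- lut$k
  perm_all <- function(v) {
    if (length(v) <= 1L) return(list(v))
    unlist(lapply(seq_along(v), function(i)
      lapply(perm_all(v[-i]), function(p) c(v[i], p))), recursive = FALSE)
  }
  pats <- list(ts$pattern)
  for (g in ts$groups) {
    pats <- unlist(lapply(pats, function(p) {
      lapply(perm_all(p[g]), function(sym) { p[g] <- sym; p })
    }), recursive = FALSE)
  }
  all(vapply(pats, function(p) {
    rows <- which(apply_pattern_match(p, k))
    length(rows) > 0L && all(lut$outputs[rows] == ts$output)
  }, TRUE))
}

#' @rdname oracles
#' @export
oracle_reachability <- function(g) {
  n <- igraph::vcount(g)
  if (n > 4096L) stop("oracle capped at 4096 vertices", call. = FALSE)
  A <- matrix(FALSE, n, n)
  el <- igraph::as_edgelist(g, names = FALSE)
  A[el] <- TRUE
  R <- A
  repeat {
    R2 <- R | ((R %*% A) > 0)
    if (identical(R2, R)) break
    R <- R2
  }
  lapply(seq_len(n), function(i) which(R[i, ]))
}

#' @rdname oracles
#' @export
oracle_matching_size <- function(net) {
  stopifnot(inherits(net, "boolean_network"))
  edges <- NULL
  for (i in seq_len(net$N)) {
    js <- match(net$nodes[[i]]$inputs, net$names)
    if (length(js)) edges <- rbind(edges, cbind(js, i))
  }
  if (is.null(edges)) return(0L)
  if (nrow(edges) > 24L) stop("oracle capped at 24 edges", call. = FALSE)
  best <- 0L
  recur <- function(idx, used_out, used_in, size) {
    best <<- max(best, size)
    if (idx > nrow(edges)) return(invisible())
    recur(idx + 1L, used_out, used_in, size)
    j <- edges[idx, 1L]; i <- edges[idx, 2L]
    if (!(j %in% used_out) && !(i %in% used_in)) {
      recur(idx + 1L, c(used_out, j), c(used_in, i), size + 1L)
    }
  }
  recur(1L, integer(0), integer(0), 0L)
  best
}

#' @rdname oracles
#' @export
oracle_dominating_set <- function(net) {
  stopifnot(inherits(net, "boolean_network"))
  N <- net$N
  if (N > 12L) stop("oracle capped at N <= 12", call. = FALSE)
  dominated_by <- lapply(seq_len(N), function(i)
    unique(c(i, match(net$nodes[[i]]$inputs, net$names))))
  for (s in seq_len(N)) {
    for (S in utils::combn(N, s, simplify = FALSE)) {
      if (all(vapply(dominated_by, function(d) any(d %in% S), TRUE))) {
        return(net$names[S])
      }
    }
  }
  net$names
}
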
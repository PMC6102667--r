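#' State-transition graph
#'
#' The state-transition graph (STG) has one vertex per network configuration
#' (all `2^N` of them) and, under deterministic synchronous update, exactly one
#' natural out-edge per vertex: the synchronous successor. Vertex names are the
#' decimal configuration encodings (first-declared node = most significant
#' bit).
#'
#' @param net A [boolean_network()].
#' @param limit Refuse networks with more nodes than this (the construction is
#'   exhaustive in `2^N`). Raise it (up to ~30, memory permitting) for larger
#'   models, or use [find_attractors()] with `method = "trajectory"` when only
#'   attractors are needed.
#' @return An object of class `transition_graph`: fields `N`, `graph` (an
#'   `igraph`), `kind` (`"stg"`), `succ` (the successor of each configuration,
#'   0-based), and `drivers` (`NULL` for an STG).
#' @export
build_stg <- function(net, limit = 20) {
  stopifnot(inherits(net, "boolean_network"))
  check_exhaustive(net$N, limit)
  succ <- successor_table(net)
  n <- 2L^net$N
  g <- config_graph(n)
  g <- igraph::add_edges(g, rbind(seq_len(n), succ + 1L))
  g <- igraph::set_edge_attr(g, "kind", value = "natural")
  structure(list(N = net$N, graph = g, kind = "stg", succ = succ,
                 drivers = NULL),
            class = "transition_graph")
}

check_exhaustive <- function(N, limit) {
  if (N > limit) {
    stop(sprintf(paste0(
      "N = %d exceeds the exhaustive state-space limit of %d nodes ",
      "(2^N configurations); raise `limit` or enumerate attractors with ",
      "method = \"trajectory\""), N, limit), call. = FALSE)
  }
}

config_graph <- function(n) {
  g <- igraph::make_empty_graph(n, directed = TRUE)
  igraph::set_vertex_attr(g, "name", value = as.character(0:(n - 1L)))
}

#' @export
print.transition_graph <- function(x, ...) {
  kinds <- igraph::edge_attr(x$graph, "kind")
  cat(sprintf("%s over %d configurations (N = %d): %d natural, %d controlled edges\n",
              toupper(x$kind), 2L^x$N, x$N,
              sum(kinds == "natural"), sum(kinds == "controlled")))
  if (!is.null(x$drivers)) {
    cat("  drivers:", paste(x$drivers, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Enumerate the attractors of a Boolean network
#'
#' Configurations that repeat under synchronous update are attractors: fixed
#' points (period 1) or limit cycles (period > 1). Two complete enumeration
#' methods are provided, which always agree on the attractor set:
#'
#' * `"exhaustive"`: walks the successor map from every configuration,
#'   labelling each with the attractor its trajectory reaches; also yields
#'   basin sizes (the basins partition the `2^N` configurations).
#' * `"trajectory"`: composes the synchronous map with itself by repeated
#'   squaring until every configuration has been projected onto its attractor
#'   (after `2^N` steps every trajectory is on its cycle), then reads the
#'   cycles off the image. No basin sizes are computed on this path.
#'
#' @param net A [boolean_network()].
#' @param method `"exhaustive"` or `"trajectory"`.
#' @param limit Exhaustive state-space limit, as in [build_stg()].
#' @return An object of class `attractor_set`: a list of attractors, each with
#'   fields `states` (the cycle as 0-based configuration encodings, starting
#'   from the smallest and following the dynamics), `period`, and `basin_size`
#'   (`NA` for `"trajectory"`). Attractors are ordered by smallest member
#'   state.
#' @examples
#' find_attractors(boolean_network(list(lut_not(name = "x", inputs = "x"))))
#' @export
find_attractors <- function(net, method = c("exhaustive", "trajectory"),
                            limit = 20) {
  stopifnot(inherits(net, "boolean_network"))
  method <- match.arg(method)
  check_exhaustive(net$N, limit)
  succ <- successor_table(net)
  if (method == "exhaustive") attractors_exhaustive(succ, net$N)
  else attractors_trajectory(succ, net$N)
}

attractors_exhaustive <- function(succ, N) {
  n <- length(succ)
  label <- integer(n)       # 0 = unvisited, else attractor id
  on_path <- integer(n)     # position in the current walk, 0 = not on it
  cycles <- list()
  basin <- integer(0)
  for (s in seq_len(n)) {
    if (label[s] > 0L) next
    path <- integer(0)
    v <- s
    while (label[v] == 0L && on_path[v] == 0L) {
      path[length(path) + 1L] <- v
      on_path[v] <- length(path)
      v <- succ[v] + 1L
    }
    if (on_path[v] > 0L) {          # new cycle discovered within this walk
      cyc <- path[on_path[v]:length(path)]
      cycles[[length(cycles) + 1L]] <- cyc - 1L
      id <- length(cycles)
      basin[id] <- 0L
    } else {
      id <- label[v]
    }
    label[path] <- id
    basin[id] <- basin[id] + length(path)
    on_path[path] <- 0L
  }
  make_attractor_set(cycles, basin)
}

attractors_trajectory <- function(succ, N) {
  # succ^(2^N) by N squarings: s_{m+1}(x) = s_m(s_m(x))
  t <- succ
  for (m in seq_len(max(N, 1L))) t <- t[t + 1L]
  cycle_states <- sort(unique(t))
  seen <- logical(length(succ))
  cycles <- list()
  for (c0 in cycle_states) {
    if (seen[c0 + 1L]) next
    cyc <- c0
    v <- succ[c0 + 1L]
    while (v != c0) {
      cyc <- c(cyc, v)
      v <- succ[v + 1L]
    }
    seen[cyc + 1L] <- TRUE
    cycles[[length(cycles) + 1L]] <- cyc
  }
  make_attractor_set(cycles, rep(NA_integer_, length(cycles)))
}

make_attractor_set <- function(cycles, basin) {
  atts <- mapply(function(cyc, b) {
    shift <- which.min(cyc)
    states <- c(cyc[shift:length(cyc)], cyc[seq_len(shift - 1L)])
    structure(list(states = states, period = length(states), basin_size = b),
              class = "attractor")
  }, cycles, basin, SIMPLIFY = FALSE)
  ord <- order(vapply(atts, function(a) as.numeric(a$states[1L]), 0))
  structure(atts[ord], class = "attractor_set")
}

#' @export
print.attractor <- function(x, ...) {
  kind <- if (x$period == 1L) "fixed point" else
    sprintf("limit cycle (period %d)", x$period)
  cat(sprintf("attractor: %s, states {%s}%s\n", kind,
              paste(x$states, collapse = ", "),
              if (is.na(x$basin_size)) "" else
                sprintf(", basin %d", x$basin_size)))
  invisible(x)
}

#' @export
print.attractor_set <- function(x, ...) {
  cat(sprintf("%d attractor(s)\n", length(x)))
  for (a in x) print(a)
  invisible(x)
}
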
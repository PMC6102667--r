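#' Controlled state-transition graph
#'
#' Control interventions are instantaneous bit-flip perturbations of a set of
#' *driver* nodes `D`. The controlled state-transition graph (CSTG) extends
#' the STG with, from every configuration, a controlled edge to each of the
#' `2^|D| - 1` configurations that differ from it on a non-empty subset of
#' `D`; natural dynamics then resume from the flipped configuration along the
#' existing natural edges. Edge labels distinguish `natural` from `controlled`
#' transitions.
#'
#' @param net A [boolean_network()].
#' @param drivers Character vector of driver node names (may be empty, giving
#'   the plain STG).
#' @param limit Exhaustive state-space limit, as in [build_stg()].
#' @return A `transition_graph` with `kind = "cstg"` and the driver set in
#'   `$drivers`.
#' @export
build_cstg <- function(net, drivers = character(0), limit = 20) {
  stopifnot(inherits(net, "boolean_network"))
  unknown <- setdiff(drivers, net$names)
  if (length(unknown)) {
    stop("unknown driver node(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  check_exhaustive(net$N, limit)
  drivers <- unique(drivers)
  succ <- successor_table(net)
  n <- 2L^net$N
  configs <- 0:(n - 1L)
  from <- seq_len(n); to <- succ + 1L
  kind <- rep("natural", n)
  dbits <- 2L^(net$N - match(drivers, net$names))  # bit value per driver
  masks <- flip_masks(dbits)
  for (m in masks) {
    from <- c(from, seq_len(n))
    to <- c(to, bitwXor(configs, m) + 1L)
    kind <- c(kind, rep("controlled", n))
  }
  g <- config_graph(n)
  g <- igraph::add_edges(g, rbind(from, to))
  g <- igraph::set_edge_attr(g, "kind", value = kind)
  structure(list(N = net$N, graph = g,
                 kind = if (length(drivers)) "cstg" else "stg",
                 succ = succ, drivers = drivers),
            class = "transition_graph")
}

# all non-empty subset XOR masks of the driver bits
flip_masks <- function(dbits) {
  masks <- 0L
  for (b in dbits) masks <- c(masks, bitwXor(masks, b))
  masks[-1L]
}

#' Fraction of reachable configurations per configuration
#'
#' For each configuration, the number of *other* configurations lying on
#' directed paths from it, normalized by `2^N - 1`. Computed by condensing the
#' graph into strongly connected components and accumulating component sizes
#' over the condensation's transitive closure.
#'
#' @param tg A `transition_graph` from [build_stg()] or [build_cstg()].
#' @return Numeric vector of length `2^N`, in configuration order, each in
#'   `[0, 1]`.
#' @export
reachability_fractions <- function(tg) {
  stopifnot(inherits(tg, "transition_graph"))
  n <- 2L^tg$N
  counts <- reachable_counts(tg$graph)
  counts / (n - 1L)
}

# per-vertex count of reachable vertices, excluding the vertex itself
reachable_counts <- function(g) {
  comp <- igraph::components(g, mode = "strong")
  C <- comp$no
  if (C > 8192L) {
    stop(sprintf(paste0("transitive closure over %d strongly connected ",
                        "components exceeds the supported 8192"), C),
         call. = FALSE)
  }
  memb <- comp$membership
  csize <- as.integer(comp$csize)
  el <- igraph::as_edgelist(g, names = FALSE)
  cf <- memb[el[, 1L]]; ct <- memb[el[, 2L]]
  keep <- cf != ct
  dag_edges <- unique(cbind(cf[keep], ct[keep]))
  # reverse topological order: components() numbers SCCs so that edges go
  # from higher to lower? not guaranteed -> do our own topological sort
  dag <- igraph::make_empty_graph(C, directed = TRUE)
  if (nrow(dag_edges)) dag <- igraph::add_edges(dag, t(dag_edges))
  topo <- as.integer(igraph::topo_sort(dag, mode = "out"))
  reach <- matrix(FALSE, C, C)  # reach[c, ] = components reachable from c
  succs <- split(dag_edges[, 2L], dag_edges[, 1L])
  for (c_ in rev(topo)) {
    sc <- succs[[as.character(c_)]]
    if (!is.null(sc)) {
      row <- reach[c_, ]
      for (s in sc) {
        row[s] <- TRUE
        row <- row | reach[s, ]
      }
      reach[c_, ] <- row
    }
  }
  own <- csize - 1L
  beyond <- as.vector(reach %*% csize)
  (own + beyond)[memb]
}

#' Reachability and controllability measures of a driver set
#'
#' The *mean fraction of reachable configurations* is the average of
#' [reachability_fractions()] over all `2^N` configurations of the controlled
#' state-transition graph; the *mean fraction of controlled configurations*
#' subtracts the same average on the uncontrolled STG, isolating what the
#' interventions add. `R_D = 1` exactly when the CSTG is strongly connected
#' (the network is fully controllable by `D`), and `C_D <= R_D` always.
#'
#' @param net A [boolean_network()].
#' @param drivers Character vector of driver node names.
#' @param per_config Also return the per-configuration fractions `r` (on the
#'   CSTG) and `c = r - r_stg`.
#' @param limit Exhaustive state-space limit.
#' @return An object of class `control_report`: fields `drivers`, `Rbar`,
#'   `Cbar`, `Rbar_empty`, and (if requested) `r`, `c`.
#' @export
control_measures <- function(net, drivers = character(0), per_config = FALSE,
                             limit = 20) {
  stopifnot(inherits(net, "boolean_network"))
  r0 <- reachability_fractions(build_cstg(net, character(0), limit = limit))
  r <- if (length(drivers) == 0L) r0 else
    reachability_fractions(build_cstg(net, drivers, limit = limit))
  rep_ <- list(drivers = unique(drivers), Rbar = mean(r),
               Cbar = mean(r) - mean(r0), Rbar_empty = mean(r0))
  if (per_config) {
    rep_$r <- r
    rep_$c <- r - r0
  }
  structure(rep_, class = "control_report")
}

#' @export
print.control_report <- function(x, digits = 4, ...) {
  d <- if (length(x$drivers)) paste(x$drivers, collapse = ", ") else "(none)"
  cat(sprintf("Control report for drivers {%s}\n", d))
  cat(sprintf("  mean reachable fraction   R = %.*g\n", digits, x$Rbar))
  cat(sprintf("  mean controlled fraction  C = %.*g\n", digits, x$Cbar))
  if (!is.null(x$Abar)) {
    cat(sprintf("  mean reachable attractors A = %.*g\n", digits, x$Abar))
  }
  invisible(x)
}

#' Controlled attractor graph
#'
#' The graph whose vertices are the attractors of the uncontrolled network and
#' whose edge `k -> g` records the existence of at least one path in the
#' controlled state-transition graph from (any configuration of) attractor `k`
#' to attractor `g`. Cycle members are mutually reachable, so any
#' representative gives the same edges. Self-edges are not stored.
#'
#' @param net A [boolean_network()].
#' @param drivers Character vector of driver node names.
#' @param limit Exhaustive state-space limit.
#' @return An object of class `controlled_attractor_graph`: fields
#'   `attractors` (the [find_attractors()] result), `graph` (an `igraph` on
#'   vertices `A1 ... Am`), and `drivers`.
#' @export
build_cag <- function(net, drivers = character(0), limit = 20) {
  atts <- find_attractors(net, limit = limit)
  cstg <- build_cstg(net, drivers, limit = limit)
  m <- length(atts)
  state_of <- lapply(atts, `[[`, "states")
  edges <- NULL
  for (k in seq_len(m)) {
    rep_v <- state_of[[k]][1L] + 1L
    reach <- as.integer(igraph::subcomponent(cstg$graph, rep_v, mode = "out"))
    for (g_ in seq_len(m)) {
      if (g_ == k) next
      if (any((state_of[[g_]] + 1L) %in% reach)) {
        edges <- rbind(edges, c(k, g_))
      }
    }
  }
  g <- igraph::make_empty_graph(m, directed = TRUE)
  g <- igraph::set_vertex_attr(g, "name", value = paste0("A", seq_len(m)))
  if (!is.null(edges)) g <- igraph::add_edges(g, t(edges))
  structure(list(attractors = atts, graph = g, drivers = unique(drivers)),
            class = "controlled_attractor_graph")
}

#' @export
print.controlled_attractor_graph <- function(x, ...) {
  cat(sprintf(
    "Controlled attractor graph: %d attractors, %d edges, drivers {%s}\n",
    length(x$attractors), igraph::ecount(x$graph),
    paste(x$drivers, collapse = ", ")))
  invisible(x)
}

#' Mean fraction of reachable attractors
#'
#' Averages, over the attractors of the network, the fraction of *other*
#' attractors reachable from each in the controlled attractor graph
#' (reachability in the CSTG is transitive, so these are the out-neighbors).
#' Defined as 1 when the network has a single attractor; equals 1 whenever
#' the CSTG is strongly connected (e.g. all nodes driven) and 0 for the empty
#' driver set whenever several attractors exist.
#'
#' @inheritParams build_cag
#' @param cag Optionally, a precomputed [build_cag()] result.
#' @return A single number in `[0, 1]`.
#' @export
attractor_control <- function(net, drivers = character(0), limit = 20,
                              cag = NULL) {
  if (is.null(cag)) cag <- build_cag(net, drivers, limit = limit)
  m <- length(cag$attractors)
  if (m == 1L) return(1)
  mean(igraph::degree(cag$graph, mode = "out") / (m - 1L))
}

#' Sweep driver subsets
#'
#' Computes the control measures for every driver subset up to a given size.
#' Exhaustive over subsets, so capped by default at size 4.
#'
#' @param net A [boolean_network()].
#' @param max_size Largest subset size to enumerate (capped in cost by
#'   `choose(N, max_size)` full CSTG analyses).
#' @param attractors Also compute the mean fraction of reachable attractors.
#' @param limit Exhaustive state-space limit.
#' @return A data frame with columns `drivers` (comma-separated), `size`,
#'   `Rbar`, `Cbar`, and optionally `Abar`.
#' @export
driver_sweep <- function(net, max_size = 2, attractors = TRUE, limit = 20) {
  stopifnot(inherits(net, "boolean_network"), max_size >= 1)
  if (max_size > 4) {
    stop("driver sweeps are capped at subsets of size 4", call. = FALSE)
  }
  max_size <- min(max_size, net$N)
  res <- list()
  for (s in seq_len(max_size)) {
    sets <- utils::combn(net$names, s, simplify = FALSE)
    for (D in sets) {
      cm <- control_measures(net, D, limit = limit)
      row <- data.frame(drivers = paste(D, collapse = ","), size = s,
                        Rbar = cm$Rbar, Cbar = cm$Cbar)
      if (attractors) row$Abar <- attractor_control(net, D, limit = limit)
      res[[length(res) + 1L]] <- row
    }
  }
  do.call(rbind, res)
}
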
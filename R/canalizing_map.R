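#' Canalizing map of a Boolean automaton
#'
#' A threshold-network (McCulloch-Pitts style) rendering of the canalizing
#' logic of one automaton. Two unit kinds appear: *s-units*, one per
#' node-state pair (`node=0`, `node=1`), and *t-units*, numerical threshold
#' conditions. Each wildcard schema with `L >= 2` specified inputs (literals)
#' becomes a t-unit of threshold `L`, fed by an input-condition edge from each
#' literal's s-unit and firing one output-determination edge into the s-unit
#' of the schema's output state. A single-literal schema is drawn as a direct
#' s-to-s edge, avoiding a threshold-1 unit. A constant automaton determines
#' its output s-unit unconditionally (recorded in `unconditional`).
#'
#' Permutation groups from the two-symbol redescription are attached as
#' annotations (`fibers`): for each two-symbol schema, the permutable input
#' groups with their literal values — the group-disjunction fibers of the
#' drawn map — without structurally merging the underlying t-units.
#'
#' @param lut A [lookup_table()].
#' @return An object of class `canalizing_map` with fields `units` (data frame:
#'   `id`, `kind` (`"s"`/`"t"`), `node`, `state`, `threshold`), `edges` (data
#'   frame: `from`, `to`, `kind` in input-condition / output-determination /
#'   direct), `unconditional` (ids of unconditionally determined s-units), and
#'   `fibers` (group annotations).
#' @examples
#' canalizing_map(lut_and())
#' @export
canalizing_map <- function(lut) {
  stopifnot(inherits(lut, "lookup_table"))
  units <- s_unit_frame(lut$name)
  edges <- empty_edge_frame()
  uncond <- character(0)
  for (value in 0:1) {
    target <- s_id(lut$name, value)
    pis <- prime_implicants(lut, value)
    for (ii in seq_along(pis)) {
      pat <- pis[[ii]]$pattern
      lit <- which(pat != "#")
      if (length(lit) == 0L) {
        uncond <- c(uncond, target)
      } else if (length(lit) == 1L) {
        src <- s_id(lut$inputs[lit], pat[lit])
        units <- add_s_units(units, lut$inputs[lit], pat[lit])
        edges <- rbind(edges, data.frame(from = src, to = target,
                                         kind = "direct"))
      } else {
        tid <- sprintf("%s:t%d", target, ii)
        units <- rbind(units, data.frame(
          id = tid, kind = "t", node = lut$name, state = value,
          threshold = length(lit)))
        for (p in lit) {
          src <- s_id(lut$inputs[p], pat[p])
          units <- add_s_units(units, lut$inputs[p], pat[p])
          edges <- rbind(edges, data.frame(from = src, to = tid,
                                           kind = "input-condition"))
        }
        edges <- rbind(edges, data.frame(from = tid, to = target,
                                         kind = "output-determination"))
      }
    }
  }
  fibers <- list()
  for (ts in two_symbol_schemata(lut)) {
    if (length(ts$groups) == 0L) next
    fibers[[length(fibers) + 1L]] <- list(
      output = ts$output, pattern = paste(ts$pattern, collapse = ""),
      groups = lapply(ts$groups, function(g)
        data.frame(input = lut$inputs[g], symbol = ts$pattern[g])))
  }
  units <- units[!duplicated(units$id), ]
  rownames(units) <- rownames(edges) <- NULL
  structure(list(units = units, edges = edges, unconditional = unique(uncond),
                 fibers = fibers),
            class = "canalizing_map")
}

s_id <- function(node, state) sprintf("%s=%s", node, state)

s_unit_frame <- function(node) {
  data.frame(id = s_id(node, 0:1), kind = "s", node = node, state = 0:1,
             threshold = NA_integer_)
}

add_s_units <- function(units, node, state) {
  rbind(units, data.frame(id = s_id(node, state), kind = "s", node = node,
                          state = as.integer(state),
                          threshold = NA_integer_))
}

empty_edge_frame <- function() {
  data.frame(from = character(0), to = character(0), kind = character(0))
}

#' @export
print.canalizing_map <- function(x, ...) {
  ns <- sum(x$units$kind == "s"); nt <- sum(x$units$kind == "t")
  cat(sprintf("Canalizing map: %d s-unit(s), %d t-unit(s), %d edge(s)\n",
              ns, nt, nrow(x$edges)))
  for (tu in x$units$id[x$units$kind == "t"]) {
    conds <- x$edges$from[x$edges$to == tu]
    out <- x$edges$to[x$edges$from == tu &
                        x$edges$kind == "output-determination"]
    cat(sprintf("  [%s] %s -> %s\n",
                x$units$threshold[x$units$id == tu],
                paste(conds, collapse = " & "), out))
  }
  dir <- x$edges[x$edges$kind == "direct", ]
  if (nrow(dir)) {
    cat(paste0("  ", dir$from, " -> ", dir$to, collapse = "\n"), "\n")
  }
  if (length(x$unconditional)) {
    cat("  unconditional:", paste(x$unconditional, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Dynamics canalizing map of a Boolean network
#'
#' The union of the canalizing maps of all automata, sharing s-units: a
#' parsimonious rendering of the entire canalizing logic of the network. It
#' contains exactly `2N` s-units (one per node-state pair), and restricting it
#' to the units that determine one node reproduces that node's standalone
#' canalizing map (see [cm_restrict()]). Construction cost is linear in the
#' number of nodes (one look-up-table minimization each).
#'
#' @param net A [boolean_network()].
#' @return A `canalizing_map` spanning the whole network.
#' @export
dynamics_canalizing_map <- function(net) {
  stopifnot(inherits(net, "boolean_network"))
  units <- do.call(rbind, lapply(net$names, s_unit_frame))
  edges <- empty_edge_frame()
  uncond <- character(0)
  fibers <- list()
  for (nd in net$nodes) {
    cm <- canalizing_map(nd)
    units <- rbind(units, cm$units[cm$units$kind == "t", ])
    edges <- rbind(edges, cm$edges)
    uncond <- c(uncond, cm$unconditional)
    fibers <- c(fibers, lapply(cm$fibers, function(f) c(f, node = nd$name)))
  }
  units <- units[!duplicated(units$id), ]
  rownames(units) <- rownames(edges) <- NULL
  structure(list(units = units, edges = edges, unconditional = unique(uncond),
                 fibers = fibers),
            class = "canalizing_map")
}

#' Restrict a dynamics canalizing map to one node's determinations
#'
#' Keeps the t-units, direct edges and unconditional marks that determine the
#' given node, plus the s-units they touch; equals the node's standalone
#' [canalizing_map()].
#'
#' @param dcm A `canalizing_map` from [dynamics_canalizing_map()].
#' @param node Node name.
#' @return A `canalizing_map`.
#' @export
cm_restrict <- function(dcm, node) {
  stopifnot(inherits(dcm, "canalizing_map"))
  targets <- s_id(node, 0:1)
  tids <- dcm$units$id[dcm$units$kind == "t" & dcm$units$node == node]
  keep <- (dcm$edges$to %in% c(targets, tids)) |
    (dcm$edges$from %in% tids)
  edges <- dcm$edges[keep, ]
  uids <- unique(c(targets, edges$from, edges$to))
  units <- dcm$units[dcm$units$id %in% uids, ]
  rownames(units) <- rownames(edges) <- NULL
  structure(list(units = units, edges = edges,
                 unconditional = intersect(dcm$unconditional, targets),
                 fibers = Filter(function(f) identical(f$node, node),
                                 dcm$fibers)),
            class = "canalizing_map")
}
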
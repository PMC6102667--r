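#' Canalization measures of a Boolean automaton
#'
#' *Input redundancy* `k_r` is the number of inputs that on average are not
#' needed to determine the automaton's transition, tallied from the wildcard
#' symbols of the schemata that redescribe its look-up table; *effective
#' connectivity* is the complement `k_e = k - k_r`; *input symmetry* `k_s` is
#' the analogous tally of position-free symbols in the two-symbol
#' redescription. Per-input measures are also computed: for input `j`,
#' redundancy `r_j` averages, over the table rows and the schemata redescribing
#' each row, the indicator that `j` is a wildcard; effectiveness is
#' `e_j = 1 - r_j`; symmetry `s_j` averages the indicator that `j` carries a
#' position-free mark.
#'
#' Two aggregation conventions are exposed for the node-level tallies. With
#' `norm = "max"` each row contributes the *maximum* symbol count over the
#' schemata that redescribe it; with `norm = "mean"` each row contributes the
#' average wildcard indicator summed over inputs, so that identically
#' `k_r = sum_j r_j` and `k_s = sum_j s_j`. The two conventions agree for many
#' tables but not in general; `"max"` is the default node-level tally, and the
#' summation identity with the per-input measures holds under `"mean"`.
#'
#' Constant (`k = 0`) automata report `k_r = k_e = k_s = 0` by convention.
#'
#' @param lut A [lookup_table()].
#' @param norm `"max"` or `"mean"` (see above).
#' @param allow_constant_groups Passed to [two_symbol_schemata()].
#' @return An object of class `canalization_summary`: fields `node`, `k`,
#'   `k_r`, `k_e`, `k_s`, `norm`, and `per_input`, a data frame with columns
#'   `input`, `r`, `e`, `s`.
#' @examples
#' canalization(lut_xor())$k_r   # 0: parity has no redundancy
#' canalization(lut_and())$k_r   # 0.75
#' @export
canalization <- function(lut, norm = c("max", "mean"),
                         allow_constant_groups = TRUE) {
  stopifnot(inherits(lut, "lookup_table"))
  norm <- match.arg(norm)
  k <- lut$k
  if (k == 0L) {
    return(structure(list(
      node = lut$name, k = 0L, k_r = 0, k_e = 0, k_s = 0, norm = norm,
      per_input = data.frame(input = character(0), r = numeric(0),
                             e = numeric(0), s = numeric(0))),
      class = "canalization_summary"))
  }
  nrows <- 2L^k

  pis <- c(prime_implicants(lut, 0L), prime_implicants(lut, 1L))
  tss <- two_symbol_schemata(lut, allow_constant_groups = allow_constant_groups)

  wc <- tally_schemata(pis, lut, nrows, k, n_wildcards,
                       function(s) s$pattern == "#")
  pf <- tally_schemata(tss, lut, nrows, k, n_positionfree,
                       function(s) seq_len(k) %in% unlist(s$groups))

  k_r <- if (norm == "max") wc$node_max else sum(wc$per_input)
  k_s <- if (norm == "max") pf$node_max else sum(pf$per_input)

  structure(list(
    node = lut$name, k = k, k_r = k_r, k_e = k - k_r, k_s = k_s, norm = norm,
    per_input = data.frame(input = lut$inputs,
                           r = wc$per_input,
                           e = 1 - wc$per_input,
                           s = pf$per_input)),
    class = "canalization_summary")
}

# shared tally over a schema set: per-row max of a symbol count, and the
# per-input mean of a per-position indicator averaged over covering schemata
tally_schemata <- function(schemas, lut, nrows, k, count_fn, indic_fn) {
  row_max <- numeric(nrows)
  per_input_sum <- numeric(k)
  cover <- lapply(schemas, schema_coverage, lut = lut)
  counts <- vapply(schemas, count_fn, 0L)
  indic <- lapply(schemas, indic_fn)
  for (r in seq_len(nrows)) {
    covering <- which(vapply(cover, function(cv) r %in% cv, TRUE))
    stopifnot(length(covering) > 0L)  # redescription covers every row
    row_max[r] <- max(counts[covering])
    per_input_sum <- per_input_sum +
      Reduce(`+`, indic[covering]) / length(covering)
  }
  list(node_max = sum(row_max) / nrows, per_input = per_input_sum / nrows)
}

#' @export
print.canalization_summary <- function(x, digits = 4, ...) {
  cat(sprintf("Canalization of '%s' (k = %d, norm = %s)\n",
              x$node, x$k, x$norm))
  cat(sprintf("  input redundancy   k_r = %.*g\n", digits, x$k_r))
  cat(sprintf("  effective inputs   k_e = %.*g\n", digits, x$k_e))
  cat(sprintf("  input symmetry     k_s = %.*g\n", digits, x$k_s))
  if (nrow(x$per_input)) {
    cat("  per input:\n")
    print(format(x$per_input, digits = digits), row.names = FALSE)
  }
  invisible(x)
}
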
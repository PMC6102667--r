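#' Boolean automaton look-up table
#'
#' A Boolean automaton is a binary variable updated in discrete time by a
#' deterministic transition function of `k` inputs, `f: {0,1}^k -> {0,1}`,
#' tabulated as a look-up (truth) table with one output per combination of
#' input states. Rows are indexed by the integer encoding of the input tuple,
#' with the *first listed input as the most significant bit*: row 1 is
#' `00...0`, row `2^k` is `11...1`.
#'
#' `k = 0` is allowed and describes a constant automaton (a single-row table),
#' used for external inputs held fixed in regulatory models.
#'
#' @param name Node name (single string).
#' @param inputs Character vector of input node names, in row-encoding order
#'   (may be empty for a constant node).
#' @param outputs Integer/logical vector of length `2^length(inputs)` over
#'   `{0,1}`, the transition column.
#' @return An object of class `lookup_table` with fields `name`, `inputs`,
#'   `outputs` and `k`.
#' @examples
#' lookup_table("AND", c("a", "b"), c(0, 0, 0, 1))
#' @export
lookup_table <- function(name, inputs, outputs) {
  stopifnot(is.character(name), length(name) == 1L)
  inputs <- as.character(inputs)
  k <- length(inputs)
  outputs <- as.integer(outputs)
  if (length(outputs) != 2^k) {
    stop(sprintf("node '%s': expected %d output rows for k = %d, got %d",
                 name, 2^k, k, length(outputs)), call. = FALSE)
  }
  if (k > 0 && anyDuplicated(inputs)) {
    stop(sprintf("node '%s': duplicated input names", name), call. = FALSE)
  }
  if (any(is.na(outputs)) || !all(outputs %in% c(0L, 1L))) {
    stop(sprintf("node '%s': outputs must be 0/1", name), call. = FALSE)
  }
  structure(list(name = name, inputs = inputs, outputs = outputs, k = k),
            class = "lookup_table")
}

#' @export
print.lookup_table <- function(x, ...) {
  cat(sprintf("Boolean automaton '%s' (k = %d)\n", x$name, x$k))
  if (x$k == 0L) {
    cat(sprintf("  constant output: %d\n", x$outputs))
    return(invisible(x))
  }
  cat("  inputs:", paste(x$inputs, collapse = ", "), "\n")
  rows <- vapply(seq_len(2^x$k) - 1L, function(r)
    paste(int_to_bits(r, x$k), collapse = ""), "")
  cat(paste0("  ", rows, " -> ", x$outputs, collapse = "\n"), "\n")
  invisible(x)
}

#' Evaluate a look-up table on a vector of input states
#'
#' @param lut A [lookup_table()].
#' @param states Integer vector over `{0,1}` of length `k`, ordered as
#'   `lut$inputs`.
#' @return The automaton's next state (0 or 1).
#' @export
lut_eval <- function(lut, states) {
  stopifnot(inherits(lut, "lookup_table"), length(states) == lut$k)
  lut$outputs[bits_to_int(as.integer(states)) + 1L]
}

# row index (0-based) -> bit vector, first input = MSB
int_to_bits <- function(x, n) {
  if (n == 0L) return(integer(0))
  as.integer(bitwAnd(bitwShiftR(x, (n - 1L):0L), 1L))
}

bits_to_int <- function(bits) {
  n <- length(bits)
  if (n == 0L) return(0L)
  as.integer(sum(bits * 2L^((n - 1L):0L)))
}

#' Common Boolean gate look-up tables
#'
#' Convenience constructors for gates used throughout examples and tests:
#' conjunction, disjunction, parity (XOR), majority, negation, identity and
#' constants. Input names default to `in1, in2, ...`.
#'
#' @param k Number of inputs.
#' @param name Node name.
#' @param inputs Optional input names.
#' @param value Constant output value for [lut_constant()].
#' @return A [lookup_table()].
#' @name gates
NULL

gate_lut <- function(name, k, fn, inputs = NULL) {
  if (is.null(inputs)) inputs <- paste0("in", seq_len(k))
  outs <- vapply(seq_len(2^k) - 1L, function(r) fn(int_to_bits(r, k)), 0L)
  lookup_table(name, inputs, outs)
}

#' @rdname gates
#' @export
lut_and <- function(k = 2, name = "AND", inputs = NULL)
  gate_lut(name, k, function(b) as.integer(all(b == 1L)), inputs)

#' @rdname gates
#' @export
lut_or <- function(k = 2, name = "OR", inputs = NULL)
  gate_lut(name, k, function(b) as.integer(any(b == 1L)), inputs)

#' @rdname gates
#' @export
lut_xor <- function(k = 2, name = "XOR", inputs = NULL)
  gate_lut(name, k, function(b) as.integer(sum(b) %% 2L), inputs)

#' @rdname gates
#' @export
lut_majority <- function(k = 3, name = "MAJ", inputs = NULL)
  gate_lut(name, k, function(b) as.integer(sum(b) > k / 2), inputs)

#' @rdname gates
#' @export
lut_not <- function(name = "NOT", inputs = NULL)
  gate_lut(name, 1L, function(b) 1L - b, inputs)

#' @rdname gates
#' @export
lut_identity <- function(name = "ID", inputs = NULL)
  gate_lut(name, 1L, function(b) b, inputs)

#' @rdname gates
#' @export
lut_constant <- function(value, name = "CONST", inputs = character(0)) {
  k <- length(inputs)
  lookup_table(name, inputs, rep(as.integer(value), 2^k))
}
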
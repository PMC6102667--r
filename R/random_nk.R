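#' Random NK (Kauffman) Boolean network
#'
#' Generates a network from the classic NK ensemble: each of the `N` nodes
#' receives `K` distinct inputs drawn uniformly at random from the `N` nodes
#' (self-inputs allowed), and each of its `2^K` look-up table outputs is an
#' independent Bernoulli(`bias`) draw. Identical seeds give identical
#' networks; the caller's RNG state is left untouched.
#'
#' @param N Number of nodes.
#' @param K In-degree of every node (`0 <= K <= N`).
#' @param bias Probability that a look-up table entry is 1.
#' @param seed Integer seed for reproducibility (`NULL` uses, and advances,
#'   the session RNG).
#' @return A [boolean_network()] with nodes `x1 ... xN`.
#' @examples
#' random_nk(5, 2, seed = 1)
#' @export
random_nk <- function(N, K, bias = 0.5, seed = NULL) {
  stopifnot(N >= 1L, K >= 0L, bias >= 0, bias <= 1)
  if (K > N) stop("K must not exceed N", call. = FALSE)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  nms <- paste0("x", seq_len(N))
  boolean_network(lapply(seq_len(N), function(i) {
    ins <- sample.int(N, K)
    lookup_table(nms[i], nms[ins], stats::rbinom(2L^K, 1L, bias))
  }))
}
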
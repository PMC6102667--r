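#' Wildcard schemata and prime implicants
#'
#' Canalization is quantified by logical redundancy: a look-up table is
#' redescribed as a set of *wildcard schemata* in which the `#` ("don't care")
#' symbol marks inputs whose state is redundant given the remaining inputs.
#' The schemata for one output value are exactly the *prime implicants* of
#' that value, obtained with the Quine-McCluskey minimization algorithm. All
#' prime implicants are returned (maximal consistent patterns), not a minimum
#' cover: the redundancy measures are defined over the full redescription.
#'
#' @param lut A [lookup_table()].
#' @param value Output value to minimize (0 or 1).
#' @return A list of `schema` objects, each with fields `pattern` (character
#'   vector over `"0"`, `"1"`, `"#"`), `output`, and `node`. The list is in
#'   canonical (lexicographic) order.
#' @examples
#' prime_implicants(lut_and(), 0)  # (0,#) and (#,0)
#' @export
prime_implicants <- function(lut, value) {
  stopifnot(inherits(lut, "lookup_table"))
  value <- as.integer(value)
  stopifnot(value %in% c(0L, 1L))
  k <- lut$k
  minterms <- which(lut$outputs == value) - 1L
  if (length(minterms) == 0L) return(schema_list(list()))
  if (k == 0L) {
    return(schema_list(list(new_schema(character(0), value, lut$name))))
  }

  full_mask <- 2L^k - 1L
  # implicants as (bits, mask) pairs; mask bit set = input specified
  cur <- unique(data.frame(bits = minterms, mask = full_mask))
  primes <- list()
  while (nrow(cur) > 0L) {
    combined <- rep(FALSE, nrow(cur))
    nxt <- list()
    key <- paste(cur$bits, cur$mask)
    idx <- seq_len(nrow(cur))
    for (b in 0:(k - 1L)) {
      pb <- bitwShiftL(1L, b)
      cand <- idx[bitwAnd(cur$mask, pb) == pb & bitwAnd(cur$bits, pb) == 0L]
      if (length(cand) == 0L) next
      partner <- match(paste(cur$bits[cand] + pb, cur$mask[cand]), key)
      hit <- which(!is.na(partner))
      if (length(hit) == 0L) next
      i1 <- cand[hit]; i2 <- partner[hit]
      combined[i1] <- TRUE; combined[i2] <- TRUE
      nxt[[length(nxt) + 1L]] <-
        data.frame(bits = cur$bits[i1], mask = cur$mask[i1] - pb)
    }
    primes <- c(primes, split(cur[!combined, , drop = FALSE],
                              seq_len(sum(!combined))))
    cur <- if (length(nxt)) unique(do.call(rbind, nxt)) else cur[0, ]
  }

  pats <- lapply(primes, function(p)
    implicant_pattern(p$bits, p$mask, k))
  pats <- pats[!duplicated(vapply(pats, paste, "", collapse = ""))]
  schemas <- lapply(pats, new_schema, output = value, node = lut$name)
  schema_list(schemas[order(vapply(schemas, schema_key, ""))])
}

new_schema <- function(pattern, output, node = NA_character_) {
  structure(list(pattern = pattern, output = as.integer(output), node = node),
            class = "schema")
}

schema_list <- function(x) structure(x, class = "schema_list")

#' @export
print.schema <- function(x, ...) {
  pat <- if (length(x$pattern)) paste(x$pattern, collapse = "") else "(empty)"
  cat(sprintf("schema %s -> %d\n", pat, x$output))
  invisible(x)
}

#' @export
print.schema_list <- function(x, ...) {
  cat(sprintf("%d wildcard schema(ta)\n", length(x)))
  for (s in x) print(s)
  invisible(x)
}

# sort key: '#' ranked after '1'
schema_key <- function(s) {
  sym <- chartr("01#", "012", paste(s$pattern, collapse = ""))
  paste(s$output, sym)
}

implicant_pattern <- function(bits, mask, k) {
  pos_bits <- (k - 1L):0L  # bit index of pattern position 1..k (MSB first)
  ifelse(bitwAnd(mask, bitwShiftL(1L, pos_bits)) > 0L,
         as.character(bitwAnd(bitwShiftR(bits, pos_bits), 1L)),
         "#")
}

# all LUT row indices (1-based) matching a pattern
pattern_rows <- function(pattern, k) {
  stopifnot(length(pattern) == k)
  if (k == 0L) return(1L)
  pos_bits <- (k - 1L):0L
  base <- sum(ifelse(pattern == "1", bitwShiftL(1L, pos_bits), 0L))
  rows <- base
  for (b in pos_bits[pattern == "#"]) rows <- c(rows, rows + bitwShiftL(1L, b))
  sort(rows) + 1L
}

pattern_consistent <- function(pattern, lut, value) {
  all(lut$outputs[pattern_rows(pattern, lut$k)] == value)
}

#' Rows of a look-up table redescribed by a schema
#'
#' Expands every wildcard position of a schema and returns the indices of the
#' look-up table rows it redescribes (the set Upsilon of the schema). For a
#' two-symbol schema, all permutations of the marked position groups are
#' expanded as well (the set Theta).
#'
#' @param schema A `schema` (from [prime_implicants()]) or `ts_schema`
#'   (from [two_symbol_schemata()]).
#' @param lut The [lookup_table()] the schema redescribes.
#' @return Sorted integer vector of 1-based row indices; every returned row has
#'   the schema's output value.
#' @export
schema_coverage <- function(schema, lut) {
  stopifnot(inherits(lut, "lookup_table"))
  if (length(schema$pattern) != lut$k) {
    stop(sprintf("schema length %d does not match k = %d",
                 length(schema$pattern), lut$k), call. = FALSE)
  }
  pats <- if (inherits(schema, "ts_schema")) {
    ts_arrangements(schema$pattern, schema$groups)
  } else {
    list(schema$pattern)
  }
  rows <- sort(unique(unlist(lapply(pats, pattern_rows, k = lut$k))))
  bad <- lut$outputs[rows] != schema$output
  if (any(bad)) {
    stop("schema is inconsistent with the look-up table", call. = FALSE)
  }
  rows
}

n_wildcards <- function(schema) sum(schema$pattern == "#")

n_positionfree <- function(ts) length(unlist(ts$groups))

## ---- two-symbol redescription ------------------------------------------

# distinct permutations of a symbol multiset
multiset_perms <- function(symbols) {
  n <- length(symbols)
  if (n <= 1L) return(list(symbols))
  out <- list()
  for (s in unique(symbols)) {
    rest <- symbols[-match(s, symbols)]
    for (p in multiset_perms(rest)) out[[length(out) + 1L]] <- c(s, p)
  }
  out
}

# all full patterns generated by permuting symbols within each group
ts_arrangements <- function(pattern, groups) {
  pats <- list(pattern)
  for (g in groups) {
    perms <- multiset_perms(pattern[g])
    pats <- unlist(lapply(pats, function(p) {
      lapply(perms, function(sym) { p[g] <- sym; p })
    }), recursive = FALSE)
  }
  pats[!duplicated(vapply(pats, paste, "", collapse = ""))]
}

# TRUE iff every permutation of every group keeps the pattern consistent
groups_valid <- function(pattern, groups, lut, value) {
  all(vapply(ts_arrangements(pattern, groups), pattern_consistent, TRUE,
             lut = lut, value = value))
}

#' Two-symbol schemata redescription
#'
#' Augments the wildcard redescription with the *position-free* symbol: groups
#' of input positions whose symbols can permute without affecting the
#' automaton's transition (group symmetry, e.g. the two inputs of XOR). Each
#' returned schema carries `groups`, a list of disjoint position sets of size
#' at least two; permuting the pattern symbols within any group always yields
#' another valid wildcard schema of the same output.
#'
#' Groups are grown by greedy pairwise merging in position order; every merge
#' is validated by exhaustively expanding the joint permutation closure of the
#' whole proposed group set, so the construction is deterministic and
#' self-checking. By default a group whose
#' symbols are all identical is admitted (permutations are trivially valid);
#' set `allow_constant_groups = FALSE` to require at least two distinct
#' symbols, which restricts the symmetry count to "visible" permutations.
#'
#' @param lut A [lookup_table()].
#' @param allow_constant_groups Admit groups of identical symbols (default
#'   `TRUE`; this convention makes fully symmetric functions such as majority
#'   report input symmetry equal to `k`).
#' @param k_limit Refuse tables with more inputs than this (the closure check
#'   is exponential in `k`).
#' @return A list (class `schema_list`) of `ts_schema` objects covering every
#'   row of the table, for both output values, in canonical order.
#' @examples
#' two_symbol_schemata(lut_xor())
#' @export
two_symbol_schemata <- function(lut, allow_constant_groups = TRUE,
                                k_limit = 16) {
  stopifnot(inherits(lut, "lookup_table"))
  if (lut$k > k_limit) {
    stop(sprintf("k = %d exceeds the two-symbol limit of %d inputs",
                 lut$k, k_limit), call. = FALSE)
  }
  out <- list()
  for (value in 0:1) {
    for (pi in prime_implicants(lut, value)) {
      g <- find_symmetry_groups(pi$pattern, lut, value, allow_constant_groups)
      out[[length(out) + 1L]] <-
        canonical_ts(pi$pattern, g, value, lut$name)
    }
  }
  keys <- vapply(out, ts_key, "")
  out <- out[!duplicated(keys)]
  schema_list(out[order(vapply(out, ts_key, ""))])
}

# greedy agglomeration of permutable position groups
find_symmetry_groups <- function(pattern, lut, value, allow_constant_groups) {
  k <- length(pattern)
  if (k < 2L) return(list())
  groups <- as.list(seq_len(k))
  repeat {
    merged <- FALSE
    ng <- length(groups)
    for (i in seq_len(ng - 1L)) {
      for (j in (i + 1L):ng) {
        u <- sort(c(groups[[i]], groups[[j]]))
        syms <- pattern[u]
        if (!allow_constant_groups && length(unique(syms)) == 1L) next
        proposed <- groups
        proposed[[i]] <- u
        proposed[[j]] <- NULL
        # joint validation: the schema denotes the product of all group
        # permutations, so every merge is checked against the full closure
        live <- Filter(function(g) length(g) >= 2L, proposed)
        if (groups_valid(pattern, live, lut, value)) {
          groups <- proposed
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
    if (!merged) break
  }
  Filter(function(g) length(g) >= 2L, groups)
}

canonical_ts <- function(pattern, groups, output, node) {
  sym_rank <- c("0" = 1L, "1" = 2L, "#" = 3L)
  for (g in groups) pattern[sort(g)] <- pattern[g][order(sym_rank[pattern[g]])]
  groups <- lapply(groups, sort)
  groups <- groups[order(vapply(groups, `[`, 0L, 1L))]
  structure(list(pattern = pattern, output = as.integer(output),
                 groups = groups, node = node),
            class = c("ts_schema", "schema"))
}

ts_key <- function(s) {
  paste(schema_key(s),
        paste(vapply(s$groups, paste, "", collapse = ","), collapse = ";"))
}

#' @export
print.ts_schema <- function(x, ...) {
  pat <- if (length(x$pattern)) paste(x$pattern, collapse = "") else "(empty)"
  grp <- if (length(x$groups)) {
    paste0(" groups: ", paste(vapply(x$groups, function(g)
      paste0("{", paste(g, collapse = ","), "}"), ""), collapse = " "))
  } else ""
  cat(sprintf("schema %s -> %d%s\n", pat, x$output, grp))
  invisible(x)
}
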
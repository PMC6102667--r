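#' Read and write Boolean networks in the cnet truth-table dialect
#'
#' A plain-text truth-table format for Boolean networks:
#'
#' ```
#' # comment
#' .v N                      number of nodes
#' .l 1 TFL1                 optional node labels (1-based index, name)
#' .n 1 3 2 5 7              node block: index, k, then k input indices
#' 000 1                     2^k rows: k symbols over {0,1,-} and the output
#' ...
#' ```
#'
#' `-` in a row is a wildcard expanded over both values before validation. A
#' node with `k = 0` (constant) has a single row containing only the output.
#' Every LUT row must be assigned exactly once: rows left unspecified or
#' assigned twice (even consistently) are parse errors reported with their
#' line number. Indices are 1-based in files; unlabeled nodes are named
#' `x1 ... xN`.
#'
#' The writer emits labels for all nodes and fully expanded rows in ascending
#' row order, so write-then-parse round-trips to an identical network.
#'
#' @param file Path to a cnet file, or `NULL` when `text` is given.
#' @param text The file contents as a single string or character vector of
#'   lines (alternative to `file`).
#' @param net A [boolean_network()].
#' @return `parse_cnet()` a [boolean_network()]; `write_cnet()` the formatted
#'   text, invisibly, after writing it to `file` if non-`NULL`.
#' @export
parse_cnet <- function(file = NULL, text = NULL) {
  if (is.null(text)) {
    stopifnot(is.character(file), length(file) == 1L)
    text <- readLines(file, warn = FALSE)
  }
  if (length(text) == 1L && grepl("\n", text)) {
    text <- strsplit(text, "\n", fixed = TRUE)[[1L]]
  }
  lines <- sub("#.*$", "", text)
  keep <- which(trimws(lines) != "")
  toks <- lapply(keep, function(i) strsplit(trimws(lines[i]), "\\s+")[[1L]])
  lineno <- keep

  perr <- function(i, msg) {
    stop(sprintf("cnet parse error at line %d: %s", lineno[i], msg),
         call. = FALSE)
  }

  if (length(toks) == 0L || toks[[1L]][1L] != ".v") {
    stop("cnet parse error: file must start with a '.v N' line",
         call. = FALSE)
  }
  N <- suppressWarnings(as.integer(toks[[1L]][2L]))
  if (is.na(N) || N < 1L) perr(1L, "invalid node count in '.v'")

  labels <- paste0("x", seq_len(N))
  wiring <- vector("list", N)   # input indices per node
  rowsets <- vector("list", N)  # outputs per node (NA = unassigned)
  cur <- NA_integer_
  i <- 2L
  while (i <= length(toks)) {
    tk <- toks[[i]]
    if (tk[1L] == ".l") {
      idx <- as.integer(tk[2L])
      if (is.na(idx) || idx < 1L || idx > N || length(tk) < 3L) {
        perr(i, "invalid '.l' label line")
      }
      labels[idx] <- paste(tk[-(1:2)], collapse = " ")
    } else if (tk[1L] == ".n") {
      idx <- as.integer(tk[2L]); k <- as.integer(tk[3L])
      if (is.na(idx) || idx < 1L || idx > N || is.na(k) || k < 0L) {
        perr(i, "invalid '.n' node header")
      }
      if (!is.null(wiring[[idx]])) perr(i, sprintf("node %d declared twice", idx))
      ins <- as.integer(tk[-(1:3)])
      if (length(ins) != k || anyNA(ins) || any(ins < 1L | ins > N)) {
        perr(i, sprintf("expected %d valid input indices", k))
      }
      wiring[[idx]] <- ins
      rowsets[[idx]] <- rep(NA_integer_, 2L^k)
      cur <- idx
    } else {
      if (is.na(cur)) perr(i, "truth-table row before any '.n' header")
      k <- length(wiring[[cur]])
      if (k == 0L) {
        if (length(tk) != 1L || !tk %in% c("0", "1")) {
          perr(i, "constant node expects a single 0/1 output row")
        }
        pat <- character(0); out <- as.integer(tk)
      } else {
        if (length(tk) != 2L || nchar(tk[1L]) != k ||
            !grepl("^[01-]+$", tk[1L]) || !tk[2L] %in% c("0", "1")) {
          perr(i, sprintf("expected '%d symbols over {0,1,-}' and an output", k))
        }
        pat <- strsplit(tk[1L], "")[[1L]]
        pat[pat == "-"] <- "#"
        out <- as.integer(tk[2L])
      }
      rows <- pattern_rows(pat, k)
      clash <- !is.na(rowsets[[cur]][rows])
      if (any(clash)) {
        perr(i, sprintf("row %s assigned twice for node %d",
                        paste(int_to_bits(rows[clash][1L] - 1L, k),
                              collapse = ""), cur))
      }
      rowsets[[cur]][rows] <- out
    }
    i <- i + 1L
  }

  for (idx in seq_len(N)) {
    if (is.null(wiring[[idx]])) {
      stop(sprintf("cnet parse error: node %d has no '.n' block", idx),
           call. = FALSE)
    }
    if (anyNA(rowsets[[idx]])) {
      stop(sprintf("cnet parse error: node %d ('%s') has unassigned LUT rows",
                   idx, labels[idx]), call. = FALSE)
    }
  }
  if (anyDuplicated(labels)) {
    stop("cnet parse error: duplicated node labels", call. = FALSE)
  }
  boolean_network(lapply(seq_len(N), function(idx)
    lookup_table(labels[idx], labels[wiring[[idx]]], rowsets[[idx]])))
}

#' @rdname parse_cnet
#' @export
write_cnet <- function(net, file = NULL) {
  stopifnot(inherits(net, "boolean_network"))
  out <- c(sprintf(".v %d", net$N),
           sprintf(".l %d %s", seq_len(net$N), net$names))
  for (i in seq_len(net$N)) {
    nd <- net$nodes[[i]]
    out <- c(out, paste(c(".n", i, nd$k, match(nd$inputs, net$names)),
                        collapse = " "))
    if (nd$k == 0L) {
      out <- c(out, as.character(nd$outputs))
    } else {
      rows <- vapply(seq_len(2^nd$k) - 1L, function(r)
        paste(int_to_bits(r, nd$k), collapse = ""), "")
      out <- c(out, paste(rows, nd$outputs))
    }
  }
  if (!is.null(file)) writeLines(out, file)
  invisible(paste(out, collapse = "\n"))
}
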
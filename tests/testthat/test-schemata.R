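test_that("prime implicants of basic gates match hand expansion", {
  expect_equal(schema_strings(prime_implicants(lut_and(), 1)), "11>1")
  expect_equal(schema_strings(prime_implicants(lut_and(), 0)),
               c("#0>0", "0#>0"))
  expect_equal(schema_strings(prime_implicants(lut_xor(), 1)),
               c("01>1", "10>1"))
  expect_equal(schema_strings(prime_implicants(lut_constant(1, inputs = c("a", "b")), 1)),
               "##>1")
  expect_length(prime_implicants(lut_constant(1, inputs = c("a", "b")), 0), 0)
})

test_that("the TFL1 automaton minimizes to one 3-literal ON schema and three 1-literal OFF schemata", {
  lut <- tfl1_lut()
  on <- prime_implicants(lut, 1)
  expect_length(on, 1)
  expect_equal(paste(on[[1]]$pattern, collapse = ""), "#010")
  off <- prime_implicants(lut, 0)
  expect_length(off, 3)
  expect_true(all(vapply(off, function(s) sum(s$pattern != "#"), 0L) == 1L))
})

test_that("schema coverage expands wildcards to exactly the redescribed rows", {
  lut <- tfl1_lut()
  on <- prime_implicants(lut, 1)[[1]]
  rows <- schema_coverage(on, lut)
  expect_length(rows, 2)             # AP2 free, other three inputs fixed
  expect_true(all(lut$outputs[rows] == 1))

  expect_equal(schema_coverage(structure(list(pattern = c("#", "#"), output = 0L),
                                         class = "schema"),
                               lut_constant(0, inputs = c("a", "b"))),
               1:4)
  zero_hash <- Filter(function(s) identical(s$pattern, c("0", "#")),
                      prime_implicants(lut_and(), 0))[[1]]
  expect_equal(schema_coverage(zero_hash, lut_and()), c(1L, 2L))  # rows 00, 01
  expect_error(schema_coverage(prime_implicants(lut_and(), 0)[[1]], tfl1_lut()),
               "does not match")
})

test_that("prime implicant cover is exact: union of expansions equals the value's rows", {
  set.seed(11)
  for (k in 1:4) {
    for (rep in 1:25) {
      lut <- random_lut(k)
      for (v in 0:1) {
        pis <- prime_implicants(lut, v)
        rows <- sort(unique(unlist(lapply(pis, schema_coverage, lut = lut))))
        expect_identical(rows, which(lut$outputs == v))
      }
    }
  }
})

test_that("production prime implicants equal the brute-force oracle", {
  set.seed(23)
  for (k in 1:4) {
    for (rep in 1:50) {
      lut <- random_lut(k)
      for (v in 0:1) {
        expect_identical(schema_strings(prime_implicants(lut, v)),
                         schema_strings(oracle_prime_implicants(lut, v)))
      }
    }
  }
})

test_that("no returned prime implicant specializes another", {
  set.seed(31)
  for (rep in 1:20) {
    lut <- random_lut(4)
    for (v in 0:1) {
      pis <- prime_implicants(lut, v)
      pats <- lapply(pis, `[[`, "pattern")
      for (i in seq_along(pats)) for (j in seq_along(pats)) {
        if (i == j) next
        expect_false(all(pats[[j]] == pats[[i]] | pats[[j]] == "#"))
      }
    }
  }
})

test_that("two-symbol schemata capture gate symmetries", {
  xor1 <- Filter(function(s) s$output == 1L, two_symbol_schemata(lut_xor()))
  expect_length(xor1, 1)
  expect_equal(paste(xor1[[1]]$pattern, collapse = ""), "01")
  expect_equal(xor1[[1]]$groups, list(1:2))

  and0 <- Filter(function(s) s$output == 0L, two_symbol_schemata(lut_and()))
  expect_length(and0, 1)
  expect_equal(paste(and0[[1]]$pattern, collapse = ""), "0#")
  expect_equal(and0[[1]]$groups, list(1:2))

  id <- two_symbol_schemata(lut_identity())
  expect_true(all(vapply(id, function(s) length(s$groups) == 0L, TRUE)))
  expect_equal(schema_strings(id), c("0>0", "1>1"))
})

test_that("two-symbol groups pass exhaustive permutation closure and cover every row", {
  set.seed(47)
  for (k in 2:4) {
    for (rep in 1:15) {
      lut <- random_lut(k)
      tss <- two_symbol_schemata(lut)
      expect_true(all(vapply(tss, oracle_permutation_closure, TRUE, lut = lut)))
      covered <- sort(unique(unlist(lapply(tss, schema_coverage, lut = lut))))
      expect_identical(covered, seq_len(2L^k))
      for (s in tss) {
        expect_true(all(vapply(s$groups, length, 0L) >= 2L))
        expect_false(anyDuplicated(unlist(s$groups)) > 0L)
      }
    }
  }
})

test_that("two-symbol redescription is deterministic and canonical", {
  lut <- random_lut(4)
  a <- two_symbol_schemata(lut)
  b <- two_symbol_schemata(lut)
  expect_identical(a, b)
})

test_that("oversized tables are refused with the configured limit", {
  expect_error(two_symbol_schemata(lut_and(), k_limit = 1), "limit of 1")
})
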
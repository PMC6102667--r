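test_that("the controlled STG adds 2^|D|-1 controlled out-edges per configuration", {
  net <- random_nk(4, 2, seed = 8)
  for (d in 0:3) {
    D <- net$names[seq_len(d)]
    g <- build_cstg(net, D)
    kinds <- igraph::E(g$graph)$kind
    expect_equal(sum(kinds == "natural"), 2^4)
    expect_equal(sum(kinds == "controlled"), 2^4 * (2^d - 1))
    deg <- igraph::degree(g$graph, mode = "out")
    expect_true(all(deg == 1 + (2^d - 1)))
  }
  # controlled edges flip exactly the driven bits
  g1 <- build_cstg(net, "x1")
  el <- igraph::as_edgelist(g1$graph, names = FALSE)
  ctl <- el[igraph::E(g1$graph)$kind == "controlled", , drop = FALSE]
  expect_true(all(bitwXor(ctl[, 1] - 1L, ctl[, 2] - 1L) == 2^3))  # x1 is the MSB
  expect_error(build_cstg(net, "zz"), "unknown driver")
})

test_that("reachability fractions follow directed paths", {
  one <- boolean_network(list(lut_constant(1, name = "x")))
  r <- reachability_fractions(build_stg(one))
  expect_equal(r, c(1, 0))   # 0 -> 1 -> 1

  cyc <- load_example("motif_cycle")
  rc <- reachability_fractions(build_cstg(cyc, cyc$names))
  expect_true(all(rc == 1))  # fully driven => strongly connected

  two <- two_bit_net()
  r0 <- reachability_fractions(build_stg(two))
  expect_true(all(r0 == 0))  # four isolated fixed points
})

test_that("production reachability matches the matrix-closure oracle", {
  set.seed(37)
  for (rep in 1:5) {
    net <- random_nk(5, 2, seed = sample.int(1e6, 1))
    D <- sample(net$names, sample(0:2, 1))
    g <- build_cstg(net, D)
    r <- reachability_fractions(g)
    or <- oracle_reachability(g$graph)
    n <- 2^5
    ro <- vapply(seq_len(n), function(v) length(setdiff(or[[v]], v)), 0L) / (n - 1)
    expect_equal(r, ro)
  }
  # plain random digraphs too
  for (rep in 1:10) {
    g <- igraph::sample_gnp(8, 0.3, directed = TRUE)
    counts <- bncana:::reachable_counts(g)
    or <- oracle_reachability(g)
    expect_equal(counts,
                 vapply(1:8, function(v) length(setdiff(or[[v]], v)), 0L))
  }
})

test_that("driving every node makes all configurations mutually reachable", {
  for (seed in c(1, 2, 3)) {
    net <- random_nk(3, 2, seed = seed)
    cm <- control_measures(net, net$names)
    expect_identical(cm$Rbar, 1)
    expect_true(igraph::is_connected(build_cstg(net, net$names)$graph,
                                     mode = "strong"))
  }
})

test_that("control measures obey their identities on hand-checked cases", {
  one <- boolean_network(list(lut_constant(1, name = "x")))
  cm <- control_measures(one, "x", per_config = TRUE)
  expect_equal(cm$Rbar, 1)
  expect_equal(cm$Rbar_empty, 0.5)
  expect_equal(cm$Cbar, 0.5)
  expect_equal(cm$c, c(0, 1))

  net <- random_nk(4, 2, seed = 55)
  e <- control_measures(net, character(0))
  expect_equal(e$Cbar, 0)
  expect_identical(e$Rbar, e$Rbar_empty)
})

test_that("reachability and attractor control are monotone under driver inclusion", {
  set.seed(41)
  for (rep in 1:4) {
    net <- random_nk(5, 2, seed = sample.int(1e6, 1))
    perm <- sample(net$names)
    rbars <- abars <- numeric(0)
    for (d in 0:3) {
      D <- perm[seq_len(d)]
      cm <- control_measures(net, D)
      expect_lte(cm$Cbar, cm$Rbar + 1e-12)
      rbars <- c(rbars, cm$Rbar)
      abars <- c(abars, attractor_control(net, D))
    }
    expect_true(all(diff(rbars) >= -1e-12))
    expect_true(all(diff(abars) >= -1e-12))
  }
})

test_that("the controlled attractor graph spans the attractors and tracks reachability", {
  two <- two_bit_net()
  cag <- build_cag(two, "a")
  expect_equal(igraph::vcount(cag$graph), 4)
  expect_true(all(igraph::degree(cag$graph, mode = "out") == 1))
  expect_equal(attractor_control(two, "a"), 1 / 3)
  expect_equal(attractor_control(two, character(0)), 0)
  expect_equal(attractor_control(two, c("a", "b")), 1)

  single <- boolean_network(list(lut_constant(1, name = "x")))
  c1 <- build_cag(single, character(0))
  expect_equal(igraph::vcount(c1$graph), 1)
  expect_equal(igraph::ecount(c1$graph), 0)
  expect_equal(attractor_control(single, character(0)), 1)

  th <- load_example("thaliana")
  cag_th <- build_cag(th, c("UFO", "LUG", "CLF", "SEP", "TFL1"))
  expect_equal(igraph::vcount(cag_th$graph), 10)
  expect_equal(igraph::vcount(cag_th$graph), length(find_attractors(th)))
})

test_that("structural controllability drivers are the unmatched nodes", {
  chain <- boolean_network(list(
    lut_constant(0, name = "x1"),
    lut_identity(name = "x2", inputs = "x1"),
    lut_identity(name = "x3", inputs = "x2")))
  expect_equal(sc_driver_set(chain), "x1")

  cyc <- load_example("motif_cycle")
  expect_equal(sc_driver_set(cyc), "x1")   # perfect matching

  consts <- boolean_network(list(lut_constant(0, name = "a"),
                                 lut_constant(1, name = "b")))
  expect_equal(sc_driver_set(consts), c("a", "b"))

  set.seed(43)
  for (rep in 1:6) {
    net <- random_nk(5, sample(1:2, 1), seed = sample.int(1e6, 1))
    m <- oracle_matching_size(net)
    expect_length(sc_driver_set(net), max(net$N - m, 1))
  }
})

test_that("minimum dominating sets are minimal, dominating and lexicographic", {
  star <- load_example("motif_star")
  expect_equal(as.vector(mds_driver_set(star)), "hub")

  path <- boolean_network(list(
    lut_constant(0, name = "a"),
    lut_identity(name = "b", inputs = "a"),
    lut_identity(name = "c", inputs = "b")))
  expect_equal(as.vector(mds_driver_set(path)), c("a", "b"))

  complete <- boolean_network(lapply(1:3, function(i)
    lut_or(3, name = paste0("n", i), inputs = paste0("n", 1:3))))
  expect_equal(as.vector(mds_driver_set(complete)), "n1")

  set.seed(53)
  for (rep in 1:6) {
    net <- random_nk(6, sample(1:2, 1), seed = sample.int(1e6, 1))
    got <- mds_driver_set(net)
    expect_true(attr(got, "exact"))
    want <- oracle_dominating_set(net)
    expect_length(got, length(want))
    expect_equal(as.vector(got), want)   # both lexicographic-minimal
  }
})

test_that("driver sweeps tabulate measures for every subset", {
  net <- random_nk(3, 2, seed = 60)
  sw <- driver_sweep(net, max_size = 2)
  expect_equal(nrow(sw), 3 + 3)
  expect_true(all(sw$Rbar >= sw$Cbar - 1e-12))
  expect_true(all(sw$Abar >= 0 & sw$Abar <= 1))
  expect_error(driver_sweep(net, max_size = 5), "capped")
})
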
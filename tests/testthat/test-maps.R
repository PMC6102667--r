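test_that("effective weights equal per-input effectiveness and zero edges prune", {
  xors <- boolean_network(list(
    lut_xor(name = "a", inputs = c("a", "b")),
    lut_xor(name = "b", inputs = c("a", "b"))))
  eg <- effective_graph(xors)
  expect_equal(igraph::ecount(eg$graph), 4)
  expect_true(all(igraph::E(eg$graph)$weight == 1))

  th <- load_example("thaliana")
  el <- igraph::as_edgelist(effective_graph(th)$graph)
  expect_false(any(el[, 1] == "AP2" & el[, 2] == "TFL1"))
  il <- igraph::as_edgelist(interaction_graph(th))
  expect_true(any(il[, 1] == "AP2" & il[, 2] == "TFL1"))

  kept <- effective_graph(th, prune_zero = FALSE)
  kel <- igraph::as_edgelist(kept$graph)
  i <- which(kel[, 1] == "AP2" & kel[, 2] == "TFL1")
  expect_length(i, 1)
  expect_equal(igraph::E(kept$graph)$weight[i], 0)
})

test_that("the effective graph is a weighted subgraph of the interaction graph", {
  set.seed(19)
  for (rep in 1:5) {
    net <- random_nk(5, 3, seed = sample.int(1e6, 1))
    eg <- effective_graph(net)
    epairs <- apply(igraph::as_edgelist(eg$graph), 1, paste, collapse = ">")
    cpairs <- apply(igraph::as_edgelist(interaction_graph(net)), 1,
                    paste, collapse = ">")
    expect_true(all(epairs %in% cpairs))
    w <- igraph::E(eg$graph)$weight
    expect_true(all(w > 0 & w <= 1))
  }
})

test_that("in-weights sum to the effective connectivity under the mean tally", {
  net <- random_nk(5, 3, seed = 4242)
  eg <- effective_graph(net, prune_zero = FALSE)
  el <- igraph::as_edgelist(eg$graph)
  w <- igraph::E(eg$graph)$weight
  for (nd in net$nodes) {
    cz <- canalization(nd, norm = "mean")
    expect_equal(sum(w[el[, 2] == nd$name]), cz$k_e, tolerance = 1e-12)
  }
})

test_that("canalizing maps wire schemata into threshold and direct units", {
  cm <- canalizing_map(tfl1_lut())
  tu <- cm$units[cm$units$kind == "t", ]
  expect_equal(nrow(tu), 1)
  expect_equal(tu$threshold, 3)
  det <- cm$edges[cm$edges$kind == "output-determination", ]
  expect_equal(det$to, "TFL1=1")
  direct <- cm$edges[cm$edges$kind == "direct", ]
  expect_setequal(direct$from, c("EMF1=0", "AP1=1", "LFY=1"))
  expect_true(all(direct$to == "TFL1=0"))
  expect_true(all(c("TFL1=0", "TFL1=1") %in% cm$units$id))

  and <- canalizing_map(lut_and())
  expect_equal(and$units$threshold[and$units$kind == "t"], 2)
  expect_equal(sum(and$edges$kind == "direct"), 2)

  const <- canalizing_map(lut_constant(1, name = "c"))
  expect_equal(const$unconditional, "c=1")
})

test_that("every t-unit's threshold equals its distinct input conditions and it fires once", {
  set.seed(29)
  net <- random_nk(5, 3, seed = 777)
  dcm <- dynamics_canalizing_map(net)
  for (tid in dcm$units$id[dcm$units$kind == "t"]) {
    conds <- dcm$edges[dcm$edges$to == tid & dcm$edges$kind == "input-condition", ]
    expect_equal(length(unique(conds$from)),
                 dcm$units$threshold[dcm$units$id == tid])
    outs <- dcm$edges[dcm$edges$from == tid, ]
    expect_equal(nrow(outs), 1)
    expect_equal(outs$kind, "output-determination")
  }
})

test_that("the dynamics canalizing map is the s-unit-sharing union of node maps", {
  th <- load_example("thaliana")
  dcm <- dynamics_canalizing_map(th)
  expect_equal(sum(dcm$units$kind == "s"), 2 * th$N)

  lfy <- dcm$edges[dcm$edges$to == "LFY=1", ]
  expect_setequal(lfy$from, c("TFL1=0", "EMF1=0"))
  expect_true(all(lfy$kind == "direct"))

  for (node in c("TFL1", "AG", "UFO")) {
    sub <- cm_restrict(dcm, node)
    cm <- canalizing_map(th$nodes[[node]])
    expect_setequal(sub$edges$from, cm$edges$from)
    expect_identical(sub$edges[order(sub$edges$from, sub$edges$to), ],
                     cm$edges[order(cm$edges$from, cm$edges$to), ],
                     ignore_attr = TRUE)
    expect_setequal(sub$unconditional, cm$unconditional)
  }
})

test_that("graph export is byte-deterministic and structurally faithful", {
  net <- random_nk(4, 2, seed = 31)
  eg <- effective_graph(net)
  expect_identical(export_graph(eg, "dot"), export_graph(eg, "dot"))
  expect_identical(export_graph(eg, "graphml"), export_graph(eg, "graphml"))

  dot <- export_graph(eg, "dot")
  expect_match(dot, "^digraph G \\{")
  expect_equal(lengths(regmatches(dot, gregexpr("->", dot))),
               igraph::ecount(eg$graph))
  expect_equal(lengths(regmatches(dot, gregexpr("\\{", dot))),
               lengths(regmatches(dot, gregexpr("\\}", dot))))

  gml <- export_graph(eg, "graphml")
  doc <- xml2::read_xml(gml)
  ns <- xml2::xml_ns(doc)
  expect_length(xml2::xml_find_all(doc, ".//d1:node", ns), net$N)
  edges <- xml2::xml_find_all(doc, ".//d1:edge", ns)
  expect_length(edges, igraph::ecount(eg$graph))
  w <- as.numeric(xml2::xml_text(xml2::xml_find_all(doc, ".//d1:edge/d1:data", ns)))
  expect_equal(sort(w), sort(igraph::E(eg$graph)$weight), tolerance = 1e-9)

  stg <- build_stg(net)
  expect_match(export_graph(stg, "dot"), "kind=\"natural\"")
  cm_dot <- export_graph(canalizing_map(lut_and()), "dot")
  expect_match(cm_dot, "threshold=\"2\"")
  expect_error(export_graph(eg, "svg"))
})
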
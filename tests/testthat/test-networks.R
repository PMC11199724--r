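test_that("co-authorship graph matches the hand-counted adjacency", {
  g <- build_coauthorship_graph(tiny_corpus(), "author")
  expect_setequal(igraph::V(g)$name, c("A", "B", "C", "D"))
  expect_equal(igraph::V(g)$pubs[match("A", igraph::V(g)$name)], 3L)

  got <- igraph::as_data_frame(g, what = "edges")
  got <- got[order(got$from, got$to), ]
  want <- as.data.frame(tiny_author_edges())
  expect_equal(got$weight, want$weight, ignore_attr = TRUE)
  expect_equal(pmin(got$from, got$to), pmin(want$from, want$to))
  expect_equal(pmax(got$from, got$to), pmax(want$from, want$to))

  # record with a single author contributes a node but no edge
  solo <- tiny_corpus()
  solo$authors[[6]] <- "Z"
  gz <- build_coauthorship_graph(biblio_corpus(solo), "author")
  expect_true("Z" %in% igraph::V(gz)$name)
  expect_equal(igraph::degree(gz, "Z"), c(Z = 0))
})

test_that("node thresholds apply before edge construction", {
  # B has 3 pubs, D has 2: with min_docs = 3, D's edges must vanish
  g <- build_coauthorship_graph(tiny_corpus(), "author", min_docs = 3)
  expect_setequal(igraph::V(g)$name, c("A", "B", "C"))
  expect_false(any(igraph::as_data_frame(g)$from == "D"))
})

test_that("keyword co-occurrence graph is symmetric, zero-diagonal, thresholdable", {
  g <- build_keyword_cooccurrence(tiny_corpus(), "both")
  A <- igraph::as_adjacency_matrix(g, attr = "weight", sparse = FALSE)
  expect_equal(A, t(A))
  expect_true(all(diag(A) == 0))
  # k1 and x1 co-occur in records r1 and r2
  expect_equal(A["k1", "x1"], 2)

  # keyword below the occurrence threshold is absent entirely
  g10 <- build_keyword_cooccurrence(tiny_corpus(), "both", min_occurrence = 3)
  expect_false("k3" %in% igraph::V(g10)$name)
  expect_true("x1" %in% igraph::V(g10)$name)

  # permutation invariance of construction
  shuffled <- corpus_slice(tiny_corpus(), c(3, 6, 1, 5, 2, 4))
  g2 <- build_keyword_cooccurrence(shuffled, "both")
  A2 <- igraph::as_adjacency_matrix(g2, attr = "weight", sparse = FALSE)
  expect_equal(A2[rownames(A), colnames(A)], A)
})

test_that("modularity matches closed forms and the brute-force double sum", {
  gs <- small_test_graphs()

  one <- gs$single_edge
  expect_equal(modularity_score(one, c(a = 1, b = 1)), 0)
  expect_equal(modularity_score(one, c(a = 1, b = 2)), -0.5)

  tp <- gs$triangle_pair
  split <- c(a = 1, b = 1, c = 1, d = 2, e = 2, f = 2)
  expect_equal(modularity_score(tp, split), 0.5)
  # exhaustive enumeration confirms 0.5 is the optimum for the two triangles
  expect_equal(exhaustive_best_modularity(tp)$Q, 0.5)

  for (nm in names(gs)) {
    g <- gs[[nm]]
    vn <- igraph::V(g)$name
    set.seed(71)
    for (rep in 1:5) {
      memb <- stats::setNames(sample(1:3, length(vn), replace = TRUE), vn)
      expect_equal(modularity_score(g, memb), brute_force_modularity(g, memb),
                   tolerance = 1e-12, info = nm)
      # independent cross-check against igraph's implementation
      expect_equal(modularity_score(g, memb),
                   igraph::modularity(g, memb[vn], weights = igraph::E(g)$weight),
                   tolerance = 1e-12, info = nm)
    }
  }

  edgeless <- igraph::make_empty_graph(3, directed = FALSE)
  igraph::V(edgeless)$name <- c("a", "b", "c")
  expect_error(modularity_score(edgeless, c(a = 1, b = 1, c = 1)), "undefined")
  expect_error(modularity_score(gs$single_edge, c(a = 1)), "every node")
})

test_that("community detection recovers planted structure and is seed-deterministic", {
  # two disjoint 4-cliques -> exactly the cliques
  cl <- utils::combn(letters[1:4], 2)
  cl2 <- utils::combn(letters[5:8], 2)
  g <- weighted_graph(data.frame(from = c(cl[1, ], cl2[1, ]),
                                 to = c(cl[2, ], cl2[2, ]), weight = 1))
  part <- detect_communities(g, seed = 4)
  memb <- part$membership
  expect_equal(length(unique(memb)), 2)
  expect_equal(length(unique(memb[letters[1:4]])), 1)
  expect_equal(length(unique(memb[letters[5:8]])), 1)
  expect_equal(exhaustive_best_modularity(g)$Q, part$modularity)

  # complete K5: a single community is optimal
  k5 <- detect_communities(small_test_graphs()$k5, seed = 1)
  expect_equal(length(unique(k5$membership)), 1)

  # determinism for a fixed seed
  pp <- planted_partition_graph(4, 10, 0.9, 0.02, seed = 33)
  p1 <- detect_communities(pp$graph, seed = 5)
  p2 <- detect_communities(pp$graph, seed = 5)
  expect_identical(p1$membership, p2$membership)

  # Q at least that of the all-singletons partition, recomputed from scratch
  singletons <- stats::setNames(seq_len(igraph::vcount(pp$graph)),
                                igraph::V(pp$graph)$name)
  expect_gte(p1$modularity, modularity_score(pp$graph, singletons))
  expect_equal(p1$modularity, modularity_score(pp$graph, p1$membership))

  # communities never span connected components
  comp <- igraph::components(g)$membership
  expect_true(all(tapply(comp[names(memb)], memb, function(x) length(unique(x))) == 1))

  # edgeless graph: every node its own community, Q flagged undefined
  edgeless <- igraph::make_empty_graph(3, directed = FALSE)
  igraph::V(edgeless)$name <- c("x", "y", "z")
  p0 <- detect_communities(edgeless, seed = 1)
  expect_equal(unname(p0$membership), 1:3)
  expect_true(is.na(p0$modularity))
})

test_that("Louvain reaches within 0.05 of the exhaustive optimum on small graphs", {
  for (g in small_test_graphs()) {
    best <- exhaustive_best_modularity(g)$Q
    got <- detect_communities(g, seed = 2)$modularity
    expect_gte(got, best - 0.05)
  }
})

test_that("graph export writes valid GEXF/GraphML and edge lists round-trip", {
  g <- build_coauthorship_graph(tiny_corpus(), "author")
  part <- detect_communities(g, seed = 1)

  gexf <- tmp_path(".gexf")
  export_graph(g, gexf, "gexf", partition = part)
  doc <- xml2::read_xml(gexf)
  ns <- xml2::xml_ns(doc)
  expect_length(xml2::xml_find_all(doc, "//d1:node", ns), igraph::vcount(g))
  expect_length(xml2::xml_find_all(doc, "//d1:edge", ns), igraph::ecount(g))

  # partition omitted: attributes absent, file still parses
  gexf2 <- tmp_path(".gexf")
  export_graph(g, gexf2, "gexf")
  doc2 <- xml2::read_xml(gexf2)
  expect_length(xml2::xml_find_all(doc2, "//d1:attribute", xml2::xml_ns(doc2)), 1)

  graphml <- tmp_path(".graphml")
  export_graph(g, graphml, "graphml", partition = part)
  g_back <- igraph::read_graph(graphml, format = "graphml")
  expect_equal(igraph::vcount(g_back), igraph::vcount(g))

  csv <- tmp_path(".csv")
  export_graph(g, csv, "edgelist")
  g2 <- read_edgelist_csv(csv)
  A1 <- igraph::as_adjacency_matrix(g, attr = "weight", sparse = FALSE)
  A2 <- igraph::as_adjacency_matrix(g2, attr = "weight", sparse = FALSE)
  expect_equal(A2[rownames(A1), colnames(A1)], A1)

  expect_error(export_graph(g, tmp_path(".x"), "dot"), "unknown graph format")
})
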
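test_that("generation is reproducible and emits exactly n_records + n_duplicates rows", {
  p <- synth_params(n_records = 100, n_duplicates = 8, seed = 31)
  a <- generate_corpus(p)
  b <- generate_corpus(p)
  expect_equal(nrow(a$corpus), 108)
  expect_identical(tibble::as_tibble(a$corpus), tibble::as_tibble(b$corpus))
  expect_identical(a$truth$trl_labels, b$truth$trl_labels)

  # same seed => byte-identical corpus file
  f1 <- tmp_path(".csv"); f2 <- tmp_path(".csv")
  write_bibliographic_csv(a$corpus, f1)
  write_bibliographic_csv(b$corpus, f2)
  expect_identical(readLines(f1), readLines(f2))

  # different seed => different corpus
  c2 <- generate_corpus(synth_params(n_records = 100, n_duplicates = 8, seed = 32))
  expect_false(identical(tibble::as_tibble(a$corpus), tibble::as_tibble(c2$corpus)))
})

test_that("parameter validation rejects infeasible settings", {
  expect_error(synth_params(n_authors = 5, n_blocks = 10), "n_blocks")
  expect_error(synth_params(p_in = 0.1, p_out = 0.5), "p_in")
  expect_error(synth_params(overlap = 1.5), "overlap")
  expect_error(synth_params(trl_distribution = c(TRL1 = 1)), "named")
})

test_that("p_out = 0 confines co-authorship to the planted blocks", {
  sim <- generate_corpus(synth_params(n_records = 150, p_out = 0, seed = 41))
  g <- build_coauthorship_graph(sim$corpus, "author")
  comp <- igraph::components(g)$membership
  blocks <- sim$truth$author_blocks[names(comp)]
  # every connected component lies inside one block
  expect_true(all(tapply(blocks, comp, function(x) length(unique(x))) == 1))
})

test_that("TRL label marginals concentrate around the target distribution", {
  p <- synth_params(n_records = 5000, seed = 51)
  sim <- generate_corpus(p)
  emp <- table(factor(sim$truth$trl_labels, trl_categories())) / 5000
  expect_true(all(abs(as.numeric(emp) - unname(p$trl_distribution)) < 0.02))
})

test_that("benchmarks are uniform samples carrying ground-truth labels", {
  sim <- generate_corpus(synth_params(n_records = 150, seed = 61))
  bm <- make_benchmark(sim$truth, 107, seed = 1)
  expect_equal(nrow(bm), 107)
  expect_true(all(bm$record_id %in% sim$corpus$record_id))
  expect_equal(bm$category, unname(sim$truth$trl_labels[bm$record_id]))

  full <- make_benchmark(sim$truth, 150, seed = 1)
  expect_setequal(full$record_id, names(sim$truth$trl_labels))

  b1 <- make_benchmark(sim$truth, 60, seed = 2)
  b2 <- make_benchmark(sim$truth, 60, seed = 3)
  expect_false(setequal(b1$record_id, b2$record_id))
  expect_gt(length(intersect(b1$record_id, b2$record_id)), 0)

  expect_error(make_benchmark(sim$truth, 151), "cannot label")
})

test_that("planted-partition graphs have the declared shape", {
  pp <- planted_partition_graph(4, 10, 0.9, 0.02, seed = 3)
  expect_equal(igraph::vcount(pp$graph), 40)
  expect_equal(unname(table(pp$blocks)), rep(10L, 4), ignore_attr = TRUE)
  A <- igraph::as_adjacency_matrix(pp$graph, sparse = FALSE)
  expect_equal(A, t(A))
  expect_true(all(diag(A) == 0))
})

test_that("the fully separable regime is recovered end-to-end", {
  # 15 authors per block keeps every planted block densely covered
  sim <- generate_corpus(synth_params(n_records = 150, n_authors = 120,
                                      overlap = 0, p_out = 0, seed = 71))
  # block recovery through the real pipeline path
  g <- build_coauthorship_graph(sim$corpus, "author")
  part <- detect_communities(g, seed = 1)
  ari <- adjusted_rand(part$membership,
                       sim$truth$author_blocks[names(part$membership)])
  expect_equal(ari, 1)
  # label recovery
  res <- classify_corpus(sim$corpus, default_trl_keywords(),
                         measure = "jaccard", top_m = 0)
  expect_equal(mean(res$predicted != sim$truth$trl_labels[res$record_id]), 0)
})
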
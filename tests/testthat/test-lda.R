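test_that("preprocessing lowercases, strips punctuation and stopwords, is idempotent", {
  expect_equal(preprocess("In vitro tests of the extract."),
               c("vitro", "tests", "extract"))
  expect_equal(preprocess(""), character(0))
  expect_equal(preprocess("   \t "), character(0))
  expect_equal(preprocess(NA_character_), character(0))

  texts <- c("Anti-malarial activity, in vivo!", "The EXTRACT; of 2 plants",
             tiny_corpus()$abstract)
  for (t in texts) {
    once <- preprocess(t)
    expect_equal(preprocess(paste(once, collapse = " ")), once)
  }
})

test_that("fitted topic models satisfy the normalization invariants and are reproducible", {
  sim <- generate_corpus(synth_params(n_records = 60, seed = 2))
  m <- fit_topic_model(sim$corpus, K = 5, seed = 10, iterations = 80)
  expect_equal(rowSums(m$theta), rep(1, nrow(m$theta)), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(rowSums(m$phi), rep(1, m$K), tolerance = 1e-8, ignore_attr = TRUE)
  expect_true(all(m$theta >= 0) && all(m$phi >= 0))

  m2 <- fit_topic_model(sim$corpus, K = 5, seed = 10, iterations = 80)
  expect_identical(m$theta, m2$theta)
  expect_identical(m$phi, m2$phi)

  expect_error(fit_topic_model(list(character(0), character(0)), K = 2),
               "empty")
})

test_that("identical documents receive near-identical topic distributions", {
  docs <- replicate(20, rep(c("alpha", "beta", "gamma", "delta"), 25),
                    simplify = FALSE)
  m <- fit_topic_model(docs, K = 3, seed = 4, iterations = 300)
  # topic labels are exchangeable for identical documents, so compare the
  # identifiable quantity: each document's implied word distribution
  wd <- m$theta %*% m$phi
  spread <- apply(wd, 2, function(col) max(col) - min(col))
  expect_lt(max(spread), 0.15)
})

test_that("disjoint generating vocabularies are recovered as distinct dominant topics", {
  # 5 disjoint vocabularies, K = 5: each vocabulary's words should be
  # dominated by one topic, and those topics should be distinct
  sim <- generate_corpus(synth_params(n_records = 150, overlap = 0,
                                      trl_distribution = stats::setNames(rep(0.2, 5), trl_categories()),
                                      seed = 6))
  m <- fit_topic_model(sim$corpus, K = 5, seed = 3, iterations = 250)
  vocabs <- sim$truth$vocabularies$category
  dominant <- vapply(vocabs, function(v) {
    words <- intersect(v, m$vocab)
    mass <- rowSums(m$phi[, words, drop = FALSE])
    which.max(mass)
  }, integer(1))
  expect_equal(length(unique(dominant)), 5)
  # the top-10 words of each dominant topic come from its generating vocabulary
  for (cc in names(vocabs)) {
    top10 <- top_words(m, dominant[[cc]], 10)
    expect_gte(length(intersect(top10, vocabs[[cc]])), 8)
  }
})

test_that("fold-in inference returns a proper distribution concentrated on the right topic", {
  sim <- generate_corpus(synth_params(n_records = 150, overlap = 0,
                                      trl_distribution = stats::setNames(rep(0.2, 5), trl_categories()),
                                      seed = 6))
  m <- fit_topic_model(sim$corpus, K = 5, seed = 3, iterations = 250)
  vocabs <- sim$truth$vocabularies$category
  th <- infer_theta(m, rep(vocabs$TRL2[1:10], 3))
  expect_equal(sum(th), 1, tolerance = 1e-8)
  mass <- rowSums(m$phi[, intersect(vocabs$TRL2, m$vocab), drop = FALSE])
  expect_equal(which.max(th), unname(which.max(mass)))
  # out-of-vocabulary-only input falls back to the uniform distribution
  expect_equal(infer_theta(m, c("zzz_not_seen")), rep(0.2, 5))
})
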
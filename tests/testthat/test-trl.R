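test_that("keyword sets validate category coverage and distinctness", {
  kw <- default_trl_keywords()
  expect_s3_class(kw, "trl_keyword_set")
  expect_setequal(names(kw), trl_categories())
  expect_true(all(lengths(kw) > 0))

  bad <- unclass(kw)
  bad$TRL3 <- bad$TRL2
  expect_error(trl_keyword_set(bad), "identical anchor sets")
  expect_error(trl_keyword_set(bad[1:4]), "exactly the categories")
})

test_that("category and document representations behave per mode", {
  kw <- default_trl_keywords()
  sets <- category_representation(kw, mode = "token_set")
  # anchors are matched on preprocessed tokens: "in vitro" contributes "vitro"
  expect_true("vitro" %in% sets$TRL3)
  expect_false("in" %in% sets$TRL3)

  toks <- preprocess("isolation and fractionation of rare compounds")
  expect_setequal(document_representation(toks, mode = "token_set", top_m = 0),
                  unique(toks))

  sim <- generate_corpus(synth_params(n_records = 80, overlap = 0, seed = 12))
  m <- fit_topic_model(sim$corpus, K = 5, seed = 2, iterations = 150)
  th <- document_representation(preprocess(sim$corpus$abstract[1]), m,
                                mode = "topic_distribution")
  expect_equal(sum(th), 1, tolerance = 1e-8)

  # token set grows monotonically with top_m
  toks2 <- preprocess(sim$corpus$abstract[1])
  prev <- character(0)
  for (tm in c(0, 3, 6, 12)) {
    cur <- document_representation(toks2, m, mode = "token_set", top_m = tm)
    expect_true(all(prev %in% cur))
    prev <- cur
  }

  dists <- category_representation(kw, m, mode = "topic_distribution")
  expect_true(all(abs(vapply(dists, sum, numeric(1)) - 1) < 1e-8))
  # with disjoint per-category vocabularies the category embeddings are
  # pairwise farther apart (JS) than each is to its own regenerated copy
  regen <- category_representation(kw, m, mode = "topic_distribution")
  for (a in trl_categories()) {
    self_d <- trl_distance(dists[[a]], regen[[a]], "jensen_shannon")
    for (b in setdiff(trl_categories(), a)) {
      expect_gt(trl_distance(dists[[a]], dists[[b]], "jensen_shannon"), self_d)
    }
  }

  empty_kw <- trl_keyword_set(list(TRL1 = "qq_zz", TRL2 = kw$TRL2, TRL3 = kw$TRL3,
                                   TRL4_5 = kw$TRL4_5, TRL6_9 = kw$TRL6_9))
  expect_error(category_representation(empty_kw, m, "topic_distribution"), "TRL1")
  expect_error(document_representation(character(0), mode = "token_set"), "no usable tokens")
})

test_that("classification takes the argmin and breaks ties toward the lower category", {
  kw <- default_trl_keywords()
  rec <- tiny_corpus()[1, ]

  # abstract made solely of TRL2 anchors
  rec$abstract <- "isolation, fractionation and chemical characterization"
  res <- classify_corpus(biblio_corpus(rec), kw, measure = "jaccard", top_m = 0)
  expect_equal(res$predicted, "TRL2")
  expect_equal(unname(which.min(unlist(res[1, paste0("d_", trl_categories())]))), 2)

  # no overlap with any anchor set: equidistant, tie resolves to TRL1
  rec$abstract <- "entirely unrelated wording about geology"
  res0 <- classify_corpus(biblio_corpus(rec), kw, measure = "jaccard", top_m = 0)
  expect_equal(res0$predicted, "TRL1")

  # duplicated tokens do not change a token-set classification
  rec$abstract <- "isolation isolation fractionation fractionation isolation"
  resdup <- classify_corpus(biblio_corpus(rec), kw, measure = "jaccard", top_m = 0)
  expect_equal(resdup$predicted, "TRL2")

  # empty abstract: unclassifiable, excluded and counted
  rec2 <- tiny_corpus()[1:2, ]
  rec2$abstract[2] <- ""
  res2 <- classify_corpus(biblio_corpus(rec2), kw, measure = "jaccard", top_m = 0)
  expect_equal(nrow(res2), 1)
  expect_equal(attr(res2, "unclassifiable"), "r2")

  # distribution measures require a model
  expect_error(classify_corpus(biblio_corpus(rec), kw, measure = "hellinger"),
               "requires a fitted model")
})

test_that("fully separable synthetic corpora are classified without error", {
  sim <- generate_corpus(synth_params(n_records = 200, overlap = 0, seed = 17))
  res <- classify_corpus(sim$corpus, default_trl_keywords(), measure = "jaccard",
                         top_m = 0)
  expect_equal(res$predicted,
               unname(sim$truth$trl_labels[res$record_id]))
})

test_that("evaluation computes error rates and a consistent confusion matrix", {
  res <- structure(
    tibble::tibble(record_id = c("a", "b", "c", "d"),
                   predicted = c("TRL1", "TRL2", "TRL2", "TRL6_9")),
    class = c("trl_classification", class(tibble::tibble()))
  )
  bench <- tibble::tibble(record_id = c("a", "b", "c", "d"),
                          category = c("TRL1", "TRL2", "TRL3", "TRL6_9"))
  ev <- evaluate(res, bench)
  expect_equal(ev$error_rate, 0.25)
  expect_equal(sum(diag(ev$confusion)) / ev$n, 1 - ev$error_rate)
  expect_equal(unname(rowSums(ev$confusion)),
               unname(as.integer(table(factor(bench$category, trl_categories())))))

  expect_equal(evaluate(res, bench[c(1, 2, 4), ])$error_rate, 0)
  expect_error(evaluate(res, bench[0, ]), "empty")
  expect_error(evaluate(res, tibble::tibble(record_id = "zz", category = "TRL1")),
               "missing")
})

test_that("measure selection minimizes benchmark error with the fixed tie order", {
  sim <- generate_corpus(synth_params(n_records = 120, overlap = 0, seed = 19))
  m <- fit_topic_model(sim$corpus, K = 5, seed = 2, iterations = 150)
  bench <- make_benchmark(sim$truth, 40, seed = 3)

  single <- select_measure(sim$corpus, default_trl_keywords(), m, bench,
                           measures = "hellinger")
  expect_equal(single$measure, "hellinger")

  sel <- select_measure(sim$corpus, default_trl_keywords(), m, bench, top_m = 0)
  expect_equal(nrow(sel$errors), 4)
  # on a fully separable corpus every measure scores 0: jaccard wins the tie
  expect_equal(sel$measure, "jaccard")
  jac <- sel$errors$error_rate[sel$errors$measure == "jaccard"]
  expect_true(all(jac <= sel$errors$error_rate))
})

test_that("TRL distributions reproduce the printed share table and cross-tabs balance", {
  counts <- c(26, 834, 83, 464, 442)
  res <- structure(
    tibble::tibble(
      record_id = sprintf("r%04d", seq_len(sum(counts))),
      predicted = rep(trl_categories(), counts)
    ),
    class = c("trl_classification", class(tibble::tibble()))
  )
  dist <- trl_distribution(res, decimals = 0)
  expect_equal(dist$n, counts)
  expect_equal(dist$share, c(1, 45, 4, 25, 24))

  ten <- structure(
    tibble::tibble(record_id = sprintf("r%d", 1:10), predicted = "TRL2"),
    class = c("trl_classification", class(tibble::tibble()))
  )
  d10 <- trl_distribution(ten)
  expect_equal(d10$n[d10$category == "TRL2"], 10L)
  expect_equal(d10$share[d10$category == "TRL2"], 100)

  sim <- generate_corpus(synth_params(n_records = 150, seed = 23))
  res2 <- classify_corpus(sim$corpus, default_trl_keywords(), measure = "jaccard",
                          top_m = 0)
  tab <- trl_by_country(res2, sim$corpus, top_k = 100)
  long <- tibble::tibble(
    country = unlist(sim$corpus$countries),
    n = 1L
  )
  per_country <- dplyr::count(long, country, wt = n)
  expect_equal(tab$total[match(per_country$country, tab$country)], per_country$n)
})

test_that("classification error is non-decreasing in vocabulary overlap", {
  eps_grid <- c(0, 0.2, 0.4, 0.6)
  mean_err <- vapply(eps_grid, function(eps) {
    errs <- vapply(1:3, function(s) {
      sim <- generate_corpus(synth_params(n_records = 120, overlap = eps,
                                          seed = 100 + s))
      res <- classify_corpus(sim$corpus, default_trl_keywords(),
                             measure = "jaccard", top_m = 0)
      mean(res$predicted != sim$truth$trl_labels[res$record_id])
    }, numeric(1))
    mean(errs)
  }, numeric(1))
  expect_true(all(diff(mean_err) >= 0))
})
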
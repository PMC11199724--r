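# Shared fixtures and independent oracles.

empty_lists <- function(n) replicate(n, character(0), simplify = FALSE)

# Six hand-written records used for network and metric checks.
tiny_corpus <- function() {
  biblio_corpus(tibble::tibble(
    record_id = sprintf("r%d", 1:6),
    doi = c("10.1/a", "10.1/b", NA, "10.1/d", NA, "10.1/f"),
    title = sprintf("Paper %d", 1:6),
    abstract = c(
      "isolation and fractionation of compounds",
      "in vitro tests of the extract",
      "clinical trial of efficacy in patients",
      "in vivo assays with rats",
      "chemical characterization by chromatography",
      "ethnobotanical survey of plants"
    ),
    year = c(2010L, 2010L, 2010L, 2011L, 2012L, 2012L),
    doc_type = c("article", "article", "review", "article", "article", "other"),
    language = c("English", "English", "English", "Portuguese", "English", "English"),
    authors = list(c("A", "B"), c("A", "B"), c("A", "C"), "C", c("B", "C", "D"), "D"),
    institutions = list("UFAM", c("UFAM", "USP"), "USP", "USP", "INPA", "INPA"),
    countries = list("Brazil", c("Brazil", "Spain"), "Spain", "Peru", "Brazil", "Brazil"),
    author_keywords = list(c("k1", "k2"), c("k1", "k3"), "k2", "k1", c("k2", "k3"), character(0)),
    index_keywords = list("x1", "x1", character(0), "x2", "x1", "x2"),
    citation_count = c(10L, 5L, 3L, 0L, 7L, 2L)
  ))
}

# Hand-counted co-authorship adjacency of tiny_corpus() at author level:
# r1,r2 give A-B twice; r3 gives A-C; r5 gives B-C, B-D, C-D.
tiny_author_edges <- function() {
  tibble::tibble(
    from = c("A", "A", "B", "B", "C"),
    to = c("B", "C", "C", "D", "D"),
    weight = c(2L, 1L, 1L, 1L, 1L)
  )
}

# Brute-force weighted modularity: direct double sum over ordered node
# pairs, Q = 1/(2W) * sum_ij (A_ij - k_i k_j / (2W)) [c_i == c_j],
# with the self-pair term -k_i^2/(2W) included (A_ii = 0, no self-loops).
brute_force_modularity <- function(graph, membership) {
  A <- as.matrix(igraph::as_adjacency_matrix(graph, attr = "weight", sparse = FALSE))
  vn <- igraph::V(graph)$name
  m <- membership[vn]
  k <- rowSums(A)
  W2 <- sum(A) # = 2W
  q <- 0
  for (i in seq_along(vn)) {
    for (j in seq_along(vn)) {
      if (m[i] == m[j]) q <- q + A[i, j] - k[i] * k[j] / W2
    }
  }
  unname(q / W2)
}

# All set partitions of n labeled items, as membership integer vectors
# (restricted-growth strings).
all_partitions <- function(n) {
  out <- list()
  recurse <- function(prefix, maxv) {
    if (length(prefix) == n) {
      out[[length(out) + 1]] <<- prefix
      return(invisible())
    }
    for (v in seq_len(maxv + 1)) {
      recurse(c(prefix, v), max(maxv, v))
    }
  }
  recurse(integer(0), 0L)
  out
}

# Exhaustive modularity optimum over every partition of the graph's nodes.
exhaustive_best_modularity <- function(graph) {
  vn <- igraph::V(graph)$name
  best <- -Inf
  best_part <- NULL
  for (p in all_partitions(length(vn))) {
    q <- modularity_score(graph, stats::setNames(p, vn))
    if (q > best) {
      best <- q
      best_part <- stats::setNames(p, vn)
    }
  }
  list(Q = best, membership = best_part)
}

weighted_graph <- function(edges) {
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  if (is.null(igraph::E(g)$weight)) igraph::E(g)$weight <- 1
  g
}

# Small graphs exercised by the modularity oracle checks.
small_test_graphs <- function() {
  list(
    single_edge = weighted_graph(data.frame(from = "a", to = "b", weight = 1)),
    triangle_pair = weighted_graph(data.frame(
      from = c("a", "b", "c", "d", "e", "f"),
      to = c("b", "c", "a", "e", "f", "d"),
      weight = 1
    )),
    path5 = weighted_graph(data.frame(from = letters[1:4], to = letters[2:5], weight = 1)),
    k5 = weighted_graph(as.data.frame(t(utils::combn(letters[1:5], 2)) |>
                                        `colnames<-`(c("from", "to")))),
    weighted7 = weighted_graph(data.frame(
      from = c("a", "a", "b", "c", "d", "e", "f", "a"),
      to = c("b", "c", "c", "d", "e", "f", "g", "g"),
      weight = c(3, 2, 4, 1, 5, 2, 3, 1)
    ))
  )
}

adjusted_rand <- function(a, b) mclust::adjustedRandIndex(a, b)

tmp_path <- function(ext) tempfile(fileext = ext)

# Compare the record content of two corpora, ignoring provenance bookkeeping.
expect_same_records <- function(a, b) {
  xa <- tibble::as_tibble(a); xb <- tibble::as_tibble(b)
  attr(xa, "provenance") <- NULL; attr(xb, "provenance") <- NULL
  class(xa) <- class(tibble::tibble()); class(xb) <- class(tibble::tibble())
  expect_equal(xa, xb)
}
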
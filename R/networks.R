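graph_from_tallies <- function(node_tbl, pair_tbl, level) {
  g <- igraph::graph_from_data_frame(
    d = pair_tbl, directed = FALSE,
    vertices = node_tbl
  )
  igraph::graph_attr(g, "level") <- level
  g
}

# Tally unordered within-record entity pairs over a list of per-record
# entity vectors (already restricted to retained nodes, already unique).
pair_tally <- function(entity_lists) {
  pairs <- lapply(entity_lists, function(e) {
    if (length(e) < 2) return(NULL)
    e <- sort(e)
    idx <- utils::combn(length(e), 2)
    data.frame(from = e[idx[1, ]], to = e[idx[2, ]])
  })
  pairs <- dplyr::bind_rows(pairs)
  if (nrow(pairs) == 0) {
    return(tibble::tibble(from = character(0), to = character(0), weight = integer(0)))
  }
  dplyr::summarise(dplyr::group_by(pairs, .data$from, .data$to),
                   weight = dplyr::n(), .groups = "drop")
}

#' Build a co-authorship graph
#'
#' Nodes are entities (countries, institutions, or authors); node weight
#' `pubs` is the entity's whole-counted publication total; an edge's weight
#' counts the records on which both endpoints appear together.  Entities
#' below `min_docs` publications are removed *before* edges are formed, so
#' the threshold defines the network's node set.  A record listing a single
#' retained entity contributes a node but no edge; a record listing the same
#' entity twice counts it once (no self-loops).
#'
#' @param corpus a `biblio_corpus`.
#' @param level `"country"`, `"institution"`, or `"author"`.
#' @param min_docs minimum publications for a node to enter the graph.
#' @return an undirected `igraph` with vertex attribute `pubs`, edge
#'   attribute `weight`, and graph attribute `level`.
#' @export
build_coauthorship_graph <- function(corpus, level, min_docs = 1) {
  stopifnot(is_biblio_corpus(corpus))
  level <- match.arg(level, c("country", "institution", "author"))
  field <- level_field(level)
  counts <- entity_counts(corpus, level, min_docs = min_docs)
  keep <- counts$entity
  node_tbl <- data.frame(name = sort(keep),
                         pubs = counts$publication_count[match(sort(keep), counts$entity)])
  lists <- lapply(corpus[[field]], function(e) intersect(unique(e), keep))
  graph_from_tallies(node_tbl, pair_tally(lists), level)
}

#' Build a keyword co-occurrence graph
#'
#' Nodes are keywords; node weight `pubs` is the number of publications
#' containing the keyword; edge weight counts records containing both
#' keywords.  Keywords occurring in fewer than `min_occurrence` records are
#' removed before edge construction.
#'
#' @param corpus a `biblio_corpus`.
#' @param which `"both"` (author plus index keywords, the "total keywords"
#'   convention), `"author"`, or `"indexed"`.
#' @param min_occurrence minimum record count for a keyword node.
#' @return an undirected `igraph` (see [build_coauthorship_graph()]).
#' @export
build_keyword_cooccurrence <- function(corpus, which = "both", min_occurrence = 1) {
  stopifnot(is_biblio_corpus(corpus))
  which <- match.arg(which, c("both", "author", "indexed"))
  lists <- switch(which,
    author = corpus$author_keywords,
    indexed = corpus$index_keywords,
    both = Map(function(a, b) unique(c(a, b)),
               corpus$author_keywords, corpus$index_keywords)
  )
  lists <- lapply(lists, unique)
  occ <- table(unlist(lists, use.names = FALSE))
  keep <- names(occ)[occ >= min_occurrence]
  node_tbl <- data.frame(name = sort(keep), pubs = as.integer(occ[sort(keep)]))
  lists <- lapply(lists, intersect, y = keep)
  graph_from_tallies(node_tbl, pair_tally(lists), "keyword")
}

#' Weighted Newman-Girvan modularity
#'
#' For a partition of an undirected weighted graph into communities,
#' `Q = sum_c [ w_c / W - (s_c / (2 W))^2 ]`, where `w_c` is the total
#' intra-community edge weight, `s_c` the total weighted degree of nodes in
#' community `c`, and `W` the total edge weight of the graph.  `Q` lies in
#' `[-1, 1)` and is invariant under community relabeling.
#'
#' @param graph an undirected `igraph` with at least one edge; edge weights
#'   taken from the `weight` attribute (1 if absent).
#' @param membership named vector (node name -> community id) or a vector in
#'   vertex order; must cover every node.
#' @return the modularity score.
#' @export
modularity_score <- function(graph, membership) {
  if (igraph::ecount(graph) == 0) {
    abort_arg("modularity is undefined for a graph with no edges")
  }
  vn <- igraph::V(graph)$name
  if (!is.null(names(membership))) {
    if (!setequal(names(membership), vn)) {
      abort_arg("partition must assign every node exactly one community")
    }
    membership <- membership[vn]
  } else if (length(membership) != length(vn)) {
    abort_arg("partition must assign every node exactly one community")
  }
  comm <- as.integer(factor(membership))
  w <- igraph::E(graph)$weight %||% rep(1, igraph::ecount(graph))
  if (is.null(igraph::E(graph)$weight)) w <- rep(1, igraph::ecount(graph))
  ends <- igraph::ends(graph, igraph::E(graph), names = FALSE)
  W <- sum(w)
  deg <- igraph::strength(graph, weights = w)
  # intra-community weight per community: credit the edge to its (shared)
  # community; inter-community edges contribute nothing
  intra <- rep(0, max(comm))
  same <- comm[ends[, 1]] == comm[ends[, 2]]
  if (any(same)) {
    agg <- tapply(w[same], comm[ends[same, 1]], sum)
    intra[as.integer(names(agg))] <- agg
  }
  s_c <- tapply(deg, comm, sum)
  s_full <- rep(0, max(comm))
  s_full[as.integer(names(s_c))] <- s_c
  sum(intra / W - (s_full / (2 * W))^2)
}

#' Louvain community detection
#'
#' Multilevel modularity optimization (local moving plus graph aggregation)
#' on a weighted undirected graph.  The seed fixes the node-visiting order,
#' making the result reproducible.  Communities are always subsets of
#' connected components, and the returned partition's modularity is at least
#' that of the all-singletons partition.
#'
#' @param graph an undirected `igraph`; edge weights from `weight`.
#' @param seed integer RNG seed.
#' @return a `community_partition`: list with `membership` (named integer
#'   vector) and `modularity` (`NA` for an edgeless graph, where every node
#'   becomes its own community).
#' @export
detect_communities <- function(graph, seed = 1L) {
  vn <- igraph::V(graph)$name
  if (igraph::ecount(graph) == 0) {
    memb <- stats::setNames(seq_along(vn), vn)
    return(structure(list(membership = memb, modularity = NA_real_,
                          seed = seed), class = "community_partition"))
  }
  w <- igraph::E(graph)$weight
  if (is.null(w)) w <- rep(1, igraph::ecount(graph))
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  cl <- igraph::cluster_louvain(graph, weights = w, resolution = 1)
  memb <- stats::setNames(as.integer(igraph::membership(cl)), vn)
  structure(list(
    membership = memb,
    modularity = modularity_score(graph, memb),
    seed = seed
  ), class = "community_partition")
}

#' @export
print.community_partition <- function(x, ...) {
  cat(sprintf("<community_partition> %d nodes, %d communities, Q = %s\n",
              length(x$membership), length(unique(x$membership)),
              format(x$modularity, digits = 4)))
  invisible(x)
}

#' Export a graph to GEXF, GraphML, or an edge-list CSV
#'
#' Node attributes written: `pubs` (publication count) and, when a partition
#' is supplied, `community`.  Edge attribute: `weight`.
#'
#' @param graph a non-empty `igraph`.
#' @param path output file path.
#' @param format `"gexf"`, `"graphml"`, or `"edgelist"`.
#' @param partition optional `community_partition` (or named membership
#'   vector); omitted attributes simply do not appear in the file.
#' @return `path`, invisibly.
#' @export
export_graph <- function(graph, path, format = c("gexf", "graphml", "edgelist"),
                         partition = NULL) {
  if (igraph::vcount(graph) == 0) abort_arg("cannot export an empty graph")
  format <- tryCatch(match.arg(format),
                     error = function(e) abort_arg("unknown graph format: ",
                                                   paste(format, collapse = "/")))
  memb <- NULL
  if (!is.null(partition)) {
    memb <- if (inherits(partition, "community_partition")) partition$membership else partition
    memb <- memb[igraph::V(graph)$name]
  }
  if (format == "graphml") {
    g <- graph
    if (!is.null(memb)) igraph::V(g)$community <- as.integer(memb)
    igraph::write_graph(g, path, format = "graphml")
  } else if (format == "edgelist") {
    ends <- igraph::ends(graph, igraph::E(graph))
    w <- igraph::E(graph)$weight
    if (is.null(w)) w <- rep(1L, igraph::ecount(graph))
    readr::write_csv(tibble::tibble(source = ends[, 1], target = ends[, 2],
                                    weight = w), path, progress = FALSE)
  } else {
    write_gexf(graph, path, memb)
  }
  invisible(path)
}

# Hand-built GEXF 1.2 writer (node weights, community attribute, edge weights).
write_gexf <- function(graph, path, membership = NULL) {
  doc <- xml2::xml_new_root("gexf",
    xmlns = "http://www.gexf.net/1.2draft", version = "1.2")
  gr <- xml2::xml_add_child(doc, "graph", defaultedgetype = "undirected")
  attrs <- xml2::xml_add_child(gr, "attributes", class = "node")
  xml2::xml_add_child(attrs, "attribute", id = "0", title = "pubs", type = "integer")
  if (!is.null(membership)) {
    xml2::xml_add_child(attrs, "attribute", id = "1", title = "community", type = "integer")
  }
  nodes <- xml2::xml_add_child(gr, "nodes")
  vn <- igraph::V(graph)$name
  pubs <- igraph::V(graph)$pubs
  for (i in seq_along(vn)) {
    nd <- xml2::xml_add_child(nodes, "node", id = vn[i], label = vn[i])
    av <- xml2::xml_add_child(nd, "attvalues")
    if (!is.null(pubs)) {
      xml2::xml_add_child(av, "attvalue", `for` = "0", value = as.character(pubs[i]))
    }
    if (!is.null(membership)) {
      xml2::xml_add_child(av, "attvalue", `for` = "1",
                          value = as.character(as.integer(membership[i])))
    }
  }
  edges <- xml2::xml_add_child(gr, "edges")
  if (igraph::ecount(graph) > 0) {
    ends <- igraph::ends(graph, igraph::E(graph))
    w <- igraph::E(graph)$weight
    if (is.null(w)) w <- rep(1, igraph::ecount(graph))
    for (i in seq_len(nrow(ends))) {
      xml2::xml_add_child(edges, "edge", id = as.character(i - 1),
                          source = ends[i, 1], target = ends[i, 2],
                          weight = as.character(w[i]))
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read an edge-list CSV back into a graph
#'
#' Round-trip companion of `export_graph(format = "edgelist")`.
#'
#' @param path CSV with columns `source`, `target`, `weight`.
#' @return an undirected weighted `igraph`.
#' @export
read_edgelist_csv <- function(path) {
  df <- readr::read_csv(path, col_types = "ccd", progress = FALSE)
  igraph::graph_from_data_frame(df, directed = FALSE)
}
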
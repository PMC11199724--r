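#!/usr/bin/env Rscript
# Stage 4: collaboration and keyword co-occurrence networks with Louvain
# communities, for the full window and the two sub-periods.

library(phytometrics)

corpus <- read_corpus_jsonl("results/data/corpus_clean.jsonl")
dir.create("results/graphs", recursive = TRUE, showWarnings = FALSE)

periods <- list(full = c(2002, 2022), p1 = c(2002, 2012), p2 = c(2013, 2022))
thresholds <- list(country = 10, institution = 10, author = 5)

for (pname in names(periods)) {
  p <- periods[[pname]]
  sub <- filter_by_period(corpus, p[1], p[2])
  cat(sprintf("[%s] %d records\n", pname, nrow(sub)))
  for (level in c("country", "institution", "author")) {
    g <- build_coauthorship_graph(sub, level, thresholds[[level]])
    if (igraph::ecount(g) == 0) next
    part <- detect_communities(g, seed = 1)
    cat(sprintf("  %-12s %3d nodes %4d edges  %d communities  Q = %.3f\n",
                level, igraph::vcount(g), igraph::ecount(g),
                length(unique(part$membership)), part$modularity))
    export_graph(g, sprintf("results/graphs/%s_%s.gexf", pname, level),
                 "gexf", partition = part)
    export_graph(g, sprintf("results/graphs/%s_%s_edges.csv", pname, level),
                 "edgelist")
  }
  kg <- build_keyword_cooccurrence(sub, "both", min_occurrence = 10)
  if (igraph::ecount(kg) > 0) {
    kpart <- detect_communities(kg, seed = 1)
    cat(sprintf("  %-12s %3d nodes %4d edges  %d communities  Q = %.3f\n",
                "keyword", igraph::vcount(kg), igraph::ecount(kg),
                length(unique(kpart$membership)), kpart$modularity))
    export_graph(kg, sprintf("results/graphs/%s_keyword.gexf", pname),
                 "gexf", partition = kpart)
  }
}
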
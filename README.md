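# phytometrics

Scientometrics of the medicinal-plant and herbal-medicine literature:
corpus cleaning, bibliometric indicators, collaboration networks, and
Technology Readiness Level (TRL) classification of publication abstracts.

Research planners working on phytomedicine (and, more broadly, on any
regulated R&D pipeline) need to know not just *who* publishes and *with
whom*, but *how mature* the published work is — basic extract
identification, compound isolation, in vitro testing, animal studies, or
clinical trials. This package implements that full analysis path for
Scopus-style bibliographic exports:

- **corpus I/O and cleaning** — CSV parsing with multi-value fields,
  DOI/title-year deduplication, idempotent alias maps for entity-name
  normalization, period filtering, JSON-lines interchange format;
- **bibliometrics** — annual series, whole-counted entity rankings,
  percentage shares and citation ratios with half-up reporting rounding;
- **networks** — co-authorship graphs (country / institution / author) and
  keyword co-occurrence graphs with document thresholds applied to the node
  set, weighted Newman–Girvan modularity
  `Q = Σ_c [ w_c/W − (s_c/2W)² ]`, seeded Louvain community detection, and
  GEXF / GraphML / edge-list export;
- **TRL classification** — the nine TRL levels grouped into five categories
  (TRL1, TRL2, TRL3, TRL4-5, TRL6-9), anchor-keyword sets per category, a
  built-in collapsed-Gibbs LDA topic model, and argmin classification under
  Jaccard (term sets), Hellinger, Kullback–Leibler, or Jensen–Shannon
  (topic distributions), with benchmark-driven measure selection;
- **synthetic corpora** — a generator with ground truth (planted
  collaboration blocks, TRL labels, injected duplicates and name variants)
  so every stage is testable without proprietary data.

## Worked example

```r
library(phytometrics)

sim    <- generate_corpus(synth_params(n_records = 600, seed = 20260927))
corpus <- deduplicate(sim$corpus)

head(entity_counts(corpus, "country"), 3)
#>   entity        publication_count citation_total citation_ratio
#> 1 Brazil                      416           5683           13.7
#> 2 United States               118           1801           15.3
#> 3 Spain                        54            675           12.5

g    <- build_coauthorship_graph(corpus, "author", min_docs = 5)
part <- detect_communities(g, seed = 1)
part
#> <community_partition> 200 nodes, 8 communities, Q = 0.6623

model  <- fit_topic_model(corpus, K = 20, seed = 1)
result <- classify_corpus(corpus, default_trl_keywords(), model,
                          measure = "jaccard")
trl_distribution(result, decimals = 0)
#>   category     n share
#> 1 TRL1        11     2
#> 2 TRL2       240    40
#> 3 TRL3        26     4
#> 4 TRL4_5     179    30
#> 5 TRL6_9     144    24
```

The ranking table reads: Brazil appears on 416 of 600 records (whole
counting — a record credits every country it lists), with 13.7 citations
per record. The eight detected author communities match the generator's
eight planted collaboration blocks (modularity 0.66). The TRL table says
the simulated literature concentrates in TRL2 (isolation/characterization,
40%) with substantial TRL4-5 (animal/formulation, 30%) and TRL6-9
(clinical, 24%) segments — the mixture the generator was asked to
produce.

The numbered scripts under `analysis/` run the same stages as a narrated
workflow (simulate → clean → indicators → networks → TRL), writing tables
and GEXF graphs under `results/`.

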
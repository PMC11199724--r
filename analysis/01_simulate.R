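#!/usr/bin/env Rscript
# Stage 1: generate the working corpus.
#
# The original bibliographic snapshot is proprietary, so the analysis runs on
# a synthetic corpus that reproduces its statistical structure: 2002-2022
# with a post-2010 surge, one dominant country (~66%), eight planted author
# collaboration blocks, the observed five-category TRL mixture, and a known
# set of injected duplicates and institution name variants for the cleaning
# stage to find.

library(phytometrics)

dir.create("results/data", recursive = TRUE, showWarnings = FALSE)

params <- synth_params(
  n_records = 600, n_duplicates = 20, n_name_variants = 4,
  n_authors = 160, seed = 20260927
)
sim <- generate_corpus(params)

write_bibliographic_csv(sim$corpus, "results/data/corpus_raw.csv")
jsonlite::write_json(
  list(
    trl_labels = as.list(sim$truth$trl_labels),
    author_blocks = as.list(sim$truth$author_blocks),
    duplicate_pairs = sim$truth$duplicate_pairs,
    name_variants = as.list(sim$truth$name_variants)
  ),
  "results/data/ground_truth.json",
  auto_unbox = TRUE, dataframe = "rows"
)
bench <- make_benchmark(sim$truth, 107, seed = 1)
readr::write_csv(bench, "results/data/benchmark.csv")

cat(sprintf("generated %d rows (%d records + %d injected duplicates)\n",
            nrow(sim$corpus), params$n_records, params$n_duplicates))
cat(sprintf("benchmark: %d manually-labeled-style records\n", nrow(bench)))
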
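#!/usr/bin/env Rscript
# Stage 5: TRL classification -- fit the topic model, pick the distance
# measure on the labeled benchmark, classify every abstract, and tabulate
# the maturity distribution overall and per country.

library(phytometrics)

corpus <- read_corpus_jsonl("results/data/corpus_clean.jsonl")
bench <- readr::read_csv("results/data/benchmark.csv", col_types = "cc")
bench <- bench[bench$record_id %in% corpus$record_id, ]
keywords <- default_trl_keywords()

model <- fit_topic_model(corpus, K = 20, seed = 1)
cat(sprintf("LDA: K = %d, vocabulary %d terms\n", model$K, length(model$vocab)))

sel <- select_measure(corpus, keywords, model, bench)
cat("benchmark error per measure:\n")
for (i in seq_len(nrow(sel$errors))) {
  cat(sprintf("  %-18s %.1f%%\n", sel$errors$measure[i],
              100 * sel$errors$error_rate[i]))
}
cat(sprintf("selected measure: %s\n", sel$measure))

result <- classify_corpus(corpus, keywords, model, measure = sel$measure)
readr::write_csv(result, "results/tables/trl_classification.csv")
cat(sprintf("classified %d records (%d unclassifiable)\n", nrow(result),
            length(attr(result, "unclassifiable"))))

dist <- trl_distribution(result, decimals = 0)
readr::write_csv(dist, "results/tables/trl_distribution.csv")
cat("TRL distribution:\n")
for (i in seq_len(nrow(dist))) {
  cat(sprintf("  %-7s %4d records (%d%%)\n", dist$category[i], dist$n[i],
              dist$share[i]))
}

by_country <- trl_by_country(result, corpus, top_k = 5)
readr::write_csv(by_country, "results/tables/trl_by_country.csv")

ev <- evaluate(result, bench)
cat(sprintf("benchmark error with %s: %.1f%% (n = %d)\n",
            sel$measure, 100 * ev$error_rate, ev$n))
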
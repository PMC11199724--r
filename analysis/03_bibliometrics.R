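#!/usr/bin/env Rscript
# Stage 3: descriptive indicators -- annual series, entity rankings with
# citation ratios, document-type shares.

library(phytometrics)

corpus <- read_corpus_jsonl("results/data/corpus_clean.jsonl")
dir.create("results/tables", recursive = TRUE, showWarnings = FALSE)

annual <- annual_counts(corpus)
readr::write_csv(annual, "results/tables/annual_counts.csv")
cat(sprintf("peak year: %d (%d records)\n",
            annual$year[which.max(annual$n)], max(annual$n)))

for (level in c("country", "institution", "author")) {
  tab <- entity_counts(corpus, level)
  tab$citation_ratio <- round_half_up(tab$citation_ratio, 1)
  readr::write_csv(tab, sprintf("results/tables/ranking_%s.csv", level))
}

countries <- entity_counts(corpus, "country")
top <- utils::head(countries, 5)
cat("top countries (whole counting):\n")
for (i in seq_len(nrow(top))) {
  cat(sprintf("  %-15s %4d records (%.1f%%), citation ratio %.1f\n",
              top$entity[i], top$publication_count[i],
              share(top$publication_count[i], nrow(corpus), 1),
              round_half_up(top$citation_ratio[i], 1)))
}

types <- entity_counts(corpus, "doc_type")
cat("document types:\n")
for (i in seq_len(nrow(types))) {
  cat(sprintf("  %-8s %.1f%%\n", types$entity[i],
              share(types$publication_count[i], nrow(corpus), 1)))
}
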
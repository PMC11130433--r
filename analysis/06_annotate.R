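#!/usr/bin/env Rscript
# Stage 6: candidate genes within 15 kb of every high-confidence SNP,
# from the simulated GFF3 annotation.

library(tempoqtl)

config <- default_run_config(out_dir = "results/pipeline", seed = 1)
config$stages <- "annotate"
run_pipeline(config)

cand <- utils::read.table(file.path(config$out_dir, "candidates.tsv"),
  header = TRUE, sep = "\t"
)
if (nrow(cand)) {
  cat(sprintf(
    "%d candidate gene/marker pair(s); %d with the marker inside the gene body.\n",
    nrow(cand), sum(cand$relation == "contains")
  ))
  print(utils::head(cand, 5), row.names = FALSE)
} else {
  cat("No high-confidence marker fell within 15 kb of a simulated gene.\n")
}
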
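#!/usr/bin/env Rscript
# Stage 3: per-day broad-sense heritability for every trait from the
# one-way random-effects model over replicates, and a summary of when
# each trait is most heritable.

library(tempoqtl)

config <- default_run_config(out_dir = "results/pipeline", seed = 1)
config$stages <- "heritability"
run_pipeline(config)

h2 <- utils::read.table(file.path(config$out_dir, "heritability.tsv"),
  header = TRUE, sep = "\t"
)
h2 <- h2[h2$DAP >= 12, ] # early days are dominated by germination timing
peaks <- do.call(rbind, lapply(split(h2, h2$trait), function(d) {
  d[which.max(d$H2), c("trait", "DAP", "H2")]
}))
utils::write.table(peaks, "results/heritability_peaks.tsv",
  sep = "\t", quote = FALSE, row.names = FALSE
)
cat("Peak heritability per trait (written to results/heritability_peaks.tsv):\n")
print(peaks, row.names = FALSE)
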
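#!/usr/bin/env Rscript
# Stage 2: derive the analysis traits from the raw measurement tables —
# composite area from the three camera views, germination/death calling
# and accession exclusion, 40-MAD artifact removal, per-plant loess
# smoothing, biomass calibration against endpoint fresh weight, WUE and
# RGR — then aggregate replicates by their median.

library(tempoqtl)

config <- default_run_config(out_dir = "results/pipeline", seed = 1)
config$stages <- "traits"
run_pipeline(config)

acc <- utils::read.table(file.path(config$out_dir, "traits_accession.tsv"),
  header = TRUE, sep = "\t"
)
pheno <- utils::read.csv(file.path(config$out_dir, "phenotypes.csv"))
cat(sprintf(
  "Derived %s for %d accessions (of %d simulated) over DAP %d-%d.\n",
  paste(unique(acc$trait), collapse = ", "),
  length(unique(acc$accession)), length(unique(pheno$accession)),
  min(acc$DAP), max(acc$DAP)
))
a51 <- acc[acc$trait == "area" & acc$DAP == 51, "value"]
cat(sprintf(
  "Median accession area at 51 DAP: %.0f px (IQR %.0f-%.0f).\n",
  median(a51), quantile(a51, 0.25), quantile(a51, 0.75)
))
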
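#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study — structured inbred genotypes, one
# planted transient growth-rate QTL (DAP 20-30), daily pixel-level
# phenotypes under the three-phase temperature schedule, watering records
# and a toy gene annotation. All downstream scripts read the plain-text
# files this writes under results/pipeline/.

library(tempoqtl)

config <- default_run_config(out_dir = "results/pipeline", seed = 1)
config$stages <- "simulate"
run_pipeline(config)

truth <- jsonlite::read_json(file.path(config$out_dir, "truth.json"))
geno <- read_dosage_tsv(file.path(config$out_dir, "genotypes.tsv"))
qtl <- truth$qtl_specs[[1]]
cat(sprintf(
  "Panel: %d accessions x %d markers; planted QTL at marker index %d (%s), rate effect %.2f/day active DAP %d-%d.\n",
  nrow(geno$dosages), ncol(geno$dosages), qtl$marker_index,
  geno$map$marker[qtl$marker_index], qtl$effect_size,
  qtl$window[[1]], qtl$window[[2]]
))
cat(sprintf(
  "%d plants never germinate; %d outlier cells injected.\n",
  length(truth$nongerminated), length(truth$outliers)
))
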
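#!/usr/bin/env Rscript
# Stage 4: temporal trait profiles — Ward clustering of the WUE profiles
# over DAP 12-56, a silhouette-vs-k curve to sanity-check the cluster
# count, and early/late ideotype classification from window-averaged
# WUE and height:biomass percentiles.

library(tempoqtl)

config <- default_run_config(out_dir = "results/pipeline", seed = 1)
config$stages <- c("cluster", "ideotype")
run_pipeline(config)

assign <- utils::read.table(
  file.path(config$out_dir, "cluster_assignments.tsv"),
  header = TRUE, sep = "\t"
)
cat(sprintf(
  "WUE profiles cluster into %d groups; sizes: %s.\n",
  config$k_clusters, paste(table(assign$cluster), collapse = ", ")
))

acc <- utils::read.table(file.path(config$out_dir, "traits_accession.tsv"),
  header = TRUE, sep = "\t"
)
sil <- silhouette_curve(acc, config$cluster_trait, k_range = 2:9)
utils::write.table(sil, "results/silhouette_vs_k.tsv",
  sep = "\t", quote = FALSE, row.names = FALSE
)
cat(sprintf(
  "Mean silhouette is maximal at k = %d (curve in results/silhouette_vs_k.tsv).\n",
  sil$k[which.max(sil$mean_silhouette)]
))

for (w in c("early", "late")) {
  rep_ <- jsonlite::read_json(
    file.path(config$out_dir, paste0("ideotype_", w, ".json")),
    simplifyVector = TRUE
  )
  cat(sprintf(
    "%s window (DAP %d-%d): %d ideotype-positive, %d ideotype-negative accession(s).\n",
    w, rep_$window[1], rep_$window[2],
    length(rep_$positives), length(rep_$negatives)
  ))
}
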
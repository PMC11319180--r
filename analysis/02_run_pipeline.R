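#!/usr/bin/env Rscript
# Step 2: full discovery -> replication -> meta-analysis scan.
#
# Reads the synthetic study written by 01_simulate_study.R, runs the
# complete MR pipeline per lipid (instrument selection, five
# estimators, sensitivity battery), applies BH-FDR across lipids,
# selects candidates on the discovery cohort, re-analyses candidates on
# the replication cohort, and pools the two with DerSimonian-Laird
# random-effects meta-analysis. Tables land in results/pipeline/.

library(lipidmr)

data_dir <- "results/data"
manifest <- read.delim(file.path(data_dir, "manifest.tsv"))
exposures <- lapply(manifest$exposure, function(id) {
  list(discovery = file.path(data_dir, id, "exposure_discovery.tsv"),
       replication = file.path(data_dir, id, "exposure_replication.tsv"))
})
names(exposures) <- manifest$exposure

cfg <- pipeline_config(
  exposures,
  outcome_discovery = file.path(data_dir, "outcome_discovery.tsv"),
  outcome_replication = file.path(data_dir, "outcome_replication.tsv"),
  outcome_id = "ICH",
  seed = 90210L, n_boot = 1000, n_sim = 1000,
  out_dir = "results/pipeline"
)
res <- run_pipeline(cfg)
print(res)

dec <- res$decisions
cat("\nIVW-significant lipids:",
    sum(dec$ivw_sig), "of", nrow(dec), "\n")
cat("candidates after the sensitivity battery:",
    paste(dec$exposure[dec$candidate], collapse = ", "), "\n")
truth <- manifest$exposure[manifest$theta != 0]
cat("planted causal lipids:", paste(truth, collapse = ", "), "\n")
hit <- sort(dec$exposure[dec$candidate])
cat(if (identical(hit, sort(truth))) {
  "planted-truth recovery: exact\n"
} else "planted-truth recovery: MISMATCH (see tables)\n")
cat("meta-analysed candidates:", length(res$meta),
    "| forest rows:", nrow(res$forest), "\n")
cat("outputs under results/pipeline/\n")
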
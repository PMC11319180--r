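#!/usr/bin/env Rscript
# Step 1: generate the synthetic two-cohort study.
#
# Builds a scan of 20 synthetic lipid-species exposures against one
# binary outcome, with three lipids carrying a true causal effect
# (log-OR 0.1 per SD) and the rest null. Each lipid gets 10 independent
# instruments; discovery and replication cohorts are drawn at the
# sample-size scale of the real study design (exposure GWAS of 7,174;
# outcome effective sizes from 4,056/371,717 and 1,935/471,578
# case/control designs). Everything is written as canonical TSVs under
# results/data/ together with a YAML ground-truth sidecar per lipid.

library(lipidmr)

seed <- 20260927L
n_lipids <- 20
causal <- c(3, 11, 17)
theta <- 0.1
out_dir <- "results/data"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

outcome_disc <- NULL
outcome_repl <- NULL
manifest <- NULL
for (i in seq_len(n_lipids)) {
  id <- sprintf("lipid%02d", i)
  th <- if (i %in% causal) theta else 0
  truth <- simulation_truth(theta = th, j_snps = 10, seed = seed + i,
                            gamma_range = c(0.15, 0.5),
                            maf_range = c(0.2, 0.5))
  sim <- simulate_two_sample(truth)
  relabel <- function(x) {
    x$snp_id <- sprintf("%s_%s", id, x$snp_id)
    x
  }
  lipid_dir <- file.path(out_dir, id)
  write_simulation(sim, lipid_dir)  # raw four tables + truth.yaml
  write_summary_stats(relabel(sim$discovery$exposure),
                      file.path(lipid_dir, "exposure_discovery.tsv"))
  write_summary_stats(relabel(sim$replication$exposure),
                      file.path(lipid_dir, "exposure_replication.tsv"))
  outcome_disc <- rbind(outcome_disc, relabel(sim$discovery$outcome))
  outcome_repl <- rbind(outcome_repl, relabel(sim$replication$outcome))
  manifest <- rbind(manifest,
                    data.frame(exposure = id, theta = th,
                               j_snps = 10, seed = seed + i))
}
write_summary_stats(outcome_disc, file.path(out_dir, "outcome_discovery.tsv"))
write_summary_stats(outcome_repl, file.path(out_dir, "outcome_replication.tsv"))
write.table(manifest, file.path(out_dir, "manifest.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)

cat(sprintf("simulated %d lipids (%d causal at theta = %.2f) -> %s\n",
            n_lipids, length(causal), theta, out_dir))
cat("causal lipids:", sprintf("lipid%02d", causal), "\n")
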
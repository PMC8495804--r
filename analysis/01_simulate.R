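#!/usr/bin/env Rscript
# Step 1 — build the synthetic study.
#
# Generates everything the downstream steps consume: AF/BF and RF/SF
# ortholog quartets evolved from shared ancestors (mostly purifying,
# a few genes under positive selection), 13-taxon conservation panels
# carrying the three planted fox-exclusive substitutions, unigenes
# with planted SSR tracts, and a synthetic annotation map — plus TSV
# truth tables for scoring every later step.

library(farmfox)

study_dir <- "results/study"
cfg <- sim_config(n_genes = 30, n_codons = 300, omega_target = 0.2,
                  n_positive = 3, omega_positive = 3, n_events = 120,
                  seed = 1, n_ssr_seqs = 20, ssr_seq_len = 500)
truth <- generate_study(cfg, study_dir)

cat("study written to", study_dir, "\n")
cat(sprintf("  %d genes (%d evolved under omega = %g, rest at %g)\n",
            cfg$n_genes, cfg$n_positive, cfg$omega_positive,
            cfg$omega_target))
cat(sprintf("  %d conservation panels, %d planted substitution sites: %s\n",
            length(list.files(file.path(study_dir, "panels"))),
            nrow(truth$panel_truth),
            paste(truth$panel_truth$nt_site, collapse = ", ")))
cat(sprintf("  %d unigenes with planted SSRs (units %s)\n",
            nrow(truth$ssr_truth),
            paste(sort(unique(truth$ssr_truth$unit_size)),
                  collapse = ",")))
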
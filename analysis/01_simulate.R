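#!/usr/bin/env Rscript
# Step 1: simulate the study cohort.
#
# Two cohorts mirroring the immunodeficient (n = 8) vs immunocompetent
# (n = 7) design, one shared tumor genotype (toy proteome + spiked somatic
# variants + planted MHC binders), and RNA expression in which
# neoantigen-bearing transcripts are down-scaled by 2^-2 in the
# immunocompetent cohort. Everything is written as FASTA/VCF/TSV under
# results/sim/ so the later steps consume only standard files.

suppressPackageStartupMessages(library(neoedit))

cfg <- sim_config(seed = 20260926, editing_factor_delta = 2)
sim <- simulate_cohort(cfg)
print(cfg)
print(sim)

paths <- write_simulation(sim, "results/sim")
cat("\nWrote", length(paths), "files under results/sim/:\n")
cat(paste(" -", basename(paths)), sep = "\n")
cat(sprintf("\n%d of %d variants carry planted binders across %d transcripts\n",
            sum(sim$truth$planted), nrow(sim$variants),
            length(sim$neo_transcripts)))
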
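#!/usr/bin/env Rscript
# Step 3: candidate mutant peptide enumeration.
#
# Applies each variant to its transcript, derives the consequence, and
# enumerates all 8-11mer mutant peptides: sliding windows around the
# substituted residue for missense variants (aligned reference peptide
# kept), every window of the novel divergent suffix for frameshifts and
# stop-losses (no reference). Stop-gain and synonymous variants yield
# nothing.

suppressPackageStartupMessages(library(neoedit))

tx <- read_transcripts("results/sim/transcripts_cds.fa")
vcf <- read_variant_vcf("results/sim/variants.vcf")
vcf <- vcf[vcf$sample_id == vcf$sample_id[1], ] # variant set is shared
variants <- annotate_variants(vcf, tx)
pairs <- enumerate_pairs(variants, tx)

write_peptide_pairs(pairs, "results/peptide_pairs.tsv")
cat("Enumerated", nrow(pairs), "peptide pairs for",
    length(unique(pairs$variant_id)), "variants\n")
cat("By source:\n")
print(table(pairs$source))
cat("By length:\n")
print(table(pairs$length))
cat("Variants yielding no peptides (stop-gain/synonymous):",
    sum(!variants$variant_id %in% pairs$variant_id), "\n")
cat("Wrote results/peptide_pairs.tsv and results/peptide_pairs.peptides.txt\n")
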
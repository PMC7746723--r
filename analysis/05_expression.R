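#!/usr/bin/env Rscript
# Step 5: RNA-level neoantigen expression.
#
# Normalizes the gene count matrix (FPKM, upper-quartile scaled, log2),
# calls each neoantigenic variant expressed when both alleles have >= 5
# RNA-seq reads, and computes the per-sample expression fraction and the
# mean normalized expression of neoantigen-bearing genes.

suppressPackageStartupMessages(library(neoedit))

sim <- read_simulation("results/sim")
calls <- read.delim("results/neoantigen_calls.tsv", stringsAsFactors = FALSE)
neo_ids <- calls$variant_id[calls$is_neoantigenic]
neo_genes <- unique(sim$variants$contig[sim$variants$variant_id %in% neo_ids])

normalized <- upper_quartile_log2(fpkm(sim$counts, sim$gene_lengths))
write.table(data.frame(transcript_id = rownames(normalized), normalized,
                       check.names = FALSE),
            "results/normalized_expression.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

per_sample <- do.call(rbind, lapply(seq_len(nrow(sim$samples)), function(i) {
  s <- sim$samples$sample_id[i]
  ac <- sim$allele_counts[sim$allele_counts$sample_id == s, ]
  data.frame(
    sample_id = s, cohort = sim$samples$cohort[i],
    expression_fraction = expression_fraction(neo_ids, ac),
    mean_neo_gene_expr = mean_neoantigen_gene_expression(normalized, s,
                                                         neo_genes))
}))
write.table(per_sample, "results/expression_calls.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("Upper-quartile scale factors (per sample):\n")
print(round(attr(normalized, "scale_factors"), 2))
cat("\nPer-sample neoantigen expression (results/expression_calls.tsv):\n")
print(per_sample, row.names = FALSE)
cat("\nCohort means of neoantigen-gene expression:\n")
print(tapply(per_sample$mean_neo_gene_expr, per_sample$cohort, mean))
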
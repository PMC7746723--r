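#!/usr/bin/env Rscript
# Step 4: MHC binding and neoantigen classification.
#
# Scores every peptide against H2-Kb and H2-Db (here: the simulation's
# affinity table; a netMHC output file plugs in through netmhc_predictor())
# and classifies each variant by the dual criterion: some pair with mutant
# IC50 < 500 nM and reference IC50 > 500 nM on the same allele.
# Novel-stretch peptides have no reference and pass on the mutant
# condition alone.

suppressPackageStartupMessages(library(neoedit))

pairs <- read.delim("results/peptide_pairs.tsv", stringsAsFactors = FALSE)
affinities <- read.delim("results/sim/affinities.tsv",
                         stringsAsFactors = FALSE)
truth <- read.delim("results/sim/ground_truth.tsv",
                    stringsAsFactors = FALSE)

calls <- classify_variants(pairs, affinities)
write.table(calls, "results/neoantigen_calls.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("Classified", nrow(calls), "variants;",
    sum(calls$is_neoantigenic), "neoantigenic\n")
planted <- truth$variant_id[truth$planted]
called <- calls$variant_id[calls$is_neoantigenic]
cat("Planted binders recovered:", length(intersect(called, planted)),
    "of", length(planted), "\n")
cat("Coincidental (hash-background) neoantigens:",
    length(setdiff(called, planted)), "\n")
cat("Wrote results/neoantigen_calls.tsv\n")
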
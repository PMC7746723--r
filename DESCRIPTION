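Package: neoedit
Title: Neoantigen Prediction and Transcriptional Immunoediting Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for quantifying immunoediting in tumor
    sequencing cohorts: somatic-variant depth and dbSNP filtering with tumor
    mutational burden, enumeration of mutant 8-11mer peptides with aligned
    reference peptides (sliding windows for missense variants, novel-stretch
    extraction for frameshift and stop-loss), MHC class I binding-based
    neoantigen classification under the dual 500 nM IC50 criterion,
    RNA-read-level neoantigen expression calling, upper-quartile-normalized
    log2 FPKM expression of neoantigen-bearing genes, and two-cohort
    comparisons. Ships a fully deterministic synthetic-cohort generator
    (toy proteome, spiked nonsynonymous variants, planted MHC binders, and a
    tunable immunoediting down-scaling of neoantigen-gene expression) so the
    whole analysis runs with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    vcfR,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    seqinr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
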
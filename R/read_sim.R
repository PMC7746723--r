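#' Read a simulated cohort back from files
#'
#' Reconstructs a cohort object from a directory written by
#' [write_simulation()]: transcripts from the CDS FASTA, variant records and
#' per-sample depths from the VCF, counts/lengths/allele counts/affinities/
#' sample sheet from their TSVs. Variant consequences are re-derived from
#' the transcripts and peptide pairs re-enumerated, so the result feeds
#' [run_pipeline()] exactly like an in-memory [simulate_cohort()] object.
#'
#' @param dir Directory holding the simulation files.
#' @param alleles Alleles expected in the affinity table.
#' @return A list of class `neo_sim` (without `config`; the configuration
#'   JSON, if present, is attached as `config_json`).
#' @export
read_simulation <- function(dir, alleles = DEFAULT_ALLELES) {
  transcripts <- read_transcripts(file.path(dir, "transcripts_cds.fa"))
  vcf <- read_variant_vcf(file.path(dir, "variants.vcf"))
  first <- vcf[vcf$sample_id == vcf$sample_id[1L], , drop = FALSE]
  variants <- annotate_variants(
    first[, c("variant_id", "contig", "pos", "ref_allele", "alt_allele",
              "alt_depth", "total_depth", "in_dbsnp")],
    transcripts)
  dna_depths <- vcf[, c("sample_id", "variant_id", "alt_depth",
                        "total_depth")]
  pairs <- enumerate_pairs(variants, transcripts)
  counts_df <- read.delim(file.path(dir, "gene_counts.tsv"),
                          check.names = FALSE, stringsAsFactors = FALSE)
  counts <- as.matrix(counts_df[, -1, drop = FALSE])
  rownames(counts) <- counts_df[[1L]]
  lengths_df <- read.delim(file.path(dir, "gene_lengths.tsv"),
                           stringsAsFactors = FALSE)
  truth_path <- file.path(dir, "ground_truth.tsv")
  truth <- if (file.exists(truth_path)) {
    read.delim(truth_path, stringsAsFactors = FALSE)
  }
  cfg_path <- file.path(dir, "config.json")
  structure(list(
    transcripts = transcripts,
    variants = variants,
    truth = truth,
    pairs = pairs,
    affinities = read.delim(file.path(dir, "affinities.tsv"),
                            stringsAsFactors = FALSE),
    samples = read.delim(file.path(dir, "samples.tsv"),
                         stringsAsFactors = FALSE),
    dna_depths = dna_depths,
    counts = counts,
    allele_counts = read.delim(file.path(dir, "allele_counts.tsv"),
                               stringsAsFactors = FALSE),
    gene_lengths = setNames(lengths_df$gene_length,
                            lengths_df$transcript_id),
    alleles = alleles,
    config_json = if (file.exists(cfg_path)) {
      jsonlite::read_json(cfg_path, simplifyVector = TRUE)
    }
  ), class = "neo_sim")
}
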
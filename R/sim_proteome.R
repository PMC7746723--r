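#' Generate a toy proteome
#'
#' Draws `n_transcripts` random coding sequences: each starts with ATG,
#' continues with sense codons drawn uniformly, and ends with one of the
#' three stop codons (no internal stop). A random 3' flank of
#' `flank_length` nt is attached per transcript so that stop-loss variants
#' can read through. The protein column is the translation of the CDS with
#' the terminal stop removed; `gene_length` is the CDS length in nt
#' (including the stop codon) and is used downstream for FPKM.
#'
#' @param config A [sim_config()] object.
#' @return A data.frame with columns `transcript_id`, `cds`,
#'   `three_prime_flank`, `protein`, `gene_length`.
#' @examples
#' tx <- generate_proteome(sim_config(seed = 1, n_transcripts = 3))
#' nchar(tx$cds) == 3 * (nchar(tx$protein) + 1)
#' @export
generate_proteome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_transcripts
  lens <- seq(config$cds_length_range[1L], config$cds_length_range[2L])
  len_aa <- lens[sample.int(length(lens), n, replace = TRUE)]
  sense <- .sense_codons()
  cds <- vapply(len_aa, function(L) {
    paste0("ATG",
           paste(sample(sense, L - 1L, replace = TRUE), collapse = ""),
           sample(.STOP_CODONS, 1L))
  }, character(1))
  flank <- vapply(seq_len(n), function(i) {
    paste(sample(.ACGT, config$flank_length, replace = TRUE), collapse = "")
  }, character(1))
  data.frame(
    transcript_id = sprintf("TX%04d", seq_len(n)),
    cds = cds,
    three_prime_flank = flank,
    protein = translate_cds(cds),
    gene_length = nchar(cds),
    stringsAsFactors = FALSE
  )
}

#' Write transcripts as CDS and protein FASTA
#'
#' Writes `<prefix>_cds.fa` holding each CDS plus a companion record
#' `<transcript_id>_flank` with the 3' flank, and `<prefix>_protein.fa`
#' with the translations. Standard 60-column FASTA wrapping.
#'
#' @param transcripts Output of [generate_proteome()].
#' @param dir Output directory (created if missing).
#' @param prefix File-name prefix, default `"transcripts"`.
#' @return Invisibly, the two file paths.
#' @export
write_proteome <- function(transcripts, dir, prefix = "transcripts") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cds_path <- file.path(dir, paste0(prefix, "_cds.fa"))
  prot_path <- file.path(dir, paste0(prefix, "_protein.fa"))
  nt <- c(setNames(transcripts$cds, transcripts$transcript_id),
          setNames(transcripts$three_prime_flank,
                   paste0(transcripts$transcript_id, "_flank")))
  # interleave so each transcript's flank follows its CDS
  ord <- order(names(nt))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(nt[ord]),
                              cds_path, width = 60L)
  aa <- setNames(transcripts$protein, transcripts$transcript_id)
  Biostrings::writeXStringSet(Biostrings::AAStringSet(aa),
                              prot_path, width = 60L)
  invisible(c(cds = cds_path, protein = prot_path))
}

#' Read a transcript FASTA written by [write_proteome()]
#'
#' Reconstructs the transcript table from a CDS FASTA in which 3' flanks are
#' stored as records suffixed `_flank`.
#'
#' @param cds_fasta Path to the CDS FASTA.
#' @return A data.frame with the same columns as [generate_proteome()].
#' @export
read_transcripts <- function(cds_fasta) {
  seqs <- Biostrings::readDNAStringSet(cds_fasta)
  nm <- names(seqs)
  is_flank <- grepl("_flank$", nm)
  cds <- as.character(seqs[!is_flank])
  flank <- as.character(seqs[is_flank])
  names(flank) <- sub("_flank$", "", nm[is_flank])
  ids <- names(cds)
  data.frame(
    transcript_id = ids,
    cds = unname(cds),
    three_prime_flank = unname(flank[ids]),
    protein = translate_cds(unname(cds)),
    gene_length = nchar(unname(cds)),
    stringsAsFactors = FALSE
  )
}
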
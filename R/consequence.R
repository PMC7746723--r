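# Protein-level consequence of a transcript-space variant. Replaces external
# effect annotation: the edit is applied directly to the CDS and both alleles
# are re-translated, reading into the 3' flank when the stop codon is lost
# or shifted out of frame.

#' Derive the protein consequence of a variant
#'
#' Applies the REF->ALT edit to the transcript CDS and translates the result
#' up to the first stop codon, continuing into `three_prime_flank` when the
#' original stop is lost or shifted. Consequence classes:
#' \describe{
#'   \item{missense}{same-length proteins differing at exactly one residue}
#'   \item{frameshift}{indel whose length difference is not divisible by 3}
#'   \item{stop_gain}{mutant protein is a proper prefix of the reference}
#'   \item{stop_loss}{reference protein is a proper prefix of the mutant}
#'   \item{synonymous}{identical proteins}
#'   \item{other}{in-frame indels and multi-residue substitutions}
#' }
#'
#' @param variant One variant record (list or one-row data.frame with
#'   `pos`, `ref_allele`, `alt_allele`).
#' @param transcript One transcript row (with `cds`, `three_prime_flank`,
#'   `protein`).
#' @return A list with `consequence`, `mutant_protein`,
#'   `reference_protein` and `first_divergent` (1-based position of the
#'   first differing residue; NA for synonymous variants).
#' @examples
#' tx <- list(cds = "ATGGCTGCTGCTGCTTGA", three_prime_flank = strrep("A", 300),
#'            protein = "MAAAA")
#' v <- list(pos = 5, ref_allele = "C", alt_allele = "T")
#' derive_consequence(v, tx)$consequence # missense (A2V)
#' @export
derive_consequence <- function(variant, transcript) {
  pos <- as.integer(variant$pos)
  ref <- as.character(variant$ref_allele)
  alt <- as.character(variant$alt_allele)
  cds <- transcript$cds
  if (!nzchar(ref) || !nzchar(alt) || identical(ref, alt)) {
    stop("ref and alt alleles must be nonempty and differ", call. = FALSE)
  }
  if (is.na(pos) || pos < 1L || pos + nchar(ref) - 1L > nchar(cds)) {
    stop("variant does not lie within the CDS", call. = FALSE)
  }
  observed <- substr(cds, pos, pos + nchar(ref) - 1L)
  if (observed != ref) {
    stop(sprintf("REF mismatch at %s:%d (VCF says %s, transcript has %s)",
                 transcript$transcript_id %||% "?", pos, ref, observed),
         call. = FALSE)
  }
  mutated <- paste0(substr(cds, 1L, pos - 1L), alt,
                    substr(cds, pos + nchar(ref), nchar(cds)))
  tr <- .translate_to_first_stop(paste0(mutated, transcript$three_prime_flank))
  if (!tr$stopped) {
    warning("no stop codon found before the end of the 3' flank for ",
            transcript$transcript_id %||% "transcript",
            "; using the full read-through suffix", call. = FALSE)
  }
  mut_prot <- tr$protein
  ref_prot <- transcript$protein
  len_diff <- nchar(alt) - nchar(ref)
  first_div <- .first_divergence(mut_prot, ref_prot)
  consequence <- if (len_diff != 0L) {
    if (abs(len_diff) %% 3L != 0L) "frameshift" else "other"
  } else if (identical(mut_prot, ref_prot)) {
    "synonymous"
  } else if (nchar(mut_prot) < nchar(ref_prot) &&
             startsWith(ref_prot, mut_prot)) {
    "stop_gain"
  } else if (nchar(mut_prot) > nchar(ref_prot) &&
             startsWith(mut_prot, ref_prot)) {
    "stop_loss"
  } else if (nchar(mut_prot) == nchar(ref_prot) &&
             sum(strsplit(mut_prot, "")[[1L]] !=
                 strsplit(ref_prot, "")[[1L]]) == 1L) {
    "missense"
  } else {
    "other"
  }
  list(consequence = consequence,
       mutant_protein = mut_prot,
       reference_protein = ref_prot,
       first_divergent = first_div)
}

#' Annotate variant records with derived consequences
#'
#' Runs [derive_consequence()] for every variant against its transcript
#' (matched by `contig` = `transcript_id`) and appends `consequence`,
#' `mutant_protein` and `first_divergent` columns. If the input already
#' carries a `consequence` column that disagrees with the derived one, the
#' derived value wins and a warning reports the conflicts.
#'
#' @param variants Variant records (data.frame with `contig`, `pos`,
#'   `ref_allele`, `alt_allele`).
#' @param transcripts Transcript table as from [generate_proteome()].
#' @return `variants` with annotation columns appended.
#' @export
annotate_variants <- function(variants, transcripts) {
  idx <- match(variants$contig, transcripts$transcript_id)
  if (anyNA(idx)) {
    stop("variants reference unknown transcripts: ",
         paste(unique(variants$contig[is.na(idx)]), collapse = ", "),
         call. = FALSE)
  }
  ann <- lapply(seq_len(nrow(variants)), function(i) {
    derive_consequence(variants[i, ], transcripts[idx[i], ])
  })
  derived <- vapply(ann, `[[`, character(1), "consequence")
  if ("consequence" %in% names(variants)) {
    clash <- !is.na(variants$consequence) & variants$consequence != derived
    if (any(clash)) {
      warning(sum(clash), " supplied consequence label(s) disagree with the ",
              "derived ones; keeping the derived values", call. = FALSE)
    }
  }
  variants$consequence <- derived
  variants$mutant_protein <- vapply(ann, `[[`, character(1), "mutant_protein")
  variants$first_divergent <- vapply(ann, function(x) {
    as.integer(x$first_divergent %||% NA_integer_)
  }, integer(1))
  variants
}
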
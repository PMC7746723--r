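# Independent oracles used to cross-check the implementation. Translation
# goes through seqinr (a different code path from the package's Biostrings
# route); enumeration is exhaustive substring generation.

# Translate a nucleotide string up to (not including) the first stop codon.
oracle_translate_to_stop <- function(nt) {
  n <- (nchar(nt) %/% 3L) * 3L
  if (n == 0L) return("")
  aa <- seqinr::translate(strsplit(tolower(substr(nt, 1L, n)), "")[[1L]])
  stop_at <- which(aa == "*")
  if (length(stop_at) > 0L) aa <- aa[seq_len(stop_at[1L] - 1L)]
  paste(aa, collapse = "")
}

# Full translation of a complete CDS, stop removed.
oracle_translate_cds <- function(cds) {
  vapply(cds, oracle_translate_to_stop, character(1), USE.NAMES = FALSE)
}

# Re-derive the protein consequence of a variant by string surgery +
# seqinr translation + diff.
oracle_consequence <- function(cds, flank, pos, ref, alt) {
  stopifnot(substr(cds, pos, pos + nchar(ref) - 1L) == ref)
  mut_nt <- paste0(substr(cds, 1L, pos - 1L), alt,
                   substr(cds, pos + nchar(ref), nchar(cds)))
  ref_prot <- oracle_translate_to_stop(cds)
  mut_prot <- oracle_translate_to_stop(paste0(mut_nt, flank))
  ld <- nchar(alt) - nchar(ref)
  cons <- if (ld != 0L) {
    if (abs(ld) %% 3L != 0L) "frameshift" else "other"
  } else if (mut_prot == ref_prot) {
    "synonymous"
  } else if (nchar(mut_prot) < nchar(ref_prot) &&
             substr(ref_prot, 1L, nchar(mut_prot)) == mut_prot) {
    "stop_gain"
  } else if (nchar(mut_prot) > nchar(ref_prot) &&
             substr(mut_prot, 1L, nchar(ref_prot)) == ref_prot) {
    "stop_loss"
  } else {
    a <- strsplit(mut_prot, "")[[1L]]
    b <- strsplit(ref_prot, "")[[1L]]
    if (length(a) == length(b) && sum(a != b) == 1L) "missense" else "other"
  }
  d <- oracle_first_div(mut_prot, ref_prot)
  list(consequence = cons, mutant_protein = mut_prot,
       reference_protein = ref_prot, first_divergent = d)
}

oracle_first_div <- function(a, b) {
  ca <- strsplit(a, "")[[1L]]
  cb <- strsplit(b, "")[[1L]]
  n <- min(length(ca), length(cb))
  if (n > 0L) {
    d <- which(ca[seq_len(n)] != cb[seq_len(n)])
    if (length(d) > 0L) return(d[1L])
  }
  if (length(ca) == length(cb)) NA_integer_ else n + 1L
}

# Every substring of length 8-11 of the mutant protein that covers
# position p, paired with the same window of the reference protein.
oracle_saav_pairs <- function(mut, ref, p) {
  out <- character(0)
  L <- nchar(mut)
  for (k in 8:11) {
    for (s in seq_len(max(L - k + 1L, 0L))) {
      if (s <= p && p <= s + k - 1L) {
        out <- c(out, paste(substr(mut, s, s + k - 1L),
                            substr(ref, s, s + k - 1L), sep = "/"))
      }
    }
  }
  unique(out)
}

# Every substring of length 8-11 of the novel suffix (no reference).
oracle_novel_pairs <- function(mut, first_div) {
  if (is.na(first_div)) return(character(0))
  stretch <- substr(mut, first_div, nchar(mut))
  out <- character(0)
  for (k in 8:11) {
    n <- nchar(stretch)
    if (n >= k) {
      for (s in seq_len(n - k + 1L)) {
        out <- c(out, paste(substr(stretch, s, s + k - 1L), NA, sep = "/"))
      }
    }
  }
  unique(out)
}

# Expected pair set for one variant, from the oracle consequence.
oracle_variant_pairs <- function(cds, flank, pos, ref, alt) {
  oc <- oracle_consequence(cds, flank, pos, ref, alt)
  switch(oc$consequence,
    missense = oracle_saav_pairs(oc$mutant_protein, oc$reference_protein,
                                 oc$first_divergent),
    frameshift = ,
    stop_loss = oracle_novel_pairs(oc$mutant_protein, oc$first_divergent),
    character(0)
  )
}

pair_keys <- function(pairs) {
  unique(paste(pairs$mutant_peptide, pairs$reference_peptide, sep = "/"))
}

# Small handcrafted transcript: 30 codons + stop, with enough flank.
toy_transcript <- function(protein_codons = rep("GCT", 29),
                           flank = strrep("ACGT", 100)) {
  cds <- paste0("ATG", paste(protein_codons, collapse = ""), "TGA")
  list(transcript_id = "TOY1", cds = cds, three_prime_flank = flank,
       protein = neoedit::translate_cds(cds), gene_length = nchar(cds))
}
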
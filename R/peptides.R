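# Enumeration of candidate mutant 8-11mer peptides. Missense variants are
# scanned with a sliding window of 8-11 residues around the substituted
# position; frameshift and stop-loss variants contribute every 8-11mer of
# the novel amino-acid stretch (the divergent suffix), which has no aligned
# reference peptide.

.PEP_LENGTHS <- 8:11

.empty_pairs <- function() {
  data.frame(variant_id = character(0), length = integer(0),
             window_start = integer(0), mutant_peptide = character(0),
             reference_peptide = character(0), source = character(0),
             stringsAsFactors = FALSE)
}

#' Enumerate sliding-window peptide pairs around a substituted residue
#'
#' For a single amino-acid substitution at protein position `p`, returns
#' every window of length 8, 9, 10 and 11 that covers `p`: for each length
#' k the window starts run from `max(1, p - k + 1)` to `min(p, L - k + 1)`.
#' The reference peptide is the same window of the reference protein.
#' Duplicate (mutant, reference) pairs are removed.
#'
#' @param mutant_protein,reference_protein Equal-length amino-acid strings.
#' @param p 1-based substituted position.
#' @param variant_id Identifier carried into the output.
#' @return A data.frame of peptide pairs (`variant_id`, `length`,
#'   `window_start`, `mutant_peptide`, `reference_peptide`,
#'   `source = "saav_window"`).
#' @examples
#' m <- paste0(strrep("A", 49), "V", strrep("A", 50)) # L = 100, p = 50
#' r <- strrep("A", 100)
#' nrow(enumerate_saav_windows(m, r, 50)) # 38 windows
#' @export
enumerate_saav_windows <- function(mutant_protein, reference_protein, p,
                                   variant_id = NA_character_) {
  L <- nchar(mutant_protein)
  if (nchar(reference_protein) != L) {
    stop("mutant and reference proteins must have equal length for ",
         "substitution windows", call. = FALSE)
  }
  p <- as.integer(p)
  if (is.na(p) || p < 1L || p > L) {
    stop("substituted position p out of range", call. = FALSE)
  }
  out <- lapply(.PEP_LENGTHS, function(k) {
    lo <- max(1L, p - k + 1L)
    hi <- min(p, L - k + 1L)
    if (hi < lo) return(NULL)
    s <- lo:hi
    data.frame(variant_id = variant_id, length = k, window_start = s,
               mutant_peptide = substring(mutant_protein, s, s + k - 1L),
               reference_peptide = substring(reference_protein, s, s + k - 1L),
               source = "saav_window", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(list(.empty_pairs()), out))
  out[!duplicated(out[, c("mutant_peptide", "reference_peptide")]), ,
      drop = FALSE]
}

#' Enumerate peptides from a novel amino-acid stretch
#'
#' For frameshift and stop-loss variants the novel peptide is the divergent
#' suffix `mutant_protein[first_divergent..end]`; every substring of length
#' 8-11 is returned with no reference peptide. Optionally, `novel_flank`
#' reference residues immediately preceding the divergence are prepended
#' before extracting windows, so junction-spanning peptides can be included.
#' A novel stretch shorter than 8 residues yields no peptides.
#'
#' @param mutant_protein Mutant amino-acid string.
#' @param first_divergent 1-based position of the first novel residue.
#' @param variant_id Identifier carried into the output.
#' @param novel_flank Number of reference residues to prepend (default 0).
#' @return A data.frame of peptide rows (`reference_peptide` is NA,
#'   `source = "novel_stretch"`; `window_start` is the 1-based start in the
#'   mutant protein).
#' @export
enumerate_novel_stretch <- function(mutant_protein, first_divergent,
                                    variant_id = NA_character_,
                                    novel_flank = 0L) {
  first_divergent <- as.integer(first_divergent)
  if (is.na(first_divergent) || first_divergent < 1L) return(.empty_pairs())
  start <- max(1L, first_divergent - as.integer(novel_flank))
  stretch <- substr(mutant_protein, start, nchar(mutant_protein))
  n <- nchar(stretch)
  out <- lapply(.PEP_LENGTHS, function(k) {
    if (n < k) return(NULL)
    s <- seq_len(n - k + 1L)
    data.frame(variant_id = variant_id, length = k,
               window_start = start + s - 1L,
               mutant_peptide = substring(stretch, s, s + k - 1L),
               reference_peptide = NA_character_,
               source = "novel_stretch", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(list(.empty_pairs()), out))
  out[!duplicated(out$mutant_peptide), , drop = FALSE]
}

#' Enumerate candidate peptides for one variant
#'
#' Dispatches on the derived consequence: missense variants go through
#' [enumerate_saav_windows()] at the substituted position, frameshift and
#' stop-loss variants through [enumerate_novel_stretch()] at the first
#' divergent residue. Stop-gain, synonymous and other variants yield no
#' peptides (truncation creates no novel residues; in-frame events are not
#' enumerated).
#'
#' @param variant One variant record (needs `pos`, `ref_allele`,
#'   `alt_allele`, and `variant_id` if available).
#' @param transcript The matching transcript row.
#' @param novel_flank Passed to [enumerate_novel_stretch()].
#' @return A data.frame of peptide pairs (possibly empty).
#' @export
enumerate_variant <- function(variant, transcript, novel_flank = 0L) {
  dc <- derive_consequence(variant, transcript)
  vid <- as.character(variant$variant_id %||% NA_character_)
  pairs <- switch(dc$consequence,
    missense = enumerate_saav_windows(dc$mutant_protein,
                                      dc$reference_protein,
                                      dc$first_divergent, vid),
    frameshift = ,
    stop_loss = enumerate_novel_stretch(dc$mutant_protein,
                                        dc$first_divergent, vid,
                                        novel_flank = novel_flank),
    .empty_pairs()
  )
  bad <- grepl(sprintf("[^%s]", .AA_ALPHABET), pairs$mutant_peptide)
  if (any(bad)) {
    stop("enumerated peptide contains a non-standard residue", call. = FALSE)
  }
  pairs
}

#' Enumerate peptide pairs for a set of variants
#'
#' Vectorized driver over [enumerate_variant()]: joins variants to their
#' transcripts by `contig` and concatenates the per-variant pair tables.
#'
#' @param variants Variant records (data.frame).
#' @param transcripts Transcript table.
#' @param novel_flank Passed through.
#' @return A single data.frame of peptide pairs for all variants.
#' @export
enumerate_pairs <- function(variants, transcripts, novel_flank = 0L) {
  idx <- match(variants$contig, transcripts$transcript_id)
  if (anyNA(idx)) {
    stop("variants reference unknown transcripts", call. = FALSE)
  }
  out <- lapply(seq_len(nrow(variants)), function(i) {
    enumerate_variant(variants[i, ], transcripts[idx[i], ],
                      novel_flank = novel_flank)
  })
  do.call(rbind, c(list(.empty_pairs()), out))
}

#' Write peptide pairs and a plain peptide list
#'
#' Writes the pair table as TSV and, alongside it, a deduplicated plain list
#' of peptides (one per line) suitable as input for external MHC binding
#' predictors.
#'
#' @param pairs Pair table from [enumerate_pairs()].
#' @param path Output TSV path; the peptide list gets extension
#'   `.peptides.txt`.
#' @return Invisibly, the two paths.
#' @export
write_peptide_pairs <- function(pairs, path) {
  write.table(pairs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  lst <- unique(c(pairs$mutant_peptide,
                  pairs$reference_peptide[!is.na(pairs$reference_peptide)]))
  lst_path <- sub("\\.tsv$", "", path)
  lst_path <- paste0(lst_path, ".peptides.txt")
  writeLines(lst, lst_path)
  invisible(c(pairs = path, peptides = lst_path))
}
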
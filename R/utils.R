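# Internal helpers shared across the pipeline: codon tables, translation,
# peptide validation and the seeded deterministic hash behind the mock
# affinity predictor.

.ACGT <- c("A", "C", "G", "T")
.STOP_CODONS <- c("TAA", "TAG", "TGA")
.AA_ALPHABET <- "ACDEFGHIKLMNPQRSTVWY"

# Standard genetic code as a named character vector (codon -> one-letter aa,
# stop = "*"), taken from Biostrings.
.codon_table <- function() {
  Biostrings::GENETIC_CODE
}

# Sense codons (everything but the three stops).
.sense_codons <- function() {
  setdiff(names(.codon_table()), .STOP_CODONS)
}

#' Translate complete coding sequences
#'
#' Translates CDS nucleotide strings (starting at the first base, standard
#' genetic code) and strips a trailing stop symbol if present. Sequences must
#' have length divisible by three.
#'
#' @param cds Character vector of nucleotide sequences (A/C/G/T).
#' @return Character vector of amino-acid sequences without the terminal stop.
#' @examples
#' translate_cds("ATGGCTTGA") # "MA"
#' @export
translate_cds <- function(cds) {
  if (length(cds) == 0L) return(character(0))
  if (any(nchar(cds) %% 3L != 0L)) {
    stop("all CDS lengths must be divisible by 3")
  }
  aa <- as.character(Biostrings::translate(Biostrings::DNAStringSet(cds)))
  unname(sub("\\*$", "", aa))
}

# Translate nucleotide strings up to (not including) the first stop codon.
# The tail that does not fill a codon is dropped. Returns the protein and
# whether a stop codon was actually reached.
.translate_to_first_stop <- function(nt) {
  n_full <- (nchar(nt) %/% 3L) * 3L
  trimmed <- substr(nt, 1L, n_full)
  aa <- character(length(nt))
  ok <- n_full > 0L
  if (any(ok)) {
    aa[ok] <- as.character(Biostrings::translate(Biostrings::DNAStringSet(trimmed[ok])))
  }
  stop_at <- regexpr("*", aa, fixed = TRUE)
  stopped <- stop_at > 0L
  protein <- ifelse(stopped, substr(aa, 1L, stop_at - 1L), aa)
  list(protein = protein, stopped = stopped)
}

# First position at which two amino-acid strings differ; if one is a proper
# prefix of the other, the position just past the prefix; NA if identical.
.first_divergence <- function(a, b) {
  la <- nchar(a)
  lb <- nchar(b)
  n <- min(la, lb)
  if (n > 0L) {
    ca <- strsplit(a, "", fixed = TRUE)[[1L]][seq_len(n)]
    cb <- strsplit(b, "", fixed = TRUE)[[1L]][seq_len(n)]
    d <- which(ca != cb)
    if (length(d) > 0L) return(d[1L])
  }
  if (la == lb) NA_integer_ else n + 1L
}

# Validate peptides: standard 20-residue alphabet only.
.check_peptides <- function(peptides, lengths = NULL) {
  bad <- grepl(sprintf("[^%s]", .AA_ALPHABET), peptides)
  if (any(bad)) {
    stop("peptide contains non-standard residues: ", peptides[bad][1L])
  }
  if (!is.null(lengths) && any(!nchar(peptides) %in% lengths)) {
    off <- peptides[!nchar(peptides) %in% lengths][1L]
    stop("peptide length outside ", paste(range(lengths), collapse = "-"),
         ": ", off)
  }
  invisible(TRUE)
}

# Deterministic string hash mapped to [0, 1). Independent of R's RNG so that
# mock affinities are reproducible across sessions for a given seed. A simple
# 31-multiplier polynomial hash modulo the Mersenne prime 2^31 - 1; doubles
# hold the intermediate products exactly (31 * 2^31 << 2^53).
.hash01 <- function(x, seed) {
  m <- 2147483647
  salt <- as.numeric(seed) %% m
  vapply(x, function(s) {
    h <- salt
    for (code in utf8ToInt(s)) {
      h <- (h * 31 + code) %% m
    }
    # one extra mixing round reduces correlation between similar strings
    h <- (h * 48271) %% m
    h / m
  }, numeric(1), USE.NAMES = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
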
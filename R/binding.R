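# MHC class I binding through a pluggable predictor contract: any function
# (peptides, allele) -> IC50 nM vector. Built-ins are the seeded mock
# predictor and an adapter over netMHC-style tabular output. Classification
# applies the dual criterion: a peptide pair passes on an allele when the
# mutant IC50 is < 500 nM and the reference IC50 is > 500 nM (strict
# inequalities; novel-stretch peptides without a reference pass on the
# mutant condition alone).

#' Default MHC class I alleles
#'
#' The H2-Kb / H2-Db haplotype of C57BL/6-background mice.
#' @export
DEFAULT_ALLELES <- c("H2-Kb", "H2-Db")

#' Deterministic pseudo-IC50 values for peptides
#'
#' Maps each (peptide, allele) to an IC50 in `range` nM through a seeded
#' string hash: deterministic across sessions, uniform on a skewed log scale
#' so that strong binders are rare (with the default range, about 0.2% of
#' random peptides fall below 500 nM, mimicking the sparsity of true MHC-I
#' binders).
#'
#' @param peptides Character vector of 8-11mer peptides.
#' @param allele Allele name (part of the hash input).
#' @param seed Integer seed.
#' @param range Length-2 numeric: IC50 bounds in nM.
#' @param skew Exponent applied to the uniform hash value on the log scale;
#'   larger values make low IC50s rarer. `skew = 1` gives log-uniform.
#' @return Numeric vector of IC50 values (nM).
#' @export
mock_ic50 <- function(peptides, allele, seed, range = c(1, 50000),
                      skew = 11) {
  .check_peptides(peptides, lengths = .PEP_LENGTHS)
  u <- .hash01(paste0(allele, "|", peptides), seed)
  lo <- log10(range[1L])
  hi <- log10(range[2L])
  # the 1/skew root concentrates mass near the upper bound: strong binders
  # stay rare
  10^(lo + (u^(1 / skew)) * (hi - lo))
}

#' Build a seeded mock binding predictor
#'
#' Returns a predictor function satisfying the contract
#' `function(peptides, allele) -> ic50_nm`, backed by [mock_ic50()].
#'
#' @inheritParams mock_ic50
#' @return A predictor function.
#' @export
mock_predictor <- function(seed, range = c(1, 50000), skew = 11) {
  force(seed); force(range); force(skew)
  function(peptides, allele) mock_ic50(peptides, allele, seed, range, skew)
}

#' Parse netMHC-style tabular output
#'
#' Reads the whitespace-delimited per-peptide table produced by netMHC-class
#' predictors: data lines start with a numeric position and carry allele,
#' peptide and the affinity column in nM. Dashed rules, headers and
#' strong/weak-binder annotations are ignored; only the raw IC50 is kept.
#'
#' @param path Path to the predictor output file.
#' @param affinity_col 1-based index of the affinity (nM) field on data
#'   lines (default 13, the standard layout).
#' @return A data.frame with `peptide`, `allele`, `ic50_nm`.
#' @export
read_netmhc <- function(path, affinity_col = 13L) {
  lines <- readLines(path)
  lines <- trimws(lines)
  keep <- nzchar(lines) & !startsWith(lines, "#") & !startsWith(lines, "-")
  fields <- strsplit(lines[keep], "[[:space:]]+")
  rows <- Filter(function(f) {
    length(f) >= affinity_col && grepl("^[0-9]+$", f[1L]) &&
      !is.na(suppressWarnings(as.numeric(f[affinity_col])))
  }, fields)
  if (length(rows) == 0L) {
    return(data.frame(peptide = character(0), allele = character(0),
                      ic50_nm = numeric(0), stringsAsFactors = FALSE))
  }
  data.frame(
    peptide = vapply(rows, `[[`, character(1), 3L),
    allele = vapply(rows, `[[`, character(1), 2L),
    ic50_nm = vapply(rows, function(f) as.numeric(f[affinity_col]),
                     numeric(1)),
    stringsAsFactors = FALSE
  )
}

#' Build a predictor backed by netMHC output files
#'
#' @param files Named character vector: allele name -> output file path.
#' @param affinity_col Passed to [read_netmhc()].
#' @return A predictor function `(peptides, allele) -> ic50_nm` that errors
#'   on peptides absent from the parsed tables.
#' @export
netmhc_predictor <- function(files, affinity_col = 13L) {
  tabs <- lapply(files, read_netmhc, affinity_col = affinity_col)
  lookup <- do.call(rbind, lapply(names(tabs), function(a) {
    data.frame(allele = a, peptide = tabs[[a]]$peptide,
               ic50_nm = tabs[[a]]$ic50_nm, stringsAsFactors = FALSE)
  }))
  function(peptides, allele) {
    sub <- lookup[lookup$allele == allele, , drop = FALSE]
    idx <- match(peptides, sub$peptide)
    if (anyNA(idx)) {
      stop("no affinity available for peptide ", peptides[is.na(idx)][1L],
           " on allele ", allele, call. = FALSE)
    }
    sub$ic50_nm[idx]
  }
}

#' Predict binding affinities for a peptide set
#'
#' Runs the predictor for every (peptide, allele) combination and returns
#' the long affinity table. Deterministic for a fixed predictor.
#'
#' @param peptides Character vector of 8-11mer peptides (deduplicated).
#' @param alleles Character vector of allele names.
#' @param predictor A predictor function `(peptides, allele) -> ic50_nm`.
#' @return A data.frame with `peptide`, `allele`, `ic50_nm`.
#' @export
predict_affinities <- function(peptides, alleles = DEFAULT_ALLELES,
                               predictor) {
  peptides <- unique(peptides)
  .check_peptides(peptides, lengths = .PEP_LENGTHS)
  out <- lapply(alleles, function(a) {
    ic50 <- predictor(peptides, a)
    if (length(ic50) != length(peptides) || any(!is.finite(ic50)) ||
        any(ic50 <= 0)) {
      bad <- if (length(ic50) == length(peptides)) {
        peptides[!is.finite(ic50) | ic50 <= 0][1L]
      } else "(length mismatch)"
      stop("predictor failed on allele ", a, ", peptide ", bad,
           call. = FALSE)
    }
    data.frame(peptide = peptides, allele = a, ic50_nm = ic50,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# Fast lookup: named numeric vector keyed by "allele|peptide".
.affinity_lookup <- function(affinities) {
  setNames(affinities$ic50_nm,
           paste0(affinities$allele, "|", affinities$peptide))
}

.lookup_ic50 <- function(lookup, allele, peptide) {
  key <- paste0(allele, "|", peptide)
  out <- lookup[key]
  miss <- is.na(out) & !is.na(peptide)
  if (any(miss)) {
    stop("missing affinity for peptide ", peptide[miss][1L], " on allele ",
         allele, call. = FALSE)
  }
  unname(out)
}

#' Classify one peptide pair by the dual IC50 criterion
#'
#' TRUE iff, for at least one allele, the mutant peptide's IC50 is strictly
#' below `threshold_nm` and the reference peptide's IC50 is strictly above
#' it. A pair without a reference peptide (novel stretch) passes on the
#' mutant condition alone; values exactly at the threshold fail.
#'
#' @param mutant_peptide,reference_peptide Peptide strings
#'   (`reference_peptide` may be NA).
#' @param affinities Affinity table from [predict_affinities()] (or any
#'   data.frame with `peptide`, `allele`, `ic50_nm`).
#' @param alleles Alleles to consider.
#' @param threshold_nm IC50 threshold, default 500 nM.
#' @return Logical scalar.
#' @export
classify_pair <- function(mutant_peptide, reference_peptide, affinities,
                          alleles = DEFAULT_ALLELES, threshold_nm = 500) {
  lookup <- .affinity_lookup(affinities)
  any(vapply(alleles, function(a) {
    mut <- .lookup_ic50(lookup, a, mutant_peptide)
    if (is.na(reference_peptide)) return(mut < threshold_nm)
    ref <- .lookup_ic50(lookup, a, reference_peptide)
    mut < threshold_nm && ref > threshold_nm
  }, logical(1)))
}

#' Classify variants as neoantigenic
#'
#' Aggregates the dual IC50 criterion over every peptide pair of every
#' variant and allele: a variant is neoantigenic when at least one of its
#' pairs passes on at least one allele. `best_mutant_ic50_nm` is the
#' minimum mutant IC50 over passing (pair, allele) combinations (NA when no
#' pair passes). Novel-stretch pairs lack a reference peptide; for them the
#' reference condition is waived and `reference_rule` records it.
#'
#' @param pairs Peptide-pair table from [enumerate_pairs()].
#' @param affinities Affinity table covering every peptide in `pairs` on
#'   every allele.
#' @param alleles Alleles to consider.
#' @param threshold_nm IC50 threshold, default 500 nM.
#' @return A data.frame with one row per variant: `variant_id`,
#'   `n_pairs_tested`, `n_pairs_passing`, `is_neoantigenic`,
#'   `best_mutant_ic50_nm`, `reference_rule`.
#' @export
classify_variants <- function(pairs, affinities, alleles = DEFAULT_ALLELES,
                              threshold_nm = 500) {
  if (nrow(pairs) == 0L) {
    return(data.frame(variant_id = character(0), n_pairs_tested = integer(0),
                      n_pairs_passing = integer(0),
                      is_neoantigenic = logical(0),
                      best_mutant_ic50_nm = numeric(0),
                      reference_rule = character(0),
                      stringsAsFactors = FALSE))
  }
  lookup <- .affinity_lookup(affinities)
  pass_by_allele <- matrix(FALSE, nrow(pairs), length(alleles))
  best_by_allele <- matrix(NA_real_, nrow(pairs), length(alleles))
  has_ref <- !is.na(pairs$reference_peptide)
  for (j in seq_along(alleles)) {
    mut <- .lookup_ic50(lookup, alleles[j], pairs$mutant_peptide)
    ref <- rep(NA_real_, nrow(pairs))
    if (any(has_ref)) {
      ref[has_ref] <- .lookup_ic50(lookup, alleles[j],
                                   pairs$reference_peptide[has_ref])
    }
    ok <- mut < threshold_nm & (!has_ref | ref > threshold_nm)
    pass_by_allele[, j] <- ok
    best_by_allele[ok, j] <- mut[ok]
  }
  pair_pass <- rowSums(pass_by_allele) > 0L
  pair_best <- suppressWarnings(apply(best_by_allele, 1L, min, na.rm = TRUE))
  pair_best[!is.finite(pair_best)] <- NA_real_
  split_idx <- split(seq_len(nrow(pairs)), pairs$variant_id)
  out <- lapply(names(split_idx), function(v) {
    i <- split_idx[[v]]
    passing <- pair_pass[i]
    best <- suppressWarnings(min(pair_best[i][passing], na.rm = TRUE))
    data.frame(
      variant_id = v,
      n_pairs_tested = length(i),
      n_pairs_passing = sum(passing),
      is_neoantigenic = any(passing),
      best_mutant_ic50_nm = if (is.finite(best)) best else NA_real_,
      reference_rule = if (all(has_ref[i])) "applied"
                       else if (any(has_ref[i])) "partially waived"
                       else "waived",
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, out)
  res[order(res$variant_id), , drop = FALSE]
}
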
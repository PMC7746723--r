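#' Simulate binding affinities with planted true binders
#'
#' Assigns every peptide in the pair table a deterministic pseudo-IC50 per
#' allele via [mock_ic50()], then plants a ground-truth set of binders: each
#' peptide-yielding variant is selected with probability
#' `true_binder_rate`; for selected ("planted") variants every mutant
#' peptide is overridden to an IC50 below 500 nM and every reference
#' peptide to one above 500 nM, on all alleles, so downstream
#' classification is guaranteed to call exactly these variants neoantigenic
#' when the background produces no coincidental binders.
#'
#' With `background = "hash"` unplanted peptides get the skewed hash IC50 in
#' `[1, 50000]` nM (rare coincidental binders possible); with
#' `background = "none"` they are mapped into `(500, 50000]` nM so no
#' coincidental binder can occur.
#'
#' In the rare event a peptide string is simultaneously a planted variant's
#' mutant peptide and another variant's reference peptide, the mutant
#' (strong-binder) override wins.
#'
#' @param pairs Peptide-pair table from [enumerate_pairs()].
#' @param config A [sim_config()] object (`seed`, `true_binder_rate`).
#' @param alleles Allele names to score.
#' @param background `"hash"` (default) or `"none"`.
#' @return A list with `affinities` (`peptide`, `allele`, `ic50_nm`) and
#'   `planted` (character vector of planted variant ids).
#' @export
simulate_affinities <- function(pairs, config, alleles = DEFAULT_ALLELES,
                                background = c("hash", "none")) {
  stopifnot(inherits(config, "sim_config"))
  background <- match.arg(background)
  set.seed(config$seed + 2L)
  vids <- unique(pairs$variant_id)
  planted <- vids[runif(length(vids)) < config$true_binder_rate]
  planted_rows <- pairs$variant_id %in% planted
  mut_strong <- unique(pairs$mutant_peptide[planted_rows])
  ref_weak <- setdiff(
    unique(na.omit(pairs$reference_peptide[planted_rows])), mut_strong)
  all_pep <- unique(c(pairs$mutant_peptide,
                      na.omit(pairs$reference_peptide)))
  bg_range <- if (background == "hash") c(1, 50000) else c(500.5, 50000)
  bg_skew <- if (background == "hash") 11 else 1
  aff <- do.call(rbind, lapply(alleles, function(a) {
    ic50 <- mock_ic50(all_pep, a, config$seed, bg_range, bg_skew)
    strong <- all_pep %in% mut_strong
    weak <- all_pep %in% ref_weak
    # planted overrides: log-uniform in [1, 500) / (500, 50000]
    ic50[strong] <- mock_ic50(all_pep[strong], a, config$seed + 101L,
                              c(1, 499.9), skew = 1)
    ic50[weak] <- mock_ic50(all_pep[weak], a, config$seed + 102L,
                            c(500.5, 50000), skew = 1)
    data.frame(peptide = all_pep, allele = a, ic50_nm = ic50,
               stringsAsFactors = FALSE)
  }))
  list(affinities = aff, planted = planted)
}
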
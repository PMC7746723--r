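#' Configuration for the synthetic immunoediting cohort generator
#'
#' Bundles and validates every knob of the synthetic-data module. All
#' randomness downstream flows from `seed`: the same configuration produces
#' byte-identical FASTA/VCF/TSV outputs across runs.
#'
#' The defaults emulate the study design the generator targets: two cohorts
#' (immunodeficient n = 8, immunocompetent n = 7), clonal heterozygous
#' variants (VAF 0.5), log-normal baseline expression, and an editing factor
#' `editing_factor_delta` giving the log2 down-scaling applied to
#' neoantigen-bearing transcripts in edited (immunocompetent) samples.
#'
#' @param seed Integer seed driving every random draw.
#' @param n_transcripts Number of toy transcripts in the proteome.
#' @param cds_length_range Length-2 integer vector: min/max CDS length in
#'   codons (excluding the stop codon). Lower bound must be >= 15 so every
#'   11mer window fits around any variant site.
#' @param n_snv Number of spiked missense SNVs.
#' @param n_frameshift Number of spiked 1-bp insertions/deletions.
#' @param n_stopgain Number of spiked stop-introducing SNVs.
#' @param true_binder_rate Probability in \[0, 1\] that a peptide-yielding
#'   variant is planted as a true MHC binder.
#' @param editing_factor_delta Non-negative log2 down-scaling of
#'   neoantigen-gene expected counts in edited samples (0 = no editing).
#' @param mean_total_depth_dna Mean DNA read depth at variant sites (Poisson).
#' @param mean_total_depth_rna Mean RNA read depth at variant sites for a
#'   transcript of average expression.
#' @param vaf Variant allele fraction in (0, 1\]; allele depths are binomial
#'   at this rate.
#' @param cohort_sizes Named integer vector mapping cohort label to sample
#'   count; exactly the cohorts to simulate.
#' @param expr_meanlog,expr_sdlog Parameters of the log-normal baseline
#'   expected count per transcript.
#' @param expr_cell_sdlog Standard deviation (log scale) of the per-cell
#'   log-normal jitter on expected counts, giving RNA-seq-like
#'   overdispersion beyond Poisson sampling.
#' @param flank_length Length (nt) of the random 3' flank emitted per
#'   transcript for stop-loss read-through; must be >= 300.
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(seed = 1, n_transcripts = 10, n_snv = 4,
#'                   n_frameshift = 1, n_stopgain = 1)
#' @export
sim_config <- function(seed = 1L,
                       n_transcripts = 60L,
                       cds_length_range = c(60L, 300L),
                       n_snv = 20L,
                       n_frameshift = 5L,
                       n_stopgain = 3L,
                       true_binder_rate = 0.35,
                       editing_factor_delta = 0,
                       mean_total_depth_dna = 80L,
                       mean_total_depth_rna = 60L,
                       vaf = 0.5,
                       cohort_sizes = c(immunodeficient = 8L,
                                        immunocompetent = 7L),
                       expr_meanlog = 5,
                       expr_sdlog = 1,
                       expr_cell_sdlog = 0.3,
                       flank_length = 300L) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  seed <- as.integer(seed)
  n_transcripts <- as.integer(n_transcripts)
  cds_length_range <- as.integer(cds_length_range)
  if (length(cds_length_range) != 2L ||
      cds_length_range[1L] > cds_length_range[2L]) {
    stop("cds_length_range must be c(min, max) with min <= max",
         call. = FALSE)
  }
  if (cds_length_range[1L] < 15L) {
    stop("cds_length_range lower bound must be >= 15 codons ",
         "(11mer windows must fit around any site)", call. = FALSE)
  }
  counts <- c(n_transcripts = n_transcripts, n_snv = as.integer(n_snv),
              n_frameshift = as.integer(n_frameshift),
              n_stopgain = as.integer(n_stopgain))
  if (any(counts < 0L) || n_transcripts < 1L) {
    stop("transcript and variant counts must be non-negative ",
         "(n_transcripts >= 1)", call. = FALSE)
  }
  n_var <- as.integer(n_snv) + as.integer(n_frameshift) +
    as.integer(n_stopgain)
  # hard upper bound on placeable codons (codons 2..L-1 of each CDS);
  # realized capacity is re-checked in spike_variants()
  if (n_var > n_transcripts * (cds_length_range[2L] - 1L)) {
    stop("not enough placeable codons for the requested variants",
         call. = FALSE)
  }
  if (true_binder_rate < 0 || true_binder_rate > 1) {
    stop("true_binder_rate must lie in [0, 1]", call. = FALSE)
  }
  if (editing_factor_delta < 0) {
    stop("editing_factor_delta must be non-negative", call. = FALSE)
  }
  if (vaf <= 0 || vaf > 1) stop("vaf must lie in (0, 1]", call. = FALSE)
  if (mean_total_depth_dna < 1 || mean_total_depth_rna < 1) {
    stop("mean depths must be positive", call. = FALSE)
  }
  if (is.null(names(cohort_sizes)) || any(!nzchar(names(cohort_sizes)))) {
    stop("cohort_sizes must be a named vector of sample counts",
         call. = FALSE)
  }
  if (any(cohort_sizes < 1L)) {
    stop("each cohort needs at least one sample", call. = FALSE)
  }
  if (expr_sdlog < 0 || expr_cell_sdlog < 0) {
    stop("expression sdlog parameters must be non-negative", call. = FALSE)
  }
  if (flank_length < 300L) {
    stop("flank_length must be >= 300 nt", call. = FALSE)
  }
  structure(list(
    seed = seed,
    n_transcripts = n_transcripts,
    cds_length_range = cds_length_range,
    n_snv = as.integer(n_snv),
    n_frameshift = as.integer(n_frameshift),
    n_stopgain = as.integer(n_stopgain),
    true_binder_rate = true_binder_rate,
    editing_factor_delta = editing_factor_delta,
    mean_total_depth_dna = as.integer(mean_total_depth_dna),
    mean_total_depth_rna = as.integer(mean_total_depth_rna),
    vaf = vaf,
    cohort_sizes = setNames(as.integer(cohort_sizes), names(cohort_sizes)),
    expr_meanlog = expr_meanlog,
    expr_sdlog = expr_sdlog,
    expr_cell_sdlog = expr_cell_sdlog,
    flank_length = as.integer(flank_length)
  ), class = "sim_config")
}

#' @export
#' @method print sim_config
print.sim_config <- function(x, ...) {
  cat("Synthetic cohort configuration (seed ", x$seed, ")\n", sep = "")
  cat("  transcripts: ", x$n_transcripts, " (",
      x$cds_length_range[1L], "-", x$cds_length_range[2L], " codons)\n",
      sep = "")
  cat("  variants: ", x$n_snv, " missense + ", x$n_frameshift,
      " frameshift + ", x$n_stopgain, " stop-gain\n", sep = "")
  cat("  true binder rate: ", x$true_binder_rate,
      "; editing delta (log2): ", x$editing_factor_delta, "\n", sep = "")
  cat("  cohorts:", paste(names(x$cohort_sizes), x$cohort_sizes,
                          sep = "=", collapse = ", "), "\n")
  invisible(x)
}
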
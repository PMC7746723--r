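#' Simulate RNA expression for one cohort
#'
#' Baseline expected counts are log-normal per transcript
#' (`expr_meanlog`, `expr_sdlog`), drawn under `seed + 3` so every cohort of
#' the same configuration shares the same baselines. When `edited = TRUE`,
#' transcripts carrying planted neoantigens have their expected counts
#' multiplied by `2^-editing_factor_delta`. Observed counts per cell are
#' Poisson around the expected count times a per-cell log-normal jitter
#' (`expr_cell_sdlog`), giving RNA-seq-like overdispersion. RNA allele
#' counts per variant are binomial at `vaf` from a depth drawn Poisson with
#' mean proportional to the transcript's count in that sample (scaled so a
#' transcript of average expression has mean depth `mean_total_depth_rna`);
#' a zero count yields zero allele reads.
#'
#' Per-sample draws use the RNG stream in force after the baseline draw, so
#' callers (e.g. [simulate_cohort()]) seed distinct streams per cohort.
#'
#' @param transcripts Transcript table from [generate_proteome()].
#' @param neo_transcripts Character vector of transcript ids carrying
#'   planted neoantigens.
#' @param config A [sim_config()] object.
#' @param sample_ids Sample names (columns of the count matrix).
#' @param edited Logical: apply the editing down-scaling?
#' @param variants Optional variant records (`variant_id`, `contig`) for
#'   which RNA allele counts are drawn.
#' @param stream_seed Optional seed set after the baseline draw, giving the
#'   per-sample randomness its own stream.
#' @return A list with `counts` (genes x samples integer matrix),
#'   `allele_counts` (long data.frame: `sample_id`, `variant_id`,
#'   `ref_reads`, `alt_reads`) and `expected` (the per-transcript expected
#'   counts in force, after editing).
#' @export
simulate_expression <- function(transcripts, neo_transcripts, config,
                                sample_ids, edited = FALSE,
                                variants = NULL, stream_seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 3L)
  mu <- rlnorm(nrow(transcripts), config$expr_meanlog, config$expr_sdlog)
  names(mu) <- transcripts$transcript_id
  if (!is.null(stream_seed)) set.seed(as.integer(stream_seed))
  is_neo <- transcripts$transcript_id %in% neo_transcripts
  expected <- mu
  if (edited) {
    expected[is_neo] <- expected[is_neo] * 2^(-config$editing_factor_delta)
  }
  n_g <- nrow(transcripts)
  n_s <- length(sample_ids)
  jitter <- matrix(exp(rnorm(n_g * n_s, 0, config$expr_cell_sdlog)),
                   n_g, n_s)
  counts <- matrix(rpois(n_g * n_s, expected * jitter), n_g, n_s,
                   dimnames = list(transcripts$transcript_id, sample_ids))
  allele_counts <- NULL
  if (!is.null(variants) && nrow(variants) > 0L) {
    # depth scale: transcript of average expression -> mean_total_depth_rna
    k <- config$mean_total_depth_rna /
      exp(config$expr_meanlog + config$expr_sdlog^2 / 2)
    g_idx <- match(variants$contig, transcripts$transcript_id)
    rows <- lapply(seq_len(n_s), function(s) {
      depth <- rpois(nrow(variants), counts[cbind(g_idx, s)] * k)
      alt <- rbinom(nrow(variants), depth, config$vaf)
      data.frame(sample_id = sample_ids[s],
                 variant_id = variants$variant_id,
                 ref_reads = depth - alt, alt_reads = alt,
                 stringsAsFactors = FALSE)
    })
    allele_counts <- do.call(rbind, rows)
  }
  list(counts = counts, allele_counts = allele_counts, expected = expected)
}
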
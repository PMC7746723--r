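# End-to-end analysis over a simulated (or assembled) cohort, and the
# repeated-seed editing-recovery experiment.

#' Run the full neoantigen immunoediting analysis on a cohort
#'
#' For every sample: dbSNP and depth filtering of the variant records, TMB,
#' neoantigen classification (dual IC50 criterion over the cohort affinity
#' table), neoantigen fraction, RNA-level expression fraction, and the mean
#' upper-quartile log2 FPKM expression of neoantigen-bearing genes.
#'
#' @param sim A `neo_sim` object from [simulate_cohort()], or a list with
#'   the same components (`variants` annotated with consequences, `pairs`,
#'   `affinities`, `samples`, `dna_depths`, `counts`, `allele_counts`,
#'   `gene_lengths`, `alleles`).
#' @param min_alt_depth,min_total_depth Somatic depth filter thresholds.
#' @param threshold_nm IC50 threshold for the dual binding criterion.
#' @param min_reads,strict RNA expression rule, see [is_expressed()].
#' @param restrict_to_expressed Restrict the neoantigen-gene set of the
#'   expression average to genes with an expressed neoantigenic variant.
#' @return An object of class `neo_result`: list with `summaries` (one row
#'   per sample), `calls` (per-variant classification), `normalized`
#'   (normalized expression matrix), `neo_genes`, and the settings used.
#' @export
run_pipeline <- function(sim,
                         min_alt_depth = 4L, min_total_depth = 15L,
                         threshold_nm = 500, min_reads = 5L,
                         strict = FALSE, restrict_to_expressed = FALSE) {
  variants <- sim$variants
  stopifnot("consequence" %in% names(variants))
  calls <- classify_variants(sim$pairs, sim$affinities,
                             alleles = sim$alleles %||% DEFAULT_ALLELES,
                             threshold_nm = threshold_nm)
  neo_ids <- calls$variant_id[calls$is_neoantigenic]
  gene_of <- setNames(variants$contig, variants$variant_id)
  normalized <- upper_quartile_log2(fpkm(sim$counts, sim$gene_lengths))

  rows <- lapply(seq_len(nrow(sim$samples)), function(i) {
    s <- sim$samples$sample_id[i]
    d <- sim$dna_depths[sim$dna_depths$sample_id == s, , drop = FALSE]
    vs <- variants
    vs$alt_depth <- d$alt_depth[match(vs$variant_id, d$variant_id)]
    vs$total_depth <- d$total_depth[match(vs$variant_id, d$variant_id)]
    vs <- filter_depth(filter_dbsnp(vs), min_alt_depth, min_total_depth)
    tmb <- count_tmb(vs)
    neo_s <- intersect(neo_ids, vs$variant_id)
    ac_s <- sim$allele_counts[sim$allele_counts$sample_id == s, ,
                              drop = FALSE]
    expr_frac <- expression_fraction(neo_s, ac_s, min_reads = min_reads,
                                     strict = strict)
    genes_s <- unique(gene_of[neo_s])
    if (restrict_to_expressed && length(neo_s) > 0L) {
      idx <- match(neo_s, ac_s$variant_id)
      expressed <- !is.na(idx) &
        is_expressed(ac_s$alt_reads[idx], ac_s$ref_reads[idx],
                     min_reads = min_reads, strict = strict)
      genes_s <- unique(gene_of[neo_s[expressed]])
    }
    data.frame(
      sample_id = s,
      cohort = sim$samples$cohort[i],
      tmb = tmb,
      n_neoantigenic = length(neo_s),
      neoantigen_fraction = neoantigen_fraction(length(neo_s), tmb),
      expression_fraction = expr_frac,
      mean_neo_gene_expr = mean_neoantigen_gene_expression(
        normalized, s, genes_s),
      stringsAsFactors = FALSE
    )
  })
  structure(list(
    summaries = do.call(rbind, rows),
    calls = calls,
    normalized = normalized,
    neo_genes = unique(unname(gene_of[neo_ids])),
    settings = list(min_alt_depth = min_alt_depth,
                    min_total_depth = min_total_depth,
                    threshold_nm = threshold_nm, min_reads = min_reads,
                    strict = strict,
                    restrict_to_expressed = restrict_to_expressed)
  ), class = "neo_result")
}

#' @export
#' @method print neo_result
print.neo_result <- function(x, ...) {
  cat("Neoantigen immunoediting analysis:", nrow(x$summaries),
      "samples,", sum(x$calls$is_neoantigenic), "neoantigenic variants\n")
  print(x$summaries, row.names = FALSE)
  invisible(x)
}

#' Repeated-seed editing-recovery experiment
#'
#' Simulates a fresh cohort and runs the full pipeline for each of
#' `n_seeds` seeds (derived deterministically from `config$seed`), then
#' tests the chosen per-sample metric between the two cohorts. Used both
#' for the power of the generator's editing effect (delta > 0) and for its
#' type-I error (delta = 0).
#'
#' @param config Base [sim_config()]; seed `i` of the experiment uses
#'   `(config$seed + i * 1009) mod (2^31 - 1)`.
#' @param n_seeds Number of replicate simulations.
#' @param metric Summary column to test (default `"mean_neo_gene_expr"`).
#' @param method Test passed to [compare_cohorts()].
#' @param edited_cohort,background Passed to [simulate_cohort()].
#' @param alpha Rejection level used for the returned rejection rate.
#' @return A list with `results` (data.frame `seed`, `estimate`,
#'   `p_value`; NA when the comparison was undefined for that seed),
#'   `n_defined` (seeds with a defined comparison) and `rejection_rate`
#'   (over the defined seeds).
#' @export
run_editing_experiment <- function(config, n_seeds = 100L,
                                   metric = "mean_neo_gene_expr",
                                   method = "welch_t",
                                   edited_cohort = "immunocompetent",
                                   background = "hash",
                                   alpha = 0.05) {
  res <- lapply(seq_len(n_seeds), function(i) {
    cfg <- config
    cfg$seed <- as.integer((config$seed + i * 1009) %% 2147483647)
    sim <- simulate_cohort(cfg, edited_cohort = edited_cohort,
                           background = background)
    out <- run_pipeline(sim)
    # a simulated tumor without any neoantigenic variant leaves the metric
    # undefined for every sample; such seeds contribute no test
    cmp <- tryCatch(
      suppressMessages(
        compare_cohorts(out$summaries, metric, method = method,
                        cohort_order = names(config$cohort_sizes))),
      error = function(e) NULL)
    if (is.null(cmp)) {
      return(data.frame(seed = cfg$seed, estimate = NA_real_,
                        p_value = NA_real_))
    }
    data.frame(seed = cfg$seed, estimate = cmp$estimate,
               p_value = cmp$p_value)
  })
  results <- do.call(rbind, res)
  defined <- !is.na(results$p_value)
  if (sum(defined) < n_seeds) {
    message(n_seeds - sum(defined),
            " seed(s) had an undefined cohort comparison and were dropped")
  }
  list(results = results,
       n_defined = sum(defined),
       rejection_rate = mean(results$p_value[defined] < alpha))
}
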
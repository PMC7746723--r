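#' Simulate a complete two-cohort study with known ground truth
#'
#' Runs the whole generator: toy proteome, spiked somatic variants, peptide
#' enumeration, planted binding affinities, per-sample DNA depths, and
#' per-cohort RNA expression with the configured editing factor applied to
#' the `edited_cohort`. Everything flows from `config$seed`; identical
#' configurations give identical objects and byte-identical files from
#' [write_simulation()].
#'
#' @param config A [sim_config()] object.
#' @param edited_cohort Name of the cohort whose neoantigen-bearing
#'   transcripts are down-scaled by `2^-editing_factor_delta` (default
#'   `"immunocompetent"`; must be one of `names(config$cohort_sizes)` or
#'   NULL for no editing anywhere).
#' @param alleles MHC alleles to score.
#' @param background Mock-affinity background, see [simulate_affinities()].
#' @return An object of class `neo_sim`: a list with `config`,
#'   `transcripts`, `variants` (annotated with derived consequences),
#'   `truth` (intended consequences plus `planted` flag), `planted`
#'   (variant ids), `neo_transcripts`, `pairs`, `affinities`, `samples`
#'   (sample_id, cohort, edited), `dna_depths` (long per-sample),
#'   `counts`, `allele_counts`, `gene_lengths`, `alleles`.
#' @examples
#' sim <- simulate_cohort(sim_config(seed = 7, n_transcripts = 20,
#'                                   n_snv = 6, n_frameshift = 2,
#'                                   n_stopgain = 1))
#' @export
simulate_cohort <- function(config,
                            edited_cohort = "immunocompetent",
                            alleles = DEFAULT_ALLELES,
                            background = c("hash", "none")) {
  stopifnot(inherits(config, "sim_config"))
  background <- match.arg(background)
  if (!is.null(edited_cohort) &&
      !edited_cohort %in% names(config$cohort_sizes)) {
    stop("edited_cohort must name one of the configured cohorts",
         call. = FALSE)
  }
  transcripts <- generate_proteome(config)
  sv <- spike_variants(transcripts, config)
  variants <- annotate_variants(sv$variants, transcripts)
  pairs <- enumerate_pairs(variants, transcripts)
  aff <- simulate_affinities(pairs, config, alleles, background)
  truth <- sv$truth
  truth$planted <- truth$variant_id %in% aff$planted
  neo_tx <- unique(truth$transcript_id[truth$planted])

  cohorts <- names(config$cohort_sizes)
  samples <- data.frame(
    sample_id = unlist(lapply(cohorts, function(co) {
      sprintf("%s_%02d", co, seq_len(config$cohort_sizes[[co]]))
    }), use.names = FALSE),
    cohort = rep(cohorts, config$cohort_sizes),
    stringsAsFactors = FALSE
  )
  samples$edited <- !is.null(edited_cohort) &
    samples$cohort == edited_cohort

  # per-sample DNA depths (variant set shared across the cohort)
  set.seed(config$seed + 7L)
  dna_depths <- do.call(rbind, lapply(samples$sample_id, function(s) {
    d <- draw_depths(nrow(variants), config)
    data.frame(sample_id = s, variant_id = variants$variant_id,
               alt_depth = d$alt_depth, total_depth = d$total_depth,
               stringsAsFactors = FALSE)
  }))

  counts <- NULL
  allele_counts <- NULL
  for (ci in seq_along(cohorts)) {
    ids <- samples$sample_id[samples$cohort == cohorts[ci]]
    ed <- !is.null(edited_cohort) && cohorts[ci] == edited_cohort
    ex <- simulate_expression(transcripts, neo_tx, config, ids,
                              edited = ed, variants = variants,
                              stream_seed = config$seed + 10L + ci)
    counts <- if (is.null(counts)) ex$counts else cbind(counts, ex$counts)
    allele_counts <- rbind(allele_counts, ex$allele_counts)
  }

  structure(list(
    config = config,
    transcripts = transcripts,
    variants = variants,
    truth = truth,
    planted = aff$planted,
    neo_transcripts = neo_tx,
    pairs = pairs,
    affinities = aff$affinities,
    samples = samples,
    dna_depths = dna_depths,
    counts = counts,
    allele_counts = allele_counts,
    gene_lengths = setNames(transcripts$gene_length,
                            transcripts$transcript_id),
    alleles = alleles,
    background = background,
    edited_cohort = edited_cohort
  ), class = "neo_sim")
}

#' @export
#' @method print neo_sim
print.neo_sim <- function(x, ...) {
  cat("Synthetic immunoediting cohort (seed ", x$config$seed, ")\n",
      sep = "")
  cat("  ", nrow(x$transcripts), " transcripts, ", nrow(x$variants),
      " variants (", sum(x$truth$planted), " planted binders)\n", sep = "")
  cat("  ", nrow(x$samples), " samples: ",
      paste(names(x$config$cohort_sizes), x$config$cohort_sizes,
            sep = "=", collapse = ", "), "\n", sep = "")
  cat("  editing delta ", x$config$editing_factor_delta, " applied to ",
      x$edited_cohort %||% "none", "\n", sep = "")
  invisible(x)
}

#' Write a simulated cohort to standard-format files
#'
#' Emits the whole simulation in the formats the pipeline consumes: CDS and
#' protein FASTA, a multi-sample VCF v4.2 with AD/DP, gene counts TSV
#' (rows = transcript, columns = sample), gene lengths TSV, RNA allele
#' counts TSV (`sample_id`, `variant_id`, `ref_reads`, `alt_reads`),
#' affinity TSV, sample sheet, ground-truth TSV and the configuration as
#' JSON. No timestamps: identical simulations give byte-identical files.
#'
#' @param sim A `neo_sim` object.
#' @param dir Output directory (created if missing).
#' @return Invisibly, a named vector of file paths.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "neo_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- write_proteome(sim$transcripts, dir)
  vcf <- file.path(dir, "variants.vcf")
  write_variant_vcf(sim$variants, vcf, transcripts = sim$transcripts,
                    sample_depths = sim$dna_depths)
  tsv <- function(x, name, ...) {
    p <- file.path(dir, name)
    write.table(x, p, sep = "\t", quote = FALSE, ...)
    p
  }
  counts <- tsv(data.frame(transcript_id = rownames(sim$counts),
                           sim$counts, check.names = FALSE),
                "gene_counts.tsv", row.names = FALSE)
  lengths <- tsv(data.frame(transcript_id = names(sim$gene_lengths),
                            gene_length = unname(sim$gene_lengths)),
                 "gene_lengths.tsv", row.names = FALSE)
  ac <- tsv(sim$allele_counts, "allele_counts.tsv", row.names = FALSE)
  aff <- tsv(sim$affinities, "affinities.tsv", row.names = FALSE)
  smp <- tsv(sim$samples, "samples.tsv", row.names = FALSE)
  gt <- tsv(sim$truth, "ground_truth.tsv", row.names = FALSE)
  cfg <- file.path(dir, "config.json")
  jsonlite::write_json(unclass(sim$config), cfg, auto_unbox = TRUE,
                       digits = NA)
  invisible(c(paths, vcf = vcf, counts = counts, lengths = lengths,
              allele_counts = ac, affinities = aff, samples = smp,
              truth = gt, config = cfg))
}
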
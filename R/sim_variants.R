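# Spiking somatic variants into the toy proteome. The synthetic "genome" is
# transcript space: one contig per transcript, 1-based positions on the CDS.

# Single-base neighbors of a codon together with their consequence class
# relative to the original amino acid.
.codon_neighbors <- function(codon) {
  tab <- .codon_table()
  aa0 <- tab[[codon]]
  out <- list()
  bases <- strsplit(codon, "", fixed = TRUE)[[1L]]
  for (b in 1:3) {
    for (nb in setdiff(.ACGT, bases[b])) {
      alt <- bases
      alt[b] <- nb
      alt_codon <- paste(alt, collapse = "")
      aa1 <- tab[[alt_codon]]
      cls <- if (aa1 == "*") "stop_gain"
             else if (aa1 == aa0) "synonymous"
             else "missense"
      out[[length(out) + 1L]] <- list(offset = b, ref = bases[b], alt = nb,
                                      class = cls)
    }
  }
  out
}

#' Spike somatic variants into a toy proteome
#'
#' Places `n_snv` missense SNVs, `n_frameshift` 1-bp insertions/deletions and
#' `n_stopgain` stop-introducing SNVs, each in a distinct codon drawn across
#' all transcripts (codons 2..L-1: the start and stop codons are never hit).
#' Positions are 1-based on the transcript sequence with the transcript id as
#' contig. Indels use VCF anchored representation (REF/ALT share a leading
#' base). Tumor allele depths are drawn as total ~ Poisson(mean DNA depth)
#' and alt ~ Binomial(total, vaf).
#'
#' @param transcripts Output of [generate_proteome()].
#' @param config A [sim_config()] object.
#' @return A list with `variants` (VCF-shaped records: `variant_id`,
#'   `contig`, `pos`, `ref_allele`, `alt_allele`, `alt_depth`,
#'   `total_depth`, `in_dbsnp`) and `truth` (per-variant intended
#'   consequence).
#' @export
spike_variants <- function(transcripts, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  n_codons <- nchar(transcripts$cds) %/% 3L # includes the stop codon
  slots <- data.frame(
    tx = rep.int(seq_len(nrow(transcripts)), pmax(n_codons - 2L, 0L)),
    codon = unlist(lapply(n_codons, function(k) seq(2L, k - 1L)),
                   use.names = FALSE)
  )
  n_var <- config$n_snv + config$n_frameshift + config$n_stopgain
  if (n_var > nrow(slots)) {
    stop("not enough placeable codons for the requested variants",
         call. = FALSE)
  }
  used <- logical(nrow(slots))
  pick_slots <- function(n, eligible) {
    idx <- which(eligible & !used)
    if (length(idx) < n) {
      stop("not enough placeable codons for the requested variants",
           call. = FALSE)
    }
    chosen <- idx[sample.int(length(idx), n)]
    used[chosen] <<- TRUE
    chosen
  }
  codons <- substring(transcripts$cds[slots$tx],
                      (slots$codon - 1L) * 3L + 1L, slots$codon * 3L)
  neighbors <- lapply(unique(codons), .codon_neighbors)
  names(neighbors) <- unique(codons)
  has_class <- function(cls) {
    vapply(codons, function(cd) {
      any(vapply(neighbors[[cd]], function(x) x$class == cls, logical(1)))
    }, logical(1), USE.NAMES = FALSE)
  }

  rows <- list()
  add_snv <- function(i, cls) {
    cd <- codons[i]
    opts <- Filter(function(x) x$class == cls, neighbors[[cd]])
    ch <- opts[[sample.int(length(opts), 1L)]]
    pos <- (slots$codon[i] - 1L) * 3L + ch$offset
    list(tx = slots$tx[i], pos = pos, ref = ch$ref, alt = ch$alt,
         consequence = cls, codon_index = slots$codon[i])
  }
  # stop-gain first (most constrained), then missense, then frameshift
  for (i in pick_slots(config$n_stopgain, has_class("stop_gain"))) {
    rows[[length(rows) + 1L]] <- add_snv(i, "stop_gain")
  }
  for (i in pick_slots(config$n_snv, has_class("missense"))) {
    rows[[length(rows) + 1L]] <- add_snv(i, "missense")
  }
  for (i in pick_slots(config$n_frameshift, rep(TRUE, nrow(slots)))) {
    q <- (slots$codon[i] - 1L) * 3L + 1L # first base of the codon
    cds <- transcripts$cds[slots$tx[i]]
    if (runif(1) < 0.5) {
      # 1-bp deletion of base q, anchored at q-1
      rows[[length(rows) + 1L]] <- list(
        tx = slots$tx[i], pos = q - 1L,
        ref = substr(cds, q - 1L, q), alt = substr(cds, q - 1L, q - 1L),
        consequence = "frameshift", codon_index = slots$codon[i])
    } else {
      # 1-bp insertion after base q
      rows[[length(rows) + 1L]] <- list(
        tx = slots$tx[i], pos = q,
        ref = substr(cds, q, q),
        alt = paste0(substr(cds, q, q), sample(.ACGT, 1L)),
        consequence = "frameshift", codon_index = slots$codon[i])
    }
  }
  v <- do.call(rbind, lapply(rows, as.data.frame,
                             stringsAsFactors = FALSE))
  v$contig <- transcripts$transcript_id[v$tx]
  v <- v[order(v$contig, v$pos), , drop = FALSE]
  v$variant_id <- sprintf("VAR%04d", seq_len(nrow(v)))
  depths <- draw_depths(nrow(v), config)
  variants <- data.frame(
    variant_id = v$variant_id,
    contig = v$contig,
    pos = as.integer(v$pos),
    ref_allele = v$ref,
    alt_allele = v$alt,
    alt_depth = depths$alt_depth,
    total_depth = depths$total_depth,
    in_dbsnp = FALSE,
    stringsAsFactors = FALSE
  )
  truth <- data.frame(
    variant_id = v$variant_id,
    transcript_id = v$contig,
    codon_index = as.integer(v$codon_index),
    consequence = v$consequence,
    stringsAsFactors = FALSE
  )
  list(variants = variants, truth = truth)
}

#' Draw tumor allele depths
#'
#' Total depth ~ Poisson(mean depth), mutant-allele depth ~ Binomial(total,
#' vaf). Uses the current RNG stream (no internal seeding) so callers control
#' reproducibility.
#'
#' @param n Number of variants.
#' @param config A [sim_config()] object (uses `mean_total_depth_dna`, `vaf`).
#' @return A data.frame with `alt_depth` and `total_depth`.
#' @export
draw_depths <- function(n, config) {
  total <- rpois(n, config$mean_total_depth_dna)
  alt <- rbinom(n, total, config$vaf)
  data.frame(alt_depth = alt, total_depth = total)
}

#' Write variants as a VCF v4.2 file
#'
#' Emits a transcript-space VCF: one contig per transcript, FORMAT fields
#' `AD` (ref,alt) and `DP`, one column per sample. Depths are taken from
#' `sample_depths` (long data.frame: `sample_id`, `variant_id`,
#' `alt_depth`, `total_depth`); when NULL, the depths carried on `variants`
#' are written as a single column `TUMOR`. Output contains no timestamps, so
#' identical inputs give byte-identical files.
#'
#' @param variants Variant records as from [spike_variants()].
#' @param path Output path.
#' @param transcripts Optional transcript table; adds contig lengths to the
#'   header.
#' @param sample_depths Optional long per-sample depth table.
#' @return Invisibly, `path`.
#' @export
write_variant_vcf <- function(variants, path, transcripts = NULL,
                              sample_depths = NULL) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=neoedit-synthetic-cohort",
    if (!is.null(transcripts)) {
      sprintf("##contig=<ID=%s,length=%d>", transcripts$transcript_id,
              nchar(transcripts$cds) + nchar(transcripts$three_prime_flank))
    },
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths (ref,alt)\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Total read depth\">"
  )
  if (is.null(sample_depths)) {
    sample_ids <- "TUMOR"
    cells <- matrix(sprintf("%d,%d:%d",
                            variants$total_depth - variants$alt_depth,
                            variants$alt_depth, variants$total_depth),
                    ncol = 1L)
  } else {
    sample_ids <- unique(sample_depths$sample_id)
    cells <- vapply(sample_ids, function(s) {
      d <- sample_depths[sample_depths$sample_id == s, , drop = FALSE]
      d <- d[match(variants$variant_id, d$variant_id), , drop = FALSE]
      sprintf("%d,%d:%d", d$total_depth - d$alt_depth, d$alt_depth,
              d$total_depth)
    }, character(nrow(variants)))
    cells <- matrix(cells, nrow = nrow(variants))
  }
  body <- cbind(
    variants$contig, variants$pos, variants$variant_id,
    variants$ref_allele, variants$alt_allele, ".", "PASS", ".", "AD:DP",
    cells
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", sample_ids), collapse = "\t"), con)
  writeLines(apply(body, 1L, paste, collapse = "\t"), con)
  invisible(path)
}
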
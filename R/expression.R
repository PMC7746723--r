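# RNA-level neoantigen expression: the >=5-read two-allele rule, FPKM,
# upper-quartile log2 normalization, the neoantigen expression fraction and
# the mean expression of neoantigen-bearing genes.

#' Is a neoantigen expressed at the RNA level?
#'
#' A neoantigen counts as expressed when both the mutant and the reference
#' alleles are supported by at least `min_reads` RNA-seq reads. With
#' `strict = TRUE` both allele counts must strictly exceed `min_reads`
#' (the ">5 mutant and >5 WT reads" convention).
#'
#' @param alt_reads,ref_reads Non-negative integer vectors of RNA read
#'   counts supporting the mutant and reference alleles.
#' @param min_reads Read threshold, default 5.
#' @param strict Use strict inequalities (default FALSE: at-least).
#' @return Logical vector.
#' @export
is_expressed <- function(alt_reads, ref_reads, min_reads = 5L,
                         strict = FALSE) {
  if (min_reads < 0) {
    stop("min_reads must be non-negative", call. = FALSE)
  }
  if (strict) {
    alt_reads > min_reads & ref_reads > min_reads
  } else {
    alt_reads >= min_reads & ref_reads >= min_reads
  }
}

#' Fragments per kilobase per million mapped fragments
#'
#' `FPKM[g, s] = counts[g, s] * 1e9 / (library_size[s] * gene_length[g])`
#' with `library_size[s]` the column sum of raw counts.
#'
#' @param counts Non-negative gene x sample count matrix with rownames.
#' @param gene_lengths Named positive vector of gene lengths in nt
#'   (names matching rownames of `counts`).
#' @return Numeric matrix of FPKM values, same shape as `counts`.
#' @export
fpkm <- function(counts, gene_lengths) {
  counts <- as.matrix(counts)
  len <- gene_lengths[rownames(counts)]
  if (anyNA(len)) {
    stop("missing gene length for ",
         rownames(counts)[is.na(len)][1L], call. = FALSE)
  }
  if (any(len <= 0)) stop("gene lengths must be positive", call. = FALSE)
  lib <- colSums(counts)
  if (any(lib == 0)) {
    stop("zero library size for sample ",
         colnames(counts)[lib == 0][1L], call. = FALSE)
  }
  counts * 1e9 / outer(as.numeric(len), lib)
}

#' Upper-quartile log2 normalization
#'
#' Per sample, the scale factor is the 75th percentile (linear-interpolation
#' quantile) of FPKM over genes with FPKM > 0 in that sample. Values are
#' rescaled by `C / scale` with `C` the median of the per-sample scale
#' factors (keeping magnitudes comparable across samples), then
#' `log2(x + 1)` transformed. Multiplying one sample's raw counts by a
#' constant leaves its normalized values unchanged.
#'
#' @param fpkm_matrix FPKM matrix from [fpkm()].
#' @return Normalized matrix, same shape, with attributes
#'   `"scale_factors"` (per-sample upper quartiles) and
#'   `"rescale_constant"` (C).
#' @export
upper_quartile_log2 <- function(fpkm_matrix) {
  fpkm_matrix <- as.matrix(fpkm_matrix)
  scales <- apply(fpkm_matrix, 2L, function(x) {
    nz <- x[x > 0]
    if (length(nz) == 0L) {
      stop("sample has no nonzero FPKM values", call. = FALSE)
    }
    quantile(nz, 0.75, names = FALSE, type = 7)
  })
  C <- median(scales)
  out <- log2(sweep(fpkm_matrix, 2L, scales, "/") * C + 1)
  attr(out, "scale_factors") <- scales
  attr(out, "rescale_constant") <- C
  out
}

#' Neoantigen expression fraction for one sample
#'
#' The number of nonsynonymous mutations with expressed neoantigens divided
#' by the total number of nonsynonymous mutations giving rise to
#' neoantigens. Neoantigenic variants without an RNA allele-count row are
#' treated as unexpressed (0 mutant / 0 reference reads) and reported via a
#' message.
#'
#' @param neo_variant_ids Character vector of neoantigenic variant ids in
#'   this sample.
#' @param allele_counts Allele-count rows for this sample (`variant_id`,
#'   `ref_reads`, `alt_reads`).
#' @param min_reads,strict Passed to [is_expressed()].
#' @return Fraction in \[0, 1\], or NA when there are no neoantigenic
#'   variants.
#' @export
expression_fraction <- function(neo_variant_ids, allele_counts,
                                min_reads = 5L, strict = FALSE) {
  if (length(neo_variant_ids) == 0L) return(NA_real_)
  idx <- match(neo_variant_ids, allele_counts$variant_id)
  if (anyNA(idx)) {
    message(sum(is.na(idx)), " neoantigenic variant(s) without RNA allele ",
            "counts; treated as unexpressed")
  }
  alt <- ifelse(is.na(idx), 0L, allele_counts$alt_reads[idx])
  ref <- ifelse(is.na(idx), 0L, allele_counts$ref_reads[idx])
  mean(is_expressed(alt, ref, min_reads = min_reads, strict = strict))
}

#' Mean normalized expression of neoantigen-bearing genes
#'
#' Average of the normalized (upper-quartile log2 FPKM) values of the genes
#' harboring at least one neoantigenic variant, for one sample.
#'
#' @param normalized Normalized matrix from [upper_quartile_log2()].
#' @param sample_id Column to read.
#' @param neo_genes Character vector of gene (transcript) ids carrying
#'   neoantigens.
#' @return Mean normalized expression, or NA for an empty gene set.
#' @export
mean_neoantigen_gene_expression <- function(normalized, sample_id,
                                            neo_genes) {
  neo_genes <- intersect(neo_genes, rownames(normalized))
  if (length(neo_genes) == 0L) return(NA_real_)
  mean(normalized[neo_genes, sample_id])
}
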
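# Post-calling somatic-variant filters and tumor mutational burden.
# Conventions follow typical somatic callers: the mutant allele depth is the
# second AD value, the total depth is DP (falling back to the AD sum), and
# multi-allelic rows are split into one record per alternate allele before
# any filtering.

#' Read somatic variants from a VCF file
#'
#' Parses a VCF v4.2 (via vcfR), splits multi-allelic rows into one record
#' per alternate allele, and extracts per-sample tumor depths from the
#' FORMAT fields: `alt_depth` from the AD entry of the matching alternate
#' allele, `total_depth` from DP or, when DP is absent, the sum of AD.
#' dbSNP membership is flagged when the ID field is an rs identifier or is
#' listed in `dbsnp_ids`.
#'
#' @param path Path to the VCF file.
#' @param sample Sample column to read; NULL (default) reads every sample.
#' @param dbsnp_ids Optional character vector of known dbSNP ids (e.g. read
#'   from a one-rsID-per-line file).
#' @return A data.frame of variant records: `variant_id`, `contig`, `pos`,
#'   `ref_allele`, `alt_allele`, `alt_depth`, `total_depth`, `in_dbsnp`,
#'   `sample_id`.
#' @export
read_variant_vcf <- function(path, sample = NULL, dbsnp_ids = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  ad <- vcfR::extract.gt(v, element = "AD")
  dp <- suppressWarnings(vcfR::extract.gt(v, element = "DP",
                                          as.numeric = TRUE))
  samples <- colnames(ad)
  if (!is.null(sample)) {
    if (!sample %in% samples) {
      stop("sample ", sample, " not present in ", path, call. = FALSE)
    }
    samples <- sample
  }
  out <- list()
  for (s in samples) {
    ad_s <- strsplit(ad[, s], ",", fixed = TRUE)
    for (i in seq_len(nrow(fix))) {
      alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1L]]
      depths <- suppressWarnings(as.integer(ad_s[[i]]))
      total <- dp[i, s]
      if (is.na(total)) total <- sum(depths, na.rm = TRUE)
      for (a in seq_along(alts)) {
        id <- fix$ID[i]
        vid <- if (is.na(id) || id == ".") {
          paste(fix$CHROM[i], fix$POS[i], fix$REF[i], alts[a], sep = ":")
        } else if (length(alts) > 1L) paste0(id, ".", a) else id
        out[[length(out) + 1L]] <- data.frame(
          variant_id = vid,
          contig = fix$CHROM[i],
          pos = as.integer(fix$POS[i]),
          ref_allele = fix$REF[i],
          alt_allele = alts[a],
          alt_depth = if (length(depths) >= a + 1L) depths[a + 1L]
                      else NA_integer_,
          total_depth = as.integer(total),
          in_dbsnp = (!is.na(id) && grepl("^rs[0-9]+$", id)) ||
                     (!is.null(dbsnp_ids) && !is.na(id) && id %in% dbsnp_ids),
          sample_id = s,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  do.call(rbind, out)
}

#' Remove variants present in dbSNP
#'
#' Returns exactly the records with `in_dbsnp = FALSE`, in their original
#' order. Variants found in dbSNP are treated as likely germline
#' polymorphisms and excluded from somatic analysis.
#'
#' @param variants Variant records with a logical `in_dbsnp` column.
#' @return The filtered data.frame.
#' @export
filter_dbsnp <- function(variants) {
  stopifnot("in_dbsnp" %in% names(variants))
  variants[!variants$in_dbsnp, , drop = FALSE]
}

#' Filter variants on tumor read depths
#'
#' Keeps records with mutant allele depth >= `min_alt_depth` and total read
#' depth >= `min_total_depth`; equivalently, variants with a mutant allele
#' depth below 4 or a total depth below 15 (the defaults) are excluded.
#'
#' @param variants Variant records with `alt_depth` and `total_depth`.
#' @param min_alt_depth Minimum mutant-allele read depth (default 4).
#' @param min_total_depth Minimum total read depth (default 15).
#' @return The filtered data.frame, order preserved.
#' @export
filter_depth <- function(variants, min_alt_depth = 4L,
                         min_total_depth = 15L) {
  if (min_alt_depth < 0 || min_total_depth < 0) {
    stop("depth thresholds must be non-negative", call. = FALSE)
  }
  keep <- variants$alt_depth >= min_alt_depth &
    variants$total_depth >= min_total_depth
  variants[keep, , drop = FALSE]
}

#' Tumor mutational burden
#'
#' Counts the somatic nonsynonymous variants (SNVs and indels) among
#' records that already passed the dbSNP and depth filters: consequences
#' missense, frameshift, stop_gain and stop_loss count; synonymous and
#' other do not.
#'
#' @param variants Filtered variant records with a `consequence` column
#'   (e.g. from [annotate_variants()]).
#' @return A non-negative integer.
#' @export
count_tmb <- function(variants) {
  if (nrow(variants) == 0L) return(0L)
  stopifnot("consequence" %in% names(variants))
  sum(variants$consequence %in%
        c("missense", "frameshift", "stop_gain", "stop_loss"))
}

#' Apply both somatic filters and log the drops
#'
#' Convenience wrapper: dbSNP removal then depth filtering, returning the
#' surviving records plus a per-variant log of why each dropped record was
#' removed.
#'
#' @inheritParams filter_depth
#' @return A list with `variants` (kept records) and `log` (data.frame
#'   `variant_id`, `reason_dropped` for removed records).
#' @export
filter_variants <- function(variants, min_alt_depth = 4L,
                            min_total_depth = 15L) {
  kept_db <- filter_dbsnp(variants)
  kept <- filter_depth(kept_db, min_alt_depth, min_total_depth)
  dropped_db <- setdiff(variants$variant_id, kept_db$variant_id)
  dropped_dp <- setdiff(kept_db$variant_id, kept$variant_id)
  log <- rbind(
    if (length(dropped_db)) data.frame(variant_id = dropped_db,
                                       reason_dropped = "dbsnp",
                                       stringsAsFactors = FALSE),
    if (length(dropped_dp)) data.frame(variant_id = dropped_dp,
                                       reason_dropped = "depth",
                                       stringsAsFactors = FALSE)
  )
  if (is.null(log)) {
    log <- data.frame(variant_id = character(0),
                      reason_dropped = character(0),
                      stringsAsFactors = FALSE)
  }
  list(variants = kept, log = log)
}
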
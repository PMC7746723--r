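# Per-sample summaries, the neoantigen fraction of nonsynonymous mutations,
# two-cohort comparisons and report writing.

#' Neoantigen fraction of nonsynonymous mutations
#'
#' @param n_neoantigenic Number of variants classified neoantigenic.
#' @param tmb Tumor mutational burden (nonsynonymous variant count).
#' @return `n_neoantigenic / tmb`, or NA when `tmb` is zero.
#' @export
neoantigen_fraction <- function(n_neoantigenic, tmb) {
  ifelse(tmb > 0, n_neoantigenic / tmb, NA_real_)
}

#' Compare a per-sample metric between two cohorts
#'
#' Two-sided test of the chosen metric between the two cohorts in
#' `summaries`. `welch_t` reports the difference of cohort means
#' (first minus second, in the order given by `cohort_order` or first
#' appearance) with an unpaired two-tailed Welch t-test; `mann_whitney`
#' reports the Hodges-Lehmann location shift with a Wilcoxon rank-sum test
#' (exact when sample sizes allow and no ties). Samples with an undefined
#' metric are dropped with a message; fewer than two remaining samples per
#' cohort, or zero variance in both cohorts under `welch_t`, is an error.
#'
#' @param summaries Per-sample summary data.frame with `cohort` and the
#'   metric column.
#' @param metric Name of the metric column.
#' @param method `"welch_t"` or `"mann_whitney"`.
#' @param cohort_order Optional length-2 character vector fixing which
#'   cohort is "first" in the effect estimate.
#' @return A one-row data.frame: `metric`, `method`, `cohort1`, `cohort2`,
#'   `n1`, `n2`, `estimate`, `p_value`, `n_dropped`.
#' @export
compare_cohorts <- function(summaries, metric,
                            method = c("welch_t", "mann_whitney"),
                            cohort_order = NULL) {
  method <- match.arg(method)
  if (!metric %in% names(summaries)) {
    stop("metric column not found: ", metric, call. = FALSE)
  }
  cohorts <- cohort_order %||% unique(summaries$cohort)
  if (length(cohorts) != 2L) {
    stop("exactly two cohorts are required (got ",
         length(cohorts), ")", call. = FALSE)
  }
  x <- summaries[summaries$cohort == cohorts[1L], metric, drop = TRUE]
  y <- summaries[summaries$cohort == cohorts[2L], metric, drop = TRUE]
  n_dropped <- sum(is.na(c(x, y)))
  if (n_dropped > 0L) {
    message(n_dropped, " sample(s) with undefined ", metric, " dropped")
  }
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  if (length(x) < 2L || length(y) < 2L) {
    stop("need at least two samples with defined ", metric,
         " in each cohort", call. = FALSE)
  }
  if (method == "welch_t") {
    if (stats::var(x) == 0 && stats::var(y) == 0) {
      stop("both cohorts have zero variance in ", metric,
           "; the Welch t-test is undefined for constant data",
           call. = FALSE)
    }
    tt <- t.test(x, y, var.equal = FALSE)
    estimate <- mean(x) - mean(y)
    p <- tt$p.value
  } else {
    wt <- suppressWarnings(wilcox.test(x, y, conf.int = TRUE))
    estimate <- unname(wt$estimate)
    p <- wt$p.value
  }
  data.frame(metric = metric, method = method,
             cohort1 = cohorts[1L], cohort2 = cohorts[2L],
             n1 = length(x), n2 = length(y),
             estimate = estimate, p_value = p, n_dropped = n_dropped,
             stringsAsFactors = FALSE)
}

#' Write the cohort report
#'
#' Writes `summaries.tsv` (one row per sample), `comparisons.tsv`, and
#' `manifest.json` recording the package version, R version, configuration
#' hash (MD5 of the canonical JSON serialization when a configuration is
#' supplied), the analysis settings in force, and a timestamp. Two runs of
#' the same analysis differ only in the timestamp.
#'
#' @param summaries Per-sample summary data.frame.
#' @param comparisons Comparison rows from [compare_cohorts()] (may be
#'   NULL).
#' @param dir Output directory (created if missing).
#' @param config Optional [sim_config()] (or any list) hashed into the
#'   manifest.
#' @param settings Optional named list of analysis settings to record.
#' @return Invisibly, named vector of file paths.
#' @export
write_report <- function(summaries, comparisons = NULL, dir,
                         config = NULL, settings = list()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sum_path <- file.path(dir, "summaries.tsv")
  write.table(summaries, sum_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  cmp_path <- file.path(dir, "comparisons.tsv")
  if (is.null(comparisons)) {
    comparisons <- data.frame(metric = character(0), method = character(0),
                              cohort1 = character(0), cohort2 = character(0),
                              n1 = integer(0), n2 = integer(0),
                              estimate = numeric(0), p_value = numeric(0),
                              n_dropped = integer(0))
  }
  write.table(comparisons, cmp_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  config_hash <- NA_character_
  if (!is.null(config)) {
    tmp <- tempfile(fileext = ".json")
    on.exit(unlink(tmp), add = TRUE)
    jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE,
                         digits = NA)
    config_hash <- unname(tools::md5sum(tmp))
  }
  manifest <- list(
    package = "neoedit",
    package_version = as.character(utils::packageVersion("neoedit")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    config_hash = config_hash,
    settings = settings,
    n_samples = nrow(summaries),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  man_path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, man_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(c(summaries = sum_path, comparisons = cmp_path,
              manifest = man_path))
}
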
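# MHC binding classification: predictor contract, netMHC parser, dual IC50
# criterion.

# Small affinity table builder.
aff_table <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(peptide = r[[1]], allele = r[[2]],
               ic50_nm = as.numeric(r[[3]]), stringsAsFactors = FALSE)
  }))
}

one_pair <- function(mut, ref) {
  data.frame(variant_id = "v1", length = nchar(mut), window_start = 1L,
             mutant_peptide = mut, reference_peptide = ref,
             source = ifelse(is.na(ref), "novel_stretch", "saav_window"),
             stringsAsFactors = FALSE)
}

test_that("the dual 500 nM criterion uses strict inequalities", {
  cases <- list(
    list(mut = 100, ref = 600, pass = TRUE),
    list(mut = 499, ref = 501, pass = TRUE),
    list(mut = 500, ref = 501, pass = FALSE),
    list(mut = 499, ref = 500, pass = FALSE),
    list(mut = 100, ref = 100, pass = FALSE),
    list(mut = 600, ref = 5000, pass = FALSE)
  )
  for (cs in cases) {
    aff <- aff_table(list("SIINFEKL", "H2-Kb", cs$mut),
                     list("SIINFEKR", "H2-Kb", cs$ref))
    expect_equal(
      classify_pair("SIINFEKL", "SIINFEKR", aff, alleles = "H2-Kb"),
      cs$pass,
      info = sprintf("mut=%g ref=%g", cs$mut, cs$ref))
  }
  # no reference peptide: mutant condition alone decides
  aff <- aff_table(list("SIINFEKL", "H2-Kb", 100))
  expect_true(classify_pair("SIINFEKL", NA, aff, alleles = "H2-Kb"))
})

test_that("the pair criterion is evaluated within each allele", {
  # mutant binds on Kb, reference weak only on Db: no allele satisfies both
  aff <- aff_table(list("SIINFEKL", "H2-Kb", 100),
                   list("SIINFEKR", "H2-Kb", 200),
                   list("SIINFEKL", "H2-Db", 900),
                   list("SIINFEKR", "H2-Db", 900))
  expect_false(classify_pair("SIINFEKL", "SIINFEKR", aff,
                             alleles = c("H2-Kb", "H2-Db")))
  # flipping the Db mutant to a binder passes on Db
  aff$ic50_nm[aff$peptide == "SIINFEKL" & aff$allele == "H2-Db"] <- 100
  expect_true(classify_pair("SIINFEKL", "SIINFEKR", aff,
                            alleles = c("H2-Kb", "H2-Db")))
})

test_that("predict_affinities covers the peptide x allele product", {
  pred <- mock_predictor(seed = 7)
  out <- predict_affinities(c("SIINFEKL", "AAYAAAAL"),
                            alleles = c("H2-Kb", "H2-Db"), predictor = pred)
  expect_equal(nrow(out), 4)
  out2 <- predict_affinities(c("SIINFEKL", "AAYAAAAL"),
                             alleles = c("H2-Kb", "H2-Db"),
                             predictor = pred)
  expect_identical(out, out2)
  expect_error(predict_affinities("BADPEPX1", predictor = pred),
               "non-standard")
})

test_that("the netMHC table adapter parses affinities and skips banners", {
  path <- system.file("extdata", "synthetic_netmhc_output.txt",
                      package = "neoedit")
  tab <- read_netmhc(path)
  expect_equal(nrow(tab), 4)
  expect_equal(tab$peptide,
               c("SIINFEKL", "AAYAAAAL", "AAAAAAAL", "KAVYNFATM"))
  expect_equal(tab$ic50_nm, c(13.2, 450, 15830, 789.5))
  expect_equal(unique(tab$allele), "H-2-Kb")
  pred <- netmhc_predictor(c("H-2-Kb" = path))
  expect_equal(pred("AAYAAAAL", "H-2-Kb"), 450)
  expect_error(pred("NOTINFILE", "H-2-Kb"), "no affinity")
})

test_that("classify_variants aggregates pairs with min passing IC50", {
  pairs <- rbind(one_pair("AAAAAAAA", "CCCCCCCC"),
                 one_pair("DDDDDDDD", "EEEEEEEE"),
                 one_pair("FFFFFFFF", "GGGGGGGG"))
  aff <- aff_table(list("AAAAAAAA", "H2-Kb", 100),
                   list("CCCCCCCC", "H2-Kb", 600),
                   list("DDDDDDDD", "H2-Kb", 50),
                   list("EEEEEEEE", "H2-Kb", 5000),
                   list("FFFFFFFF", "H2-Kb", 400),
                   list("GGGGGGGG", "H2-Kb", 100))
  calls <- classify_variants(pairs, aff, alleles = "H2-Kb")
  expect_equal(calls$n_pairs_tested, 3)
  expect_equal(calls$n_pairs_passing, 2)
  expect_true(calls$is_neoantigenic)
  expect_equal(calls$best_mutant_ic50_nm, 50)
  # none passing: FALSE with NA best
  aff_none <- aff_table(list("AAAAAAAA", "H2-Kb", 900),
                        list("CCCCCCCC", "H2-Kb", 600),
                        list("DDDDDDDD", "H2-Kb", 800),
                        list("EEEEEEEE", "H2-Kb", 5000),
                        list("FFFFFFFF", "H2-Kb", 700),
                        list("GGGGGGGG", "H2-Kb", 100))
  calls0 <- classify_variants(pairs, aff_none, alleles = "H2-Kb")
  expect_false(calls0$is_neoantigenic)
  expect_equal(calls0$n_pairs_passing, 0)
  expect_true(is.na(calls0$best_mutant_ic50_nm))
  # missing affinity is an error naming the peptide
  expect_error(classify_variants(pairs, aff[-1, ], alleles = "H2-Kb"),
               "AAAAAAAA")
})

test_that("classification is invariant under pair order", {
  set.seed(12)
  cfg <- sim_config(seed = 12, n_transcripts = 15, n_snv = 6,
                    n_frameshift = 2, n_stopgain = 1)
  sim <- simulate_cohort(cfg)
  c1 <- classify_variants(sim$pairs, sim$affinities)
  c2 <- classify_variants(sim$pairs[sample(nrow(sim$pairs)), ],
                          sim$affinities)
  expect_equal(c1, c2)
})

test_that("adding an allele can only add passing pairs", {
  cfg <- sim_config(seed = 14, n_transcripts = 15, n_snv = 6,
                    n_frameshift = 2, n_stopgain = 1)
  sim <- simulate_cohort(cfg)
  one <- classify_variants(sim$pairs, sim$affinities, alleles = "H2-Kb")
  both <- classify_variants(sim$pairs, sim$affinities,
                            alleles = c("H2-Kb", "H2-Db"))
  expect_true(all(both$n_pairs_passing >= one$n_pairs_passing))
  expect_true(all(one$is_neoantigenic <= both$is_neoantigenic))
})
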
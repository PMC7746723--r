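# Synthetic-cohort generator: structure, determinism, ground-truth closure
# and the analytic properties of the expression model.

test_that("configuration invariants are enforced", {
  expect_error(sim_config(cds_length_range = c(10, 20)), "15 codons")
  expect_error(sim_config(cds_length_range = c(30, 20)), "min <= max")
  expect_error(sim_config(vaf = 0), "vaf")
  expect_error(sim_config(true_binder_rate = 1.2), "true_binder_rate")
  expect_error(sim_config(editing_factor_delta = -1), "non-negative")
  expect_error(sim_config(cohort_sizes = c(4, 4)), "named")
  expect_error(sim_config(n_transcripts = 1, cds_length_range = c(15, 15),
                          n_snv = 50, n_frameshift = 0, n_stopgain = 0),
               "placeable codons")
})

test_that("toy proteome has valid CDS structure and translation", {
  cfg <- sim_config(seed = 1, n_transcripts = 50, cds_length_range = c(20, 80),
                    n_snv = 5, n_frameshift = 0, n_stopgain = 0)
  tx <- generate_proteome(cfg)
  expect_equal(nrow(tx), 50)
  expect_true(all(startsWith(tx$cds, "ATG")))
  expect_true(all(substring(tx$cds, nchar(tx$cds) - 2) %in%
                    c("TAA", "TAG", "TGA")))
  expect_true(all(nchar(tx$cds) %% 3 == 0))
  # no internal stop: protein length is (codons - 1)
  expect_equal(nchar(tx$protein), nchar(tx$cds) / 3 - 1)
  expect_false(any(grepl("[*]", tx$protein)))
  expect_true(all(nchar(tx$three_prime_flank) >= 300))
  # independent translation oracle reproduces every protein
  expect_equal(tx$protein, oracle_translate_cds(tx$cds))
})

test_that("a 20-codon config gives a 63 nt CDS and a 20-residue protein", {
  cfg <- sim_config(seed = 2, n_transcripts = 1,
                    cds_length_range = c(20, 20), n_snv = 1,
                    n_frameshift = 0, n_stopgain = 0)
  tx <- generate_proteome(cfg)
  expect_equal(nchar(tx$cds), 63)
  expect_equal(nchar(tx$protein), 20)
})

test_that("identical config and seed give byte-identical outputs", {
  cfg <- sim_config(seed = 33, n_transcripts = 12, n_snv = 4,
                    n_frameshift = 2, n_stopgain = 1)
  s1 <- simulate_cohort(cfg)
  s2 <- simulate_cohort(cfg)
  expect_identical(s1$transcripts, s2$transcripts)
  expect_identical(s1$variants, s2$variants)
  expect_identical(s1$counts, s2$counts)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_simulation(s1, d1)
  write_simulation(s2, d2)
  for (f in list.files(d1)) {
    expect_identical(readBin(file.path(d1, f), "raw", n = 2e6),
                     readBin(file.path(d2, f), "raw", n = 2e6))
  }
})

test_that("spiked variants have the requested counts, shapes and depths", {
  cfg <- sim_config(seed = 5, n_transcripts = 20, n_snv = 5,
                    n_frameshift = 0, n_stopgain = 0)
  sv <- spike_variants(generate_proteome(cfg), cfg)
  expect_equal(nrow(sv$variants), 5)
  expect_true(all(nchar(sv$variants$ref_allele) == 1))
  expect_true(all(nchar(sv$variants$alt_allele) == 1))
  expect_true(all(sv$variants$alt_depth <= sv$variants$total_depth))
  # degenerate binomial: vaf = 1 forces alt depth = total depth
  cfg1 <- sim_config(seed = 5, vaf = 1, mean_total_depth_dna = 100)
  sv1 <- spike_variants(generate_proteome(cfg1), cfg1)
  expect_equal(sv1$variants$alt_depth, sv1$variants$total_depth)
})

test_that("spiked SNV consequences match a brute-force codon oracle", {
  cfg <- sim_config(seed = 8, n_transcripts = 25, n_snv = 12,
                    n_frameshift = 6, n_stopgain = 4)
  tx <- generate_proteome(cfg)
  sv <- spike_variants(tx, cfg)
  for (i in seq_len(nrow(sv$variants))) {
    v <- sv$variants[i, ]
    t1 <- tx[tx$transcript_id == v$contig, ]
    oc <- oracle_consequence(t1$cds, t1$three_prime_flank, v$pos,
                             v$ref_allele, v$alt_allele)
    expect_equal(oc$consequence, sv$truth$consequence[i],
                 info = v$variant_id)
  }
})

test_that("ground truth closes over variants and planted binders", {
  sim <- simulate_cohort(sim_config(seed = 13))
  expect_setequal(sim$truth$variant_id, sim$variants$variant_id)
  expect_equal(anyDuplicated(sim$truth$variant_id), 0L)
  expect_true(all(sim$planted %in% sim$truth$variant_id))
  expect_setequal(sim$truth$variant_id[sim$truth$planted], sim$planted)
  expect_setequal(sim$neo_transcripts,
                  unique(sim$truth$transcript_id[sim$truth$planted]))
  # planted variants all yield peptides
  expect_true(all(sim$planted %in% sim$pairs$variant_id))
})

test_that("degenerate binder rates plant none or all peptide variants", {
  cfg0 <- sim_config(seed = 21, true_binder_rate = 0)
  sim0 <- simulate_cohort(cfg0)
  expect_length(sim0$planted, 0)
  cfg1 <- sim_config(seed = 21, true_binder_rate = 1)
  sim1 <- simulate_cohort(cfg1, background = "none")
  expect_setequal(sim1$planted, unique(sim1$pairs$variant_id))
  calls <- classify_variants(sim1$pairs, sim1$affinities)
  expect_true(all(calls$is_neoantigenic))
})

test_that("mock affinities are deterministic and bounded", {
  p <- c("SIINFEKL", "AAYAAAAL", "KAVYNFATM")
  a <- mock_ic50(p, "H2-Kb", seed = 7)
  b <- mock_ic50(p, "H2-Kb", seed = 7)
  expect_identical(a, b)
  expect_true(all(a >= 1 & a <= 50000))
  expect_false(identical(a, mock_ic50(p, "H2-Db", seed = 7)))
  expect_error(mock_ic50("SIINFEK", "H2-Kb", 7), "length")
  expect_error(mock_ic50("SIINFEKX", "H2-Kb", 7), "non-standard")
})

test_that("editing scales expected neoantigen-gene counts by 2^-delta", {
  cfg <- sim_config(seed = 17, n_transcripts = 40, editing_factor_delta = 2,
                    expr_cell_sdlog = 0.3)
  tx <- generate_proteome(cfg)
  neo <- tx$transcript_id[1:10]
  # many replicate draws of a single-sample cohort, both arms
  ratio_num <- 0
  ratio_den <- 0
  for (s in 1:150) {
    un <- simulate_expression(tx, neo, cfg, "s1", edited = FALSE,
                              stream_seed = 5000 + s)
    ed <- simulate_expression(tx, neo, cfg, "s1", edited = TRUE,
                              stream_seed = 9000 + s)
    ratio_num <- ratio_num + mean(ed$counts[neo, 1])
    ratio_den <- ratio_den + mean(un$counts[neo, 1])
  }
  expect_equal(ratio_num / ratio_den, 0.25, tolerance = 0.05)
  # delta = 0: identical expected counts in both arms
  cfg0 <- sim_config(seed = 17, n_transcripts = 40,
                     editing_factor_delta = 0)
  e0 <- simulate_expression(tx, neo, cfg0, "s1", edited = TRUE,
                            stream_seed = 1)
  e1 <- simulate_expression(tx, neo, cfg0, "s1", edited = FALSE,
                            stream_seed = 1)
  expect_identical(e0$expected, e1$expected)
  expect_identical(e0$counts, e1$counts)
})

test_that("a zero count yields zero RNA allele reads", {
  cfg <- sim_config(seed = 23, n_transcripts = 20, n_snv = 8,
                    n_frameshift = 0, n_stopgain = 0,
                    expr_meanlog = -4) # nearly everything unexpressed
  tx <- generate_proteome(cfg)
  sv <- spike_variants(tx, cfg)
  ex <- simulate_expression(tx, character(0), cfg, c("a", "b"),
                            variants = sv$variants, stream_seed = 2)
  ac <- ex$allele_counts
  g <- match(sv$variants$contig[match(ac$variant_id,
                                      sv$variants$variant_id)],
             rownames(ex$counts))
  zero <- ex$counts[cbind(g, match(ac$sample_id, colnames(ex$counts)))] == 0
  expect_true(any(zero))
  expect_true(all(ac$ref_reads[zero] + ac$alt_reads[zero] == 0))
})
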
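# Consequence derivation and 8-11mer enumeration.

test_that("a codon substitution is classified missense with correct protein", {
  # codon 10 GCT -> GTT is A10V; transcript is 30 codons of Ala
  tx <- toy_transcript()
  v <- list(pos = (10 - 1) * 3 + 2, ref_allele = "C", alt_allele = "T",
            variant_id = "v1")
  dc <- derive_consequence(v, tx)
  expect_equal(dc$consequence, "missense")
  expect_equal(dc$first_divergent, 10)
  expect_equal(substr(dc$mutant_protein, 10, 10), "V")
  expect_equal(nchar(dc$mutant_protein), nchar(tx$protein))
})

test_that("a 1-bp deletion frameshifts from the affected codon", {
  set.seed(42)
  codons <- sample(setdiff(names(Biostrings::GENETIC_CODE),
                           c("TAA", "TAG", "TGA")), 29, replace = TRUE)
  tx <- toy_transcript(protein_codons = codons)
  q <- (10 - 1) * 3 + 1 # first base of codon 10
  v <- list(pos = q - 1, ref_allele = substr(tx$cds, q - 1, q),
            alt_allele = substr(tx$cds, q - 1, q - 1), variant_id = "v1")
  dc <- derive_consequence(v, tx)
  expect_equal(dc$consequence, "frameshift")
  expect_equal(substr(dc$mutant_protein, 1, 9), substr(tx$protein, 1, 9))
  oc <- oracle_consequence(tx$cds, tx$three_prime_flank, v$pos,
                           v$ref_allele, v$alt_allele)
  expect_equal(dc$mutant_protein, oc$mutant_protein)
  expect_equal(dc$first_divergent, oc$first_divergent)
})

test_that("stop-loss reads through into the 3' flank", {
  tx <- toy_transcript(flank = paste0(strrep("GCA", 20), "TAA",
                                      strrep("A", 237)))
  stop_pos <- nchar(tx$cds) - 2 # the TGA stop codon starts here
  # change TGA -> TCA (Ser): pos + 1 is the G
  v <- list(pos = stop_pos + 1, ref_allele = "G", alt_allele = "C",
            variant_id = "v1")
  dc <- derive_consequence(v, tx)
  expect_equal(dc$consequence, "stop_loss")
  expect_true(startsWith(dc$mutant_protein, tx$protein))
  # read-through: S (mutated stop) + 20 Ala from the flank, then TAA stops
  expect_equal(nchar(dc$mutant_protein), nchar(tx$protein) + 21)
  expect_equal(dc$first_divergent, nchar(tx$protein) + 1)
})

test_that("REF mismatches and out-of-CDS positions are input errors", {
  tx <- toy_transcript()
  expect_error(derive_consequence(list(pos = 5, ref_allele = "T",
                                       alt_allele = "A"), tx),
               "REF mismatch")
  expect_error(derive_consequence(list(pos = 0, ref_allele = "A",
                                       alt_allele = "T"), tx),
               "within the CDS")
  expect_error(derive_consequence(list(pos = nchar(tx$cds), ref_allele = "AA",
                                       alt_allele = "A"), tx),
               "within the CDS")
})

test_that("interior and terminal substitutions give 38 and 4 windows", {
  mut <- paste0(strrep("A", 49), "V", strrep("A", 50))
  ref <- strrep("A", 100)
  expect_equal(nrow(enumerate_saav_windows(mut, ref, 50)), 38)
  mut1 <- paste0("V", strrep("A", 99))
  expect_equal(nrow(enumerate_saav_windows(mut1, ref, 1)), 4)
  mutL <- paste0(strrep("A", 99), "V")
  expect_equal(nrow(enumerate_saav_windows(mutL, ref, 100)), 4)
  expect_error(enumerate_saav_windows(mut, ref, 0), "out of range")
  expect_error(enumerate_saav_windows(mut, strrep("A", 99), 50),
               "equal length")
})

test_that("every saav window covers p and differs only at p's offset", {
  set.seed(7)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (i in 1:25) {
    L <- sample(12:60, 1)
    p <- sample(L, 1)
    ref <- paste(sample(aas, L, TRUE), collapse = "")
    mut_char <- strsplit(ref, "")[[1]]
    mut_char[p] <- setdiff(aas, mut_char[p])[1]
    mut <- paste(mut_char, collapse = "")
    pw <- enumerate_saav_windows(mut, ref, p)
    expect_setequal(pair_keys(pw), oracle_saav_pairs(mut, ref, p))
    covers <- pw$window_start <= p & p <= pw$window_start + pw$length - 1
    expect_true(all(covers))
    diff_at <- mapply(function(m, r) which(strsplit(m, "")[[1]] !=
                                             strsplit(r, "")[[1]]),
                      pw$mutant_peptide, pw$reference_peptide)
    expect_equal(unname(unlist(diff_at)), p - pw$window_start + 1)
  }
})

test_that("novel stretch window counts follow the L-k+1 arithmetic", {
  set.seed(8)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  prot20 <- paste(c(rep("A", 5), sample(aas, 20, TRUE)), collapse = "")
  # novel stretch = positions 6..25 (length 20)
  expect_equal(nrow(enumerate_novel_stretch(prot20, 6)), 46)
  # below the minimum length: no peptides, not an error
  expect_equal(nrow(enumerate_novel_stretch(strrep("A", 20), 14)), 0)
  prot11 <- paste(sample(aas, 11, FALSE), collapse = "")
  expect_equal(nrow(enumerate_novel_stretch(prot11, 1)), 10)
  # all windows lack a reference peptide
  ns <- enumerate_novel_stretch(prot20, 6)
  expect_true(all(is.na(ns$reference_peptide)))
  expect_true(all(ns$source == "novel_stretch"))
})

test_that("novel_flank prepends reference residues before the junction", {
  prot <- paste0(strrep("A", 10), strrep("W", 10))
  plain <- enumerate_novel_stretch(prot, 11)
  flanked <- enumerate_novel_stretch(prot, 11, novel_flank = 3)
  expect_true(all(plain$mutant_peptide %in% flanked$mutant_peptide))
  expect_true(any(grepl("^A", flanked$mutant_peptide)))
  expect_false(any(grepl("^A", plain$mutant_peptide)))
})

test_that("enumerate_variant dispatches on consequence", {
  set.seed(9)
  codons <- sample(setdiff(names(Biostrings::GENETIC_CODE),
                           c("TAA", "TAG", "TGA")), 59, replace = TRUE)
  cds <- paste0("ATG", paste(codons, collapse = ""), "TGA")
  tx <- list(transcript_id = "T", cds = cds,
             three_prime_flank = strrep("ACGT", 100),
             protein = translate_cds(cds))
  # synonymous: pick a codon whose third-base change is silent (GCT -> GCC)
  cds2 <- paste0("ATG", "GCT", paste(codons[-1], collapse = ""), "TGA")
  tx2 <- modifyList(tx, list(cds = cds2, protein = translate_cds(cds2)))
  v_syn <- list(pos = 6, ref_allele = "T", alt_allele = "C",
                variant_id = "syn")
  expect_equal(nrow(enumerate_variant(v_syn, tx2)), 0)
  # stop gain: design decision, truncation yields no peptides
  cds3 <- paste0("ATG", "TAC", paste(codons[-1], collapse = ""), "TGA")
  tx3 <- modifyList(tx, list(cds = cds3, protein = translate_cds(cds3)))
  v_sg <- list(pos = 6, ref_allele = "C", alt_allele = "G",
               variant_id = "sg") # TAC -> TAG stop
  expect_equal(derive_consequence(v_sg, tx3)$consequence, "stop_gain")
  expect_equal(nrow(enumerate_variant(v_sg, tx3)), 0)
})

test_that("no enumerated peptide contains a stop or non-standard residue", {
  cfg <- sim_config(seed = 31, n_transcripts = 30, n_snv = 15,
                    n_frameshift = 8, n_stopgain = 4)
  tx <- generate_proteome(cfg)
  sv <- spike_variants(tx, cfg)
  pairs <- enumerate_pairs(sv$variants, tx)
  expect_gt(nrow(pairs), 0)
  expect_false(any(grepl("[^ACDEFGHIKLMNPQRSTVWY]", pairs$mutant_peptide)))
  ok_ref <- is.na(pairs$reference_peptide) |
    !grepl("[^ACDEFGHIKLMNPQRSTVWY]", pairs$reference_peptide)
  expect_true(all(ok_ref))
  expect_true(all(pairs$length %in% 8:11))
  expect_true(all(nchar(pairs$mutant_peptide) == pairs$length))
  # per-variant deduplication
  key <- paste(pairs$variant_id, pairs$mutant_peptide,
               pairs$reference_peptide)
  expect_equal(anyDuplicated(key), 0L)
})
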
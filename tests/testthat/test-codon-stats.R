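test_that("codon counting excludes the terminal stop and keeps the start", {
  cc <- count_codons("ATGAAATAA", genetic_code(1))
  expect_equal(cc$n_codons, 2)
  expect_equal(unname(cc$counts[c("ATG", "AAA", "TAA")]), c(1, 1, 0))
  cc2 <- count_codons(paste0("ATG", strrep("GCT", 100), "TAA"),
                      genetic_code(1))
  expect_equal(unname(cc2$counts[c("ATG", "GCT")]), c(1, 100))
  expect_equal(cc2$n_codons, 101)
  expect_error(codon_count_matrix(data.frame(id = "x", seq = "ATGA")),
               "multiple of 3")
})

test_that("composition indices match hand counts", {
  code <- genetic_code(1)
  p <- composition_profile(count_codons("ATGAAAAAGTAA", code), code)
  # Lys family AAA=1, AAG=1; ATG excluded (1-fold), terminal TAA excluded
  expect_equal(p$gc3s, 0.5)
  expect_equal(p$a3s, 0.5)
  expect_equal(p$g3s, 0.5)
  expect_equal(p$t3s, 0)
  expect_equal(p$c3s, 0)
  # single-codon gene of GCG: all-GC at every position
  v <- stats::setNames(numeric(64), all_codons()); v["GCG"] <- 5
  q <- composition_profile(v, code)
  expect_equal(unname(unlist(q[c("gc", "gc1", "gc2", "gc3")])), rep(1, 4))
})

test_that("profile identities hold on random genes", {
  set.seed(101)
  for (tid in c(1, 6, 10)) {
    code <- genetic_code(tid)
    m <- do.call(rbind, lapply(1:20, function(i) random_gene_counts(code)))
    rownames(m) <- paste0("g", 1:20)
    p <- composition_profiles(m, code)
    expect_equal(p$gc12, (p$gc1 + p$gc2) / 2)
    expect_equal(p$a_pct + p$c_pct + p$g_pct + p$t_pct, rep(1, 20))
    expect_equal(p$a3s + p$t3s + p$c3s + p$g3s, rep(1, 20))
    expect_true(all(p$gc3s >= 0 & p$gc3s <= 1))
    expect_true(all(p$enc >= 2 & p$enc <= length(sense_codons(code))))
  }
})

test_that("GC3s is exactly 1 when all synonymous third positions are G/C", {
  code <- genetic_code(1)
  v <- stats::setNames(numeric(64), all_codons())
  v[c("TTC", "GCC", "GGG", "ATG")] <- c(10, 5, 3, 1)
  expect_equal(composition_profile(v, code)$gc3s, 1)
})

test_that("ENC hits its closed-form limits", {
  code <- genetic_code(1)
  tab <- table(vapply(code$families, `[[`, 1L, "degeneracy"))
  # one codon per family, well sampled: every family homozygous, ENC = 20
  v <- stats::setNames(numeric(64), all_codons())
  first <- vapply(code$families, function(f) f$codons[1], "")
  v[first] <- 10
  expect_equal(enc(v, code), 20)
  # uniform usage at high counts approaches the sense-codon count
  u <- stats::setNames(numeric(64), all_codons())
  u[sense_codons(code)] <- 10000
  expect_gt(enc(u, code), 60.9)
  u6 <- stats::setNames(numeric(64), all_codons())
  u6[sense_codons(genetic_code(6))] <- 10000
  expect_gt(enc(u6, genetic_code(6)), 62.9)
})

test_that("ENC agrees with a step-by-step family-enumeration oracle", {
  set.seed(202)
  for (tid in c(1, 6, 10)) {
    code <- genetic_code(tid)
    for (i in 1:20) {
      v <- random_gene_counts(code)
      expect_equal(enc(v, code), oracle_enc(v, code), tolerance = 1e-12)
    }
  }
  # sparse genes exercise the n<2 exclusions and the 3-fold imputation
  for (i in 1:15) {
    code <- genetic_code(sample(c(1, 6, 10), 1))
    v <- random_gene_counts(code, n_codons = sample(5:25, 1))
    expect_equal(enc(v, code), oracle_enc(v, code), tolerance = 1e-12)
  }
})

test_that("expected ENC follows the null formula and its shifted symmetry", {
  expect_equal(expected_enc(0), 31)
  expect_equal(expected_enc(0.5), 60.5)
  expect_equal(expected_enc(1), 32)
  x <- seq(0, 1, length.out = 101)
  expect_equal(expected_enc(x) - x, expected_enc(1 - x) - (1 - x))
  expect_error(expected_enc(1.2), "\\[0, 1\\]")
})

test_that("RSCU matches the definitional formula and normalizes by family", {
  code <- genetic_code(1)
  v <- stats::setNames(numeric(64), all_codons())
  v["TTT"] <- 4
  r <- rscu(v, code)
  expect_equal(r$rscu[r$codon == "TTT"], 2)
  expect_equal(r$rscu[r$codon == "TTC"], 0)
  v["TTT"] <- 3; v["TTC"] <- 1
  r <- rscu(v, code)
  expect_equal(r$rscu[r$codon == "TTT"], 1.5)
  expect_equal(r$rscu[r$codon == "TTC"], 0.5)
  # uniform usage: every RSCU exactly 1
  u <- stats::setNames(numeric(64), all_codons())
  u[sense_codons(code)] <- 7
  expect_true(all(rscu(u, code)$rscu == 1))
  # per-family sums equal the degeneracy on random genes
  set.seed(303)
  for (tid in c(1, 6, 10)) {
    codet <- genetic_code(tid)
    for (i in 1:10) {
      r <- rscu(random_gene_counts(codet), codet)
      sums <- tapply(r$rscu, r$amino_acid, sum)
      degs <- tapply(r$degeneracy, r$amino_acid, max)
      ok <- !is.na(sums)
      expect_equal(as.numeric(sums[ok]), as.numeric(degs[ok]),
                   tolerance = 1e-9)
    }
  }
  # stop codons and 1-fold families never appear in the table
  expect_false(any(c("ATG", "TGG", "TAA") %in% rscu(u, code)$codon))
  # ... but TAA does appear under the ciliate code (Gln family)
  u6 <- stats::setNames(numeric(64), all_codons())
  u6[sense_codons(genetic_code(6))] <- 7
  expect_true("TAA" %in% rscu(u6, genetic_code(6))$codon)
})

test_that("undefined statistics are NA, never zero", {
  code <- genetic_code(1)
  v <- stats::setNames(numeric(64), all_codons())
  v[c("ATG", "TGG")] <- 3  # only 1-fold families observed
  p <- composition_profile(v, code)
  expect_true(is.na(p$gc3s))
  expect_true(is.na(p$a3s))
})
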
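test_that("dinucleotide counting matches hand enumeration with N-skip", {
  cases <- list("ACAC", "A", "", "ANAT", "acgtn", "TATA", "CATG",
                "NNNN", "CAACGGTTAN")
  for (s in cases)
    expect_identical(dinucleotide_counts(s), oracle_dinuc(s), info = s)
  expect_identical(sum(dinucleotide_counts("ACAC")), 3L)
  expect_identical(unname(dinucleotide_counts("ANAT")[["AT"]]), 1L)
  expect_identical(sum(dinucleotide_counts("ANAT")), 1L)
})

test_that("RIP indices on hand-enumerated examples", {
  expect_equal(tpa_apt_index("TATA"), 2)
  expect_true(is.na(tpa_apt_index("GCGC")))
  expect_equal(composite_rip_index("CAAC"), 1)
  expect_true(is.na(composite_rip_index("CATG")))
})

test_that("property: both indices are strand-symmetric and N-concatenation-consistent", {
  withr::local_seed(99)
  for (i in 1:200) {
    s <- rand_seq(sample(10:80, 1), gc = runif(1, 0.2, 0.8))
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    expect_equal(tpa_apt_index(s), tpa_apt_index(rc))
    expect_equal(composite_rip_index(s), composite_rip_index(rc))
    # concatenation via single N separator adds counts
    t_ <- rand_seq(sample(10:80, 1))
    expect_identical(dinucleotide_counts(paste(s, t_, sep = "N")),
                     dinucleotide_counts(s) + dinucleotide_counts(t_))
  }
})

test_that("composite index on long random sequence sits near 1 under the null", {
  withr::local_seed(7)
  vals <- replicate(200, composite_rip_index(rand_seq(10000, gc = 0.5)))
  expect_true(mean(vals >= 0.8 & vals <= 1.25) >= 0.99)
})

test_that("classify_rip_genes applies printed thresholds and denominators", {
  # threshold boundary: TpA/ApT exactly 0.89 is affected; composite exactly
  # 1.03 is affected
  ann <- fixture_rip_fraction(3, 10)
  res <- classify_rip_genes(ann, "tpa_apt")
  expect_identical(res$n_affected, 3L)
  expect_equal(res$affected_pct, 30.0)
  expect_identical(res$per_gene$call[4], "unaffected")

  # undefined-index genes counted in denominator, never affected
  ann2 <- mk_ann(4, cds = "GCGCGC")
  res2 <- classify_rip_genes(ann2, "tpa_apt")
  expect_identical(res2$n_affected, 0L)
  expect_equal(res2$affected_pct, 0.0)
  expect_true(all(res2$per_gene$call == "undefined"))
})

test_that("stop codon census counts and ratios", {
  ann <- mk_ann(3, cds = c("ATGTAA", "ATGTAA", "ATGTGA"))
  cen <- stop_codon_census(ann)
  expect_identical(cen$taa, 2L)
  expect_identical(cen$tga, 1L)
  expect_equal(cen$taa_tga_ratio, 2.0)
  expect_identical(cen$other, 0L)

  # non-canonical final codon counts as other; subsetting by gene set
  ann2 <- mk_ann(4, cds = c("ATGTAA", "ATGAAA", "ATGTAG", "ATGTGA"))
  cen2 <- stop_codon_census(ann2)
  expect_identical(cen2$other, 1L)
  expect_identical(cen2$taa + cen2$tag + cen2$tga + cen2$other, cen2$n_genes)
  cen3 <- stop_codon_census(ann2, gene_set = c("g001", "g002"))
  expect_identical(cen3$n_genes, 2L)
  expect_true(is.na(cen3$taa_tga_ratio))  # tga = 0 -> undefined
})

test_that("dinucleotide fold change: arithmetic, identity and RIP sign", {
  # constructed frequencies: target TA freq double the control
  fc <- dinucleotide_foldchange("TATA", "TAAA")  # TA:2/3 vs 1/3
  expect_equal(unname(fc[["TA"]]), log10(2))
  s <- rand_seq(2000, 0.5)
  expect_true(all(dinucleotide_foldchange(s, s) == 0, na.rm = TRUE))

  withr::local_seed(5)
  originals <- replicate(5, rand_seq(2000, 0.5))
  ripped <- vapply(seq_along(originals), function(i)
    apply_rip(originals[i], 0.5, seed = i), character(1))
  fc2 <- dinucleotide_foldchange(ripped, originals)
  expect_gt(fc2[["TA"]], 0)
  expect_lt(fc2[["TG"]], 0)
  expect_lt(fc2[["CA"]], 0)
  expect_error(dinucleotide_foldchange(character(0), "ACGT"), "non-empty")
})

test_that("compare_rip_fractions equals exhaustive hypergeometric enumeration", {
  expect_equal(compare_rip_fractions(3, 4, 1, 4), 17 / 70)
  expect_gt(compare_rip_fractions(5, 9, 5, 9), 0.5)
  # brute force over all tables with totals <= 12
  for (ta in c(3, 5)) for (tb in c(4, 7)) {
    for (aa in 0:ta) for (ab in 0:tb) {
      expect_equal(compare_rip_fractions(aa, ta, ab, tb),
                   oracle_hyper_tail(aa, aa + ab, ta + tb, ta),
                   info = paste(aa, ta, ab, tb))
    }
  }
  expect_lt(compare_rip_fractions(533, 695, 4181, 10959), 1e-10)
  expect_error(compare_rip_fractions(1, 0, 1, 4), "positive")
})
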
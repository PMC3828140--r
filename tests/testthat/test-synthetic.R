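test_that("apply_rip hand-applied rules and edge cases", {
  expect_identical(apply_rip("CACA", 1, seed = 1), "TATA")
  expect_identical(apply_rip("TG", 1, seed = 1), "TA")
  s <- rand_seq(500)
  expect_identical(apply_rip(s, 0, seed = 3), s)
  expect_identical(apply_rip("CATG", 1, seed = 2), "TATA")
  expect_error(apply_rip("CACA", 1.5), "rates")
  # single pass on the original: the created TA does not re-trigger
  expect_identical(apply_rip("CCA", 1, seed = 1), "CTA")
})

test_that("property: apply_rip never decreases TA count and is length-preserving", {
  withr::local_seed(31)
  for (i in 1:100) {
    s <- rand_seq(sample(20:400, 1), gc = runif(1, 0.3, 0.7))
    r <- apply_rip(s, runif(1), seed = i)
    expect_identical(nchar(r), nchar(s))
    expect_gte(dinucleotide_counts(r)[["TA"]], dinucleotide_counts(s)[["TA"]])
  }
})

test_that("TpA/ApT index responds monotonically to the RIP rate", {
  rates <- c(0, 0.2, 0.5, 0.9)
  means <- vapply(seq_along(rates), function(k) {
    vals <- vapply(1:30, function(i)
      tpa_apt_index(apply_rip(rand_seq_seeded(2000, i), rates[k],
                              seed = 1000 * k + i)),
      numeric(1))
    mean(vals)
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("generate_genome: determinism, planted arithmetic, capacity error", {
  cfg <- genome_config(n_contigs = 2, genes_per_contig = 30,
                       planted_tandem_runs = c(2L, 2L, 3L), seed = 5)
  g1 <- generate_genome(cfg)
  g2 <- generate_genome(cfg)
  expect_identical(g1$annotation$genes, g2$annotation$genes)
  expect_identical(g1$annotation$contigs, g2$annotation$contigs)
  expect_identical(g1$truth, g2$truth)

  # run-to-pair arithmetic: (2-1)+(2-1)+(3-1) = 4 pairs among planted runs
  tr <- find_tandem_pairs(g1$annotation)
  planted_pairs <- g1$truth$tandem_pairs
  expect_identical(nrow(planted_pairs), 4L)
  got <- paste(tr$pairs$gene_a, tr$pairs$gene_b)
  expect_true(all(paste(planted_pairs$gene_a, planted_pairs$gene_b) %in% got))

  # no secreted genes -> nothing clusterable
  g3 <- generate_genome(genome_config(n_contigs = 1, genes_per_contig = 30,
                                      frac_secreted = 0,
                                      planted_clusters = list(), seed = 2))
  expect_identical(nrow(detect_clusters(g3$annotation)), 0L)

  expect_error(generate_genome(
    genome_config(n_contigs = 1, genes_per_contig = 8,
                  planted_tandem_runs = c(5L, 5L),
                  planted_clusters = list(), seed = 1)),
    "capacity")
})

test_that("generated CDS are well-formed", {
  gen <- generate_genome(genome_config(n_contigs = 2, genes_per_contig = 25,
                                       seed = 9))
  g <- gen$annotation$genes
  expect_true(all(nchar(g$cds) %% 3 == 0))
  stops <- substr(g$cds, nchar(g$cds) - 2, nchar(g$cds))
  expect_true(all(stops %in% c("TAA", "TAG", "TGA")))
  # RIP-mutated duplicate copies may lose the ATG (TpG target in pos 2-3)
  fresh <- !(g$gene_id %in% gen$truth$rip_genes)
  expect_true(all(substr(g$cds[fresh], 1, 3) == "ATG"))
  # CDS embedded in contig at stated coordinates and strand
  for (i in seq_len(nrow(g))) {
    s <- substr(gen$annotation$contigs[[g$contig[i]]], g$start[i], g$end[i])
    if (g$strand[i] == "-")
      s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    expect_identical(s, g$cds[i])
  }
})

test_that("generate_expression: determinism, planted recovery, null centering", {
  gen <- generate_genome(genome_config(n_contigs = 1, genes_per_contig = 60,
                                       seed = 3))
  ids <- gen$annotation$genes$gene_id
  cfg <- expression_config(planted_up_10x = ids[1:5],
                           planted_up_2x = ids[6:10],
                           nb_dispersion = 0.01, seed = 8)
  t1 <- generate_expression(gen$annotation, cfg)
  t2 <- generate_expression(gen$annotation, cfg)
  expect_identical(t1$counts, t2$counts)

  sets <- regulation_sets(normalize_counts(t1), "knob", "infection")
  expect_true(all(ids[1:5] %in% sets$up10))
  expect_true(all(ids[6:10] %in% sets$up2))

  # empty planted sets: fold changes centre at 1
  t0 <- normalize_counts(generate_expression(gen$annotation,
                                             expression_config(seed = 4)))
  s0 <- regulation_sets(t0, "knob", "infection")
  expect_lt(abs(median(log2(s0$fold_change), na.rm = TRUE)), 0.5)
  expect_error(generate_expression(gen$annotation,
                                   expression_config(planted_up_10x = "nope")),
               "gene ids")
})
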
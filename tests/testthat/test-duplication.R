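test_that("find_tandem_pairs on hand-scanned family sequences", {
  # [f1,f1,f2,f3,f3,f3] -> pairs 3, genes 5, runs 2
  ann <- mk_ann(6, family = c("f1", "f1", "f2", "f3", "f3", "f3"))
  tr <- find_tandem_pairs(ann)
  expect_identical(tr$n_pairs, 3L)
  expect_identical(tr$n_genes, 5L)
  expect_identical(nrow(tr$runs), 2L)
  expect_equal(tr$pct_genes, round_half_up(100 * 5 / 6, 1))

  # all singletons
  tr0 <- find_tandem_pairs(mk_ann(5, family = paste0("f", 1:5)))
  expect_identical(tr0$n_pairs, 0L)
  expect_equal(tr0$pct_genes, 0)

  # NA families never pair; contig boundaries break pairs
  ann2 <- mk_ann(4, family = c("f1", NA, "f1", "f1"),
                 contig = c("c1", "c1", "c1", "c2"))
  expect_identical(find_tandem_pairs(ann2)$n_pairs, 0L)
})

test_that("property: TandemResult arithmetic identity on random annotations", {
  withr::local_seed(77)
  for (i in 1:50) {
    n <- sample(5:40, 1)
    fams <- sample(c(NA, paste0("f", 1:4)), n, replace = TRUE)
    ann <- mk_ann(n, family = fams,
                  contig = sample(c("c1", "c2"), n, replace = TRUE))
    tr <- find_tandem_pairs(ann)
    expect_identical(tr$n_pairs, sum(tr$runs$length - 1L))
    expect_identical(tr$n_genes, sum(tr$runs$length))
    expect_identical(nrow(tr$runs), tr$n_genes - tr$n_pairs)
  }
})

test_that("tandem permutation test: degenerate and planted cases", {
  # all singletons: observed 0, P = 1
  ann0 <- mk_ann(10, family = paste0("f", 1:10))
  expect_equal(tandem_permutation_test(ann0, 50, seed = 1)$p_value, 1)

  # two genes, same family: every permutation gives the same pair
  ann2 <- mk_ann(2, family = "f1")
  res2 <- tandem_permutation_test(ann2, 100, seed = 1)
  expect_identical(res2$observed, 1L)
  expect_equal(res2$p_value, 1)

  # planted run of 10 in 1,000 genes: P at the add-one floor
  fams <- c(rep("BIG", 10), rep(NA_character_, 990))
  ann <- mk_ann(1000, family = fams)
  res <- tandem_permutation_test(ann, 1000, seed = 42)
  expect_identical(res$observed, 9L)
  expect_equal(res$p_value, 1 / 1001)
})

test_that("te_proximity distance rule with strict threshold", {
  genes <- data.frame(gene_id = c("a", "b"), contig = "c1",
                      start = c(1000L, 1000L), end = c(2000L, 2000L),
                      strand = "+", cds = "ATGTAA", protein = "M",
                      stringsAsFactors = FALSE)
  genes$gene_id <- c("a", "b"); genes$start <- c(1000L, 5000L)
  genes$end <- c(2000L, 6000L)
  flags <- data.frame(gene_id = c("a", "b"), secreted = FALSE,
                      protein_length = 10L, family_id = "f1",
                      stringsAsFactors = FALSE)
  ann <- genome_annotation(genes, flags)
  tr <- find_tandem_pairs(ann)

  near <- function(te_start, te_end, max_dist = 10000L) {
    te <- data.frame(contig = "c1", start = te_start, end = te_end)
    te_proximity(tr, ann, te, max_dist)
  }
  # gene a [1000,2000], TE [5000,5100]: gap 3000 -> near; overlaps gene b
  expect_identical(near(5000L, 5100L)$per_gene$distance, c(3000L, 0L))
  expect_identical(near(8000L, 8100L)$per_gene$distance, c(6000L, 2000L))
  # boundary: gap 10001 not near under strict <
  r <- near(12001L, 12100L)
  expect_identical(r$per_gene$distance, c(10001L, 6001L))
  expect_identical(r$per_gene$near, c(FALSE, TRUE))
  # overlap -> distance 0
  expect_identical(near(1500L, 1600L)$per_gene$distance[1], 0L)
  # unknown contig ignored with warning
  expect_warning(
    te_proximity(tr, ann, data.frame(contig = "cX", start = 1, end = 2)),
    "unknown contig")
})

test_that("pairwise identity: forced examples and DP-oracle score equivalence", {
  expect_equal(pairwise_identity("ACGT", "ACGT"),
               list(identity = 1, aligned_length = 4L, score = 4,
                    aligned_a = "ACGT", aligned_b = "ACGT"))
  expect_equal(pairwise_identity("ACGT", "ACGA")$identity, 0.75)
  expect_error(pairwise_identity("", "ACGT"), "non-empty")

  withr::local_seed(13)
  for (i in 1:150) {
    a <- rand_seq(sample(1:6, 1)); b <- rand_seq(sample(1:6, 1))
    got <- pairwise_identity(a, b)
    ora <- oracle_align(a, b)
    expect_equal(got$score, ora$score, info = paste(a, b))
    # reported identity agrees with the returned alignment
    ca <- strsplit(got$aligned_a, "")[[1]]
    cb <- strsplit(got$aligned_b, "")[[1]]
    expect_equal(got$identity,
                 sum(ca == cb & ca != "-") / length(ca), info = paste(a, b))
  }
})

test_that("recent_duplicates thresholds are strict/inclusive as stated", {
  cds500 <- rand_seq_seeded(501, 1)
  cds300 <- rand_seq_seeded(300, 2)
  ann <- mk_ann(3, cds = c(cds500, cds500, cds300))
  rd <- recent_duplicates(ann)
  expect_identical(nrow(rd), 1L)
  expect_equal(rd$identity, 1)
  expect_setequal(c(rd$gene_a, rd$gene_b), c("g001", "g002"))

  # genes exactly at 400 bp are excluded (strict >)
  cds400 <- rand_seq_seeded(400, 3)
  ann2 <- mk_ann(2, cds = c(cds400, cds400))
  expect_identical(nrow(recent_duplicates(ann2)), 0L)

  # heavy RIP on a CA/TG-rich duplicate drives identity below 0.80
  base <- paste(rep("CAGTG", 101), collapse = "")  # 505 bp, 40% in targets
  ripped <- apply_rip(base, 1, seed = 4)
  ann3 <- mk_ann(2, cds = c(base, ripped))
  expect_identical(nrow(recent_duplicates(ann3)), 0L)
  expect_lt(pairwise_identity(base, ripped)$identity, 0.8)
})
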
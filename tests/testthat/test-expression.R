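mk_table <- function(counts, conditions = c("knob", "knob", "infection",
                                            "infection")) {
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("g%03d", seq_len(nrow(counts)))
  expression_table(counts, conditions)
}

test_that("median-of-ratios size factors: symmetry, doubling, DESeq2 oracle", {
  withr::local_seed(1)
  m <- matrix(rpois(200, 50), ncol = 2)
  m <- cbind(m[, 1], m[, 1])
  rownames(m) <- sprintf("g%03d", 1:100)
  tbl <- normalize_counts(expression_table(m, c("a", "b")))
  expect_equal(unname(tbl$size_factors), c(1, 1))

  withr::local_seed(2)
  base <- matrix(rpois(100, 100) + 1, ncol = 1)
  m2 <- cbind(base, 2 * base)
  rownames(m2) <- sprintf("g%03d", 1:100)
  tbl2 <- normalize_counts(expression_table(m2, c("a", "b")))
  expect_equal(tbl2$size_factors[[2]] / tbl2$size_factors[[1]], 2)

  # independent oracle: DESeq2's estimator on a noisy matrix
  m3 <- matrix(rnbinom(600, mu = 80, size = 10) + 1, ncol = 4)
  rownames(m3) <- sprintf("g%03d", seq_len(nrow(m3)))
  got <- normalize_counts(mk_table(m3))$size_factors
  want <- DESeq2::estimateSizeFactorsForMatrix(m3)
  expect_equal(unname(got), unname(want))

  # scaling invariance of fold changes
  t_a <- normalize_counts(mk_table(m3))
  t_b <- normalize_counts(mk_table(m3 * 3))
  expect_equal(regulation_sets(t_a)$fold_change,
               regulation_sets(t_b)$fold_change)

  expect_error(normalize_counts(mk_table(matrix(0, 2, 4))), "all-zero")
})

test_that("regulation sets: strict thresholds, infinities, invariants", {
  m <- rbind(g1 = c(10, 10, 100, 100),   # 10x -> up2 but not up10 (strict)
             g2 = c(10, 10, 101, 101),   # just over 10x
             g3 = c(10, 10, 20, 20),     # exactly 2x -> not up2
             g4 = c(0, 0, 50, 50),       # control silent -> up10
             g5 = c(50, 50, 0, 0),       # infection silent -> down10
             g6 = c(0, 0, 0, 0),         # excluded
             g7 = c(40, 40, 41, 41))
  tbl <- mk_table(m)
  tbl$size_factors <- rep(1, 4)
  tbl$normalized <- m
  sets <- regulation_sets(tbl)
  expect_false("g1" %in% sets$up10)
  expect_true("g1" %in% sets$up2)
  expect_true("g2" %in% sets$up10)
  expect_false("g3" %in% sets$up2)
  expect_true("g4" %in% sets$up10)
  expect_identical(sets$fold_change[["g4"]], Inf)
  expect_true("g5" %in% sets$down10)
  expect_true(is.na(sets$fold_change[["g6"]]))
  expect_true(all(sets$up10 %in% sets$up2))
  expect_true(all(sets$down10 %in% sets$down2))
  expect_length(intersect(sets$up2, sets$down2), 0)
  expect_error(regulation_sets(tbl, "nope", "infection"), "unknown condition")
})

test_that("top_expressed: floor rule and deterministic tie-break", {
  m <- matrix(1, nrow = 20, ncol = 2)
  rownames(m) <- sprintf("g%03d", 20:1)  # ids deliberately unsorted
  tbl <- mk_table(m, c("knob", "infection"))
  tbl$size_factors <- c(1, 1); tbl$normalized <- m
  top <- top_expressed(tbl, "infection", 0.1)
  expect_identical(top, c("g001", "g002"))  # all-ties -> lexicographic

  m2 <- m; m2[3, 2] <- 50; m2[7, 2] <- 40
  tbl2 <- mk_table(m2, c("knob", "infection"))
  tbl2$size_factors <- c(1, 1); tbl2$normalized <- m2
  expect_identical(top_expressed(tbl2, "infection", 0.1),
                   rownames(m2)[c(3, 7)])

  # zero-expression genes drop out of the universe
  withr::local_seed(4)
  m3 <- matrix(rpois(80, 30), ncol = 4)
  m3[1:7, 3:4] <- 0
  rownames(m3) <- sprintf("g%03d", seq_len(nrow(m3)))
  tbl3 <- normalize_counts(mk_table(m3))
  expect_length(top_expressed(tbl3, "infection", 0.5),
                floor(0.5 * sum(rowMeans(tbl3$normalized[, 3:4]) > 0)))
})

test_that("hypergeometric enrichment equals exhaustive enumeration", {
  expect_equal(enrichment_test(3, 3, 5, 10), 10 / 120)
  expect_equal(enrichment_test(0, 4, 6, 12), 1.0)
  for (N in c(8, 12)) for (K in c(2, 5)) for (k in c(3, 6)) {
    for (h in 0:min(K, k)) {
      expect_equal(enrichment_test(h, k, K, N),
                   oracle_hyper_tail(h, K, N, k),
                   info = paste(h, k, K, N))
    }
  }
  expect_error(enrichment_test(5, 3, 6, 10), "inconsistent")
})

test_that("infection_report cohort fractions and degenerate case", {
  fx <- fixture_infection_cohort(n_focal = 100, n_secreted_focal = 60,
                                 n_ssp_focal = 30, n_cys_rich_ssp = 12,
                                 n_expanded_focal = 25, n_universe = 1000)
  rep_ <- infection_report(fx$sets, fx$flags)
  expect_identical(rep_$n_focal, 100L)
  expect_equal(rep_$secreted$pct, 60)
  expect_equal(rep_$ssp$n, 30L)
  expect_equal(rep_$expanded_family$pct, 25)
  expect_identical(rep_$cysteine_rich_ssp, 12L)
  # cohort is the entire secreted class here -> strong enrichment
  expect_lt(rep_$secreted$p_enrichment, 1e-10)

  empty_sets <- structure(list(up2 = character(0), up10 = character(0),
                               down2 = character(0), down10 = character(0),
                               fold_change = numeric(0),
                               top_decile = character(0)),
                          class = "RegulationSets")
  rep0 <- infection_report(empty_sets, fx$flags)
  expect_identical(rep0$n_focal, 0L)
  expect_true(is.na(rep0$secreted$pct))
})

test_that("ortholog comparison: strict ratio classes and q-value summary", {
  pairs <- data.frame(gene_a = c("a1", "a2", "a3", "a4"),
                      gene_b = c("b1", "b2", "b3", "b4"),
                      expr_a = c(100, 101, 5, 0),
                      expr_b = c(10, 10, 100, 10),
                      stringsAsFactors = FALSE)
  oc <- ortholog_compare(pairs)
  expect_identical(oc$per_pair$class, c("neither", "a_up", "b_up", "b_up"))

  # both-silent pairs excluded with warning; Inf ratio -> a_up
  pairs2 <- rbind(pairs,
                  data.frame(gene_a = "a5", gene_b = "b5",
                             expr_a = c(0, 50), expr_b = c(0, 0)))
  expect_warning(oc2 <- ortholog_compare(pairs2), "silent")
  expect_identical(nrow(oc2$per_pair), 5L)
  expect_identical(oc2$per_pair$class[5], "a_up")

  fx <- fixture_ortholog_pairs(100, 32)
  s <- ortholog_compare(fx)$summary
  expect_identical(s$n_significant, 32L)
  expect_equal(s$pct_significant, 32)
  expect_identical(s$n_a_up, 0L)
})

test_that("planted fold-change recovery: sensitivity and type-I error", {
  withr::local_seed(20)
  ids <- sprintf("g%04d", 1:300)
  hits <- 0L; total <- 0L; fp <- 0L; null_total <- 0L
  for (seed in 1:10) {
    cfg <- expression_config(planted_up_10x = ids[1:20],
                             nb_dispersion = 0.05, seed = seed)
    sets <- regulation_sets(normalize_counts(generate_expression(ids, cfg)))
    hits <- hits + sum(ids[1:20] %in% sets$up10)
    total <- total + 20L
    fp <- fp + sum(ids[-(1:20)] %in% sets$up10)
    null_total <- null_total + 280L
  }
  expect_gte(hits / total, 0.99)
  expect_lte(fp / null_total, 0.01)
})
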
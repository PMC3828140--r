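#' Construct an expression count table
#'
#' @param counts non-negative integer matrix, genes x samples, with gene
#'   ids as rownames and sample names as colnames.
#' @param conditions character vector of condition labels, one per sample.
#' @param species optional species tag (recycled).
#' @return an object of class `ExpressionTable` with `counts`, `samples`
#'   (sample/condition/species), and `size_factors`/`normalized` slots
#'   populated by [normalize_counts()].
#' @export
expression_table <- function(counts, conditions, species = NA_character_) {
  counts <- as.matrix(counts)
  abort_if(is.null(rownames(counts)), "counts must have gene ids as rownames")
  abort_if(any(counts < 0), "counts must be non-negative")
  abort_if(length(conditions) != ncol(counts),
           "one condition label per sample required")
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0(conditions, "_", seq_len(ncol(counts)))
  structure(list(counts = counts,
                 samples = data.frame(sample = colnames(counts),
                                      condition = as.character(conditions),
                                      species = rep_len(species, ncol(counts)),
                                      stringsAsFactors = FALSE),
                 size_factors = NULL,
                 normalized = NULL),
            class = "ExpressionTable")
}

#' Read a count table from TSV
#'
#' First column gene ids, one column per sample.
#'
#' @param path TSV path.
#' @param conditions condition label per sample column.
#' @param species optional species tag.
#' @return an [expression_table()].
#' @export
read_expression_tsv <- function(path, conditions, species = NA_character_) {
  df <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  expression_table(m, conditions, species)
}

#' Median-of-ratios count normalization
#'
#' Per-sample size factors are the median, over genes with a finite
#' positive geometric mean across samples, of the ratio of the gene's count
#' to its geometric mean (the DESeq size-factor estimator). Normalized
#' values are counts / size factor, making fold changes invariant to
#' per-sample sequencing depth.
#'
#' @param table an [expression_table()].
#' @return the table with `size_factors` and `normalized` populated.
#' @export
normalize_counts <- function(table) {
  stopifnot(inherits(table, "ExpressionTable"))
  cts <- table$counts
  abort_if(any(colSums(cts) == 0), "sample with all-zero counts")
  log_geomeans <- rowMeans(log(cts))
  usable <- is.finite(log_geomeans)
  abort_if(!any(usable),
           "no gene with nonzero counts in every sample; cannot normalize")
  sf <- apply(cts, 2, function(col)
    exp(median((log(col) - log_geomeans)[usable & col > 0])))
  abort_if(any(!is.finite(sf) | sf <= 0), "degenerate size factor")
  table$size_factors <- sf
  table$normalized <- sweep(cts, 2, sf, "/")
  table
}

cond_means <- function(table, label) {
  abort_if(is.null(table$normalized), "call normalize_counts() first")
  sel <- table$samples$condition == label
  abort_if(!any(sel), "unknown condition label '%s'", label)
  rowMeans(table$normalized[, sel, drop = FALSE])
}

#' Build fold-change regulation sets
#'
#' Fold change per gene is mean normalized infection expression over mean
#' normalized control expression. Membership uses strict inequalities: up2
#' iff FC > 2, up10 iff FC > 10, with down sets defined on 1/FC. A gene
#' silent in the control but expressed during infection has FC = +Inf and
#' is a member of all up sets; genes silent in both conditions are
#' excluded (FC = NA).
#'
#' @param table a normalized [expression_table()].
#' @param control_label,infection_label condition labels.
#' @return a `RegulationSets` list: `fold_change` (named numeric), `up2`,
#'   `down2`, `up10`, `down10` (character vectors), `top_decile` (filled by
#'   [top_expressed()], NULL here).
#' @export
regulation_sets <- function(table, control_label = "knob",
                            infection_label = "infection") {
  ctrl <- cond_means(table, control_label)
  inf_ <- cond_means(table, infection_label)
  fc <- ifelse(ctrl == 0 & inf_ == 0, NA_real_,
        ifelse(ctrl == 0, Inf, inf_ / ctrl))
  ids <- rownames(table$counts)
  names(fc) <- ids
  ok <- !is.na(fc)
  structure(list(fold_change = fc,
                 up2 = ids[ok & fc > 2],
                 up10 = ids[ok & fc > 10],
                 down2 = ids[ok & fc < 1 / 2],
                 down10 = ids[ok & fc < 1 / 10],
                 top_decile = NULL),
            class = "RegulationSets")
}

#' Top-fraction expressed genes in a condition
#'
#' Ranks genes with nonzero mean normalized expression in the condition,
#' descending, and returns the top floor(fraction * n_expressed); ties are
#' broken by ascending gene id so the set is deterministic.
#'
#' @param table a normalized [expression_table()].
#' @param condition_label condition to rank in.
#' @param fraction in (0, 1] (default 0.10).
#' @return character vector of gene ids.
#' @export
top_expressed <- function(table, condition_label = "infection",
                          fraction = 0.10) {
  abort_if(fraction <= 0 || fraction > 1, "fraction must be in (0,1]")
  mu <- cond_means(table, condition_label)
  expressed <- mu[mu > 0]
  n_take <- floor(fraction * length(expressed))
  if (n_take == 0) return(character(0))
  ord <- order(-expressed, names(expressed))
  names(expressed)[ord][seq_len(n_take)]
}

#' One-sided hypergeometric enrichment test
#'
#' Upper-tail probability of observing at least `hits_in_set` marked genes
#' in a draw of `set_size` from a background of `background_size` genes of
#' which `hits_in_background` are marked (equivalently a one-sided Fisher
#' exact test).
#'
#' @param hits_in_set,set_size,hits_in_background,background_size counts.
#' @return P(X >= hits_in_set).
#' @export
enrichment_test <- function(hits_in_set, set_size, hits_in_background,
                            background_size) {
  abort_if(hits_in_set > set_size || set_size > background_size ||
           hits_in_set > hits_in_background ||
           hits_in_background > background_size,
           "inconsistent counts")
  stats::phyper(hits_in_set - 1, hits_in_background,
                background_size - hits_in_background, set_size,
                lower.tail = FALSE)
}

#' Report the infection-regulated highly expressed gene cohort
#'
#' The focal cohort is the intersection of the >10-fold upregulated set and
#' the top-decile expression set (or the up10 set alone when no top set is
#' available). Reports secreted / SSP / category / expanded-family counts
#' with percentages (half-up; class percentages printed at 0 decimals as in
#' conventional genome reports) and one-sided hypergeometric enrichment
#' P-values of each class against its genome-wide background.
#'
#' @param sets a [regulation_sets()] result; its `top_decile` slot is used
#'   when `top` is NULL.
#' @param flags a flags data.frame (the gene universe).
#' @param top optional character vector, the top-expressed set.
#' @param max_len_aa SSP threshold (default 300).
#' @param min_cys cysteine-richness threshold (default 5).
#' @return list of cohort counts, percentages and enrichment P-values.
#' @export
infection_report <- function(sets, flags, top = NULL, max_len_aa = 300L,
                             min_cys = 5L) {
  if (is.null(top)) top <- sets$top_decile
  focal <- if (is.null(top)) sets$up10 else intersect(sets$up10, top)
  focal <- intersect(focal, flags$gene_id)
  n <- length(focal)
  universe <- flags$gene_id
  cls <- classify_ssp(flags, max_len_aa)
  f_focal <- flags[match(focal, flags$gene_id), , drop = FALSE]

  class_stat <- function(in_focal, in_genome) {
    list(n = in_focal,
         pct = if (n == 0) NA_real_ else round_half_up(100 * in_focal / n, 0),
         p_enrichment = if (n == 0) NA_real_ else
           enrichment_test(in_focal, n, in_genome, length(universe)))
  }
  sec_focal <- sum(f_focal$secreted)
  ssp_focal <- sum(cls$ssp[focal])
  out <- list(
    n_focal = n,
    secreted = class_stat(sec_focal, cls$n_secreted),
    ssp = class_stat(ssp_focal, cls$n_ssp),
    expanded_family = class_stat(sum(f_focal$expanded_family),
                                 sum(flags$expanded_family)),
    cysteine_rich_ssp = cysteine_rich(
      flags, focal[cls$ssp[focal] %in% TRUE], min_cys),
    categories = lapply(setNames(nm = CATEGORIES), function(cat_)
      class_stat(sum(f_focal$category == cat_),
                 sum(flags$category == cat_))))
  out
}

#' Compare infection expression of ortholog pairs across two species
#'
#' Classifies each ortholog pair by the ratio of mean normalized infection
#' expression (species A over species B): `a_up` iff ratio strictly above
#' `fold_threshold`, `b_up` iff strictly below its reciprocal, otherwise
#' `neither`. Pairs silent in both species are excluded with a warning.
#' When a `qvalue` column (externally computed differential-expression
#' q-values) is present, the summary reports the fraction of significant
#' pairs at `q_cutoff`. Cross-species size-factor comparability is the
#' caller's responsibility.
#'
#' @param pairs data.frame with columns `gene_a`, `gene_b`, `expr_a`,
#'   `expr_b` and optionally `qvalue`.
#' @param fold_threshold strict ratio threshold (default 10).
#' @param q_cutoff q-value significance cutoff (default 0.01).
#' @return list with `per_pair` (ratio and class) and `summary` (`n_pairs`,
#'   `n_a_up`, `n_b_up`, `n_significant`, `pct_significant` at 0 decimals).
#' @export
ortholog_compare <- function(pairs, fold_threshold = 10, q_cutoff = 0.01) {
  need <- c("gene_a", "gene_b", "expr_a", "expr_b")
  abort_if(!all(need %in% names(pairs)), "pairs must have columns %s",
           paste(need, collapse = ", "))
  silent <- pairs$expr_a == 0 & pairs$expr_b == 0
  if (any(silent)) {
    warning(sprintf("%d pair(s) silent in both species excluded", sum(silent)))
    pairs <- pairs[!silent, , drop = FALSE]
  }
  ratio <- ifelse(pairs$expr_b == 0, Inf, pairs$expr_a / pairs$expr_b)
  cls <- ifelse(ratio > fold_threshold, "a_up",
         ifelse(ratio < 1 / fold_threshold, "b_up", "neither"))
  per_pair <- data.frame(pairs[, intersect(names(pairs),
                                           c(need, "qvalue")), drop = FALSE],
                         ratio = ratio, class = cls,
                         stringsAsFactors = FALSE)
  n_sig <- if ("qvalue" %in% names(pairs))
    sum(pairs$qvalue < q_cutoff, na.rm = TRUE) else NA_integer_
  list(per_pair = per_pair,
       summary = list(n_pairs = nrow(per_pair),
                      n_a_up = sum(cls == "a_up"),
                      n_b_up = sum(cls == "b_up"),
                      n_significant = n_sig,
                      pct_significant = if (is.na(n_sig)) NA_real_ else
                        pct_of(n_sig, nrow(per_pair), 0)))
}

#' Assemble an ortholog-pair expression table from two species
#'
#' @param table_a,table_b normalized [expression_table()]s.
#' @param map data.frame with columns `gene_a`, `gene_b`.
#' @param condition_a,condition_b infection condition labels.
#' @return data.frame ready for [ortholog_compare()].
#' @export
ortholog_pair_table <- function(table_a, table_b, map,
                                condition_a = "infection",
                                condition_b = "infection") {
  mu_a <- cond_means(table_a, condition_a)
  mu_b <- cond_means(table_b, condition_b)
  abort_if(!all(map$gene_a %in% names(mu_a)) ||
           !all(map$gene_b %in% names(mu_b)),
           "ortholog map contains unknown gene ids")
  data.frame(gene_a = map$gene_a, gene_b = map$gene_b,
             expr_a = unname(mu_a[map$gene_a]),
             expr_b = unname(mu_b[map$gene_b]),
             stringsAsFactors = FALSE)
}
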
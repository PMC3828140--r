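#' Classify small secreted proteins (SSPs)
#'
#' An SSP is a secreted protein strictly shorter than `max_len_aa` amino
#' acids (default 300). SSPs are candidate host-interaction effectors.
#'
#' @param flags a flags data.frame (e.g. `ann$flags`).
#' @param max_len_aa strict length threshold (default 300).
#' @return list with `ssp` (named logical per gene), `n_secreted`, `n_ssp`.
#' @export
classify_ssp <- function(flags, max_len_aa = 300L) {
  ssp <- flags$secreted & flags$protein_length < max_len_aa
  list(ssp = setNames(ssp, flags$gene_id),
       n_secreted = sum(flags$secreted),
       n_ssp = sum(ssp))
}

#' Count cysteine-rich genes in a set
#'
#' Inclusive threshold count of genes whose protein has at least `min_cys`
#' cysteines; disulphide potential suggesting an extracellularly stable
#' fold.
#'
#' @param flags a flags data.frame.
#' @param gene_set character vector of gene ids.
#' @param min_cys inclusive cysteine threshold (default 5).
#' @return integer count.
#' @export
cysteine_rich <- function(flags, gene_set, min_cys = 5L) {
  f <- flags[flags$gene_id %in% gene_set, , drop = FALSE]
  sum(f$cysteines >= min_cys)
}

#' Detect secreted-protein gene clusters
#'
#' Per contig, finds maximal chains of secreted genes in which consecutive
#' secreted genes are separated by at most one non-secreted gene, and
#' reports chains containing at least three secreted genes. This unifies
#' the published two-pronged rule ("at least three adjacent secreted genes,
#' or groups of more than three genes with at most one non-secreted gene in
#' between"): the pure-secreted form is the zero-gap special case, and any
#' chain with a gap has at least four genes. Cluster members run from the
#' first to the last secreted gene inclusive; contig boundaries break
#' chains.
#'
#' @param ann a [genome_annotation()].
#' @param max_len_aa SSP length threshold used for the per-cluster SSP
#'   count (default 300).
#' @return data.frame with one row per cluster: `cluster_id`, `contig`,
#'   `members` (semicolon-joined, genomic order), `n_secreted`,
#'   `n_nonsecreted`, `n_ssp`, `span_genes`.
#' @export
detect_clusters <- function(ann, max_len_aa = 300L) {
  g <- ann$genes
  secreted <- ann$flags$secreted
  ssp <- classify_ssp(ann$flags, max_len_aa)$ssp
  rows <- list()
  for (ctg in unique(g$contig)) {
    idx <- which(g$contig == ctg)
    s_pos <- idx[secreted[idx]]
    if (length(s_pos) < 3) next
    # chain secreted genes while the index gap is <= 2 (<= 1 gene between)
    brk <- c(0L, cumsum(diff(s_pos) > 2L))
    for (grp in split(s_pos, brk)) {
      if (length(grp) < 3) next
      members <- seq.int(min(grp), max(grp))
      rows[[length(rows) + 1L]] <- data.frame(
        contig = ctg,
        members = paste(g$gene_id[members], collapse = ";"),
        n_secreted = length(grp),
        n_nonsecreted = length(members) - length(grp),
        n_ssp = sum(ssp[g$gene_id[members]]),
        span_genes = length(members),
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(contig = character(0), members = character(0),
               n_secreted = integer(0), n_nonsecreted = integer(0),
               n_ssp = integer(0), span_genes = integer(0),
               stringsAsFactors = FALSE)
  out <- cbind(cluster_id = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

#' Validate detected gene clusters against the cluster rule
#'
#' Independent post-hoc check of the `GeneCluster` invariants: first and
#' last members secreted, at least three secreted members, never two
#' consecutive non-secreted members, and span = secreted + non-secreted.
#'
#' @param clusters output of [detect_clusters()].
#' @param ann the annotation they came from.
#' @return TRUE, or stops with the offending cluster id.
#' @export
validate_clusters <- function(clusters, ann) {
  sec <- setNames(ann$flags$secreted, ann$flags$gene_id)
  for (i in seq_len(nrow(clusters))) {
    m <- strsplit(clusters$members[i], ";", fixed = TRUE)[[1]]
    s <- sec[m]
    ok <- s[1] && s[length(s)] && sum(s) >= 3 &&
      !any(!s[-length(s)] & !s[-1]) &&
      clusters$span_genes[i] == clusters$n_secreted[i] + clusters$n_nonsecreted[i] &&
      sum(s) == clusters$n_secreted[i]
    abort_if(!ok, "cluster %d violates the cluster rule", clusters$cluster_id[i])
  }
  TRUE
}

#' Summarise secreted-protein gene clusters
#'
#' Computes cluster counts and in-cluster fractions of the genome-wide
#' secreted and SSP classes, and (optionally) of an upregulated secreted
#' gene set. Percentages are 100 * in-cluster / genome-wide count of the
#' class, half-up to 1 decimal; NA when the class is empty.
#'
#' @param clusters output of [detect_clusters()].
#' @param flags a flags data.frame (the gene universe).
#' @param upregulated optional character vector of upregulated gene ids.
#' @param max_len_aa SSP threshold (default 300).
#' @return list of counts and percentages.
#' @export
cluster_summary <- function(clusters, flags, upregulated = NULL,
                            max_len_aa = 300L) {
  cls <- classify_ssp(flags, max_len_aa)
  member_ids <- unlist(strsplit(clusters$members, ";", fixed = TRUE),
                       use.names = FALSE)
  sec <- setNames(flags$secreted, flags$gene_id)
  in_cluster_secreted <- member_ids[sec[member_ids]]
  n_sec_in <- length(in_cluster_secreted)
  n_ssp_in <- sum(cls$ssp[member_ids])
  out <- list(
    n_clusters = nrow(clusters),
    n_secreted_in_clusters = n_sec_in,
    pct_secreted_in_clusters = pct_of(n_sec_in, cls$n_secreted, 1),
    n_ssp_in_clusters = n_ssp_in,
    pct_ssp_in_clusters = pct_of(n_ssp_in, cls$n_ssp, 1),
    n_clusters_with_ssp = sum(clusters$n_ssp > 0))
  if (!is.null(upregulated)) {
    up_sec <- intersect(upregulated, names(sec)[sec])
    n_up_in <- length(intersect(up_sec, in_cluster_secreted))
    out$n_upregulated_secreted_in_clusters <- n_up_in
    out$pct_upregulated_secreted_in_clusters <-
      pct_of(n_up_in, length(up_sec), 1)
  }
  out
}
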
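#' Find tandemly duplicated gene pairs
#'
#' Scans each contig's start-sorted gene list; two consecutive genes sharing
#' a non-null ortholog family id form a tandem pair, and maximal stretches
#' of same-family consecutive genes form runs. Strand and intergenic
#' distance are ignored (set `same_strand = TRUE` to additionally require
#' matching strand).
#'
#' @param ann a [genome_annotation()].
#' @param same_strand require pair members on the same strand (default FALSE).
#' @return a `TandemResult` list: `pairs` (data.frame gene_a/gene_b/contig/
#'   family_id), `runs` (data.frame contig/family_id/length/members),
#'   `n_pairs`, `n_genes` (distinct genes in pairs), `pct_genes` (half-up,
#'   1 decimal, of all genes), `p_value` (NULL until
#'   [tandem_permutation_test()] is run).
#' @export
find_tandem_pairs <- function(ann, same_strand = FALSE) {
  g <- ann$genes
  fam <- ann$flags$family_id
  pair_rows <- list()
  run_rows <- list()
  for (ctg in unique(g$contig)) {
    idx <- which(g$contig == ctg)
    if (length(idx) < 2) next
    f <- fam[idx]
    adj <- !is.na(f[-length(f)]) & !is.na(f[-1]) &
      f[-length(f)] == f[-1]
    if (same_strand)
      adj <- adj & g$strand[idx][-length(idx)] == g$strand[idx][-1]
    if (!any(adj)) next
    pair_rows[[ctg]] <- data.frame(
      gene_a = g$gene_id[idx][which(adj)],
      gene_b = g$gene_id[idx][which(adj) + 1L],
      contig = ctg, family_id = f[which(adj)],
      stringsAsFactors = FALSE)
    # maximal runs: consecutive TRUE stretches of adj join len+1 genes
    r <- rle(adj)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      members <- idx[starts[k]:(ends[k] + 1L)]
      run_rows[[length(run_rows) + 1L]] <- data.frame(
        contig = ctg, family_id = f[starts[k]],
        length = length(members),
        members = paste(g$gene_id[members], collapse = ";"),
        stringsAsFactors = FALSE)
    }
  }
  pairs <- if (length(pair_rows)) do.call(rbind, pair_rows) else
    data.frame(gene_a = character(0), gene_b = character(0),
               contig = character(0), family_id = character(0),
               stringsAsFactors = FALSE)
  rownames(pairs) <- NULL
  runs <- if (length(run_rows)) do.call(rbind, run_rows) else
    data.frame(contig = character(0), family_id = character(0),
               length = integer(0), members = character(0),
               stringsAsFactors = FALSE)
  n_genes <- length(unique(c(pairs$gene_a, pairs$gene_b)))
  structure(list(pairs = pairs, runs = runs,
                 n_pairs = nrow(pairs), n_genes = n_genes,
                 pct_genes = pct_of(n_genes, nrow(g), 1),
                 p_value = NULL),
            class = "TandemResult")
}

# adjacency pair count of a family-label vector with contig segmentation
count_adjacent_pairs <- function(fam, contig_sizes) {
  boundary <- cumsum(contig_sizes)
  keep <- setdiff(seq_len(length(fam) - 1L), boundary)
  f1 <- fam[keep]; f2 <- fam[keep + 1L]
  sum(!is.na(f1) & !is.na(f2) & f1 == f2)
}

#' Permutation test for tandem duplication excess
#'
#' Tests whether the observed number of adjacent same-family gene pairs
#' exceeds chance expectation by shuffling family labels uniformly over all
#' gene positions genome-wide (per-contig gene counts fixed; adjacency
#' never crosses a contig boundary). The P-value uses the add-one
#' Monte-Carlo estimator (1 + #\{permuted >= observed\}) / (1 + n_perm), so
#' it is never exactly zero.
#'
#' @param ann a [genome_annotation()].
#' @param n_perm number of permutations (default 1000).
#' @param seed integer seed.
#' @param per_contig shuffle labels within each contig instead of
#'   genome-wide (default FALSE).
#' @return list with `observed`, `p_value`, `n_perm`.
#' @export
tandem_permutation_test <- function(ann, n_perm = 1000L, seed = 1L,
                                    per_contig = FALSE) {
  abort_if(n_perm < 1, "n_perm must be >= 1")
  g <- ann$genes
  fam <- ann$flags$family_id
  sizes <- as.integer(table(factor(g$contig, levels = unique(g$contig))))
  observed <- count_adjacent_pairs(fam, sizes)
  withr::local_seed(seed)
  offsets <- c(0L, cumsum(sizes))
  k <- 0L
  for (i in seq_len(n_perm)) {
    perm <- if (per_contig) {
      unlist(lapply(seq_along(sizes), function(ci)
        sample(fam[(offsets[ci] + 1L):offsets[ci + 1L]])))
    } else sample(fam)
    if (count_adjacent_pairs(perm, sizes) >= observed) k <- k + 1L
  }
  list(observed = observed, p_value = (1 + k) / (1 + n_perm), n_perm = n_perm)
}

#' Read TE intervals from BED or GFF3
#'
#' BED is 0-based half-open and converted to 1-based inclusive at the
#' boundary; GFF3 is used as is.
#'
#' @param path interval file path.
#' @param format `"bed"` or `"gff3"` (default: guessed from extension).
#' @return data.frame with columns contig, start, end (1-based inclusive).
#' @export
read_te_intervals <- function(path, format = NULL) {
  if (is.null(format))
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "gff3"
  gr <- rtracklayer::import(path, format = format)
  data.frame(contig = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

#' Annotate tandem genes by transposable-element proximity
#'
#' Distance between a gene and a TE interval is 0 when they overlap and
#' otherwise the gap between nearest endpoints; a gene is "near" a TE iff
#' its minimal distance is strictly less than `max_dist_bp`.
#'
#' @param result a `TandemResult` from [find_tandem_pairs()].
#' @param ann the [genome_annotation()] the result came from.
#' @param te_intervals data.frame(contig, start, end), 1-based inclusive
#'   (see [read_te_intervals()]).
#' @param max_dist_bp strict distance threshold in bp (default 10000).
#' @return list with `n_near` and `per_gene` (gene_id, distance, near).
#' @export
te_proximity <- function(result, ann, te_intervals, max_dist_bp = 10000L) {
  stopifnot(inherits(result, "TandemResult"))
  genes <- unique(c(result$pairs$gene_a, result$pairs$gene_b))
  g <- ann$genes[match(genes, ann$genes$gene_id), , drop = FALSE]
  unknown <- !(te_intervals$contig %in% ann$genes$contig)
  if (any(unknown)) {
    warning(sprintf("%d TE interval(s) on unknown contig(s) ignored",
                    sum(unknown)))
    te_intervals <- te_intervals[!unknown, , drop = FALSE]
  }
  dist_one <- function(gs, ge, ts, te) {
    if (ts <= ge && te >= gs) 0L else max(ts - ge, gs - te)
  }
  distance <- vapply(seq_len(nrow(g)), function(i) {
    te <- te_intervals[te_intervals$contig == g$contig[i], , drop = FALSE]
    if (nrow(te) == 0) return(NA_integer_)
    min(vapply(seq_len(nrow(te)), function(j)
      dist_one(g$start[i], g$end[i], te$start[j], te$end[j]), integer(1)))
  }, integer(1))
  near <- !is.na(distance) & distance < max_dist_bp
  list(n_near = sum(near),
       per_gene = data.frame(gene_id = genes, distance = distance,
                             near = near, stringsAsFactors = FALSE))
}

#' Global pairwise nucleotide identity
#'
#' Needleman-Wunsch global alignment with match +1, mismatch -1 and affine
#' gaps (a gap of length L costs open + L * extend; defaults open 2,
#' extend 1). Identity is matches / alignment columns of the returned
#' optimal alignment; when several alignments share the optimal score the
#' identity refers to the one returned (the score is unambiguous).
#'
#' @param seq_a,seq_b non-empty nucleotide strings.
#' @param match,mismatch,gap_open,gap_ext scoring parameters (penalties
#'   positive).
#' @return list with `identity`, `aligned_length`, `score`.
#' @export
pairwise_identity <- function(seq_a, seq_b, match = 1, mismatch = -1,
                              gap_open = 2, gap_ext = 1) {
  abort_if(nchar(seq_a) == 0 || nchar(seq_b) == 0,
           "sequences must be non-empty")
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch,
                                                  baseOnly = TRUE)
  aln <- Biostrings::pairwiseAlignment(toupper(seq_a), toupper(seq_b),
                                       type = "global",
                                       substitutionMatrix = mat,
                                       gapOpening = gap_open,
                                       gapExtension = gap_ext)
  pa <- as.character(Biostrings::pattern(aln))
  sa <- as.character(Biostrings::subject(aln))
  cols <- nchar(pa)
  list(identity = Biostrings::nmatch(aln) / cols,
       aligned_length = cols,
       score = Biostrings::score(aln),
       aligned_a = pa, aligned_b = sa)
}

#' Screen for recent gene duplicates
#'
#' All-vs-all global alignment of genes whose CDS is strictly longer than
#' `min_len_bp`, keeping pairs with identity at least `min_identity`
#' (inclusive). These are the duplicates young enough to still be
#' recognisable by the RIP machinery; a genome with active RIP is expected
#' to yield few or none.
#'
#' @param ann a [genome_annotation()].
#' @param min_len_bp strict CDS length threshold (default 400).
#' @param min_identity inclusive identity threshold (default 0.80).
#' @return data.frame(gene_a, gene_b, identity, aligned_length) sorted by
#'   descending identity.
#' @export
recent_duplicates <- function(ann, min_len_bp = 400L, min_identity = 0.80) {
  g <- ann$genes
  cand <- which(nchar(g$cds) > min_len_bp)
  out <- list()
  if (length(cand) >= 2) {
    mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                    baseOnly = TRUE)
    seqs <- toupper(g$cds[cand])
    for (jj in seq.int(2L, length(cand))) {
      # batch: all earlier candidates against candidate jj
      aln <- Biostrings::pairwiseAlignment(
        Biostrings::DNAStringSet(seqs[seq_len(jj - 1L)]), seqs[jj],
        type = "global", substitutionMatrix = mat,
        gapOpening = 2, gapExtension = 1)
      cols <- nchar(as.character(Biostrings::pattern(aln)))
      idents <- Biostrings::nmatch(aln) / cols
      hit <- which(idents >= min_identity)
      for (h in hit)
        out[[length(out) + 1L]] <- data.frame(
          gene_a = g$gene_id[cand[h]], gene_b = g$gene_id[cand[jj]],
          identity = idents[h], aligned_length = cols[h],
          stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(gene_a = character(0), gene_b = character(0),
               identity = numeric(0), aligned_length = integer(0),
               stringsAsFactors = FALSE)
  res[order(-res$identity, res$gene_a, res$gene_b), , drop = FALSE]
}
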
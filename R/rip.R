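#' Thresholds for the two RIP indices
#'
#' A TpA/ApT index of at least 0.89 is taken as evidence of RIP products
#' (TpA enrichment); a composite (CpA+TpG)/(ApC+GpT) index of at most 1.03
#' as evidence of RIP target depletion.
#' @name rip-thresholds
#' @keywords internal
NULL

TPA_APT_THRESHOLD <- 0.89
COMPOSITE_THRESHOLD <- 1.03

DINUCS <- as.vector(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                          paste0))

#' Count overlapping dinucleotides
#'
#' Counts all overlapping width-2 windows over \{A,C,G,T\}; windows
#' containing N are skipped, so the counts of a concatenation joined by a
#' single N equal the sum of per-piece counts. Case-insensitive.
#'
#' @param seq a nucleotide string over A/C/G/T/N (any case).
#' @return named integer vector of length 16 (all dinucleotides over ACGT).
#' @examples
#' dinucleotide_counts("ACAC") # AC = 2, CA = 1
#' @export
dinucleotide_counts <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (is.na(seq) || nchar(seq) < 2)
    return(setNames(integer(16), DINUCS))
  f <- Biostrings::dinucleotideFrequency(Biostrings::DNAString(toupper(seq)))
  setNames(as.integer(f[DINUCS]), DINUCS)
}

# vectorised dinucleotide counts for many sequences: rows = sequences
dinucleotide_counts_matrix <- function(seqs) {
  if (length(seqs) == 0)
    return(matrix(integer(0), nrow = 0, ncol = 16,
                  dimnames = list(NULL, DINUCS)))
  m <- Biostrings::dinucleotideFrequency(
    Biostrings::DNAStringSet(toupper(seqs)))
  m[, DINUCS, drop = FALSE]
}

#' TpA/ApT RIP index
#'
#' Ratio of TA to AT dinucleotide counts. The index measures the product of
#' RIP mutations (CpA on either strand mutating to TpA) while correcting
#' for overall AT bias. Undefined (NA) when the sequence has no AT windows.
#'
#' @param seq a nucleotide string.
#' @return numeric, or NA when the denominator is zero.
#' @export
tpa_apt_index <- function(seq) {
  cnt <- dinucleotide_counts(seq)
  if (cnt[["AT"]] == 0) return(NA_real_)
  cnt[["TA"]] / cnt[["AT"]]
}

#' Composite RIP index (CpA+TpG)/(ApC+GpT)
#'
#' Estimates the depletion of RIP target sites: RIP converts CpA (and its
#' reverse-strand complement TpG) to TpA, so a RIP-eroded sequence has a low
#' value. Undefined (NA) when the denominator is zero.
#'
#' @param seq a nucleotide string.
#' @return numeric, or NA when ApC + GpT = 0.
#' @export
composite_rip_index <- function(seq) {
  cnt <- dinucleotide_counts(seq)
  den <- cnt[["AC"]] + cnt[["GT"]]
  if (den == 0) return(NA_real_)
  (cnt[["CA"]] + cnt[["TG"]]) / den
}

#' Call RIP-affected genes across an annotation
#'
#' Computes the chosen RIP index on every gene's CDS (coding orientation;
#' both indices are strand-symmetric so orientation is immaterial) and calls
#' each gene affected, unaffected, or undefined. A gene is affected iff
#' TpA/ApT >= 0.89, or iff composite <= 1.03, matching the published
#' thresholds. Undefined-index genes count in the denominator of the
#' affected fraction but never as affected.
#'
#' @param ann a [genome_annotation()].
#' @param index `"tpa_apt"` or `"composite"`.
#' @return list with `per_gene` (data.frame of gene_id, value, call),
#'   `n_affected`, `n_total`, and `affected_pct` (half-up, 1 decimal).
#' @export
classify_rip_genes <- function(ann, index = c("tpa_apt", "composite")) {
  index <- match.arg(index)
  g <- ann$genes
  no_cds <- is.na(g$cds) | nchar(g$cds) == 0
  if (any(no_cds))
    warning(sprintf("%d gene(s) without CDS counted as undefined", sum(no_cds)))
  cnt <- dinucleotide_counts_matrix(ifelse(no_cds, "A", g$cds))
  if (index == "tpa_apt") {
    den <- cnt[, "AT"]
    num <- cnt[, "TA"]
    value <- ifelse(den == 0, NA_real_, num / den)
    affected <- !is.na(value) & value >= TPA_APT_THRESHOLD
  } else {
    den <- cnt[, "AC"] + cnt[, "GT"]
    num <- cnt[, "CA"] + cnt[, "TG"]
    value <- ifelse(den == 0, NA_real_, num / den)
    affected <- !is.na(value) & value <= COMPOSITE_THRESHOLD
  }
  value[no_cds] <- NA_real_
  affected[no_cds] <- FALSE
  call_ <- ifelse(is.na(value), "undefined",
                  ifelse(affected, "affected", "unaffected"))
  list(per_gene = data.frame(gene_id = g$gene_id, value = value, call = call_,
                             stringsAsFactors = FALSE),
       index = index,
       n_affected = sum(affected),
       n_total = nrow(g),
       affected_pct = pct_of(sum(affected), nrow(g), 1))
}

#' Stop-codon census of a gene set
#'
#' Tallies the final codon (last 3 nt of the CDS, uppercased) over a gene
#' set and reports the TAA/TGA and TAG/TGA ratios. RIP mutations create TA
#' dinucleotides, so a RIP-exposed gene set is expected to favour TAA (and
#' TAG) over TGA stops. CDS not ending in a canonical stop count as `other`.
#'
#' @param ann a [genome_annotation()].
#' @param gene_set character vector of gene ids (default: all genes).
#' @return list with `n_genes`, `taa`, `tag`, `tga`, `other`,
#'   `taa_tga_ratio`, `tag_tga_ratio` (half-up, 1 decimal; NA when tga = 0).
#' @export
stop_codon_census <- function(ann, gene_set = NULL) {
  g <- ann$genes
  if (!is.null(gene_set)) {
    missing <- setdiff(gene_set, g$gene_id)
    abort_if(length(missing) > 0, "unknown gene id(s): %s",
             paste(utils::head(missing, 3), collapse = ", "))
    g <- g[g$gene_id %in% gene_set, , drop = FALSE]
  }
  abort_if(any(nchar(g$cds) < 3), "gene(s) with CDS shorter than 3 nt")
  stops <- toupper(substr(g$cds, nchar(g$cds) - 2, nchar(g$cds)))
  taa <- sum(stops == "TAA")
  tag <- sum(stops == "TAG")
  tga <- sum(stops == "TGA")
  ratio <- function(x) if (tga == 0) NA_real_ else round_half_up(x / tga, 1)
  list(n_genes = nrow(g), taa = taa, tag = tag, tga = tga,
       other = nrow(g) - taa - tag - tga,
       taa_tga_ratio = ratio(taa), tag_tga_ratio = ratio(tag))
}

#' Dinucleotide frequency fold change versus control sequences
#'
#' Pools dinucleotide counts over each sequence set, converts to
#' frequencies (pooled counts / pooled N-free windows) and reports the
#' per-dinucleotide log10 fold change of target over control, the summary
#' used to visualise a CpA-to-TpA RIP signature in repeat families (high
#' TA, low CA/TG in the target set).
#'
#' @param target_seqs,control_seqs non-empty character vectors of sequences.
#' @return named numeric vector (length 16) of log10 fold changes; NA where
#'   either pooled frequency is zero.
#' @export
dinucleotide_foldchange <- function(target_seqs, control_seqs) {
  abort_if(length(target_seqs) == 0 || length(control_seqs) == 0,
           "both sequence sets must be non-empty")
  pool <- function(seqs) {
    cnt <- colSums(dinucleotide_counts_matrix(seqs))
    tot <- sum(cnt)
    abort_if(tot == 0, "sequence set has no countable dinucleotides")
    cnt / tot
  }
  ft <- pool(target_seqs)
  fc <- pool(control_seqs)
  out <- ifelse(ft == 0 | fc == 0, NA_real_, log10(ft / fc))
  setNames(out, DINUCS)
}

#' Compare two RIP-affected fractions
#'
#' One-sided Fisher exact test of whether group A has a larger affected
#' fraction than group B (e.g. SSPs versus all genes).
#'
#' @param affected_a,total_a affected and total counts in group A.
#' @param affected_b,total_b affected and total counts in group B.
#' @return one-sided P-value for fraction A > fraction B.
#' @export
compare_rip_fractions <- function(affected_a, total_a, affected_b, total_b) {
  abort_if(total_a == 0 || total_b == 0, "totals must be positive")
  abort_if(affected_a < 0 || affected_a > total_a ||
           affected_b < 0 || affected_b > total_b,
           "affected counts must lie in [0, total]")
  m <- affected_a + affected_b
  n <- (total_a - affected_a) + (total_b - affected_b)
  stats::phyper(affected_a - 1, m, n, total_a, lower.tail = FALSE)
}
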
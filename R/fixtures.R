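# Worked-example fixture builders.
#
# Summary statistics of the kind this package reports (RIP-affected
# fractions, stop-codon ratios, tandem/cluster percentages, cohort
# enrichment fractions) are pure functions of class counts. These
# constructors assemble an annotation with a prescribed composition so a
# published count profile can be replayed through the real analysis code
# paths and the reported statistic checked digit-for-digit. All fixtures
# are synthetic stand-ins: sequences are minimal templates, not biological
# sequences.

# template CDS with TpA/ApT = 1.0 (>= 0.89 threshold -> affected)
CDS_RIP_AFFECTED <- "ATGTATTAA"
# template CDS with TpA/ApT = 0 (< 0.89 -> unaffected)
CDS_RIP_UNAFFECTED <- "ATGGCCTGA"

base_flags <- function(gene_id, secreted = FALSE, protein_length = 100L,
                       cysteines = 0L, family_id = NA_character_,
                       category = "core", expanded_family = FALSE) {
  data.frame(gene_id = gene_id,
             secreted = rep_len(secreted, length(gene_id)),
             protein_length = rep_len(as.integer(protein_length), length(gene_id)),
             cysteines = rep_len(as.integer(cysteines), length(gene_id)),
             family_id = rep_len(family_id, length(gene_id)),
             category = rep_len(category, length(gene_id)),
             orphan = FALSE, pfam_families = "",
             expanded_family = rep_len(expanded_family, length(gene_id)),
             qvalue = NA_real_, stringsAsFactors = FALSE)
}

genes_on_contig <- function(gene_id, cds, contig = "c1") {
  w <- nchar(cds)
  end <- cumsum(w + 50L)
  data.frame(gene_id = gene_id, contig = contig,
             start = end - w + 1L, end = end, strand = "+",
             cds = cds, protein = translate_cds_many(cds),
             stringsAsFactors = FALSE)
}

#' Fixture: annotation with a prescribed RIP-affected gene count
#'
#' Builds `n_total` genes of which exactly `n_affected` carry a CDS with
#' TpA/ApT above the 0.89 call threshold, for replaying published
#' affected-fraction counts through [classify_rip_genes()].
#'
#' @param n_affected,n_total affected and total gene counts.
#' @param secreted,protein_length flag values applied to every gene (set
#'   `protein_length < 300` with `secreted = TRUE` to build an SSP set).
#' @return a [genome_annotation()].
#' @export
fixture_rip_fraction <- function(n_affected, n_total, secreted = FALSE,
                                 protein_length = 100L) {
  stopifnot(n_affected <= n_total)
  ids <- sprintf("g%05d", seq_len(n_total))
  cds <- rep(CDS_RIP_UNAFFECTED, n_total)
  cds[seq_len(n_affected)] <- CDS_RIP_AFFECTED
  genome_annotation(genes_on_contig(ids, cds),
                    base_flags(ids, secreted = secreted,
                               protein_length = protein_length))
}

#' Fixture: annotation with prescribed stop-codon counts
#'
#' @param taa,tag,tga gene counts by stop codon.
#' @return a [genome_annotation()] with `taa + tag + tga` genes.
#' @export
fixture_stop_codons <- function(taa, tag, tga) {
  n <- taa + tag + tga
  ids <- sprintf("g%05d", seq_len(n))
  cds <- c(rep("ATGTAA", taa), rep("ATGTAG", tag), rep("ATGTGA", tga))
  genome_annotation(genes_on_contig(ids, cds), base_flags(ids))
}

#' Fixture: annotation with planted tandem runs
#'
#' Plants `runs_of_2` family runs of length 2 and `runs_of_3` of length 3
#' (each with a fresh family id, separated by singleton genes) in a genome
#' of `n_total` genes, for replaying tandem-pair counts through
#' [find_tandem_pairs()].
#'
#' @param runs_of_2,runs_of_3 run counts.
#' @param n_total total gene count (must fit the runs plus separators).
#' @return a [genome_annotation()].
#' @export
fixture_tandem <- function(runs_of_2, runs_of_3, n_total) {
  lens <- c(rep(2L, runs_of_2), rep(3L, runs_of_3))
  abort_if(sum(lens) + length(lens) > n_total,
           "runs plus separators exceed n_total")
  fam <- character(0)
  for (i in seq_along(lens))
    fam <- c(fam, rep(sprintf("F%04d", i), lens[i]), NA_character_)
  fam <- c(fam, rep(NA_character_, n_total - length(fam)))
  ids <- sprintf("g%05d", seq_len(n_total))
  flags <- base_flags(ids)
  flags$family_id <- fam
  genome_annotation(genes_on_contig(ids, rep("ATGTAA", n_total)), flags)
}

#' Fixture: annotation with planted secreted-gene clusters
#'
#' Plants pure secreted runs (cluster sizes given as secreted-member
#' counts, each run separated by two non-secreted genes so runs stay
#' distinct), then isolated secreted genes to reach `n_secreted_total`,
#' padding with non-secreted genes. SSP labels (protein length 100 aa vs
#' 400 aa) are distributed `ssp_per_cluster[i]` to cluster i and the
#' remainder over the isolated secreted genes to reach `n_ssp_total`.
#'
#' @param cluster_sizes integer vector of secreted members per cluster
#'   (each >= 3).
#' @param n_secreted_total,n_ssp_total genome-wide class totals.
#' @param ssp_per_cluster integer vector (recycled length of
#'   `cluster_sizes`) of SSP members per cluster.
#' @return a [genome_annotation()].
#' @export
fixture_clusters <- function(cluster_sizes, n_secreted_total, n_ssp_total,
                             ssp_per_cluster = 0L) {
  stopifnot(all(cluster_sizes >= 3))
  ssp_per_cluster <- rep_len(ssp_per_cluster, length(cluster_sizes))
  stopifnot(all(ssp_per_cluster <= cluster_sizes))
  secreted <- logical(0); ssp <- logical(0)
  for (i in seq_along(cluster_sizes)) {
    k <- cluster_sizes[i]
    secreted <- c(secreted, rep(TRUE, k), FALSE, FALSE)
    ssp <- c(ssp, rep(TRUE, ssp_per_cluster[i]),
             rep(FALSE, k - ssp_per_cluster[i]), FALSE, FALSE)
  }
  n_iso <- n_secreted_total - sum(cluster_sizes)
  abort_if(n_iso < 0, "cluster members exceed n_secreted_total")
  n_iso_ssp <- n_ssp_total - sum(ssp_per_cluster)
  abort_if(n_iso_ssp < 0 || n_iso_ssp > n_iso,
           "SSP totals inconsistent with cluster assignment")
  for (i in seq_len(n_iso)) {
    secreted <- c(secreted, TRUE, FALSE, FALSE)
    ssp <- c(ssp, i <= n_iso_ssp, FALSE, FALSE)
  }
  n <- length(secreted)
  ids <- sprintf("g%05d", seq_len(n))
  flags <- base_flags(ids, secreted = secreted,
                      protein_length = ifelse(ssp, 100L, 400L))
  genome_annotation(genes_on_contig(ids, rep("ATGTAA", n)), flags)
}

#' Fixture: flags and regulation sets for an infection cohort
#'
#' Builds a gene universe whose focal cohort (the >10-fold upregulated,
#' top-decile-expressed genes) has prescribed secreted / SSP /
#' cysteine-rich / expanded-family composition, for replaying cohort
#' fractions through [infection_report()].
#'
#' @param n_focal cohort size.
#' @param n_secreted_focal secreted genes in the cohort.
#' @param n_ssp_focal SSPs among those (protein length set below 300 aa).
#' @param n_cys_rich_ssp cohort SSPs given >= 5 cysteines.
#' @param n_expanded_focal cohort genes from expanded Pfam families.
#' @param n_universe gene universe size.
#' @return list with `flags`, `sets` (a `RegulationSets` whose up10 and
#'   top_decile are the cohort), and `focal` ids.
#' @export
fixture_infection_cohort <- function(n_focal, n_secreted_focal, n_ssp_focal,
                                     n_cys_rich_ssp, n_expanded_focal,
                                     n_universe = 10000L) {
  stopifnot(n_ssp_focal <= n_secreted_focal, n_focal <= n_universe,
            n_cys_rich_ssp <= n_ssp_focal)
  ids <- sprintf("g%05d", seq_len(n_universe))
  focal <- ids[seq_len(n_focal)]
  flags <- base_flags(ids)
  flags$secreted[seq_len(n_secreted_focal)] <- TRUE
  flags$protein_length <- 400L
  flags$protein_length[seq_len(n_ssp_focal)] <- 150L
  flags$cysteines[seq_len(n_cys_rich_ssp)] <- 6L
  flags$expanded_family[seq_len(n_expanded_focal)] <- TRUE
  sets <- structure(list(fold_change = setNames(rep(Inf, n_focal), focal),
                         up2 = focal, up10 = focal,
                         down2 = character(0), down10 = character(0),
                         top_decile = focal),
                    class = "RegulationSets")
  list(flags = flags, sets = sets, focal = focal)
}

#' Fixture: ortholog pair table with a prescribed significant fraction
#'
#' @param n_pairs total ortholog pairs.
#' @param n_significant pairs flagged with qvalue below 0.01.
#' @return data.frame for [ortholog_compare()].
#' @export
fixture_ortholog_pairs <- function(n_pairs, n_significant) {
  stopifnot(n_significant <= n_pairs)
  data.frame(gene_a = sprintf("a%05d", seq_len(n_pairs)),
             gene_b = sprintf("b%05d", seq_len(n_pairs)),
             expr_a = 100, expr_b = 100,
             qvalue = c(rep(0.001, n_significant),
                        rep(0.5, n_pairs - n_significant)),
             stringsAsFactors = FALSE)
}
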
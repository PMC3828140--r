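#' Configuration for the synthetic genome generator
#'
#' Defaults emulate the published genome profile of a nematode-trapping
#' fungus at desk scale: GC content ~45%, ~15.2% secreted genes of which
#' ~41.7% are SSPs (<300 aa), a mean protein around 400 aa (core genes
#' are longer than species-specific ones in the real genomes; a single
#' distribution is used here), a handful of planted tandem runs and
#' secreted-gene clusters, and a moderate RIP rate applied to tandem
#' duplicate copies.
#'
#' @param n_contigs number of contigs.
#' @param genes_per_contig genes per contig.
#' @param gene_length_aa list(mean, sd, min) for protein length (aa).
#' @param intergenic_bp list(mean, sd, min) for intergenic spacer length.
#' @param gc_content GC fraction in (0,1).
#' @param frac_secreted fraction of background genes flagged secreted.
#' @param frac_ssp_of_secreted fraction of secreted genes drawn short (<300 aa).
#' @param planted_clusters list of integer pairs
#'   `c(n_secreted_members, n_interspersed_nonsecreted)`; each cluster needs
#'   `n_secreted_members >= 3` and at most one non-secreted gene between any
#'   two consecutive secreted members.
#' @param planted_tandem_runs integer vector of run lengths (>= 2); each run
#'   is a block of adjacent genes sharing a fresh family id.
#' @param rip_rate per-target mutation probability applied to tandem
#'   duplicate copies (see [apply_rip()]).
#' @param rip_rate_tpg optional separate rate for the TpG (reverse-strand)
#'   target; default equal to `rip_rate`.
#' @param scattered_families list(n, size_range): non-adjacent multi-member
#'   families sprinkled over background genes, so permutation nulls see a
#'   realistic family-size distribution.
#' @param stop_probs named sampling probabilities for TAA/TAG/TGA stops.
#' @param category_probs sampling probabilities for homology categories.
#' @param frac_pfam fraction of non-orphan genes given Pfam labels.
#' @param frac_orphan_of_ss orphan fraction among species-specific genes.
#' @param frac_expanded probability that a Pfam-labelled gene belongs to an
#'   expanded domain family.
#' @param seed integer seed; the generator is a pure function of
#'   (config, seed).
#' @return a validated `GenomeConfig` list.
#' @export
genome_config <- function(n_contigs = 4,
                          genes_per_contig = 150,
                          gene_length_aa = list(mean = 400, sd = 150, min = 60),
                          intergenic_bp = list(mean = 1500, sd = 500, min = 100),
                          gc_content = 0.45,
                          frac_secreted = 0.152,
                          frac_ssp_of_secreted = 0.417,
                          planted_clusters = list(c(3L, 0L), c(4L, 1L), c(3L, 1L)),
                          planted_tandem_runs = c(2L, 2L, 3L),
                          rip_rate = 0.3,
                          rip_rate_tpg = NULL,
                          scattered_families = list(n = 20, size_range = c(2, 4)),
                          stop_probs = c(TAA = 1/3, TAG = 1/3, TGA = 1/3),
                          category_probs = c(core = 0.62, lineage_specific = 0.20,
                                             species_specific = 0.16,
                                             unclassified = 0.02),
                          frac_pfam = 0.68,
                          frac_orphan_of_ss = 0.71,
                          frac_expanded = 0.12,
                          seed = 1L) {
  cfg <- as.list(environment())
  abort_if(gc_content <= 0 || gc_content >= 1, "gc_content must be in (0,1)")
  for (f in c("frac_secreted", "frac_ssp_of_secreted", "rip_rate",
              "frac_pfam", "frac_orphan_of_ss", "frac_expanded"))
    abort_if(cfg[[f]] < 0 || cfg[[f]] > 1, "%s must be in [0,1]", f)
  abort_if(any(planted_tandem_runs < 2), "tandem runs must have length >= 2")
  for (cl in planted_clusters) {
    abort_if(length(cl) != 2, "planted_clusters entries must be length-2")
    abort_if(cl[1] < 3, "planted clusters need >= 3 secreted members")
    abort_if(cl[2] > cl[1] - 1,
             "at most one interspersed gene per consecutive secreted pair")
  }
  abort_if(!all(names(stop_probs) == c("TAA", "TAG", "TGA")),
           "stop_probs must be named TAA, TAG, TGA")
  class(cfg) <- "GenomeConfig"
  cfg
}

#' Apply a RIP mutation pass to a sequence
#'
#' Simulates one round of repeat-induced point mutation on duplex DNA as a
#' single left-to-right pass over the original sequence: each forward-strand
#' CpA has its C replaced by T with probability `rate`, and each
#' forward-strand TpG (the reverse-strand CpA) has its G replaced by A with
#' probability `rate_tpg`. Targets are identified on the original sequence,
#' so mutations never create new targets within the pass; length is
#' preserved and each mutation converts a CA or TG window into TA.
#'
#' @param seq nucleotide string over A/C/G/T/N.
#' @param rate mutation probability per CpA target, in \[0,1\].
#' @param seed integer seed.
#' @param rate_tpg optional separate probability for TpG targets
#'   (default `rate`), exposing possible strand asymmetry of the machinery.
#' @return the mutated sequence.
#' @examples
#' apply_rip("CACA", 1, seed = 1) # "TATA"
#' @export
apply_rip <- function(seq, rate, seed = 1L, rate_tpg = rate) {
  abort_if(rate < 0 || rate > 1 || rate_tpg < 0 || rate_tpg > 1,
           "rates must be in [0,1]")
  ch <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  n <- length(ch)
  if (n < 2) return(seq)
  withr::local_seed(seed)
  ca <- which(ch[-n] == "C" & ch[-1] == "A")      # mutate the C
  tg <- which(ch[-n] == "T" & ch[-1] == "G") + 1L  # mutate the G
  if (length(ca) > 0) {
    hit <- ca[runif(length(ca)) < rate]
    ch[hit] <- "T"
  }
  if (length(tg) > 0) {
    hit <- tg[runif(length(tg)) < rate_tpg]
    ch[hit] <- "A"
  }
  paste(ch, collapse = "")
}

# random sequence at given GC content
random_seq <- function(n, gc) {
  if (n <= 0) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# random CDS: ATG start, stop-free body at the given GC, sampled stop codon
random_cds <- function(aa_len, gc, stop_probs) {
  body_codons <- aa_len - 1L
  nt <- sample(c("A", "C", "G", "T"), 3L * body_codons, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
  codons <- matrix(nt, nrow = 3L)
  repeat {
    cod <- paste0(codons[1, ], codons[2, ], codons[3, ])
    bad <- which(cod %in% c("TAA", "TAG", "TGA"))
    if (length(bad) == 0) break
    codons[, bad] <- sample(c("A", "C", "G", "T"), 3L * length(bad),
                            replace = TRUE,
                            prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
  }
  stop_codon <- sample(names(stop_probs), 1L, prob = stop_probs)
  paste0("ATG", paste(cod, collapse = ""), stop_codon)
}

#' Generate a synthetic annotated genome with plantable ground truth
#'
#' Builds contigs of single-exon genes separated by random intergenic
#' spacers, plants tandem-duplication runs (adjacent genes sharing a fresh
#' family id; copies after the first are RIP-mutated duplicates of the
#' first) and secreted-gene clusters (runs of secreted genes with the
#' configured number of single-gene non-secreted interruptions), and draws
#' background flags (secretion, SSP-sized lengths, scattered non-adjacent
#' families, homology categories, orphan and Pfam labels). Two forced
#' non-secreted buffer genes flank every planted cluster so background
#' secretion noise cannot extend a planted member set.
#'
#' @param cfg a [genome_config()].
#' @return list with `annotation` (a [genome_annotation()]) and `truth`
#'   (planted tandem runs/pairs, cluster member sets, RIP-mutated gene ids).
#' @export
generate_genome <- function(cfg) {
  stopifnot(inherits(cfg, "GenomeConfig"))
  withr::local_seed(cfg$seed)
  G <- cfg$genes_per_contig
  n_total <- cfg$n_contigs * G

  # --- plan planted structure positions -------------------------------
  structures <- c(
    lapply(seq_along(cfg$planted_tandem_runs), function(i)
      list(kind = "tandem", id = i, span = cfg$planted_tandem_runs[i])),
    lapply(seq_along(cfg$planted_clusters), function(i) {
      cl <- cfg$planted_clusters[[i]]
      list(kind = "cluster", id = i, s = cl[1], gaps = cl[2],
           span = cl[1] + cl[2])
    })
  )
  placement <- vector("list", length(structures))
  contig_i <- 1L
  cursor <- 3L  # leave >= 2 buffer genes at the contig start
  for (k in seq_along(structures)) {
    span <- structures[[k]]$span
    while (cursor + span + 1L > G) {  # need 2 trailing buffer genes
      contig_i <- contig_i + 1L
      cursor <- 3L
      abort_if(contig_i > cfg$n_contigs,
               "planted structures exceed genome capacity")
    }
    placement[[k]] <- list(contig = contig_i,
                           pos = seq.int(cursor, cursor + span - 1L))
    cursor <- cursor + span + 2L  # 2 buffer genes between structures
  }

  # global gene index = (contig - 1) * G + position
  gidx <- function(p) (p$contig - 1L) * G + p$pos

  secreted <- runif(n_total) < cfg$frac_secreted
  family <- rep(NA_character_, n_total)
  planted_gene <- logical(n_total)   # inside a planted structure
  buffer_gene <- logical(n_total)    # forced non-secreted flank

  cluster_truth <- list()
  tandem_truth <- list()
  for (k in seq_along(structures)) {
    st <- structures[[k]]
    idx <- gidx(placement[[k]])
    planted_gene[idx] <- TRUE
    lo <- min(idx); hi <- max(idx)
    ctg0 <- (placement[[k]]$contig - 1L) * G
    buf <- intersect(c(lo - 2L, lo - 1L, hi + 1L, hi + 2L),
                     seq.int(ctg0 + 1L, ctg0 + G))
    buffer_gene[buf] <- TRUE
    if (st$kind == "tandem") {
      family[idx] <- sprintf("FAM_T%03d", st$id)
      secreted[idx] <- runif(length(idx)) < cfg$frac_secreted
      tandem_truth[[st$id]] <- idx
    } else {
      # secretion pattern: interleave the configured number of single
      # non-secreted genes between the first `gaps` secreted pairs
      pat <- rep(TRUE, st$s)
      if (st$gaps > 0)
        for (j in seq_len(st$gaps)) pat <- append(pat, FALSE, after = 2L * j - 1L)
      secreted[idx] <- pat
      cluster_truth[[st$id]] <- list(all = idx, secreted = idx[pat])
    }
  }
  secreted[buffer_gene] <- FALSE

  # scattered non-adjacent families over background genes
  free <- which(!planted_gene)
  sf <- cfg$scattered_families
  if (sf$n > 0 && length(free) > 4) {
    for (i in seq_len(sf$n)) {
      size <- sample(seq(sf$size_range[1], sf$size_range[2]), 1L)
      fam_id <- sprintf("FAM_S%03d", i)
      chosen <- integer(0)
      pool <- free[is.na(family[free])]
      for (j in seq_len(size)) {
        ok <- pool[!(pool %in% c(chosen, chosen - 1L, chosen + 1L))]
        if (length(ok) == 0) break
        pick <- ok[sample.int(length(ok), 1L)]
        chosen <- c(chosen, pick)
        pool <- setdiff(pool, pick)
      }
      if (length(chosen) >= 2) family[chosen] <- fam_id
    }
  }

  # protein lengths: secreted genes mix SSP-sized and long; others normal
  draw_len <- function(n) {
    pmax(cfg$gene_length_aa$min,
         round(rnorm(n, cfg$gene_length_aa$mean, cfg$gene_length_aa$sd)))
  }
  aa_len <- draw_len(n_total)
  sec_idx <- which(secreted)
  if (length(sec_idx) > 0) {
    is_ssp <- runif(length(sec_idx)) < cfg$frac_ssp_of_secreted
    aa_len[sec_idx[is_ssp]] <- sample(seq(max(60, cfg$gene_length_aa$min), 299),
                                      sum(is_ssp), replace = TRUE)
    aa_len[sec_idx[!is_ssp]] <- pmax(300, aa_len[sec_idx[!is_ssp]])
  }

  # CDS sequences; tandem copies after the first are RIPped duplicates
  cds <- character(n_total)
  for (i in seq_len(n_total))
    cds[i] <- random_cds(aa_len[i], cfg$gc_content, cfg$stop_probs)
  rip_genes <- integer(0)
  rate_tpg <- if (is.null(cfg$rip_rate_tpg)) cfg$rip_rate else cfg$rip_rate_tpg
  for (run in tandem_truth) {
    for (j in run[-1]) {
      cds[j] <- apply_rip(cds[run[1]], cfg$rip_rate,
                          seed = sample.int(2^31 - 1, 1L),
                          rate_tpg = rate_tpg)
      aa_len[j] <- aa_len[run[1]]
      if (cfg$rip_rate > 0) rip_genes <- c(rip_genes, j)
    }
  }
  protein <- translate_cds_many(cds)

  gene_id <- sprintf("SYN_%05d", seq_len(n_total))
  strand <- sample(c("+", "-"), n_total, replace = TRUE)
  embedded_cds <- cds
  embedded_cds[strand == "-"] <- revcomp(cds[strand == "-"])

  # assemble contigs
  contig_names <- sprintf("ctg%02d", seq_len(cfg$n_contigs))
  contig_of <- rep(contig_names, each = G)
  start <- integer(n_total); end <- integer(n_total)
  contig_seqs <- character(cfg$n_contigs)
  for (ci in seq_len(cfg$n_contigs)) {
    idx <- which(contig_of == contig_names[ci])
    parts <- character(0)
    pos <- 0L
    for (i in idx) {
      gap <- max(cfg$intergenic_bp$min,
                 round(rnorm(1, cfg$intergenic_bp$mean, cfg$intergenic_bp$sd)))
      parts <- c(parts, random_seq(gap, cfg$gc_content))
      pos <- pos + gap
      start[i] <- pos + 1L
      end[i] <- pos + nchar(cds[i])
      parts <- c(parts, embedded_cds[i])
      pos <- pos + nchar(cds[i])
    }
    parts <- c(parts, random_seq(cfg$intergenic_bp$min, cfg$gc_content))
    contig_seqs[ci] <- paste(parts, collapse = "")
  }
  names(contig_seqs) <- contig_names

  # flags
  category <- sample(names(cfg$category_probs), n_total, replace = TRUE,
                     prob = cfg$category_probs)
  orphan <- category == "species_specific" &
    runif(n_total) < cfg$frac_orphan_of_ss
  pfam <- rep("", n_total)
  has_pfam <- !orphan & runif(n_total) < cfg$frac_pfam
  pfam_pool <- sprintf("PFX%04d", 1:60)
  pfam[has_pfam] <- vapply(which(has_pfam), function(i)
    paste(sample(pfam_pool, sample(1:2, 1L)), collapse = ";"), character(1))
  expanded <- has_pfam & runif(n_total) < cfg$frac_expanded

  genes <- data.frame(gene_id = gene_id, contig = contig_of, start = start,
                      end = end, strand = strand, cds = cds, protein = protein,
                      stringsAsFactors = FALSE)
  flags <- data.frame(gene_id = gene_id,
                      secreted = secreted,
                      protein_length = nchar(protein),
                      cysteines = nchar(protein) -
                        nchar(gsub("C", "", protein, fixed = TRUE)),
                      family_id = family,
                      category = category,
                      orphan = orphan,
                      pfam_families = pfam,
                      expanded_family = expanded,
                      qvalue = NA_real_,
                      stringsAsFactors = FALSE)

  ann <- genome_annotation(genes, flags, contig_seqs)
  truth <- list(
    tandem_runs = lapply(tandem_truth, function(idx) gene_id[idx]),
    tandem_pairs = do.call(rbind, lapply(tandem_truth, function(idx)
      if (length(idx) >= 2)
        data.frame(gene_a = gene_id[idx[-length(idx)]],
                   gene_b = gene_id[idx[-1]], stringsAsFactors = FALSE))),
    clusters = lapply(cluster_truth, function(cl)
      list(all = gene_id[cl$all], secreted = gene_id[cl$secreted])),
    rip_genes = gene_id[rip_genes],
    seed = cfg$seed)
  list(annotation = ann, truth = truth)
}

#' Configuration for synthetic expression counts
#'
#' Emulates the study's two-replicate design: a control condition (isolated
#' knobs / traps) and an infection condition, with negative-binomial counts
#' (variance = mean + dispersion * mean^2) around per-gene baselines and
#' planted 10x / 2x infection fold changes.
#'
#' @param n_samples_per_condition replicates per condition (default 2).
#' @param nb_mean median of the per-gene log-normal baseline mean.
#' @param nb_dispersion NB dispersion (0 = Poisson).
#' @param planted_up_10x,planted_up_2x disjoint gene-id sets planted as
#'   members of the ">10-fold" and ">2-fold" upregulated classes.
#' @param fold_up10,fold_up2 infection-mean multipliers for the planted
#'   sets. Defaults are twice the class thresholds (20 and 4): the
#'   regulation classes are open ("more than ten-fold"), so a gene planted
#'   exactly at 10x sits on the class boundary and an unbiased fold-change
#'   estimate falls below it half the time; planting at twice the threshold
#'   makes class membership of the ground truth unambiguous under sampling
#'   noise while keeping 2x-class genes out of the 10x class (4 < 10).
#' @param baseline_sdlog sdlog of the per-gene baseline distribution.
#' @param control_label,infection_label condition labels.
#' @param seed integer seed.
#' @return a validated `ExpressionConfig` list.
#' @export
expression_config <- function(n_samples_per_condition = 2L,
                              nb_mean = 100,
                              nb_dispersion = 0.05,
                              planted_up_10x = character(0),
                              planted_up_2x = character(0),
                              fold_up10 = 20,
                              fold_up2 = 4,
                              baseline_sdlog = 1,
                              control_label = "knob",
                              infection_label = "infection",
                              seed = 1L) {
  abort_if(nb_dispersion < 0, "dispersion must be >= 0")
  abort_if(length(intersect(planted_up_10x, planted_up_2x)) > 0,
           "planted 10x and 2x sets must be disjoint")
  cfg <- as.list(environment())
  class(cfg) <- "ExpressionConfig"
  cfg
}

#' Generate a synthetic expression count table
#'
#' @param ann a [genome_annotation()] (or a character vector of gene ids).
#' @param cfg an [expression_config()].
#' @return an [expression_table()] of raw counts with condition labels.
#' @export
generate_expression <- function(ann, cfg) {
  stopifnot(inherits(cfg, "ExpressionConfig"))
  ids <- if (inherits(ann, "GenomeAnnotation")) ann$genes$gene_id
         else as.character(ann)
  planted <- c(cfg$planted_up_10x, cfg$planted_up_2x)
  abort_if(!all(planted %in% ids), "planted gene sets must be genome gene ids")
  withr::local_seed(cfg$seed)
  n <- length(ids)
  base_mu <- exp(rnorm(n, log(cfg$nb_mean), cfg$baseline_sdlog))
  fold <- rep(1, n)
  fold[ids %in% cfg$planted_up_10x] <- cfg$fold_up10
  fold[ids %in% cfg$planted_up_2x] <- cfg$fold_up2
  k <- cfg$n_samples_per_condition
  draw <- function(mu) {
    if (cfg$nb_dispersion == 0) rpois(length(mu), mu)
    else rnbinom(length(mu), mu = mu, size = 1 / cfg$nb_dispersion)
  }
  counts <- matrix(0L, nrow = n, ncol = 2L * k,
                   dimnames = list(ids, c(sprintf("%s_%d", cfg$control_label, seq_len(k)),
                                          sprintf("%s_%d", cfg$infection_label, seq_len(k)))))
  for (j in seq_len(k)) counts[, j] <- draw(base_mu)
  for (j in seq_len(k)) counts[, k + j] <- draw(base_mu * fold)
  expression_table(counts,
                   conditions = rep(c(cfg$control_label, cfg$infection_label),
                                    each = k))
}

#' Pair genes of two synthetic species as orthologs
#'
#' Links a random fraction of gene ids positionally between two gene
#' universes, mimicking a bidirectional-best-hit ortholog table.
#'
#' @param ids_a,ids_b gene id vectors of the two species.
#' @param frac fraction of the smaller universe linked (default 0.7).
#' @param seed integer seed.
#' @return data.frame with columns `gene_a`, `gene_b`.
#' @export
generate_ortholog_map <- function(ids_a, ids_b, frac = 0.7, seed = 1L) {
  withr::local_seed(seed)
  n <- floor(frac * min(length(ids_a), length(ids_b)))
  pick <- sort(sample.int(min(length(ids_a), length(ids_b)), n))
  data.frame(gene_a = ids_a[pick], gene_b = ids_b[pick],
             stringsAsFactors = FALSE)
}
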
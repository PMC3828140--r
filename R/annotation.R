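#' @importFrom stats median rnbinom rnorm rpois runif setNames
#' @importFrom utils read.delim write.table
NULL

FLAG_COLUMNS <- c("gene_id", "secreted", "protein_length", "cysteines",
                  "family_id", "category", "orphan", "pfam_families",
                  "expanded_family", "qvalue")

CATEGORIES <- c("core", "lineage_specific", "species_specific", "unclassified")

#' Construct a genome annotation
#'
#' The central container used by every analysis in the package: per-gene
#' coordinates and sequences plus a per-gene flag table of annotation labels
#' (secretion, protein length, cysteine count, ortholog family, homology
#' category, orphan status, Pfam families, expanded-family membership and an
#' optional externally computed q-value).
#'
#' Coordinates are 1-based inclusive (GFF3 convention). Genes are stored
#' sorted by (contig, start, end, gene_id); "adjacent" genes throughout the
#' package means consecutive in this ordering, regardless of strand or
#' intergenic distance. CDS sequences are spliced, in coding orientation,
#' and include the stop codon.
#'
#' @param genes data.frame with columns `gene_id`, `contig`, `start`, `end`,
#'   `strand` (`+`/`-`), `cds`, `protein`.
#' @param flags data.frame with columns `gene_id`, `secreted` (logical),
#'   `protein_length`, `cysteines`, `family_id` (NA = singleton),
#'   `category` (core / lineage_specific / species_specific / unclassified),
#'   `orphan` (logical), `pfam_families` (semicolon-joined string, "" = none),
#'   `expanded_family` (logical), `qvalue` (numeric or NA). Genes absent from
#'   `flags` are filled in as unclassified, non-secreted, with a warning.
#' @param contigs optional named character vector of contig sequences.
#' @return an object of class `GenomeAnnotation`.
#' @export
genome_annotation <- function(genes, flags, contigs = NULL) {
  stopifnot(is.data.frame(genes))
  need <- c("gene_id", "contig", "start", "end", "strand", "cds", "protein")
  abort_if(!all(need %in% names(genes)),
           "genes is missing columns: %s",
           paste(setdiff(need, names(genes)), collapse = ", "))
  genes <- genes[, need, drop = FALSE]
  genes$gene_id <- as.character(genes$gene_id)
  genes$contig <- as.character(genes$contig)
  genes$start <- as.integer(genes$start)
  genes$end <- as.integer(genes$end)
  abort_if(anyDuplicated(genes$gene_id) > 0, "duplicate gene_id in annotation")
  abort_if(any(genes$start > genes$end), "gene with start > end")
  abort_if(!all(genes$strand %in% c("+", "-")), "strand must be '+' or '-'")

  genes <- genes[order(genes$contig, genes$start, genes$end, genes$gene_id), ,
                 drop = FALSE]
  rownames(genes) <- NULL

  flags <- normalize_flags(flags)
  missing <- setdiff(genes$gene_id, flags$gene_id)
  if (length(missing) > 0) {
    warning(sprintf("%d gene(s) missing from flags table; defaulting to unclassified/non-secreted",
                    length(missing)))
    fill <- default_flags(missing,
                          nchar(genes$protein[match(missing, genes$gene_id)]))
    flags <- rbind(flags, fill)
  }
  flags <- flags[match(genes$gene_id, flags$gene_id), , drop = FALSE]
  rownames(flags) <- NULL

  if (!is.null(contigs)) {
    contigs <- setNames(toupper(as.character(contigs)), names(contigs))
    known <- genes$contig %in% names(contigs)
    abort_if(!all(known), "gene(s) on contig(s) absent from contig sequences")
    too_long <- genes$end > nchar(contigs)[genes$contig]
    abort_if(any(too_long), "gene coordinates exceed contig length")
  }

  structure(list(genes = genes, flags = flags, contigs = contigs),
            class = "GenomeAnnotation")
}

default_flags <- function(gene_ids, protein_lengths) {
  data.frame(gene_id = gene_ids,
             secreted = FALSE,
             protein_length = as.integer(pmax(1L, protein_lengths)),
             cysteines = 0L,
             family_id = NA_character_,
             category = "unclassified",
             orphan = FALSE,
             pfam_families = "",
             expanded_family = FALSE,
             qvalue = NA_real_,
             stringsAsFactors = FALSE)
}

normalize_flags <- function(flags) {
  stopifnot(is.data.frame(flags))
  abort_if(!all(c("gene_id", "secreted", "protein_length") %in% names(flags)),
           "flags table must contain at least gene_id, secreted, protein_length")
  out <- data.frame(gene_id = as.character(flags$gene_id),
                    stringsAsFactors = FALSE)
  as_bool <- function(x) {
    if (is.logical(x)) return(x)
    tolower(as.character(x)) %in% c("true", "t", "1", "yes")
  }
  n <- nrow(out)
  out$secreted <- as_bool(flags$secreted)
  out$protein_length <- as.integer(flags$protein_length)
  out$cysteines <- if ("cysteines" %in% names(flags))
    as.integer(flags$cysteines) else rep_len(0L, n)
  fam <- if ("family_id" %in% names(flags))
    as.character(flags$family_id) else rep_len(NA_character_, n)
  fam[!is.na(fam) & fam == ""] <- NA_character_
  out$family_id <- fam
  cat_ <- if ("category" %in% names(flags))
    as.character(flags$category) else rep_len("unclassified", n)
  cat_[is.na(cat_) | !(cat_ %in% CATEGORIES)] <- "unclassified"
  out$category <- cat_
  out$orphan <- if ("orphan" %in% names(flags)) as_bool(flags$orphan)
    else rep_len(FALSE, n)
  pf <- if ("pfam_families" %in% names(flags))
    as.character(flags$pfam_families) else rep_len("", n)
  pf[is.na(pf)] <- ""
  out$pfam_families <- pf
  out$expanded_family <- if ("expanded_family" %in% names(flags))
    as_bool(flags$expanded_family) else rep_len(FALSE, n)
  out$qvalue <- if ("qvalue" %in% names(flags))
    suppressWarnings(as.numeric(flags$qvalue)) else rep_len(NA_real_, n)

  abort_if(anyDuplicated(out$gene_id) > 0, "duplicate gene_id in flags table")
  abort_if(any(out$protein_length <= 0, na.rm = TRUE),
           "protein_length must be positive")
  abort_if(any(out$cysteines > out$protein_length, na.rm = TRUE),
           "cysteines cannot exceed protein_length")
  bad_orphan <- out$orphan & out$pfam_families != ""
  if (any(bad_orphan)) {
    warning("orphan gene(s) with Pfam families; clearing orphan flag")
    out$orphan[bad_orphan] <- FALSE
  }
  out
}

#' @export
print.GenomeAnnotation <- function(x, ...) {
  cat(sprintf("GenomeAnnotation: %d genes on %d contig(s)%s\n",
              nrow(x$genes), length(unique(x$genes$contig)),
              if (is.null(x$contigs)) " (no contig sequences)" else ""))
  invisible(x)
}

#' Number of genes in an annotation
#' @param ann a `GenomeAnnotation`.
#' @return integer gene count.
#' @export
n_genes <- function(ann) nrow(ann$genes)

#' Load a genome annotation from standard files
#'
#' Reads gene models from GFF3 (gene/mRNA/CDS features), sequences from
#' FASTA and per-gene flags from a tab-separated table (header required,
#' booleans as true/false). When a genome FASTA is supplied and no CDS FASTA
#' is given, CDS sequences are extracted from the contigs; when both are
#' given the FASTA-supplied CDS wins and a coordinate-inconsistent gene is
#' retained with a warning. Proteins are translated from the CDS when no
#' protein FASTA is supplied.
#'
#' @param gff3_path path to a GFF3 file.
#' @param flags_tsv path to the flags TSV.
#' @param genome_fasta,protein_fasta,cds_fasta optional FASTA paths.
#' @return a [genome_annotation()] object.
#' @export
load_annotation <- function(gff3_path, flags_tsv, genome_fasta = NULL,
                            protein_fasta = NULL, cds_fasta = NULL) {
  gr <- rtracklayer::import(gff3_path, format = "gff3")
  genes_gr <- gr[tolower(as.character(gr$type)) == "gene"]
  ids <- as.character(genes_gr$ID)
  abort_if(anyDuplicated(ids) > 0, "duplicate gene_id in GFF3: %s",
           paste(unique(ids[duplicated(ids)]), collapse = ", "))

  contigs <- NULL
  if (!is.null(genome_fasta)) {
    cs <- Biostrings::readDNAStringSet(genome_fasta)
    contigs <- setNames(as.character(cs), sub("\\s.*$", "", names(cs)))
  }

  cds <- rep(NA_character_, length(ids))
  if (!is.null(cds_fasta)) {
    cf <- Biostrings::readDNAStringSet(cds_fasta)
    cds_map <- setNames(as.character(cf), sub("\\s.*$", "", names(cf)))
    cds <- unname(cds_map[ids])
  }

  st <- GenomicRanges::start(genes_gr)
  en <- GenomicRanges::end(genes_gr)
  strand_ <- as.character(GenomicRanges::strand(genes_gr))
  strand_[!(strand_ %in% c("+", "-"))] <- "+"
  ctg <- as.character(GenomicRanges::seqnames(genes_gr))

  if (!is.null(contigs)) {
    extracted <- substr(contigs[ctg], st, en)
    minus <- strand_ == "-"
    extracted[minus] <- revcomp(extracted[minus])
    inconsistent <- !is.na(cds) & nchar(cds) != nchar(extracted)
    if (any(inconsistent))
      warning(sprintf("%d gene(s) with CDS length inconsistent with coordinates; keeping FASTA CDS",
                      sum(inconsistent)))
    cds[is.na(cds)] <- extracted[is.na(cds)]
  }
  abort_if(anyNA(cds),
           "CDS sequences unavailable: supply cds_fasta or genome_fasta")

  if (!is.null(protein_fasta)) {
    pf <- Biostrings::readAAStringSet(protein_fasta)
    prot_map <- setNames(as.character(pf), sub("\\s.*$", "", names(pf)))
    protein <- unname(prot_map[ids])
    abort_if(anyNA(protein), "protein FASTA missing sequences for some genes")
  } else {
    protein <- translate_cds_many(cds)
  }

  genes <- data.frame(gene_id = ids, contig = ctg, start = st, end = en,
                      strand = strand_, cds = toupper(cds), protein = protein,
                      stringsAsFactors = FALSE)
  flags <- read_flags_tsv(flags_tsv)
  genome_annotation(genes, flags, contigs)
}

# translate CDS (with terminal stop) into AA strings without the terminal
# stop; internal stops (e.g. RIP-introduced) become 'X'. Vectorised.
translate_cds_many <- function(cds) {
  if (length(cds) == 0) return(character(0))
  n <- nchar(cds)
  body <- substr(cds, 1, n - n %% 3)
  aa <- suppressWarnings(as.character(
    Biostrings::translate(Biostrings::DNAStringSet(body),
                          if.fuzzy.codon = "solve")))
  aa <- sub("\\*$", "", aa)
  gsub("*", "X", aa, fixed = TRUE)
}

translate_cds <- function(cds) translate_cds_many(cds)[[1]]

# vectorised reverse complement on plain character vectors
revcomp <- function(seqs) {
  if (length(seqs) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(seqs)))
}

read_flags_tsv <- function(path) {
  df <- read.delim(path, sep = "\t", header = TRUE, quote = "",
                   colClasses = "character", na.strings = "NA",
                   stringsAsFactors = FALSE)
  normalize_flags(df)
}

#' Write a genome annotation to standard files
#'
#' Emits `genes.gff3`, `flags.tsv`, `cds.fasta`, `proteins.fasta` and (when
#' contig sequences are present) `genome.fasta` such that
#' [load_annotation()] on the outputs reproduces the annotation exactly.
#'
#' @param ann a `GenomeAnnotation`.
#' @param out_dir output directory (created if needed).
#' @return invisibly, a named character vector of written paths.
#' @export
write_annotation <- function(ann, out_dir) {
  stopifnot(inherits(ann, "GenomeAnnotation"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  abort_if(!dir.exists(out_dir), "cannot create directory %s", out_dir)
  g <- ann$genes

  paths <- c(gff3 = file.path(out_dir, "genes.gff3"),
             flags = file.path(out_dir, "flags.tsv"),
             cds = file.path(out_dir, "cds.fasta"),
             proteins = file.path(out_dir, "proteins.fasta"))

  feats <- function(type, ids, parents) {
    GenomicRanges::GRanges(
      seqnames = g$contig,
      ranges = IRanges::IRanges(g$start, g$end),
      strand = g$strand,
      type = rep_len(type, nrow(g)), ID = ids,
      Parent = if (is.null(parents))
        S4Vectors::List(rep(list(character(0)), nrow(g)))
      else S4Vectors::List(as.list(parents)))
  }
  p0 <- function(...) paste0(..., recycle0 = TRUE)
  gr <- c(feats("gene", g$gene_id, NULL),
          feats("mRNA", p0(g$gene_id, ".t1"), g$gene_id),
          feats("CDS", p0(g$gene_id, ".cds"), p0(g$gene_id, ".t1")))
  gr$source <- rep_len("parasitome", length(gr))
  if (length(gr) == 0) {
    # rtracklayer cannot export an empty GRanges with list columns
    writeLines("##gff-version 3", paths[["gff3"]])
  } else {
    rtracklayer::export(gr, paths[["gff3"]], format = "gff3")
  }

  write_flags_tsv(ann$flags, paths[["flags"]])
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(setNames(g$cds, g$gene_id)), paths[["cds"]])
  Biostrings::writeXStringSet(
    Biostrings::AAStringSet(setNames(g$protein, g$gene_id)), paths[["proteins"]])
  if (!is.null(ann$contigs)) {
    paths <- c(paths, genome = file.path(out_dir, "genome.fasta"))
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(ann$contigs), paths[["genome"]])
  }
  invisible(paths)
}

write_flags_tsv <- function(flags, path) {
  out <- flags
  for (col in c("secreted", "orphan", "expanded_family"))
    out[[col]] <- ifelse(out[[col]], "true", "false")
  out$family_id[is.na(out$family_id)] <- "NA"
  out$qvalue <- ifelse(is.na(out$qvalue), "NA", format(out$qvalue, digits = 15))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}
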
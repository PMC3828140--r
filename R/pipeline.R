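REPORT_SCHEMA_VERSION <- "1.0"

#' Build a pipeline configuration
#'
#' Inputs are either file paths (GFF3 + flags TSV, optional FASTAs, TE
#' intervals, count TSVs) or synthetic generator configs. All analysis
#' thresholds are recorded in the config and echoed into the report.
#'
#' @param inputs list of input paths: `gff3`, `flags`, `genome`, `cds`,
#'   `proteins`, `te`, plus optional expression inputs.
#' @param synthetic list with `genome` (a [genome_config()]), optional
#'   `genome_b` for a second species, `expression` / `expression_b`
#'   ([expression_config()]s), and `ortholog_frac`.
#' @param thresholds named list overriding defaults: `tpa_apt` (0.89),
#'   `composite` (1.03), `n_perm` (1000), `te_max_dist` (10000),
#'   `dup_min_len` (400), `dup_min_identity` (0.8), `ssp_max_len` (300),
#'   `min_cys` (5), `fold2` (2), `fold10` (10), `top_fraction` (0.1),
#'   `enrichment_alpha` (0.001), `q_cutoff` (0.01),
#'   `recent_scope` ("families" or "all").
#' @param seed master seed; every stochastic stage derives its own
#'   substream seed from it (see [derive_seed()]).
#' @param out_dir output directory for the report bundle.
#' @return a `PipelineConfig` list.
#' @export
pipeline_config <- function(inputs = NULL, synthetic = NULL,
                            thresholds = list(), seed = 1L,
                            out_dir = tempfile("parasitome_")) {
  defaults <- list(tpa_apt = 0.89, composite = 1.03, n_perm = 1000L,
                   te_max_dist = 10000L, dup_min_len = 400L,
                   dup_min_identity = 0.8, ssp_max_len = 300L, min_cys = 5L,
                   fold2 = 2, fold10 = 10, top_fraction = 0.1,
                   enrichment_alpha = 0.001, q_cutoff = 0.01,
                   recent_scope = "families")
  thresholds <- utils::modifyList(defaults, thresholds)
  abort_if(is.null(inputs) && is.null(synthetic),
           "either inputs or synthetic config required")
  structure(list(inputs = inputs, synthetic = synthetic,
                 thresholds = thresholds, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "PipelineConfig")
}

pipeline_log <- function(con, msg) {
  line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), msg)
  message(line)
  if (!is.null(con)) writeLines(line, con)
  invisible(NULL)
}

#' Run the full genome-architecture and infection-expression pipeline
#'
#' Executes every analysis stage on real inputs or on a freshly generated
#' synthetic dataset: RIP-affected gene calling under both indices,
#' stop-codon census of the RIP-unaffected genes and the SSP set, tandem
#' duplication scan with permutation test and optional TE proximity, recent
#' duplicate screening, SSP classification, secreted-gene cluster detection
#' and summary, and (when expression data are present) normalization,
#' regulation sets, top-decile expression, the infection cohort report and
#' the cross-species ortholog comparison. Writes TSV tables, a run log and
#' a machine-readable JSON of every summary statistic; deterministic given
#' the config (including its seed).
#'
#' @param cfg a [pipeline_config()].
#' @return invisibly, the report list (also written as `report.json`).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "PipelineConfig"))
  th <- cfg$thresholds
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_con <- file(file.path(cfg$out_dir, "run.log"), open = "wt")
  on.exit(close(log_con), add = TRUE)
  t0 <- Sys.time()
  stage <- function(name, expr) {
    pipeline_log(log_con, paste("stage:", name))
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  report <- list(schema_version = REPORT_SCHEMA_VERSION,
                 seed = cfg$seed, thresholds = th)

  # ---- inputs ---------------------------------------------------------
  truth <- NULL
  two_species <- FALSE
  if (!is.null(cfg$synthetic)) {
    syn <- cfg$synthetic
    gen <- stage("synthesize_genome", {
      gcfg <- syn$genome
      gcfg$seed <- derive_seed(cfg$seed, "genome_a")
      generate_genome(gcfg)
    })
    ann <- gen$annotation
    truth <- gen$truth
    te <- NULL
    if (!is.null(syn$genome_b)) {
      gen_b <- stage("synthesize_genome_b", {
        gcfg <- syn$genome_b
        gcfg$seed <- derive_seed(cfg$seed, "genome_b")
        generate_genome(gcfg)
      })
      ann_b <- gen_b$annotation
      two_species <- TRUE
    }
  } else {
    ann <- stage("load_annotation",
                 load_annotation(cfg$inputs$gff3, cfg$inputs$flags,
                                 genome_fasta = cfg$inputs$genome,
                                 protein_fasta = cfg$inputs$proteins,
                                 cds_fasta = cfg$inputs$cds))
    te <- if (!is.null(cfg$inputs$te))
      stage("read_te", read_te_intervals(cfg$inputs$te)) else NULL
  }
  report$n_genes <- n_genes(ann)

  # ---- RIP ------------------------------------------------------------
  rip_tpa <- stage("rip_tpa_apt", classify_rip_genes(ann, "tpa_apt"))
  rip_comp <- stage("rip_composite", classify_rip_genes(ann, "composite"))
  ssp_cls <- classify_ssp(ann$flags, th$ssp_max_len)
  ssp_ids <- names(ssp_cls$ssp)[ssp_cls$ssp]
  ssp_rip <- rip_tpa$per_gene$call[match(ssp_ids, rip_tpa$per_gene$gene_id)]
  unaffected_ids <-
    rip_tpa$per_gene$gene_id[rip_tpa$per_gene$call == "unaffected"]
  census_ssp <- if (length(ssp_ids) > 0)
    stage("stops_ssp", stop_codon_census(ann, ssp_ids)) else NULL
  census_unaffected <- if (length(unaffected_ids) > 0)
    stage("stops_unaffected", stop_codon_census(ann, unaffected_ids)) else NULL
  report$rip <- list(
    tpa_apt = list(n_affected = rip_tpa$n_affected,
                   n_total = rip_tpa$n_total,
                   affected_pct = rip_tpa$affected_pct),
    composite = list(n_affected = rip_comp$n_affected,
                     n_total = rip_comp$n_total,
                     affected_pct = rip_comp$affected_pct),
    ssp_tpa_apt = list(n_affected = sum(ssp_rip == "affected"),
                       n_total = length(ssp_ids),
                       affected_pct = pct_of(sum(ssp_rip == "affected"),
                                             length(ssp_ids), 1)),
    p_ssp_vs_all = if (length(ssp_ids) > 0)
      compare_rip_fractions(sum(ssp_rip == "affected"), length(ssp_ids),
                            rip_tpa$n_affected, rip_tpa$n_total) else NA,
    stop_codons_ssp = census_ssp,
    stop_codons_unaffected = census_unaffected)
  write.table(rip_tpa$per_gene, file.path(cfg$out_dir, "rip_tpa_apt.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  # ---- duplications ---------------------------------------------------
  tandem <- stage("tandem_scan", find_tandem_pairs(ann))
  perm <- stage("tandem_permutation",
                tandem_permutation_test(ann, n_perm = th$n_perm,
                                        seed = derive_seed(cfg$seed, "perm")))
  report$tandem <- list(n_pairs = tandem$n_pairs, n_genes = tandem$n_genes,
                        pct_genes = tandem$pct_genes,
                        n_runs = nrow(tandem$runs),
                        p_value = perm$p_value)
  if (!is.null(te)) {
    prox <- stage("te_proximity",
                  te_proximity(tandem, ann, te, th$te_max_dist))
    report$tandem$n_near_te <- prox$n_near
  }
  dup_ann <- ann
  if (th$recent_scope == "families") {
    keep <- !is.na(ann$flags$family_id)
    dup_ann <- ann
    dup_ann$genes <- ann$genes[keep, , drop = FALSE]
    dup_ann$flags <- ann$flags[keep, , drop = FALSE]
  }
  recent <- stage("recent_duplicates",
                  recent_duplicates(dup_ann, th$dup_min_len,
                                    th$dup_min_identity))
  report$recent_duplicates <- list(n_pairs = nrow(recent),
                                   scope = th$recent_scope)
  write.table(tandem$pairs, file.path(cfg$out_dir, "tandem_pairs.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  # ---- secretome clusters --------------------------------------------
  clusters <- stage("detect_clusters", detect_clusters(ann, th$ssp_max_len))
  report$ssp <- list(n_secreted = ssp_cls$n_secreted, n_ssp = ssp_cls$n_ssp,
                     n_cysteine_rich_ssp = cysteine_rich(ann$flags, ssp_ids,
                                                         th$min_cys))
  write.table(clusters, file.path(cfg$out_dir, "clusters.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  # ---- expression -----------------------------------------------------
  expr_present <- !is.null(cfg$synthetic$expression) ||
    !is.null(cfg$inputs$counts)
  upregulated <- NULL
  if (expr_present) {
    tbl <- stage("expression", {
      if (!is.null(cfg$synthetic$expression)) {
        ecfg <- cfg$synthetic$expression
        ecfg$seed <- derive_seed(cfg$seed, "expr_a")
        generate_expression(ann, ecfg)
      } else {
        read_expression_tsv(cfg$inputs$counts, cfg$inputs$conditions)
      }
    })
    ctrl_lab <- if (!is.null(cfg$synthetic$expression))
      cfg$synthetic$expression$control_label else cfg$inputs$control_label
    inf_lab <- if (!is.null(cfg$synthetic$expression))
      cfg$synthetic$expression$infection_label else cfg$inputs$infection_label
    tbl <- stage("normalize", normalize_counts(tbl))
    sets <- stage("regulation_sets", regulation_sets(tbl, ctrl_lab, inf_lab))
    sets$top_decile <- stage("top_expressed",
                             top_expressed(tbl, inf_lab, th$top_fraction))
    rep_inf <- stage("infection_report",
                     infection_report(sets, ann$flags, max_len_aa = th$ssp_max_len,
                                      min_cys = th$min_cys))
    upregulated <- sets$up10
    report$expression <- list(
      n_up2 = length(sets$up2), n_down2 = length(sets$down2),
      n_up10 = length(sets$up10), n_down10 = length(sets$down10),
      n_top_decile = length(sets$top_decile),
      infection_cohort = rep_inf)
  } else {
    report$expression <- list(skipped = TRUE)
  }
  report$clusters <- stage("cluster_summary",
                           cluster_summary(clusters, ann$flags, upregulated,
                                           th$ssp_max_len))

  # ---- two-species ortholog comparison -------------------------------
  if (two_species && !is.null(cfg$synthetic$expression_b)) {
    ecfg_b <- cfg$synthetic$expression_b
    ecfg_b$seed <- derive_seed(cfg$seed, "expr_b")
    tbl_b <- stage("expression_b",
                   normalize_counts(generate_expression(ann_b, ecfg_b)))
    map <- generate_ortholog_map(ann$genes$gene_id, ann_b$genes$gene_id,
                                 frac = if (is.null(cfg$synthetic$ortholog_frac))
                                   0.7 else cfg$synthetic$ortholog_frac,
                                 seed = derive_seed(cfg$seed, "orthologs"))
    pairs <- ortholog_pair_table(tbl, tbl_b, map,
                                 cfg$synthetic$expression$infection_label,
                                 ecfg_b$infection_label)
    oc <- stage("ortholog_compare",
                ortholog_compare(pairs, th$fold10, th$q_cutoff))
    report$orthologs <- oc$summary
  } else if (!is.null(cfg$inputs$ortholog_pairs)) {
    pairs <- read.delim(cfg$inputs$ortholog_pairs, sep = "\t", header = TRUE,
                        stringsAsFactors = FALSE)
    oc <- stage("ortholog_compare",
                ortholog_compare(pairs, th$fold10, th$q_cutoff))
    report$orthologs <- oc$summary
  }

  if (!is.null(truth))
    report$ground_truth <- list(
      n_planted_tandem_runs = length(truth$tandem_runs),
      n_planted_clusters = length(truth$clusters),
      n_rip_genes = length(truth$rip_genes))

  json_path <- file.path(cfg$out_dir, "report.json")
  jsonlite::write_json(report, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  pipeline_log(log_con, sprintf("done in %.1fs; report at %s",
                                as.numeric(difftime(Sys.time(), t0, units = "secs")),
                                json_path))
  invisible(report)
}
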
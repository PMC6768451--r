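# End-to-end orchestration: simulate -> filter -> orthologs -> variants ->
# selection -> enrichment -> differential expression, with a run report.

#' Pipeline configuration
#'
#' Bundles the per-stage parameter blocks. The simulate block is a
#' [sim_config()]; the remaining blocks override stage defaults.
#'
#' @param simulate a [sim_config()]
#' @param filter list(margin, evalue_cutoff)
#' @param orthologs list(evalue_cutoff)
#' @param variants list(min_depth, hom_fraction, het_min_fraction,
#'   het_min_reads, het_denominator)
#' @param selection list(alpha, min_orf_codons)
#' @param enrich list(alpha, n_pathways)
#' @param de list(ppde_threshold, fdr_cap)
#' @param seed run seed (overrides the simulate block's seed)
#' @param outdir optional output directory; when set, all stage outputs are
#'   written there
#' @return list of class `pipeline_config`
#' @export
pipeline_config <- function(simulate = sim_config(),
                            filter = list(),
                            orthologs = list(),
                            variants = list(),
                            selection = list(),
                            enrich = list(),
                            de = list(),
                            seed = NULL,
                            outdir = NULL) {
  defaults <- list(
    filter = list(margin = 100, evalue_cutoff = 1e-10),
    orthologs = list(evalue_cutoff = 1e-50),
    variants = list(min_depth = 10, hom_fraction = 0.9,
                    het_min_fraction = 0.2, het_min_reads = 2,
                    het_denominator = "callable"),
    selection = list(alpha = 0.05, min_orf_codons = 100),
    enrich = list(alpha = 0.05, n_pathways = 20),
    de = list(ppde_threshold = 1 - 1e-5, fdr_cap = 0.05))
  cfg <- list(simulate = simulate,
              filter = utils::modifyList(defaults$filter, filter),
              orthologs = utils::modifyList(defaults$orthologs, orthologs),
              variants = utils::modifyList(defaults$variants, variants),
              selection = utils::modifyList(defaults$selection, selection),
              enrich = utils::modifyList(defaults$enrich, enrich),
              de = utils::modifyList(defaults$de, de),
              outdir = outdir)
  if (!is.null(seed)) cfg$simulate$seed <- as.integer(seed)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Load a pipeline configuration from a YAML file
#'
#' Top-level keys mirror the [pipeline_config()] arguments; the `simulate`
#' block is passed to [sim_config()].
#'
#' @param path YAML file path
#' @return a `pipeline_config`
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  sim_args <- raw$simulate %||% list()
  if (!is.null(sim_args$omega) && is.list(sim_args$omega)) {
    sim_args$omega <- list(fractions = unlist(sim_args$omega$fractions),
                           omegas = unlist(sim_args$omega$omegas))
  }
  pipeline_config(
    simulate = do.call(sim_config, sim_args),
    filter = raw$filter %||% list(),
    orthologs = raw$orthologs %||% list(),
    variants = raw$variants %||% list(),
    selection = raw$selection %||% list(),
    enrich = raw$enrich %||% list(),
    de = raw$de %||% list(),
    seed = raw$seed,
    outdir = raw$outdir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full clone-divergence pipeline on simulated data
#'
#' Stages: transcriptome + contaminant simulation; contaminant/rRNA
#' filtering of both clone assemblies; reciprocal-best-hit orthology on the
#' cleaned sets; bi-directional genotype calling and fixed-difference
#' consolidation; heterozygosity per clone; ORF detection, alternative-CDS
#' construction and NG86 Ka/Ks classification on the reference clone;
#' pathway enrichment of the positively selected set against the genes
#' carrying coding SNPs; and empirical-Bayes differential expression.
#'
#' @param config a [pipeline_config()]
#' @return list of class `clonescan_run`: `report` (stage count summary),
#'   `truth`, and per-stage results (`filter`, `orthologs`, `variants`,
#'   `kaks`, `enrichment`, `de`)
#' @export
run_all <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- proc.time()[["elapsed"]]
  simcfg <- config$simulate

  sim <- simulate_transcriptomes(simcfg)
  sim <- inject_contaminants(sim, simcfg)
  pileups <- simulate_pileups(sim, simcfg)
  cnt <- simulate_counts(simcfg, gene_ids = sim$truth$genes$gene)

  # --- filter ---------------------------------------------------------
  have_contams <- length(sim$truth$contaminants) + length(sim$truth$rrna) > 0
  if (have_contams) {
    fA <- filter_contigs(sim$cloneA, sim$ancestral, sim$contaminant_db,
                         sim$rrna_db, margin = config$filter$margin,
                         evalue_cutoff = config$filter$evalue_cutoff)
    fB <- filter_contigs(sim$cloneB, sim$ancestral, sim$contaminant_db,
                         sim$rrna_db, margin = config$filter$margin,
                         evalue_cutoff = config$filter$evalue_cutoff)
    cleanA <- fA$kept
    cleanB <- fB$kept
  } else {
    fA <- fB <- NULL
    cleanA <- sim$cloneA
    cleanB <- sim$cloneB
  }

  # --- orthologs ------------------------------------------------------
  rbh <- reciprocal_best_hits(cleanA, cleanB,
                              evalue_cutoff = config$orthologs$evalue_cutoff)

  # --- variants -------------------------------------------------------
  vp <- config$variants
  cg <- function(p) call_genotypes(p, min_depth = vp$min_depth,
                                   hom_fraction = vp$hom_fraction,
                                   het_min_fraction = vp$het_min_fraction,
                                   het_min_reads = vp$het_min_reads)
  calls_B_on_A <- cg(pileups$B_on_A)
  calls_A_on_B <- cg(pileups$A_on_B)
  fixed_B_on_A <- fixed_differences(calls_B_on_A)
  fixed_A_on_B <- fixed_differences(calls_A_on_B)
  consolidated <- consolidate_bidirectional(fixed_B_on_A, fixed_A_on_B, rbh)
  hetA <- heterozygosity(cg(pileups$A_on_A), clone = "A",
                         denominator = vp$het_denominator)
  hetB <- heterozygosity(cg(pileups$B_on_B), clone = "B",
                         denominator = vp$het_denominator)

  # --- selection ------------------------------------------------------
  sel <- config$selection
  kaks_rows <- list()
  coding_snps <- 0L
  genes_with_coding_snps <- character(0)
  for (i in seq_len(nrow(rbh$pairs))) {
    ga <- rbh$pairs$geneA[i]
    transcript <- cleanA[[ga]]
    orf <- find_orfs(transcript, min_len_codons = sel$min_orf_codons)
    if (nrow(orf) == 0) next
    vr <- consolidated[consolidated$geneA == ga, , drop = FALSE]
    cds_pos <- vr$posA - orf$start + 1L
    in_cds <- cds_pos >= 1L & cds_pos <= (orf$end - orf$start + 1L)
    if (!any(in_cds)) next
    # trim the terminal stop codon out of the Ka/Ks computation
    cds_full <- substring(transcript, orf$start, orf$end)
    ncod <- nchar(cds_full) %/% 3L
    last <- substring(cds_full, 3L * ncod - 2L, 3L * ncod)
    core_len <- if (last %in% .STOP_CODONS) 3L * (ncod - 1L) else
      3L * ncod
    cds_ref <- substring(cds_full, 1L, core_len)
    use <- in_cds & cds_pos <= core_len
    if (!any(use)) next
    genes_with_coding_snps <- c(genes_with_coding_snps, ga)
    coding_snps <- coding_snps + sum(use)
    cds_alt <- apply_fixed_variants(cds_ref, cds_pos[use],
                                    vr$alleleA[use], vr$alleleB[use])
    kaks_rows[[ga]] <- kaks_estimate(cds_ref, cds_alt, alpha = sel$alpha,
                                     gene = ga)
  }
  kaks <- do.call(rbind, kaks_rows)
  if (is.null(kaks)) kaks <- .kaks_row(character(0), numeric(0), numeric(0),
                                       numeric(0), numeric(0), numeric(0),
                                       numeric(0), numeric(0), numeric(0),
                                       numeric(0), numeric(0), character(0),
                                       character(0))
  rownames(kaks) <- NULL
  cls <- classify_selection(kaks)

  # --- enrichment -----------------------------------------------------
  background <- genes_with_coding_snps
  annotations <- simulate_pathways(sim$truth$genes$gene,
                                   n_pathways = config$enrich$n_pathways,
                                   seed = simcfg$seed)
  annotations_bg <- lapply(annotations, intersect, background)
  annotations_bg <- annotations_bg[vapply(annotations_bg, length,
                                          integer(1)) > 0]
  positive_genes <- kaks$gene[kaks$class == "positive"]
  purifying_genes <- kaks$gene[kaks$class == "purifying"]
  enr_pos <- if (length(background)) {
    pathway_enrichment(positive_genes, background, annotations_bg,
                       alpha = config$enrich$alpha)
  } else NULL
  enr_neg <- if (length(background)) {
    pathway_enrichment(purifying_genes, background, annotations_bg,
                       alpha = config$enrich$alpha)
  } else NULL

  # --- differential expression ---------------------------------------
  de_res <- fit_ppde(cnt$counts, cnt$conditions,
                     ppde_threshold = config$de$ppde_threshold)
  de_sel <- select_de(de_res, ppde_threshold = config$de$ppde_threshold,
                      fdr_cap = config$de$fdr_cap)
  sel_tab <- de_res$table[de_res$table$gene %in% de_sel$selected, ,
                          drop = FALSE]
  de_up <- sum(sel_tab$postFC > 1)
  de_down <- sum(sel_tab$postFC < 1)

  elapsed <- proc.time()[["elapsed"]] - t0
  # pathway averaging conserves the per-codon difference count, so these
  # fractional totals sum exactly to the integer coding SNP count
  syn_total <- sum(kaks$Ns)
  nonsyn_total <- sum(kaks$Nn)
  report <- list(
    seed = simcfg$seed,
    n_genes = simcfg$n_genes,
    contigs_in = length(sim$cloneA),
    contigs_kept = length(cleanA),
    contigs_removed = length(sim$cloneA) - length(cleanA),
    fixed_snps_B_on_A = nrow(fixed_B_on_A),
    fixed_snps_A_on_B = nrow(fixed_A_on_B),
    fixed_snps_consolidated = nrow(consolidated),
    rbh_pairs = nrow(rbh$pairs),
    genes_with_coding_snps = length(genes_with_coding_snps),
    coding_fixed_snps = coding_snps,
    synonymous = syn_total,
    nonsynonymous = nonsyn_total,
    positive = cls$positive,
    purifying = cls$purifying,
    unclassified = cls$unclassified,
    enriched_pathways_positive =
      if (!is.null(enr_pos)) sum(enr_pos$enriched) else 0L,
    enriched_pathways_purifying =
      if (!is.null(enr_neg)) sum(enr_neg$enriched) else 0L,
    heterozygosity_A = hetA$H,
    heterozygosity_B = hetB$H,
    de_selected = length(de_sel$selected),
    de_up = de_up,
    de_down = de_down,
    de_bayes_fdr = de_sel$bayes_fdr,
    wall_clock_sec = elapsed)

  run <- structure(list(
    report = report, config = config, truth = sim$truth,
    sequences = list(ancestral = sim$ancestral, cloneA = sim$cloneA,
                     cloneB = sim$cloneB, cleanA = cleanA, cleanB = cleanB),
    filter = list(A = fA, B = fB),
    orthologs = rbh,
    variants = list(B_on_A = fixed_B_on_A, A_on_B = fixed_A_on_B,
                    consolidated = consolidated,
                    heterozygosity = list(A = hetA, B = hetB)),
    kaks = kaks,
    enrichment = list(positive = enr_pos, purifying = enr_neg),
    counts = cnt,
    de = de_res), class = "clonescan_run")

  if (!is.null(config$outdir)) write_run(run, config$outdir)
  run
}

#' Write all pipeline outputs to a directory
#'
#' Deterministic for a fixed config + seed: the wall-clock entry is omitted
#' from report.json (it is kept in the in-memory report and written to
#' run_log.txt instead).
#'
#' @param run a `clonescan_run`
#' @param outdir output directory (created if needed)
#' @export
write_run <- function(run, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(...) file.path(outdir, ...)
  write_fasta(run$sequences$cloneA, fp("cloneA.fasta"))
  write_fasta(run$sequences$cloneB, fp("cloneB.fasta"))
  utils::write.table(run$orthologs$pairs, fp("orthologs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(run$variants$consolidated, fp("fixed_variants.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_variants_vcf(run$variants$consolidated, fp("fixed_variants.vcf"))
  utils::write.table(run$kaks, fp("kaks.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  het <- run$variants$heterozygosity
  utils::write.table(
    data.frame(clone = c("A", "B"),
               het_sites = c(het$A$het_sites, het$B$het_sites),
               total_sites = c(het$A$total_sites, het$B$total_sites),
               H = c(het$A$H, het$B$H)),
    fp("heterozygosity.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(run$enrichment$positive)) {
    utils::write.table(run$enrichment$positive, fp("enrichment_positive.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_counts(run$counts$counts, fp("counts.tsv"))
  utils::write.table(run$de$table, fp("de_results.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  rep_out <- run$report
  rep_out$wall_clock_sec <- NULL
  jsonlite::write_json(rep_out, fp("report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  # no timing here: outputs must be byte-identical across reruns
  writeLines(c(sprintf("seed: %d", run$report$seed),
               sprintf("contigs_kept: %d", run$report$contigs_kept),
               sprintf("rbh_pairs: %d", run$report$rbh_pairs)),
             fp("run_log.txt"))
  invisible(run)
}

#' @export
print.clonescan_run <- function(x, ...) {
  r <- x$report
  cat("clonescan run (seed ", r$seed, ")\n", sep = "")
  cat(sprintf("  contigs: %d in, %d kept, %d removed\n",
              r$contigs_in, r$contigs_kept, r$contigs_removed))
  cat(sprintf("  RBH pairs: %d; fixed SNPs: %d (B_on_A %d / A_on_B %d)\n",
              r$rbh_pairs, r$fixed_snps_consolidated, r$fixed_snps_B_on_A,
              r$fixed_snps_A_on_B))
  cat(sprintf("  coding SNPs: %d = %d synonymous + %d nonsynonymous\n",
              r$coding_fixed_snps, r$synonymous, r$nonsynonymous))
  cat(sprintf("  selection: %d positive, %d purifying, %d unclassified\n",
              r$positive, r$purifying, r$unclassified))
  cat(sprintf("  heterozygosity: A %.4g, B %.4g\n",
              r$heterozygosity_A, r$heterozygosity_B))
  cat(sprintf("  DE: %d selected (%d up, %d down), Bayesian FDR %.3g\n",
              r$de_selected, r$de_up, r$de_down,
              if (is.na(r$de_bayes_fdr)) NA else r$de_bayes_fdr))
  invisible(x)
}
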
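# Synthetic clone-pair transcriptome generator.
#
# Emulates two clonal lineages diverged from a common ancestor: per-gene
# omega (dN/dS) controls the ratio of planted nonsynonymous to synonymous
# fixed differences; within-clone heterozygous sites, algal-like contaminant
# and rRNA-like contigs, Poisson-depth pileups and negative-binomial count
# matrices complete the inputs the downstream stages consume.

#' Simulation configuration for a synthetic clone pair
#'
#' Defaults describe a desk-scale version of a two-clone, two-temperature
#' transcriptome study: AT-rich transcripts (~30% GC), a mostly-purifying
#' omega mixture, low synonymous divergence, clone-specific heterozygosity
#' (defaults taken from the two printed clone estimates, 0.026% and 0.138%),
#' 30x coverage and a small contaminant load.
#'
#' @param n_genes number of genes (default 200)
#' @param cds_len_codons length-2 integer range of CDS lengths in codons,
#'   including start and stop (default c(120, 400))
#' @param utr_len length-2 range for each UTR (default c(30, 150))
#' @param omega per-gene omega vector (recycled), or a mixture list
#'   `list(fractions = c(...), omegas = c(...))`; default 80% omega 0.2,
#'   15% omega 1, 5% omega 5
#' @param ks_target expected synonymous substitutions per synonymous site
#'   between the clones (default 0.05), split equally between the branches
#' @param het_rate per-site heterozygosity per clone; scalar or length-2
#'   (cloneA, cloneB); default c(0.00026, 0.00138)
#' @param coverage mean pileup depth (default 30)
#' @param error_rate per-base sequencing error probability (default 0.005)
#' @param n_contaminants,n_rrna numbers of contaminant / rRNA-like contigs
#'   injected into each clone's assembly (defaults 20 and 5)
#' @param gc_genes,gc_contaminants GC content of genes (default 0.30,
#'   mirroring the ~29.6% assembly GC) and of contaminants (default 0.55)
#' @param n_replicates_per_condition samples per condition (default 2)
#' @param de_fraction fraction of genes differentially expressed (default 0.1)
#' @param fold_change multiplicative DE effect (default 4)
#' @param nb_dispersion NB dispersion phi (variance = mu + phi mu^2;
#'   default 0.1)
#' @param indel_rate per-site probability of a spurious indel signal in the
#'   pileups (default 0; exists to test indel exclusion)
#' @param multi_hit allow more than one planted fixed difference per codon
#'   (default FALSE, keeping truth class labels unambiguous)
#' @param seed integer seed; every stage derives its own sub-stream
#' @return validated list of class `sim_config`
#' @export
sim_config <- function(n_genes = 200,
                       cds_len_codons = c(120, 400),
                       utr_len = c(30, 150),
                       omega = list(fractions = c(0.80, 0.15, 0.05),
                                    omegas = c(0.2, 1, 5)),
                       ks_target = 0.05,
                       het_rate = c(0.00026, 0.00138),
                       coverage = 30,
                       error_rate = 0.005,
                       n_contaminants = 20,
                       n_rrna = 5,
                       gc_genes = 0.30,
                       gc_contaminants = 0.55,
                       n_replicates_per_condition = 2,
                       de_fraction = 0.1,
                       fold_change = 4,
                       nb_dispersion = 0.1,
                       indel_rate = 0,
                       multi_hit = FALSE,
                       seed = 1L) {
  stopifnot(n_genes >= 1, length(cds_len_codons) == 2,
            cds_len_codons[1] >= 10, diff(cds_len_codons) >= 0,
            length(utr_len) == 2, all(utr_len >= 0),
            ks_target > 0, all(het_rate >= 0), all(het_rate <= 1),
            coverage > 0, error_rate >= 0, error_rate <= 1,
            n_contaminants >= 0, n_rrna >= 0,
            gc_genes > 0, gc_genes < 1, gc_contaminants > 0,
            gc_contaminants < 1,
            n_replicates_per_condition >= 2,
            de_fraction >= 0, de_fraction <= 1, fold_change > 0,
            nb_dispersion >= 0, indel_rate >= 0, indel_rate <= 1)
  if (is.list(omega)) {
    stopifnot(length(omega$fractions) == length(omega$omegas),
              abs(sum(omega$fractions) - 1) < 1e-8, all(omega$omegas >= 0))
  } else {
    stopifnot(all(omega >= 0))
  }
  if (length(het_rate) == 1) het_rate <- rep(het_rate, 2)
  cfg <- list(n_genes = as.integer(n_genes),
              cds_len_codons = as.integer(cds_len_codons),
              utr_len = as.integer(utr_len), omega = omega,
              ks_target = ks_target, het_rate = het_rate,
              coverage = coverage, error_rate = error_rate,
              n_contaminants = as.integer(n_contaminants),
              n_rrna = as.integer(n_rrna), gc_genes = gc_genes,
              gc_contaminants = gc_contaminants,
              n_replicates_per_condition =
                as.integer(n_replicates_per_condition),
              de_fraction = de_fraction, fold_change = fold_change,
              nb_dispersion = nb_dispersion, indel_rate = indel_rate,
              multi_hit = isTRUE(multi_hit), seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

# Deterministic per-stage sub-stream: mixes the run seed with a stage name.
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.double(seed %% 2147483647L) * 2971L + h * 7919L) %%
               2147483629)
}

.rand_bases <- function(n, gc) {
  sample(c("A", "C", "G", "T"), n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

# Stop-free random CDS: ATG + internal codons + stop codon.
.rand_cds <- function(n_codons, gc) {
  internal <- n_codons - 2L
  b <- matrix(.rand_bases(3L * internal, gc), nrow = 3L)
  codons <- paste0(b[1, ], b[2, ], b[3, ])
  repeat {
    bad <- which(codons %in% .STOP_CODONS)
    if (length(bad) == 0) break
    rb <- matrix(.rand_bases(3L * length(bad), gc), nrow = 3L)
    codons[bad] <- paste0(rb[1, ], rb[2, ], rb[3, ])
  }
  paste0("ATG", paste(codons, collapse = ""),
         sample(.STOP_CODONS, 1))
}

.draw_omegas <- function(omega, n_genes) {
  if (is.list(omega)) {
    sample(omega$omegas, n_genes, replace = TRUE, prob = omega$fractions)
  } else {
    rep_len(omega, n_genes)
  }
}

# Plant one substitution of the required class ("syn"/"nonsyn") in a CDS.
# `used` marks codon indices already carrying a planted change. Codons are
# drawn from 2..(L-1) (start and stop codons excluded); mutants that create a
# stop codon are rejected so the CDS stays a valid ORF. Returns NULL on
# failure after `max_tries`.
.plant_change <- function(codons, used, class, multi_hit,
                          max_tries = 400L) {
  L <- length(codons)
  eligible <- 2:(L - 1L)
  for (try in seq_len(max_tries)) {
    ci <- sample(eligible, 1L)
    if (!multi_hit && used[ci]) next
    cod <- strsplit(codons[ci], "")[[1]]
    p <- sample(1:3, 1L)
    b <- sample(setdiff(.BASES, cod[p]), 1L)
    mut <- cod
    mut[p] <- b
    mutc <- paste(mut, collapse = "")
    if (mutc %in% .STOP_CODONS) next
    syn <- is_synonymous_change(codons[ci], mutc)
    if ((class == "syn") != syn) next
    return(list(codon_index = ci, pos_in_codon = p,
                from = cod[p], to = b))
  }
  NULL
}

#' Simulate a diverged clone pair of transcriptomes
#'
#' Each gene is an ancestral transcript (5' UTR + stop-free CDS + 3' UTR);
#' the two clones descend from it with Poisson numbers of planted synonymous
#' and nonsynonymous fixed differences (expectations `ks_target * S` and
#' `omega * ks_target * N` per gene, split equally between the branches,
#' where S and N are the gene's NG86 site counts) and with per-clone
#' heterozygous sites at `het_rate`. Fixed differences are single-nucleotide
#' substitutions placed by rejection sampling; by default at most one per
#' codon so every planted event has an unambiguous class.
#'
#' @param config a [sim_config()]
#' @return list with `ancestral`, `cloneA`, `cloneB` (named character
#'   vectors of transcripts) and `truth` (class `sim_truth`): `genes`
#'   data.frame (gene, utr5, cds_start, cds_end, cds_codons, omega, S, N),
#'   `fixed` data.frame (gene, pos [1-based transcript], cds_pos, branch,
#'   class, anc, alt), `het` data.frame (gene, pos, clone, ref, alt)
#' @export
simulate_transcriptomes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stage_seed(config$seed, "transcriptomes"))
  n <- config$n_genes
  ids <- sprintf("gene_%04d", seq_len(n))
  omega <- .draw_omegas(config$omega, n)

  genes <- vector("list", n)
  fixed <- vector("list", n)
  anc <- character(n)
  seqA <- character(n)
  seqB <- character(n)

  for (g in seq_len(n)) {
    placed <- NULL
    for (attempt in 1:5) {
      ncod <- sample(config$cds_len_codons[1]:config$cds_len_codons[2], 1L)
      utr5 <- sample(config$utr_len[1]:config$utr_len[2], 1L)
      utr3 <- sample(config$utr_len[1]:config$utr_len[2], 1L)
      cds <- .rand_cds(ncod, config$gc_genes)
      sc <- ng86_site_counts(cds)
      n_syn <- stats::rpois(2, config$ks_target * sc$S / 2)
      n_non <- stats::rpois(2, omega[g] * config$ks_target * sc$N / 2)
      codons <- .split_codons(cds)
      used <- logical(ncod)
      events <- list()
      ok <- TRUE
      for (branch in 1:2) {
        classes <- c(rep("syn", n_syn[branch]), rep("nonsyn", n_non[branch]))
        for (cl in classes) {
          ev <- .plant_change(codons, used, cl, config$multi_hit)
          if (is.null(ev)) { ok <- FALSE; break }
          used[ev$codon_index] <- TRUE
          ev$branch <- c("A", "B")[branch]
          ev$class <- cl
          events[[length(events) + 1L]] <- ev
        }
        if (!ok) break
      }
      if (ok) {
        placed <- list(cds = cds, utr5 = utr5, utr3 = utr3, ncod = ncod,
                       S = sc$S, N = sc$N, events = events)
        break
      }
    }
    if (is.null(placed)) {
      stop("gene ", ids[g], ": could not place planted differences after ",
           "5 resampled genes (gene too short or omega incompatible)")
    }
    transcript <- paste0(
      paste(.rand_bases(placed$utr5, config$gc_genes), collapse = ""),
      placed$cds,
      paste(.rand_bases(placed$utr3, config$gc_genes), collapse = ""))
    chA <- strsplit(transcript, "")[[1]]
    chB <- chA
    evrows <- NULL
    if (length(placed$events) > 0) {
      evrows <- do.call(rbind, lapply(placed$events, function(ev) {
        pos <- placed$utr5 + (ev$codon_index - 1L) * 3L + ev$pos_in_codon
        data.frame(gene = ids[g], pos = pos,
                   cds_pos = (ev$codon_index - 1L) * 3L + ev$pos_in_codon,
                   branch = ev$branch, class = ev$class,
                   anc = ev$from, alt = ev$to, stringsAsFactors = FALSE)
      }))
      for (r in seq_len(nrow(evrows))) {
        if (evrows$branch[r] == "A") chA[evrows$pos[r]] <- evrows$alt[r]
        else chB[evrows$pos[r]] <- evrows$alt[r]
      }
    }
    anc[g] <- transcript
    seqA[g] <- paste(chA, collapse = "")
    seqB[g] <- paste(chB, collapse = "")
    genes[[g]] <- data.frame(
      gene = ids[g], utr5 = placed$utr5,
      cds_start = placed$utr5 + 1L,
      cds_end = placed$utr5 + 3L * placed$ncod,
      cds_codons = placed$ncod, omega = omega[g],
      S = placed$S, N = placed$N, stringsAsFactors = FALSE)
    fixed[[g]] <- evrows
  }

  names(anc) <- names(seqA) <- names(seqB) <- ids
  genes <- do.call(rbind, genes)
  fixed <- do.call(rbind, fixed)
  if (is.null(fixed)) {
    fixed <- data.frame(gene = character(0), pos = integer(0),
                        cds_pos = integer(0), branch = character(0),
                        class = character(0), anc = character(0),
                        alt = character(0), stringsAsFactors = FALSE)
  }

  # heterozygous sites: per clone, Bernoulli(het_rate) over the transcript,
  # never at a planted fixed-difference position (either branch)
  set.seed(stage_seed(config$seed, "heterozygosity"))
  het <- list()
  lens <- nchar(seqA)
  for (clone in c("A", "B")) {
    rate <- config$het_rate[if (clone == "A") 1 else 2]
    seqs <- if (clone == "A") seqA else seqB
    for (g in seq_len(n)) {
      nh <- stats::rbinom(1, lens[g], rate)
      if (nh == 0) next
      forbidden <- fixed$pos[fixed$gene == ids[g]]
      avail <- setdiff(seq_len(lens[g]), forbidden)
      pos <- sort(sample(avail, min(nh, length(avail))))
      refb <- substring(seqs[g], pos, pos)
      altb <- vapply(refb, function(b) sample(setdiff(.BASES, b), 1),
                     character(1))
      het[[length(het) + 1L]] <- data.frame(
        gene = ids[g], pos = pos, clone = clone, ref = refb, alt = altb,
        stringsAsFactors = FALSE)
    }
  }
  het <- if (length(het)) do.call(rbind, het) else
    data.frame(gene = character(0), pos = integer(0), clone = character(0),
               ref = character(0), alt = character(0),
               stringsAsFactors = FALSE)
  rownames(het) <- NULL

  truth <- structure(list(genes = genes, fixed = fixed, het = het,
                          contaminants = character(0), rrna = character(0)),
                     class = "sim_truth")
  list(ancestral = anc, cloneA = seqA, cloneB = seqB, truth = truth)
}

#' Inject contaminant and rRNA-like contigs into the clone assemblies
#'
#' Contaminants are GC-rich (default 55% vs ~30% for genes) random contigs;
#' the injected copies carry ~2% substitutions relative to the database
#' entries, emulating imperfect database matches. rRNA-like contigs behave
#' the same against a small rRNA database. With zero counts the input is
#' returned untouched.
#'
#' @param sim output of [simulate_transcriptomes()]
#' @param config the same [sim_config()]
#' @return `sim` with `cloneA`/`cloneB` extended by the injected contigs,
#'   `contaminant_db` and `rrna_db` added, and truth updated with the
#'   injected contig ids
#' @export
inject_contaminants <- function(sim, config) {
  if (config$n_contaminants == 0 && config$n_rrna == 0) return(sim)
  set.seed(stage_seed(config$seed, "contaminants"))
  make_set <- function(n, prefix, gc, len_range) {
    if (n == 0) return(list(db = character(0), contigs = character(0)))
    lens <- sample(len_range[1]:len_range[2], n, replace = TRUE)
    db <- vapply(lens, function(L)
      paste(.rand_bases(L, gc), collapse = ""), character(1))
    names(db) <- sprintf("%s_%03d", prefix, seq_len(n))
    contigs <- vapply(db, .mutate_seq, character(1), rate = 0.02)
    names(contigs) <- names(db)
    list(db = db, contigs = contigs)
  }
  contam <- make_set(config$n_contaminants, "contam",
                     config$gc_contaminants, c(300L, 1200L))
  rrna <- make_set(config$n_rrna, "rrna", 0.50, c(600L, 1500L))
  sim$cloneA <- c(sim$cloneA, contam$contigs, rrna$contigs)
  sim$cloneB <- c(sim$cloneB, contam$contigs, rrna$contigs)
  sim$contaminant_db <- contam$db
  sim$rrna_db <- rrna$db
  sim$truth$contaminants <- names(contam$db)
  sim$truth$rrna <- names(rrna$db)
  sim
}

.mutate_seq <- function(seq, rate) {
  ch <- strsplit(seq, "")[[1]]
  nmut <- stats::rbinom(1, length(ch), rate)
  if (nmut > 0) {
    pos <- sample(length(ch), nmut)
    ch[pos] <- vapply(ch[pos], function(b) sample(setdiff(.BASES, b), 1),
                      character(1))
  }
  paste(ch, collapse = "")
}

#' Simulate per-site read pileups for the four clone/reference combinations
#'
#' Depth is Poisson(`coverage`) per site. The reads carry the read-clone's
#' alleles: at its heterozygous sites the alternate allele is drawn
#' Binomial(depth, 0.5); every read independently mismatches to a uniform
#' other base with probability `error_rate`. Directional tables pile the
#' OTHER clone's reads on this clone's transcript; self tables pile a
#' clone's own reads on its own transcript (the heterozygosity input).
#'
#' @param sim output of [simulate_transcriptomes()] (contaminants not
#'   required; only genes are piled up)
#' @param config the [sim_config()]
#' @return list of four pileup data.frames `B_on_A`, `A_on_B`, `A_on_A`,
#'   `B_on_B`, each with columns gene, pos (1-based), ref, A, C, G, T, ins,
#'   del
#' @export
simulate_pileups <- function(sim, config) {
  set.seed(stage_seed(config$seed, "pileups"))
  ids <- sim$truth$genes$gene
  het <- sim$truth$het
  out <- list(
    B_on_A = .pileup_one(sim$cloneA[ids], sim$cloneB[ids],
                         het[het$clone == "B", ], config),
    A_on_B = .pileup_one(sim$cloneB[ids], sim$cloneA[ids],
                         het[het$clone == "A", ], config),
    A_on_A = .pileup_one(sim$cloneA[ids], sim$cloneA[ids],
                         het[het$clone == "A", ], config),
    B_on_B = .pileup_one(sim$cloneB[ids], sim$cloneB[ids],
                         het[het$clone == "B", ], config))
  out
}

# reference: named transcripts providing ref bases & coordinates
# reads_from: the clone whose reads are piled (equal lengths assumed)
# het: het table of the read clone (positions shared across clones)
.pileup_one <- function(reference, reads_from, het, config) {
  rows <- vector("list", length(reference))
  base_idx <- stats::setNames(1:4, .BASES)
  for (g in seq_along(reference)) {
    gid <- names(reference)[g]
    refb <- strsplit(reference[[g]], "")[[1]]
    trueb <- strsplit(reads_from[[g]], "")[[1]]
    L <- length(refb)
    depth <- stats::rpois(L, config$coverage)
    counts <- matrix(0L, nrow = L, ncol = 4,
                     dimnames = list(NULL, .BASES))
    hh <- het[het$gene == gid, , drop = FALSE]
    is_het <- logical(L)
    if (nrow(hh)) is_het[hh$pos] <- TRUE

    # non-het sites: depth reads of the true base, errors scattered
    idx <- which(!is_het & depth > 0)
    nerr <- stats::rbinom(length(idx), depth[idx], config$error_rate)
    counts[cbind(idx, base_idx[trueb[idx]])] <- depth[idx] - nerr
    if (any(nerr > 0)) {
      # one row per error read; error base uniform over the 3 non-true bases
      sites <- rep(idx, nerr)
      true_of_err <- trueb[sites]
      pick <- sample.int(3L, length(sites), replace = TRUE)
      # others_mat[b, r]: r-th base different from b
      others_mat <- t(vapply(.BASES, function(b) setdiff(.BASES, b),
                             character(3)))
      err_base <- others_mat[cbind(base_idx[true_of_err], pick)]
      for (b in .BASES) {
        sel <- sites[err_base == b]
        if (length(sel)) {
          counts[, b] <- counts[, b] + tabulate(sel, nbins = L)
        }
      }
    }
    # het sites: two alleles at 50/50, then errors per read
    if (nrow(hh)) {
      for (r in seq_len(nrow(hh))) {
        i <- hh$pos[r]
        d <- depth[i]
        if (d == 0) next
        nalt <- stats::rbinom(1, d, 0.5)
        alleles <- c(rep(hh$ref[r], d - nalt), rep(hh$alt[r], nalt))
        err <- stats::runif(d) < config$error_rate
        if (any(err)) {
          alleles[err] <- vapply(alleles[err], function(b)
            sample(setdiff(.BASES, b), 1), character(1))
        }
        tab <- table(factor(alleles, levels = .BASES))
        counts[i, ] <- as.integer(tab)
      }
    }
    ins <- integer(L)
    del <- integer(L)
    if (config$indel_rate > 0) {
      ind <- which(stats::runif(L) < config$indel_rate & depth > 0)
      for (i in ind) {
        k <- max(1L, stats::rbinom(1, depth[i], 0.5))
        if (stats::runif(1) < 0.5) ins[i] <- k else del[i] <- k
      }
    }
    rows[[g]] <- data.frame(gene = gid, pos = seq_len(L), ref = refb,
                            A = counts[, "A"], C = counts[, "C"],
                            G = counts[, "G"], T = counts[, "T"],
                            ins = ins, del = del, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate a negative-binomial count matrix with planted DE genes
#'
#' Gene base means are log-normal; samples get mild size factors; a
#' `de_fraction` of genes changes by `fold_change` (direction randomised) in
#' condition 2. Counts are NB with dispersion `nb_dispersion`
#' (variance = mu + phi mu^2).
#'
#' @param config a [sim_config()]
#' @param gene_ids optional gene ids (defaults to the simulator's ids)
#' @return list: `counts` (genes x samples integer matrix), `conditions`
#'   (factor per sample), `size_factors_true`, and `truth` data.frame
#'   (gene, de, fold)
#' @export
simulate_counts <- function(config, gene_ids = NULL) {
  set.seed(stage_seed(config$seed, "counts"))
  n <- config$n_genes
  if (is.null(gene_ids)) gene_ids <- sprintf("gene_%04d", seq_len(n))
  nrep <- config$n_replicates_per_condition
  samples <- c(sprintf("cond1_rep%d", seq_len(nrep)),
               sprintf("cond2_rep%d", seq_len(nrep)))
  conditions <- factor(rep(c("cond1", "cond2"), each = nrep))
  mu <- stats::rlnorm(n, meanlog = log(200), sdlog = 1.2)
  sf <- stats::rlnorm(2 * nrep, meanlog = 0, sdlog = 0.1)
  sf <- sf / exp(mean(log(sf)))
  de <- stats::runif(n) < config$de_fraction
  if (config$fold_change == 1) de[] <- FALSE
  dir_up <- stats::runif(n) < 0.5
  fold <- ifelse(de, ifelse(dir_up, config$fold_change,
                            1 / config$fold_change), 1)
  size <- if (config$nb_dispersion > 0) 1 / config$nb_dispersion else Inf
  counts <- matrix(0L, nrow = n, ncol = 2 * nrep,
                   dimnames = list(gene_ids, samples))
  for (j in seq_len(2 * nrep)) {
    m <- mu * sf[j] * (if (conditions[j] == "cond2") fold else rep(1, n))
    counts[, j] <- if (is.finite(size)) {
      stats::rnbinom(n, mu = m, size = size)
    } else {
      stats::rpois(n, m)
    }
  }
  list(counts = counts, conditions = conditions, size_factors_true = sf,
       truth = data.frame(gene = gene_ids, de = de, fold = fold,
                          stringsAsFactors = FALSE))
}

#' Simulate a pathway annotation (GMT-style) over the simulated genes
#'
#' Random gene sets used to exercise the enrichment stage; pathway
#' membership is independent of everything else in the simulation, so under
#' the null no pathway is truly enriched.
#'
#' @param gene_ids character vector of gene ids
#' @param n_pathways number of pathways (default 20)
#' @param size_range length-2 range of pathway sizes (default c(10, 40))
#' @param seed integer seed
#' @return named list of gene-id character vectors
#' @export
simulate_pathways <- function(gene_ids, n_pathways = 20,
                              size_range = c(10, 40), seed = 1L) {
  set.seed(stage_seed(seed, "pathways"))
  size_range[2] <- min(size_range[2], length(gene_ids))
  out <- lapply(seq_len(n_pathways), function(i) {
    sz <- sample(size_range[1]:size_range[2], 1)
    sort(sample(gene_ids, sz))
  })
  names(out) <- sprintf("pathway_%03d", seq_len(n_pathways))
  out
}
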
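test_that("simulated clone pairs respect the planted-divergence contract", {
  sx <- shared_sim()
  sim <- sx$sim
  truth <- sim$truth
  ids <- truth$genes$gene

  # conservation: truth fixed differences are exactly the A/B mismatches
  n_diff <- sum(mapply(function(a, b) {
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  }, sim$cloneA[ids], sim$cloneB[ids]))
  expect_equal(n_diff, nrow(truth$fixed))

  # planted positions lie inside the CDS
  gi <- match(truth$fixed$gene, truth$genes$gene)
  expect_true(all(truth$fixed$pos >= truth$genes$cds_start[gi]))
  expect_true(all(truth$fixed$pos <= truth$genes$cds_end[gi]))

  # no position is both a fixed difference and a het site
  fx_key <- paste(truth$fixed$gene, truth$fixed$pos)
  het_key <- paste(truth$het$gene, truth$het$pos)
  expect_length(intersect(fx_key, het_key), 0)

  # NG86 consistency: planted classes agree with the genetic-code tables
  # (one change per codon, so the ancestral-vs-derived codon is decisive)
  anc <- sim$ancestral
  for (r in seq_len(nrow(truth$fixed))) {
    f <- truth$fixed[r, ]
    cod_start <- truth$genes$cds_start[match(f$gene, ids)] +
      3L * ((f$cds_pos - 1L) %/% 3L)
    cod_anc <- substring(anc[[f$gene]], cod_start, cod_start + 2L)
    derived <- sub(paste0("^(.{", (f$cds_pos - 1L) %% 3L, "})."),
                   paste0("\\1", f$alt), cod_anc)
    expect_equal(is_synonymous_change(cod_anc, derived), f$class == "syn")
  }
})

test_that("simulation is deterministic and omega = 0 forbids nonsynonymous", {
  cfg <- sim_config(n_genes = 8, omega = 0, seed = 77)
  a <- simulate_transcriptomes(cfg)
  b <- simulate_transcriptomes(cfg)
  expect_identical(a, b)
  expect_true(all(a$truth$fixed$class == "syn"))

  cnt1 <- simulate_counts(cfg)
  cnt2 <- simulate_counts(cfg)
  expect_identical(cnt1$counts, cnt2$counts)
})

test_that("planted synonymous counts follow the Poisson expectation", {
  cfg <- sim_config(n_genes = 200, ks_target = 0.05, n_contaminants = 0,
                    n_rrna = 0, seed = 31)
  sim <- simulate_transcriptomes(cfg)
  truth <- sim$truth
  syn_per_gene <- tabulate(
    factor(truth$fixed$gene[truth$fixed$class == "syn"],
           levels = truth$genes$gene), nbins = nrow(truth$genes))
  expected <- 0.05 * mean(truth$genes$S)
  se <- sqrt(mean(expected) / nrow(truth$genes))
  expect_lt(abs(mean(syn_per_gene) - expected), 3 * se)
})

test_that("contaminant injection records truth and is a no-op at zero", {
  sx <- shared_sim()
  expect_length(sx$sim$truth$contaminants, 6)
  expect_length(sx$sim$truth$rrna, 2)
  expect_true(all(sx$sim$truth$contaminants %in% names(sx$sim$cloneA)))

  cfg0 <- sim_config(n_genes = 5, n_contaminants = 0, n_rrna = 0,
                     seed = 13)
  sim0 <- simulate_transcriptomes(cfg0)
  expect_identical(inject_contaminants(sim0, cfg0), sim0)
})

test_that("pileups have Poisson depth and balanced het alleles", {
  cfg <- sim_config(n_genes = 30, coverage = 50, het_rate = 0.002,
                    error_rate = 0, n_contaminants = 0, n_rrna = 0,
                    seed = 19)
  sim <- simulate_transcriptomes(cfg)
  p <- simulate_pileups(sim, cfg)
  pu <- p$A_on_A
  depth <- pu$A + pu$C + pu$G + pu$T
  expect_gt(nrow(pu), 1e4)
  expect_lt(abs(mean(depth) - 50), 3 * sqrt(50 / nrow(pu)))

  # error-free non-variant sites: all reads match the reference
  hetA <- sim$truth$het[sim$truth$het$clone == "A", ]
  key <- paste(pu$gene, pu$pos)
  clean <- !key %in% paste(hetA$gene, hetA$pos)
  bm <- as.matrix(pu[clean, c("A", "C", "G", "T")])
  ref_depth <- bm[cbind(seq_len(nrow(bm)),
                        match(pu$ref[clean], c("A", "C", "G", "T")))]
  expect_true(all(ref_depth == depth[clean]))

  # het sites: pooled alternate fraction near 0.5
  hi <- match(paste(hetA$gene, hetA$pos), key)
  bm_het <- as.matrix(pu[hi, c("A", "C", "G", "T")])
  alt_reads <- bm_het[cbind(seq_along(hi),
                            match(hetA$alt, c("A", "C", "G", "T")))]
  tot <- depth[hi]
  frac <- sum(alt_reads) / sum(tot)
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / sum(tot)))
})

test_that("count simulation plants the requested fold change", {
  cfg <- sim_config(n_genes = 1000, de_fraction = 0.2, fold_change = 4,
                    nb_dispersion = 0.1, seed = 23)
  cnt <- simulate_counts(cfg)
  up <- cnt$truth$fold == 4
  expect_gt(sum(up), 50)
  c1 <- rowMeans(cnt$counts[up, 1:2]) /
    mean(cnt$size_factors_true[1:2])
  c2 <- rowMeans(cnt$counts[up, 3:4]) /
    mean(cnt$size_factors_true[3:4])
  ratio <- sum(c2) / sum(c1)
  expect_lt(abs(ratio - 4), 0.4)

  # fold 1 forces an empty DE truth
  cfg1 <- sim_config(n_genes = 50, de_fraction = 0.5, fold_change = 1,
                     seed = 29)
  expect_false(any(simulate_counts(cfg1)$truth$de))
})
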
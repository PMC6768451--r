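test_that("ORF finder handles complete, partial and short ORFs", {
  # ATG + 120 non-stop codons + TAA: one ORF of 122 codons
  tr <- paste0("ATG", strrep("GCT", 120), "TAA")
  orf <- find_orfs(tr)
  expect_equal(orf$codons, 122L)
  expect_equal(orf$start, 1L)
  expect_equal(orf$end, 366L)
  expect_false(orf$partial5)
  # no ATG, 150 stop-free codons: 5'-partial ORF
  tr2 <- strrep("GGC", 150)
  orf2 <- find_orfs(tr2)
  expect_equal(orf2$codons, 150L)
  expect_true(orf2$partial5)
  expect_equal(nrow(find_orfs(tr2, allow_partial = FALSE)), 0L)
  # below the minimum length: empty
  expect_equal(nrow(find_orfs(paste0("ATG", strrep("GCT", 48), "TAA"))),
               0L)
  # ORF not in frame 0 is still found (partial ORFs disabled so the
  # frame-shifted stop-free repeats cannot tie the true ORF)
  tr3 <- paste0("TT", "ATG", strrep("CAT", 120), "TGA")
  orf3 <- find_orfs(tr3, allow_partial = FALSE)
  expect_equal(orf3$frame, 2L)
  expect_equal(orf3$start, 3L)
})

test_that("applying fixed variants swaps alleles and validates", {
  cds <- "ATGAAACCC"
  expect_equal(apply_fixed_variants(cds, integer(0), character(0),
                                    character(0)), cds)
  out <- apply_fixed_variants(cds, 4L, "A", "G")
  expect_equal(out, "ATGGAACCC")
  # involution: applying the reverse table restores the original
  expect_equal(apply_fixed_variants(out, 4L, "G", "A"), cds)
  # positions outside the CDS are ignored (trimming convention)
  expect_equal(apply_fixed_variants(cds, 50L, "A", "G"), cds)
  # allele mismatch is a hard error
  expect_error(apply_fixed_variants(cds, 4L, "C", "G"), "mismatch")
})

test_that("NG86 site counts match hand enumeration and conserve sites", {
  expect_equal(ng86_site_counts("ATG"), list(S = 0, N = 3, codons = 1L))
  sc <- ng86_site_counts("TTT")
  expect_equal(sc$S, 1 / 3)
  expect_equal(sc$N, 8 / 3)
  # conservation on random CDSs
  set.seed(15)
  for (i in 1:20) {
    cds <- random_cds(sample(5:40, 1))
    sc <- ng86_site_counts(cds)
    expect_equal(sc$S + sc$N, nchar(cds))
  }
})

test_that("pathway-averaged difference counts match enumeration", {
  expect_equal(ng86_difference_counts("AAA", "AAA"), list(Ns = 0, Nn = 0))
  expect_equal(ng86_difference_counts("TTT", "TTC"), list(Ns = 1, Nn = 0))
  # TTT vs GTA: average over the two 2-step pathways = (0.5, 1.5)
  d <- ng86_difference_counts("TTT", "GTA")
  expect_equal(d$Ns, 0.5)
  expect_equal(d$Nn, 1.5)
  # spot oracle equivalence incl. 3-position differences
  set.seed(21)
  codons <- setdiff(names(Biostrings::GENETIC_CODE),
                    c("TAA", "TAG", "TGA"))
  for (i in 1:50) {
    a <- sample(codons, 1)
    b <- sample(codons, 1)
    got <- ng86_difference_counts(a, b)
    want <- oracle_ng86_pair(a, b)
    expect_equal(c(got$Ns, got$Nn), want, tolerance = 1e-12)
  }
})

test_that("Jukes-Cantor correction is exact and monotone", {
  expect_equal(jukes_cantor(0), 0)
  expect_equal(jukes_cantor(0.06), -0.75 * log(1 - 0.08))
  p <- seq(0, 0.74, by = 0.01)
  expect_true(all(diff(jukes_cantor(p)) > 0))
  expect_true(is.nan(jukes_cantor(0.8)))
})

test_that("kaks_estimate classifies and flags edge cases", {
  cds <- random_cds(120)
  id <- kaks_estimate(cds, cds)
  expect_equal(id$Ka, 0)
  expect_equal(id$Ks, 0)
  expect_true(is.na(id$ratio))
  expect_equal(id$class, "unclassified")
  expect_equal(id$fisher_p, 1)

  # a strongly nonsynonymous pair is classified positive
  set.seed(33)
  # expected events (~13 syn + ~230 nonsyn) stay below the one-per-codon
  # capacity of a 400-codon gene
  cfg <- sim_config(n_genes = 1, cds_len_codons = c(400, 400),
                    omega = 5, ks_target = 0.05, utr_len = c(0, 0),
                    n_contaminants = 0, n_rrna = 0, seed = 51)
  sim <- simulate_transcriptomes(cfg)
  g <- sim$truth$genes[1, ]
  rec <- kaks_estimate(
    substring(sim$cloneA[[g$gene]], g$cds_start, g$cds_end - 3L),
    substring(sim$cloneB[[g$gene]], g$cds_start, g$cds_end - 3L))
  expect_equal(rec$class, "positive")
  expect_gt(rec$ratio, 1)
  expect_lt(rec$fisher_p, 0.05)
})

test_that("classification counts partition the records", {
  recs <- rbind(kaks_estimate("ATGAAA", "ATGAAA", gene = "a"),
                kaks_estimate("ATGAAA", "ATGAAA", gene = "b"))
  cls <- classify_selection(recs)
  expect_equal(cls$positive + cls$purifying + cls$unclassified, cls$total)
  expect_equal(cls$unclassified, 2L)
})

test_that("p-distance and divergence dating", {
  expect_equal(p_distance("ACGT", "ACGT"), 0)
  a <- paste(rep("A", 100), collapse = "")
  b <- paste(c(rep("C", 6), rep("A", 94)), collapse = "")
  expect_equal(p_distance(a, b), 0.06)
  expect_error(p_distance("----", "AC-T"), "comparable")
  expect_equal(divergence_time(0.06, 0.02), 3)
  expect_equal(divergence_time(0, 0.05), 0)
  expect_equal(divergence_time(0.04, 0.02), 2)
  expect_error(divergence_time(0.05, 0), "rate")
})
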
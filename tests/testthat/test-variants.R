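test_that("genotype caller follows the class rules", {
  # depth 30, all alternate -> hom_alt
  r <- call_genotypes(pileup_row(ref = "A", G = 30))
  expect_equal(r$class, "hom_alt")
  expect_equal(r$allele1, "G")
  # depth 30, 14 ref / 16 alt -> het (both fractions >= 0.2, ref supported)
  r <- call_genotypes(pileup_row(ref = "A", A = 14, G = 16))
  expect_equal(r$class, "het")
  expect_setequal(c(r$allele1, r$allele2), c("A", "G"))
  # depth 3 -> no_call
  expect_equal(call_genotypes(pileup_row(ref = "A", A = 3))$class,
               "no_call")
  # indel fraction >= 0.2 -> indel
  expect_equal(call_genotypes(pileup_row(ref = "A", A = 20, del = 6))$class,
               "indel")
  # clean reference site
  expect_equal(call_genotypes(pileup_row(ref = "A", A = 29, G = 1))$class,
               "hom_ref")
  # second allele at fraction 0.2 but only one read stays hom_ref
  expect_equal(call_genotypes(pileup_row(ref = "A", A = 4, G = 1),
                              min_depth = 5)$class, "hom_ref")
  # unknown reference base errors
  expect_error(call_genotypes(pileup_row(ref = "N", A = 30)), "reference")
})

test_that("fixed_differences keeps exactly the hom_alt calls", {
  pu <- rbind(pileup_row(pos = 1L, ref = "A", G = 30),          # hom_alt
              pileup_row(pos = 2L, ref = "A", A = 14, G = 16),  # het
              pileup_row(pos = 3L, ref = "A", A = 20, del = 6), # indel
              pileup_row(pos = 4L, ref = "A", A = 30))          # hom_ref
  fx <- fixed_differences(call_genotypes(pu))
  expect_equal(nrow(fx), 1L)
  expect_equal(fx$pos, 1L)
  expect_equal(fx$alt, "G")
  # all hom_ref -> empty
  expect_equal(nrow(fixed_differences(call_genotypes(
    pileup_row(ref = "C", C = 25)))), 0L)
})

test_that("call classes partition the input sites", {
  sx <- shared_sim()
  cfg <- sx$cfg
  p <- simulate_pileups(sx$sim, cfg)
  calls <- call_genotypes(p$B_on_A)
  expect_equal(nrow(calls), nrow(p$B_on_A))
  expect_true(all(calls$class %in%
                    c("hom_ref", "hom_alt", "het", "indel", "no_call")))
})

test_that("heterozygosity arithmetic and error cases", {
  calls <- data.frame(class = c(rep("hom_ref", 997), rep("het", 2),
                                "no_call"))
  h <- heterozygosity(calls, clone = "X")
  expect_equal(h$H, 2 / 999)
  expect_equal(heterozygosity(calls, denominator = "all")$H, 2 / 1000)
  expect_equal(heterozygosity(data.frame(class = rep("hom_ref", 10)))$H, 0)
  expect_error(heterozygosity(data.frame(class = character(0))), "sites")
  expect_error(heterozygosity(data.frame(class = rep("no_call", 5))),
               "callable")
})

test_that("bi-directional consolidation maps, merges and excludes", {
  rbh <- fake_rbh(c("a1", "a2"), c("b1", "b2"), c(100L, 100L))
  # a site seen in both directions, one seen singly, one in a non-RBH gene
  tab_BA <- data.frame(gene = c("a1", "a1", "zz"), pos = c(10L, 20L, 5L),
                       ref = c("A", "C", "G"), alt = c("G", "T", "A"),
                       stringsAsFactors = FALSE)
  tab_AB <- data.frame(gene = "b1", pos = 10L, ref = "G", alt = "A",
                       stringsAsFactors = FALSE)
  out <- consolidate_bidirectional(tab_BA, tab_AB, rbh)
  expect_equal(nrow(out), 2L)
  both <- out[out$posA == 10, ]
  expect_equal(both$directions, "both")
  expect_equal(both$alleleA, "A")
  expect_equal(both$alleleB, "G")
  expect_equal(out$directions[out$posA == 20], "B_on_A")
  expect_false("zz" %in% out$geneA)

  # allele conflict between directions is dropped with a warning
  tab_AB2 <- data.frame(gene = "b1", pos = 10L, ref = "T", alt = "A",
                        stringsAsFactors = FALSE)
  expect_warning(out2 <- consolidate_bidirectional(tab_BA[1, ], tab_AB2,
                                                   rbh),
                 "conflict")
  expect_equal(nrow(out2), 0L)
})

test_that("error-free high coverage recovers the truth in both directions", {
  cfg <- sim_config(n_genes = 15, coverage = 60, error_rate = 0,
                    het_rate = 0, n_contaminants = 0, n_rrna = 0,
                    seed = 41)
  sim <- simulate_transcriptomes(cfg)
  p <- simulate_pileups(sim, cfg)
  fx_BA <- fixed_differences(call_genotypes(p$B_on_A))
  fx_AB <- fixed_differences(call_genotypes(p$A_on_B))
  truth_key <- sort(paste(sim$truth$fixed$gene, sim$truth$fixed$pos))
  expect_equal(sort(paste(fx_BA$gene, fx_BA$pos)), truth_key)
  expect_equal(sort(paste(fx_AB$gene, fx_AB$pos)), truth_key)
  # oracle: consolidated counts equal the position-wise FASTA diff
  ids <- sim$truth$genes$gene
  rbh <- fake_rbh(ids, ids, nchar(sim$cloneA[ids]))
  cons <- consolidate_bidirectional(fx_BA, fx_AB, rbh)
  n_diff <- sum(mapply(function(a, b) {
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  }, sim$cloneA[ids], sim$cloneB[ids]))
  expect_equal(nrow(cons), n_diff)
  expect_true(all(cons$directions == "both"))
})
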
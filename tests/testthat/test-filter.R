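# Margin decisions are unit-tested on hand-built maps via small synthetic
# sequences; the end-to-end behaviour is covered on the shared simulation.

test_that("margin rule keeps and discards as stated", {
  set.seed(3)
  bases <- c("A", "C", "G", "T")
  ref_gene <- paste(sample(bases, 400, replace = TRUE), collapse = "")
  contam_src <- paste(sample(bases, 400, replace = TRUE,
                             prob = c(.22, .28, .28, .22)), collapse = "")
  # contig 1: a gene copy -> ref-only hit
  # contig 2: a contaminant copy -> contaminant-only hit
  # contig 3: chimera, mostly contaminant with a short gene stretch ->
  #           hits both, ref hit weaker by far -> margin-fail
  contigs <- c(c1 = ref_gene,
               c2 = contam_src,
               c3 = paste0(substr(ref_gene, 1, 60), contam_src))
  dec <- contaminant_filter(contigs, c(ref = ref_gene),
                            c(con = contam_src), margin = 100)
  expect_equal(nrow(dec), 3L)
  expect_equal(dec$reason[dec$contig == "c1"], "ref-only-hit")
  expect_true(dec$kept[dec$contig == "c1"])
  expect_equal(dec$reason[dec$contig == "c2"], "contaminant-only-hit")
  expect_false(dec$kept[dec$contig == "c2"])
  expect_equal(dec$reason[dec$contig == "c3"], "margin-fail")
  expect_false(dec$kept[dec$contig == "c3"])

  # margin-pass: both hits, difference >= 100 bits (gene copy plus a short
  # contaminant stretch)
  contigs2 <- c(c4 = paste0(ref_gene, substr(contam_src, 1, 80)))
  dec2 <- contaminant_filter(contigs2, c(ref = ref_gene),
                             c(con = contam_src), margin = 100)
  expect_equal(dec2$reason, "margin-pass")
  expect_true(dec2$kept)
  expect_gte(dec2$best_ref_bits - dec2$best_contam_bits, 100)

  # no-hit contig (4-periodic repeat cannot seed)
  dec3 <- contaminant_filter(c(c5 = strrep("ACGT", 100)),
                             c(ref = ref_gene), c(con = contam_src))
  expect_equal(dec3$reason, "no-hit")
  expect_false(dec3$kept)
})

test_that("rRNA filter removes at the inclusive e-value cutoff", {
  set.seed(5)
  rr <- paste(sample(c("A", "C", "G", "T"), 800, replace = TRUE),
              collapse = "")
  other <- paste(sample(c("A", "C", "G", "T"), 500, replace = TRUE),
                 collapse = "")
  dec <- rrna_filter(c(x = rr, y = other), c(r18S = rr))
  expect_false(dec$kept[dec$contig == "x"])
  expect_equal(dec$reason[dec$contig == "x"], "rrna")
  expect_true(dec$kept[dec$contig == "y"])

  # boundary: a hit with evalue exactly at the cutoff is removed
  hit <- local_align(rr, rr)
  expect_false(rrna_filter(c(x = rr), c(r = rr),
                           evalue_cutoff = hit$evalue)$kept)
})

test_that("filtering partitions the simulated mixture correctly", {
  sx <- shared_sim()
  sim <- sx$sim
  res <- filter_contigs(sim$cloneA, sim$ancestral, sim$contaminant_db,
                        sim$rrna_db)
  # partition: one decision per contig
  expect_equal(sort(res$decisions$contig), sort(names(sim$cloneA)))
  expect_equal(sum(res$decisions$kept) + sum(!res$decisions$kept),
               length(sim$cloneA))
  # all truth contaminants and rRNAs removed; all genes kept
  planted <- c(sim$truth$contaminants, sim$truth$rrna)
  expect_length(intersect(names(res$kept), planted), 0)
  expect_true(all(sim$truth$genes$gene %in% names(res$kept)))
})
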
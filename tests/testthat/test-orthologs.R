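test_that("best hits and reciprocity follow the stated rules", {
  mapAB <- data.frame(query = c("a1", "a2"), subject = c("b1", "b2"),
                      score = c(400, 380), bits = c(250, 240),
                      evalue = c(1e-70, 1e-68), stringsAsFactors = FALSE)
  mapBA <- data.frame(query = c("b1", "b2"), subject = c("a1", "a9"),
                      score = c(400, 380), bits = c(250, 240),
                      evalue = c(1e-70, 1e-68), stringsAsFactors = FALSE)
  rbh <- rbh_from_maps(mapAB, mapBA)
  # (a1, b1) reciprocal; a2 -> b2 -> a9 is not
  expect_equal(rbh$pairs$geneA, "a1")
  expect_equal(rbh$pairs$geneB, "b1")
  # partial matching: no gene twice
  expect_false(anyDuplicated(rbh$pairs$geneA) > 0)
})

test_that("equal-bitscore ties break to the lexicographically smallest id", {
  set.seed(9)
  s <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE),
             collapse = "")
  db <- c(z_copy = s, a_copy = s)
  hit <- search_db(c(q = s), db)
  expect_equal(hit$subject, "a_copy")
})

test_that("RBH on simulated clones finds the true partners", {
  sx <- shared_sim()
  sim <- sx$sim
  ids <- sim$truth$genes$gene
  rbh <- with_cache("shared_rbh", function() {
    reciprocal_best_hits(sim$cloneA[ids], sim$cloneB[ids])
  })
  expect_equal(sort(rbh$pairs$geneA), sort(ids))
  expect_true(all(rbh$pairs$geneA == rbh$pairs$geneB))
  # injective both ways
  expect_false(anyDuplicated(rbh$pairs$geneA) > 0)
  expect_false(anyDuplicated(rbh$pairs$geneB) > 0)
  # e-value cutoff honoured
  expect_true(all(rbh$pairs$evalueAB <= 1e-50))
  expect_true(all(rbh$pairs$evalueBA <= 1e-50))
})

test_that("position maps are consistent through the pair alignment", {
  a <- "ACGTACGTACGTACGT"
  b <- "ACGTACGAACGTACGT"  # one substitution, equal length
  rbh <- structure(list(
    pairs = data.frame(geneA = "g", geneB = "h",
                       stringsAsFactors = FALSE),
    alignments = list(g = clonescan:::.position_maps(a, b))),
    class = "rbh_pairs")
  for (pos in c(1L, 8L, 16L)) {
    m <- map_position(rbh, "g", pos, from = "A")
    expect_equal(map_position(rbh, "g", m, from = "B"), pos)
  }
  expect_true(is.na(map_position(rbh, "g", 99L, from = "A")))
})
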
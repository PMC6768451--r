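# Independent oracles and shared fixtures for the test suite.
#
# The oracles deliberately use Biostrings::GENETIC_CODE (the package
# hardcodes its own codon table) and explicit enumeration, so they share no
# code path with the implementation they check.

.oracle_translate <- function(codon) {
  unname(Biostrings::GENETIC_CODE[codon])
}

.oracle_perms <- list(
  `1` = list(1L),
  `2` = list(1:2, 2:1),
  `3` = list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
             c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L)))

# Brute-force pathway enumeration for one codon pair: average syn/nonsyn
# step counts over all orderings of the differing positions, excluding
# pathways whose intermediate codons are stops (fallback: keep all).
oracle_ng86_pair <- function(codonA, codonB) {
  a <- strsplit(codonA, "")[[1]]
  b <- strsplit(codonB, "")[[1]]
  d <- which(a != b)
  if (length(d) == 0) return(c(0, 0))
  res <- list()
  for (perm in .oracle_perms[[as.character(length(d))]]) {
    ord <- d[perm]
    cur <- a
    syn <- 0; non <- 0; stopped <- FALSE
    for (j in seq_along(ord)) {
      nxt <- cur
      nxt[ord[j]] <- b[ord[j]]
      aa1 <- .oracle_translate(paste(cur, collapse = ""))
      aa2 <- .oracle_translate(paste(nxt, collapse = ""))
      if (j < length(ord) && aa2 == "*") stopped <- TRUE
      if (aa1 == aa2) syn <- syn + 1 else non <- non + 1
      cur <- nxt
    }
    res[[length(res) + 1]] <- c(syn, non, stopped)
  }
  m <- do.call(rbind, res)
  keep <- m[, 3] == 0
  if (!any(keep)) keep <- rep(TRUE, nrow(m))
  c(mean(m[keep, 1]), mean(m[keep, 2]))
}

# Exact one-sided hypergeometric tail via explicit choose() summation.
oracle_hypergeom_p <- function(k, K, n, N) {
  j <- k:min(K, n)
  sum(exp(lchoose(n, j) + lchoose(N - n, K - j) - lchoose(N, K)))
}

# Random stop-free CDS (ATG + internal + stop) for property tests.
random_cds <- function(n_codons, gc = 0.35) {
  stops <- c("TAA", "TAG", "TGA")
  bases <- c("A", "C", "G", "T")
  prob <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  internal <- replicate(n_codons - 2, {
    repeat {
      cd <- paste(sample(bases, 3, replace = TRUE, prob = prob),
                  collapse = "")
      if (!cd %in% stops) return(cd)
    }
  })
  paste0("ATG", paste(internal, collapse = ""), sample(stops, 1))
}

# Build a one-row pileup data.frame.
pileup_row <- function(gene = "g1", pos = 1L, ref = "A", A = 0, C = 0,
                       G = 0, T = 0, ins = 0, del = 0) {
  data.frame(gene = gene, pos = pos, ref = ref, A = A, C = C, G = G, T = T,
             ins = ins, del = del, stringsAsFactors = FALSE)
}

# Identity rbh_pairs object for unit tests (equal-length partners).
fake_rbh <- function(geneA, geneB, len) {
  pairs <- data.frame(geneA = geneA, geneB = geneB,
                      bitsAB = NA_real_, bitsBA = NA_real_,
                      evalueAB = NA_real_, evalueBA = NA_real_,
                      stringsAsFactors = FALSE)
  alignments <- lapply(len, function(L) list(A2B = seq_len(L),
                                             B2A = seq_len(L)))
  names(alignments) <- geneA
  structure(list(pairs = pairs, alignments = alignments),
            class = "rbh_pairs")
}

# Shared expensive fixtures, built once per test run.
.fixture_cache <- new.env(parent = emptyenv())

with_cache <- function(key, builder) {
  hit <- .fixture_cache[[key]]
  if (!is.null(hit)) return(hit)
  val <- builder()
  assign(key, val, envir = .fixture_cache)
  val
}

# Small default-world simulation shared across module tests.
shared_sim <- function() {
  with_cache("shared_sim", function() {
    cfg <- sim_config(n_genes = 40, n_contaminants = 6, n_rrna = 2,
                      seed = 101)
    sim <- simulate_transcriptomes(cfg)
    sim <- inject_contaminants(sim, cfg)
    list(cfg = cfg, sim = sim)
  })
}

# One default pipeline run shared between pipeline and acceptance tests.
shared_run <- function() {
  with_cache("shared_run", function() {
    cfg <- sim_config(n_genes = 40, n_contaminants = 8, n_rrna = 3,
                      seed = 5)
    run_all(pipeline_config(simulate = cfg))
  })
}
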
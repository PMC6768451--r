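# Standard genetic code and NG86 codon bookkeeping.
#
# The code table is hardcoded (not taken from Biostrings) so that the test
# suite can use Biostrings::GENETIC_CODE as an independent oracle.

.BASES <- c("A", "C", "G", "T")

.GENETIC_CODE <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G"
)

.STOP_CODONS <- names(.GENETIC_CODE)[.GENETIC_CODE == "*"]

#' Translate a codon to its amino acid (one-letter, `*` for stop)
#' @param codon character vector of 3-letter codons over A/C/G/T
#' @return character vector of amino acids; NA for codons containing other
#'   letters (e.g. N)
#' @export
codon_aa <- function(codon) {
  aa <- unname(.GENETIC_CODE[toupper(codon)])
  aa
}

#' Is a single-nucleotide codon change synonymous?
#'
#' Changes creating or destroying a stop codon are nonsynonymous unless both
#' codons are stops.
#' @param from,to codon strings
#' @return logical
#' @export
is_synonymous_change <- function(from, to) {
  codon_aa(from) == codon_aa(to)
}

# All nine single-nucleotide mutants of a codon
.codon_mutants <- function(codon) {
  s <- strsplit(codon, "")[[1]]
  out <- character(0)
  for (i in 1:3) {
    for (b in setdiff(.BASES, s[i])) {
      m <- s
      m[i] <- b
      out <- c(out, paste(m, collapse = ""))
    }
  }
  out
}

# Per-codon synonymous site count under NG86: each position contributes
# f_i = (# synonymous single-nt mutants at that position) / 3.
# Mutants that create a stop codon count as nonsynonymous (unless the codon
# itself is a stop, in which case stop->stop counts synonymous).
.codon_syn_sites <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    codons <- names(.GENETIC_CODE)
    s <- vapply(codons, function(cd) {
      aa <- .GENETIC_CODE[[cd]]
      sum(codon_aa(.codon_mutants(cd)) == aa) / 3
    }, numeric(1))
    cache <<- s
    s
  }
})

# Pathway-averaged difference counts for a single codon pair.
# Enumerates all d! orderings of the differing positions; a pathway is
# excluded if any intermediate codon is a stop (if every pathway is excluded,
# all are retained as a fallback). Returns c(syn, nonsyn).
.codon_pair_diffs <- function(codonA, codonB) {
  a <- strsplit(codonA, "")[[1]]
  b <- strsplit(codonB, "")[[1]]
  d <- which(a != b)
  nd <- length(d)
  if (nd == 0L) return(c(syn = 0, nonsyn = 0))
  orders <- switch(nd,
    `1` = list(d),
    `2` = list(d, rev(d)),
    `3` = lapply(list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                      c(2, 3, 1), c(3, 1, 2), c(3, 2, 1)),
                 function(p) d[p]))
  paths <- lapply(orders, function(ord) {
    cur <- a
    syn <- 0
    nonsyn <- 0
    through_stop <- FALSE
    for (k in seq_along(ord)) {
      nxt <- cur
      nxt[ord[k]] <- b[ord[k]]
      c1 <- paste(cur, collapse = "")
      c2 <- paste(nxt, collapse = "")
      # intermediates only: the endpoints are the observed codons
      if (k < length(ord) && c2 %in% .STOP_CODONS) through_stop <- TRUE
      if (identical(codon_aa(c1), codon_aa(c2))) syn <- syn + 1 else nonsyn <- nonsyn + 1
      cur <- nxt
    }
    list(syn = syn, nonsyn = nonsyn, through_stop = through_stop)
  })
  ok <- !vapply(paths, `[[`, logical(1), "through_stop")
  if (!any(ok)) ok <- rep(TRUE, length(paths))
  syn <- mean(vapply(paths[ok], `[[`, numeric(1), "syn"))
  nonsyn <- mean(vapply(paths[ok], `[[`, numeric(1), "nonsyn"))
  c(syn = syn, nonsyn = nonsyn)
}

# Memoised pair table keyed "AAA|AAC"
.pair_cache <- new.env(parent = emptyenv())

.codon_pair_diffs_cached <- function(codonA, codonB) {
  key <- paste0(codonA, "|", codonB)
  hit <- .pair_cache[[key]]
  if (!is.null(hit)) return(hit)
  val <- .codon_pair_diffs(codonA, codonB)
  assign(key, val, envir = .pair_cache)
  val
}

.split_codons <- function(cds) {
  cds <- toupper(as.character(cds))
  n <- nchar(cds)
  if (n %% 3L != 0L) stop("CDS length must be a multiple of 3, got ", n)
  substring(cds, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
}
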
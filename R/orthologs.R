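# Reciprocal best hit orthology between the two clone transcript sets.

#' Best hit of every query against a database
#'
#' Best = maximal bitscore among hits with e-value at or below the cutoff;
#' bitscore ties are broken by lexicographically smallest subject id.
#' Queries with no qualifying hit are absent from the result.
#'
#' @param setA named query sequences
#' @param setB named subject sequences
#' @param evalue_cutoff e-value cutoff (default 1e-50)
#' @param scoring an [align_scoring()] object
#' @return data.frame: query, subject, score, bits, evalue, intervals
#' @export
best_hits <- function(setA, setB, evalue_cutoff = 1e-50,
                      scoring = align_scoring()) {
  if (length(setA) == 0 || length(setB) == 0) stop("sets must be non-empty")
  search_db(setA, setB, scoring, evalue_cutoff = evalue_cutoff,
            best_only = TRUE)
}

#' Reciprocal best hits between two transcript sets
#'
#' A pair (a, b) is reported iff b is a's best hit and a is b's best hit.
#' The result is a partial matching: every gene appears in at most one pair.
#' A global pairwise alignment is attached per pair for coordinate mapping.
#'
#' @param setA,setB named sequence sets for the two clones
#' @param evalue_cutoff e-value cutoff applied in both directions
#'   (default 1e-50)
#' @param scoring an [align_scoring()] object
#' @return object of class `rbh_pairs`: list with `pairs` data.frame
#'   (geneA, geneB, bitsAB, bitsBA, evalueAB, evalueBA) and `alignments`
#'   (per-geneA position maps between the partners)
#' @export
reciprocal_best_hits <- function(setA, setB, evalue_cutoff = 1e-50,
                                 scoring = align_scoring()) {
  setA <- .as_named_character(setA, "setA")
  setB <- .as_named_character(setB, "setB")
  mapAB <- best_hits(setA, setB, evalue_cutoff, scoring)
  mapBA <- best_hits(setB, setA, evalue_cutoff, scoring)
  rbh_from_maps(mapAB, mapBA, setA, setB)
}

#' Build RBH pairs from two precomputed best-hit maps
#'
#' @param mapAB,mapBA best-hit data.frames from [best_hits()]
#' @param setA,setB the sequences (needed for the pairwise alignments; may
#'   be NULL, in which case no coordinate maps are built)
#' @return an `rbh_pairs` object
#' @export
rbh_from_maps <- function(mapAB, mapBA, setA = NULL, setB = NULL) {
  ab <- stats::setNames(mapAB$subject, mapAB$query)
  ba <- stats::setNames(mapBA$subject, mapBA$query)
  recip <- names(ab)[!is.na(ba[ab]) & ba[ab] == names(ab)]
  pairs <- data.frame(
    geneA = recip, geneB = unname(ab[recip]), stringsAsFactors = FALSE)
  if (nrow(pairs) > 0) {
    ia <- match(pairs$geneA, mapAB$query)
    ib <- match(pairs$geneB, mapBA$query)
    pairs$bitsAB <- mapAB$bits[ia]
    pairs$bitsBA <- mapBA$bits[ib]
    pairs$evalueAB <- mapAB$evalue[ia]
    pairs$evalueBA <- mapBA$evalue[ib]
    pairs <- pairs[order(pairs$geneA), , drop = FALSE]
    rownames(pairs) <- NULL
  } else {
    pairs <- data.frame(geneA = character(0), geneB = character(0),
                        bitsAB = numeric(0), bitsBA = numeric(0),
                        evalueAB = numeric(0), evalueBA = numeric(0),
                        stringsAsFactors = FALSE)
  }
  alignments <- NULL
  if (!is.null(setA) && !is.null(setB) && nrow(pairs) > 0) {
    alignments <- lapply(seq_len(nrow(pairs)), function(i) {
      .position_maps(setA[[pairs$geneA[i]]], setB[[pairs$geneB[i]]])
    })
    names(alignments) <- pairs$geneA
  }
  structure(list(pairs = pairs, alignments = alignments),
            class = "rbh_pairs")
}

# Global alignment of an ortholog pair; returns A->B and B->A integer
# position maps (NA at gap columns).
.position_maps <- function(seqA, seqB) {
  if (nchar(seqA) == nchar(seqB) && seqA == seqB) {
    n <- nchar(seqA)
    return(list(A2B = seq_len(n), B2A = seq_len(n)))
  }
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(seqA), Biostrings::DNAString(seqB),
    type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 2, mismatch = -3, baseOnly = TRUE),
    gapOpening = 5, gapExtension = 2)
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sa <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  A2B <- rep(NA_integer_, nchar(seqA))
  B2A <- rep(NA_integer_, nchar(seqB))
  ia <- 0L
  ib <- 0L
  for (col in seq_along(pa)) {
    a_gap <- pa[col] == "-"
    b_gap <- sa[col] == "-"
    if (!a_gap) ia <- ia + 1L
    if (!b_gap) ib <- ib + 1L
    if (!a_gap && !b_gap) {
      A2B[ia] <- ib
      B2A[ib] <- ia
    }
  }
  list(A2B = A2B, B2A = B2A)
}

#' Map a position between ortholog partners
#'
#' @param pairs an `rbh_pairs` object with alignments
#' @param geneA the clone-A gene id of the pair
#' @param pos 1-based position on the `from` clone's transcript
#' @param from `"A"` (map A -> B) or `"B"` (map B -> A)
#' @return mapped 1-based position, or NA when the position falls in a gap
#'   or outside the partner
#' @export
map_position <- function(pairs, geneA, pos, from = c("A", "B")) {
  from <- match.arg(from)
  aln <- pairs$alignments[[geneA]]
  if (is.null(aln)) return(NA_integer_)
  m <- if (from == "A") aln$A2B else aln$B2A
  if (pos < 1 || pos > length(m)) return(NA_integer_)
  m[[pos]]
}

#' @export
print.rbh_pairs <- function(x, ...) {
  cat("Reciprocal best hit pairs:", nrow(x$pairs), "\n")
  if (nrow(x$pairs) > 0) print(utils::head(x$pairs), ...)
  invisible(x)
}
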
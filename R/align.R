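# Seeded Smith-Waterman local alignment with a Karlin-Altschul surrogate for
# bitscores and e-values. The dynamic program is delegated to
# Biostrings::pairwiseAlignment; seeding, scoring statistics and database
# search logic live here.

#' Alignment scoring parameters
#'
#' Defaults mirror megablast-style nucleotide scoring: match +2, mismatch -3,
#' affine gaps (open 5, extend 2). `lambda` and `K` are ungapped
#' Karlin-Altschul surrogates used to convert raw scores to bitscores:
#' `bits = (lambda * score - ln K) / ln 2`; `evalue = m * n * 2^-bits`.
#'
#' @param match,mismatch match reward (> 0) and mismatch penalty (< 0)
#' @param gap_open,gap_extend positive gap penalties
#' @param lambda,K Karlin-Altschul parameters
#' @param k k-mer length for seeding candidate subjects (default 11)
#' @param min_seeds minimum shared k-mers before the dynamic program is run
#' @param min_score minimum raw score for a reportable hit
#' @return list of class `align_scoring`
#' @export
align_scoring <- function(match = 2, mismatch = -3, gap_open = 5,
                          gap_extend = 2, lambda = 0.625, K = 0.41,
                          k = 11L, min_seeds = 5L, min_score = 20) {
  stopifnot(match > 0, mismatch < 0, gap_open > 0, gap_extend > 0,
            lambda > 0, K > 0)
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend, lambda = lambda, K = K,
                 k = as.integer(k), min_seeds = as.integer(min_seeds),
                 min_score = min_score),
            class = "align_scoring")
}

#' Bitscore from a raw alignment score
#' @param score raw score
#' @param scoring an [align_scoring()] object
#' @export
bitscore <- function(score, scoring = align_scoring()) {
  (scoring$lambda * score - log(scoring$K)) / log(2)
}

#' E-value from a bitscore for a search space of size m x n
#' @param bits bitscore
#' @param m,n query length and subject/database length
#' @export
evalue_from_bits <- function(bits, m, n) {
  m * n * 2^(-bits)
}

.submat_cache <- new.env(parent = emptyenv())

.substitution_matrix <- function(scoring) {
  key <- paste(scoring$match, scoring$mismatch)
  hit <- .submat_cache[[key]]
  if (!is.null(hit)) return(hit)
  m <- Biostrings::nucleotideSubstitutionMatrix(
    match = scoring$match, mismatch = scoring$mismatch, baseOnly = TRUE)
  assign(key, m, envir = .submat_cache)
  m
}

#' Optimal local alignment of two sequences
#'
#' Smith-Waterman optimal local score (via Biostrings' dynamic program) with
#' Karlin-Altschul bitscore and e-value. By default `n` in the e-value is the
#' subject length; database searches pass the total database length.
#'
#' @param query,subject character or DNAString sequences
#' @param scoring an [align_scoring()] object
#' @param space_n search-space length for the e-value (defaults to subject
#'   length)
#' @return `NULL` when no alignment reaches `min_score`; otherwise a one-row
#'   data.frame (an `AlignmentHit`): score, bits, evalue, and 1-based closed
#'   query/subject intervals
#' @export
local_align <- function(query, subject, scoring = align_scoring(),
                        space_n = NULL) {
  q <- as.character(query)
  s <- as.character(subject)
  if (nchar(q) == 0 || nchar(s) == 0) return(NULL)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(q), Biostrings::DNAString(s), type = "local",
    substitutionMatrix = .substitution_matrix(scoring),
    gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend)
  raw <- Biostrings::score(aln)
  if (raw < scoring$min_score) return(NULL)
  bits <- bitscore(raw, scoring)
  if (is.null(space_n)) space_n <- nchar(s)
  pat <- Biostrings::pattern(aln)
  sub <- Biostrings::subject(aln)
  data.frame(score = raw, bits = bits,
             evalue = evalue_from_bits(bits, nchar(q), space_n),
             q_start = Biostrings::start(pat), q_end = Biostrings::end(pat),
             s_start = Biostrings::start(sub), s_end = Biostrings::end(sub))
}

# --- k-mer seeding ---------------------------------------------------------

.seq_kmers <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  unique(substring(seq, 1:(n - k + 1L), k:n))
}

# Build an index: environment mapping k-mer -> integer vector of subject ids
.kmer_index <- function(seqs, k) {
  idx <- new.env(parent = emptyenv(), size = 4L * length(seqs))
  for (i in seq_along(seqs)) {
    for (km in .seq_kmers(seqs[[i]], k)) {
      idx[[km]] <- c(idx[[km]], i)
    }
  }
  idx
}

# Candidate subject indices sharing >= min_seeds distinct k-mers with query
.seed_candidates <- function(query, idx, k, min_seeds) {
  kms <- .seq_kmers(query, k)
  hits <- unlist(lapply(kms, function(km) idx[[km]]), use.names = FALSE)
  if (length(hits) == 0) return(integer(0))
  tab <- tabulate(hits)
  which(tab >= min_seeds)
}

#' Search a sequence database with seeded local alignment
#'
#' Subjects sharing at least `min_seeds` distinct k-mers with the query are
#' aligned by full dynamic programming; others are reported as no-hit. The
#' e-value uses the total database length as `n`. Ties on bitscore are broken
#' by lexicographically smallest subject id.
#'
#' @param queries,db named character vectors (or DNAStringSets) of sequences
#' @param scoring an [align_scoring()] object
#' @param evalue_cutoff keep hits with evalue <= cutoff (default Inf)
#' @param best_only return only the best hit per query (default TRUE)
#' @return data.frame: query, subject, score, bits, evalue plus interval
#'   columns; queries without a qualifying hit are absent
#' @export
search_db <- function(queries, db, scoring = align_scoring(),
                      evalue_cutoff = Inf, best_only = TRUE) {
  queries <- .as_named_character(queries, "query")
  db <- .as_named_character(db, "subject")
  idx <- .kmer_index(db, scoring$k)
  db_len <- sum(nchar(db))
  out <- vector("list", length(queries))
  for (qi in seq_along(queries)) {
    cand <- .seed_candidates(queries[[qi]], idx, scoring$k, scoring$min_seeds)
    if (length(cand) == 0) next
    rows <- lapply(cand, function(si) {
      hit <- local_align(queries[[qi]], db[[si]], scoring, space_n = db_len)
      if (is.null(hit)) return(NULL)
      cbind(data.frame(query = names(queries)[qi],
                       subject = names(db)[si],
                       stringsAsFactors = FALSE), hit)
    })
    rows <- do.call(rbind, rows)
    if (is.null(rows) || nrow(rows) == 0) next
    rows <- rows[rows$evalue <= evalue_cutoff, , drop = FALSE]
    if (nrow(rows) == 0) next
    if (best_only) {
      rows <- rows[order(-rows$bits, rows$subject), , drop = FALSE][1, ,
                                                                    drop = FALSE]
    }
    out[[qi]] <- rows
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(query = character(0), subject = character(0),
                      score = numeric(0), bits = numeric(0),
                      evalue = numeric(0), q_start = integer(0),
                      q_end = integer(0), s_start = integer(0),
                      s_end = integer(0), stringsAsFactors = FALSE)
  }
  rownames(res) <- NULL
  res
}

.as_named_character <- function(x, what) {
  if (methods::is(x, "XStringSet")) {
    out <- as.character(x)
  } else {
    out <- as.character(x)
    names(out) <- names(x)
  }
  if (is.null(names(out)) || anyNA(names(out)) || any(names(out) == "")) {
    stop(what, " sequences must be named")
  }
  if (anyDuplicated(names(out))) stop(what, " ids must be unique")
  out
}
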